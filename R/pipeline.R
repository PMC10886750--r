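run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

write_manifest <- function(path, inputs, seed, stages, outputs) {
  hash_file <- function(p) {
    if (!is.character(p) || !file.exists(p)) return(NA_character_)
    as.character(tools::md5sum(p))
  }
  manifest <- list(
    package = "melsubtype",
    version = as.character(utils::packageVersion("melsubtype")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    stages = stages,
    inputs = lapply(inputs, function(p)
      list(path = if (is.character(p)) p else "<in-memory>",
           md5 = hash_file(p))),
    outputs = outputs
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              null = "null", digits = NA), path)
  invisible(path)
}

#' Run the discovery workflow end to end
#'
#' Preprocess (missing-value and CV filters) -> modified z-scores ->
#' consensus subtype discovery -> moderated differential expression ->
#' two-step classifier fit -> training-performance evaluation. All
#' artifacts (filtered matrix, labels, DE tables, model JSON, performance
#' summary, run manifest) are written under `outdir`; on any stage error
#' the partial outputs are removed and the error names the stage.
#'
#' @param expr Expression matrix or path to an expression TSV.
#' @param signature Gene category table or path to a signature TSV.
#' @param outdir Output directory (created if needed).
#' @param cv_threshold CV filter threshold in percent (default 5).
#' @param k_max,restarts Passed to [discover_subtypes()].
#' @param top_n,max_size Passed to [two_step_classifier()].
#' @param seed Integer seed for all randomized stages.
#' @return Invisibly, a list: `labels`, `model`, `de_top`, `performance`,
#'   `paths`.
#' @export
run_discovery_pipeline <- function(expr, signature, outdir,
                                   cv_threshold = 5, k_max = 10,
                                   restarts = 50, top_n = 10, max_size = 4,
                                   seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    filtered = file.path(outdir, "expression_filtered.tsv"),
    filter_report = file.path(outdir, "filter_report.tsv"),
    labels = file.path(outdir, "labels.tsv"),
    de = file.path(outdir, "de_top_genes.tsv"),
    model = file.path(outdir, "model.json"),
    performance = file.path(outdir, "performance.tsv"),
    manifest = file.path(outdir, "manifest.json")
  )
  on_error_cleanup <- function() {
    for (p in unlist(paths)) if (file.exists(p)) unlink(p)
  }
  withCallingHandlers({
    inputs <- list(expression = if (is.character(expr)) expr,
                   signature = if (is.character(signature)) signature)
    m <- run_stage("preprocess", {
      x <- if (is.character(expr)) read_expression(expr) else expr
      preprocess_expression(x, threshold_pct = cv_threshold)
    })
    sig <- run_stage("preprocess", read_signature(signature))
    utils::write.table(attr(m, "filter_report"), paths$filter_report,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_expression(m, paths$filtered)

    disc <- run_stage("discovery", {
      z <- zscore_matrix(log2p1(m))
      discover_subtypes(z, sig, k_max = k_max, seed = seed,
                        restarts = restarts)
    })
    write_labels(disc$labels, paths$labels)

    model <- run_stage("classifier", {
      two_step_classifier(m, disc$labels, top_n = top_n,
                          max_size = max_size)
    })
    top_tab <- do.call(rbind, lapply(names(model$top_genes), function(s) {
      cbind(contrast = s, model$top_genes[[s]])
    }))
    utils::write.table(top_tab, paths$de, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    write_classifier(model, paths$model)

    perf <- run_stage("evaluate", {
      pred <- predict(model, m, type = "expression")
      lab <- disc$labels$label[match(pred$sample_id,
                                     disc$labels$sample_id)]
      keep <- lab %in% SUBTYPES
      step1 <- evaluate_binary(pred$label[keep] != "desert",
                               lab[keep] != "desert")
      acc3 <- mean(pred$label[keep] == lab[keep])
      list(step1 = step1, accuracy_3class = acc3)
    })
    perf_tab <- data.frame(
      metric = c("step1_auc", "step1_sensitivity", "step1_specificity",
                 "step1_accuracy", "accuracy_3class"),
      value = c(model$step1$auc,
                perf$step1$sensitivity[["estimate"]],
                perf$step1$specificity[["estimate"]],
                perf$step1$accuracy[["estimate"]],
                perf$accuracy_3class))
    utils::write.table(perf_tab, paths$performance, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_manifest(paths$manifest, inputs, seed,
                   stages = c("preprocess", "discovery", "diffexpr",
                              "classifier", "evaluate"),
                   outputs = lapply(paths[names(paths) != "manifest"],
                                    basename))
    invisible(list(labels = disc$labels, model = model,
                   de_top = model$top_genes, performance = perf,
                   paths = paths))
  }, error = function(e) on_error_cleanup())
}

#' Run the validation workflow on a qPCR (or expression) cohort
#'
#' qPCR quantification (replicate aggregation, efficiency-corrected
#' relative expression, cohort modified z-scores) -> two-step
#' classification -> evaluation against truth labels (three-class
#' accuracy plus per-step binary reports) -> optional survival
#' comparison.
#'
#' @param model A `two_step_classifier` or path to a model JSON.
#' @param ct A `ct_table`, a path to a Ct TSV, or `NULL` when `expr` is
#'   given.
#' @param truth A `subtype_labeling` or path to a labels TSV.
#' @param expr Optional expression matrix/TSV scored with the model's
#'   frozen reference statistics instead of a Ct table.
#' @param reference_genes qPCR reference genes.
#' @param survival_data Optional data frame (`time_months`, `event`) or
#'   TSV path; groups are the predicted subtypes.
#' @param outdir Optional output directory for predictions, performance
#'   and manifest.
#' @return List of class `validation_report`: `predictions`,
#'   `accuracy_3class`, `step1`, `step2`, `confusion`, `survival`.
#' @export
run_validation_pipeline <- function(model, ct = NULL, truth,
                                    expr = NULL,
                                    reference_genes = c("RPL13A", "GAPDH"),
                                    survival_data = NULL, outdir = NULL) {
  if (is.character(model)) model <- read_classifier(model)
  validate_model(model)
  truth_df <- if (is.character(truth)) read_labels(truth) else truth
  pred <- if (!is.null(ct)) {
    run_stage("qpcr", {
      ct_tab <- if (is.character(ct)) read_ct_table(ct) else ct
      cons <- aggregate_replicates(ct_tab)
      rel <- relative_expression(cons, reference_genes = reference_genes)
      genes <- unique(c(model$step1$genes, model$step2$genes))
      missing <- setdiff(genes, rownames(rel))
      if (length(missing)) {
        stop("model gene(s) absent from Ct table: ",
             paste(missing, collapse = ", "))
      }
      z <- qpcr_to_z(rel[genes, , drop = FALSE])
      classify_samples(z, model)
    })
  } else if (!is.null(expr)) {
    run_stage("classify", {
      x <- if (is.character(expr)) read_expression(expr) else expr
      predict(model, x, type = "expression")
    })
  } else stop("supply a Ct table or an expression matrix")

  res <- run_stage("evaluate", {
    lab <- truth_df$label[match(pred$sample_id, truth_df$sample_id)]
    if (anyNA(lab)) stop("truth labels missing for some samples")
    keep <- lab %in% SUBTYPES
    acc3 <- mean(pred$label[keep] == lab[keep])
    confusion <- table(truth = lab[keep], predicted = pred$label[keep])
    step1 <- evaluate_binary(pred$label[keep] != "desert",
                             lab[keep] != "desert")
    nd <- keep & lab != "desert" & pred$label != "desert"
    step2 <- if (sum(nd) > 1 && length(unique(lab[nd])) == 2) {
      evaluate_binary(pred$label[nd] == "excluded", lab[nd] == "excluded")
    }
    list(acc3 = acc3, confusion = confusion, step1 = step1, step2 = step2)
  })
  surv <- NULL
  if (!is.null(survival_data)) {
    surv <- run_stage("survival", {
      sd <- if (is.character(survival_data)) {
        utils::read.delim(survival_data, stringsAsFactors = FALSE)
      } else survival_data
      sd$group <- pred$label[match(sd$sample_id, pred$sample_id)]
      compare_survival(sd)
    })
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(pred, file.path(outdir, "predictions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_manifest(file.path(outdir, "manifest.json"),
                   list(ct = if (is.character(ct)) ct,
                        truth = if (is.character(truth)) truth),
                   seed = NA,
                   stages = c("qpcr", "classify", "evaluate",
                              if (!is.null(surv)) "survival"),
                   outputs = list("predictions.tsv"))
  }
  out <- list(predictions = pred, accuracy_3class = res$acc3,
              confusion = res$confusion, step1 = res$step1,
              step2 = res$step2, survival = surv)
  class(out) <- "validation_report"
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Validation report\n")
  cat(sprintf("  3-class accuracy: %.3f (n = %d)\n", x$accuracy_3class,
              sum(x$confusion)))
  cat("  confusion (truth x predicted):\n")
  print(x$confusion)
  cat("\n  Step 1 (non-desert vs desert):\n")
  print(x$step1)
  if (!is.null(x$step2)) {
    cat("\n  Step 2 (excluded vs inflamed, non-desert pool):\n")
    print(x$step2)
  }
  if (!is.null(x$survival)) print(x$survival)
  invisible(x)
}
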