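#' Step-1 score: desert vs non-desert
#'
#' Average of the modified z-scores of CD53, TNFAIP6, CD2 and IRF1 (genes
#' elevated outside the immune desert): low values flag desert tumors.
#' For a generic model the step-1 score is the mean of the signed z-scores
#' of its step-1 genes.
#'
#' @param z Named numeric vector or genes-in-rows matrix of modified
#'   z-scores containing the step-1 genes.
#' @param model A `two_step_classifier` (default: the published model).
#' @return Numeric score (one per sample).
#' @export
score1 <- function(z, model = published_classifier()) {
  combo_score(z, model$step1$genes, model$step1$signs, combine = "mean")
}

#' Step-2 score: excluded vs inflamed
#'
#' Sum of the stromal z-scores minus the sum of the inflamed-immune
#' z-scores: `z_COL5A2 + z_INHBA - z_CD8B - z_IRF1` for the published
#' model. High values flag excluded tumors.
#'
#' @inheritParams score1
#' @return Numeric score (one per sample).
#' @export
score2 <- function(z, model = published_classifier()) {
  combo_score(z, model$step2$genes, model$step2$signs, combine = "sum")
}

# signed, averaged or summed z-score combination; z is a named vector
# (one sample) or a genes x samples matrix
combo_score <- function(z, genes, signs, combine = c("mean", "sum")) {
  combine <- match.arg(combine)
  if (is.matrix(z)) {
    missing <- setdiff(genes, rownames(z))
    if (length(missing)) {
      stop("missing gene(s): ", paste(missing, collapse = ", "))
    }
    zz <- z[genes, , drop = FALSE]
    if (anyNA(zz)) stop("non-finite z-scores for model genes")
    s <- as.numeric(signs %*% zz)
    if (combine == "mean") s <- s / length(genes)
    stats::setNames(s, colnames(z))
  } else {
    missing <- setdiff(genes, names(z))
    if (length(missing)) {
      stop("missing gene(s): ", paste(missing, collapse = ", "))
    }
    if (anyNA(z[genes]) || !all(is.finite(z[genes]))) {
      stop("non-finite z-scores for model genes")
    }
    s <- sum(signs * z[genes])
    if (combine == "mean") s / length(genes) else s
  }
}

#' The published seven-gene two-step classifier
#'
#' The frozen classifier: step 1 averages the z-scores of CD53, TNFAIP6,
#' CD2 and IRF1 with cutoff -0.44 (score below the cutoff calls desert);
#' step 2 is z_COL5A2 + z_INHBA - z_CD8B - z_IRF1 with cutoff 0.13 (score
#' at or above the cutoff calls excluded, otherwise inflamed). No
#' reference statistics are attached: inputs must already be modified
#' z-scores, or reference stats supplied separately.
#'
#' @return Object of class `two_step_classifier`.
#' @export
published_classifier <- function() {
  model <- list(
    step1 = list(genes = c("CD53", "TNFAIP6", "CD2", "IRF1"),
                 signs = c(1, 1, 1, 1), cutoff = -0.44, combine = "mean"),
    step2 = list(genes = c("COL5A2", "INHBA", "CD8B", "IRF1"),
                 signs = c(1, 1, -1, -1), cutoff = 0.13, combine = "sum"),
    reference_stats = NULL,
    transform = "zscore",
    training = NULL,
    call = quote(published_classifier())
  )
  class(model) <- "two_step_classifier"
  model
}

validate_model <- function(model) {
  stopifnot(inherits(model, "two_step_classifier"))
  for (st in list(model$step1, model$step2)) {
    if (!length(st$genes)) stop("empty gene set in model")
    if (length(st$signs) != length(st$genes)) stop("signs/genes mismatch")
    if (!is.finite(st$cutoff)) stop("non-finite cutoff")
  }
  if (!is.null(model$reference_stats) && any(model$reference_stats$mad < 0)) {
    stop("negative reference MAD")
  }
  invisible(model)
}

#' Classify samples with a two-step model
#'
#' Applies the decision sequence: a sample with step-1 score below the
#' step-1 cutoff is desert; otherwise a step-2 score at or above the
#' step-2 cutoff gives excluded, else inflamed. Every sample receives
#' exactly one of the three labels.
#'
#' @param z Modified z-score matrix (genes x samples) containing all model
#'   genes, or a named vector for a single sample.
#' @param model A `two_step_classifier`.
#' @return Data frame `sample_id`, `score1`, `score2`, `label`.
#' @export
classify_samples <- function(z, model = published_classifier()) {
  validate_model(model)
  if (!is.matrix(z)) z <- matrix(z, ncol = 1, dimnames = list(names(z), "sample"))
  s1 <- score1(z, model)
  s2 <- score2(z, model)
  label <- ifelse(s1 < model$step1$cutoff, "desert",
                  ifelse(s2 >= model$step2$cutoff, "excluded", "inflamed"))
  data.frame(sample_id = colnames(z), score1 = unname(s1),
             score2 = unname(s2), label = unname(label),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Exhaustive signed-combination search
#'
#' Enumerates every subset of the candidate genes up to `max_size`, scoring
#' each sample with the signed combination of its z-scores (sign = the
#' empirical direction of each gene between the two classes, unless given),
#' and ranks combinations by AUC for `truth`; ties are broken by fewer
#' genes, then lexicographic gene ids. Youden cutoffs are attached.
#'
#' @param z Z-score matrix restricted to the candidate genes.
#' @param truth Logical vector over samples (positive class).
#' @param max_size Largest combination size (default 4).
#' @param combine `"mean"` (step-1 style average) or `"sum"` (step-2
#'   style).
#' @param signs Optional named sign vector (+1/-1) per candidate gene;
#'   default: sign of the difference in mean z between positive and
#'   negative class.
#' @return Data frame ranked by AUC: `genes` (comma-joined signed ids),
#'   `size`, `auc`, `cutoff`, `j`.
#' @export
search_combinations <- function(z, truth, max_size = 4,
                                combine = c("mean", "sum"), signs = NULL) {
  combine <- match.arg(combine)
  truth <- as.logical(truth)
  genes <- sort(rownames(z))
  if (!length(genes)) stop("empty candidate pool")
  z <- z[genes, , drop = FALSE]
  if (is.null(signs)) {
    d <- rowMeans(z[, truth, drop = FALSE]) - rowMeans(z[, !truth, drop = FALSE])
    signs <- stats::setNames(ifelse(d >= 0, 1, -1), genes)
  } else {
    signs <- signs[genes]
  }
  zs <- z * signs                       # signed once, subsets just add rows
  sets <- list()
  for (k in seq_len(min(max_size, length(genes)))) {
    cmb <- utils::combn(length(genes), k, simplify = FALSE)
    sets <- c(sets, cmb)
  }
  n1 <- sum(truth); n0 <- sum(!truth)
  res <- lapply(sets, function(idx) {
    s <- colSums(zs[idx, , drop = FALSE])
    if (combine == "mean") s <- s / length(idx)
    r <- rank(s)
    auc <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    list(idx = idx, auc = auc, score = s)
  })
  auc <- vapply(res, `[[`, numeric(1), "auc")
  size <- vapply(res, function(r) length(r$idx), numeric(1))
  key <- vapply(res, function(r) paste(genes[r$idx], collapse = ","), character(1))
  o <- order(-auc, size, key)
  top <- res[o]
  cut <- t(vapply(top, function(r) {
    yc <- youden_cutoff(r$score, truth)
    c(yc$cutoff, yc$j)
  }, numeric(2)))
  lab <- vapply(top, function(r) {
    paste0(ifelse(signs[genes[r$idx]] > 0, "+", "-"), genes[r$idx],
           collapse = ",")
  }, character(1))
  data.frame(genes = lab, size = size[o], auc = auc[o], cutoff = cut[, 1],
             j = cut[, 2], row.names = NULL, stringsAsFactors = FALSE)
}

# parse "+A,-B" back into genes/signs
parse_combo <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  signs <- ifelse(substr(parts, 1, 1) == "-", -1, 1)
  genes <- sub("^[+-]", "", parts)
  list(genes = genes, signs = signs)
}

#' Fit a two-step immune subtype classifier
#'
#' The main fitting function. From a raw expression matrix and consensus
#' subtype labels it (i) models expression on the log2(x + 1) scale and
#' forms modified z-scores, (ii) ranks genes per subtype with moderated
#' one-vs-rest contrasts, (iii) searches signed combinations of the top
#' genes for the best desert vs non-desert average score (step 1, AUC with
#' non-desert positive) and the best excluded vs inflamed summed score
#' among true non-desert samples (step 2), fixing each cutoff at the
#' Youden optimum, and (iv) freezes the per-gene reference medians/MADs so
#' new samples can be scored on the training scale.
#'
#' @param x Raw expression matrix, genes in rows, no missing values.
#' @param labels A `subtype_labeling` covering the samples; only samples
#'   labeled with a real subtype are used.
#' @param top_n Genes per subtype entering the candidate pools
#'   (default 10).
#' @param max_size Largest combination size searched per step (default 4).
#' @param log2_transform Model/z-score on log2(x + 1) (default `TRUE`).
#' @return Object of class `two_step_classifier` with components `step1`,
#'   `step2` (genes, signs, cutoff, combine, training AUC and Youden J),
#'   `reference_stats`, `top_genes`, `search` and `call`.
#' @export
two_step_classifier <- function(x, labels, top_n = 10, max_size = 4,
                                log2_transform = TRUE) {
  cl <- match.call()
  keep <- labels$label %in% SUBTYPES
  labels <- labels[keep, , drop = FALSE]
  if (length(unique(labels$label)) < 3) {
    stop("all three subtypes must be present in the training labels")
  }
  x <- x[, labels$sample_id, drop = FALSE]
  de <- de_analysis(x, labels, log2_transform = log2_transform)
  tops <- select_top_genes(de, per_subtype = top_n)
  xm <- if (log2_transform) log2p1(x) else x
  z <- zscore_matrix(xm)
  lab <- labels$label[match(colnames(z), labels$sample_id)]

  # step 1: non-desert (positive) vs desert over all candidate genes
  pool1 <- sort(unique(unlist(lapply(tops, `[[`, "gene_id"))))
  s1 <- search_combinations(z[pool1, , drop = FALSE], lab != "desert",
                            max_size = max_size, combine = "mean")
  best1 <- parse_combo(s1$genes[1])

  # step 2: excluded (positive) vs inflamed among true non-desert samples
  pool2 <- sort(unique(c(tops$excluded$gene_id, tops$inflamed$gene_id)))
  nd <- lab != "desert"
  s2 <- search_combinations(z[pool2, nd, drop = FALSE],
                            lab[nd] == "excluded",
                            max_size = max_size, combine = "sum")
  best2 <- parse_combo(s2$genes[1])

  model <- list(
    step1 = list(genes = best1$genes, signs = best1$signs,
                 cutoff = s1$cutoff[1], combine = "mean",
                 auc = s1$auc[1], j = s1$j[1]),
    step2 = list(genes = best2$genes, signs = best2$signs,
                 cutoff = s2$cutoff[1], combine = "sum",
                 auc = s2$auc[1], j = s2$j[1]),
    reference_stats = attr(z, "reference_stats"),
    transform = if (log2_transform) "log2p1" else "identity",
    top_genes = tops,
    search = list(step1 = utils::head(s1, 20), step2 = utils::head(s2, 20)),
    training = list(n = ncol(z), n_by_subtype = table(lab)),
    call = cl
  )
  class(model) <- "two_step_classifier"
  validate_model(model)
}

#' Predict immune subtypes from a fitted two-step classifier
#'
#' @param object A `two_step_classifier`.
#' @param newdata Either a modified z-score matrix (genes x samples;
#'   `type = "zscore"`), or a raw expression matrix (`type =
#'   "expression"`) which is transformed as in training and scored against
#'   the frozen reference statistics.
#' @param type How to interpret `newdata`.
#' @param ... Unused.
#' @return Data frame `sample_id`, `score1`, `score2`, `label`.
#' @export
predict.two_step_classifier <- function(object, newdata,
                                        type = c("zscore", "expression"),
                                        ...) {
  type <- match.arg(type)
  if (type == "expression") {
    if (is.null(object$reference_stats)) {
      stop("model carries no reference statistics; supply z-scores")
    }
    xm <- if (identical(object$transform, "log2p1")) log2p1(newdata) else newdata
    genes <- unique(c(object$step1$genes, object$step2$genes))
    missing <- setdiff(genes, rownames(xm))
    if (length(missing)) {
      stop("missing gene(s): ", paste(missing, collapse = ", "))
    }
    newdata <- apply_reference_zscore(xm[genes, , drop = FALSE],
                                      object$reference_stats)
  }
  classify_samples(newdata, object)
}

#' @export
print.two_step_classifier <- function(x, ...) {
  fmt_step <- function(st) {
    paste0(paste0(ifelse(st$signs > 0, "+", "-"), st$genes, collapse = " "),
           sprintf("  [%s, cutoff %.3g%s]", st$combine, st$cutoff,
                   if (!is.null(st$auc)) sprintf(", AUC %.3f", st$auc) else ""))
  }
  cat("Two-step immune subtype classifier\n")
  cat("  step 1 (score < cutoff -> desert):   ", fmt_step(x$step1), "\n")
  cat("  step 2 (score >= cutoff -> excluded, else inflamed):\n")
  cat("                                       ", fmt_step(x$step2), "\n")
  if (!is.null(x$training)) {
    cat("  trained on", x$training$n, "samples (",
        paste(names(x$training$n_by_subtype),
              as.integer(x$training$n_by_subtype), collapse = ", "), ")\n")
  }
  invisible(x)
}

#' @export
summary.two_step_classifier <- function(object, ...) {
  print(object)
  if (!is.null(object$search)) {
    cat("\nTop step-1 candidates:\n")
    print(utils::head(object$search$step1, 5), row.names = FALSE)
    cat("\nTop step-2 candidates:\n")
    print(utils::head(object$search$step2, 5), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.two_step_classifier <- function(object, ...) {
  w1 <- object$step1$signs / length(object$step1$genes)
  list(step1 = stats::setNames(w1, object$step1$genes),
       step2 = stats::setNames(object$step2$signs, object$step2$genes),
       cutoffs = c(step1 = object$step1$cutoff, step2 = object$step2$cutoff))
}

#' Plot training ROC curves of a fitted classifier
#'
#' Draws the step-1 and step-2 ROC curves recomputed on a z-matrix with
#' known labels (by default requires the data to be supplied, since the
#' model does not store its training matrix).
#'
#' @param x A `two_step_classifier`.
#' @param z Z-score matrix with all model genes.
#' @param labels A `subtype_labeling` for the columns of `z`.
#' @param ... Passed to [plot()].
#' @export
plot.two_step_classifier <- function(x, z, labels, ...) {
  lab <- labels$label[match(colnames(z), labels$sample_id)]
  r1 <- roc_auc(score1(z, x), lab != "desert")
  nd <- lab != "desert"
  r2 <- roc_auc(score2(z[, nd, drop = FALSE], x), lab[nd] == "excluded")
  oldpar <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(oldpar))
  for (r in list(list(r1, "Step 1: non-desert vs desert"),
                 list(r2, "Step 2: excluded vs inflamed"))) {
    with(r[[1]]$roc, plot(1 - specificity, sensitivity, type = "l",
                          xlim = c(0, 1), ylim = c(0, 1),
                          main = sprintf("%s (AUC %.3f)", r[[2]], r[[1]]$auc),
                          ...))
    graphics::abline(0, 1, lty = 3)
  }
  invisible(x)
}

#' Write / read a two-step classifier as JSON
#'
#' The JSON stores the gene sets, signs, cutoffs and reference statistics
#' at full double precision; a write/read round trip reproduces the model
#' bit-exactly.
#'
#' @param model A `two_step_classifier`.
#' @param path JSON path.
#' @return `path` invisibly (write); the model (read).
#' @export
write_classifier <- function(model, path) {
  validate_model(model)
  obj <- list(
    version = "1.0",
    step1 = list(genes = model$step1$genes, signs = model$step1$signs,
                 cutoff = model$step1$cutoff, combine = model$step1$combine),
    step2 = list(genes = model$step2$genes, signs = model$step2$signs,
                 cutoff = model$step2$cutoff, combine = model$step2$combine),
    transform = model$transform,
    reference_stats = model$reference_stats
  )
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE,
                           null = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                            simplifyVector = TRUE)
  model <- list(
    step1 = list(genes = obj$step1$genes, signs = as.numeric(obj$step1$signs),
                 cutoff = obj$step1$cutoff, combine = obj$step1$combine),
    step2 = list(genes = obj$step2$genes, signs = as.numeric(obj$step2$signs),
                 cutoff = obj$step2$cutoff, combine = obj$step2$combine),
    transform = obj$transform,
    reference_stats = if (!is.null(obj$reference_stats))
      as.data.frame(obj$reference_stats, stringsAsFactors = FALSE),
    training = NULL,
    call = NULL
  )
  class(model) <- "two_step_classifier"
  validate_model(model)
}
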