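#' Configuration for the synthetic melanoma cohort generator
#'
#' Defaults emulate the structure of the training cohort the pipeline is
#' designed for: three latent subtypes with block-structured expression of
#' the angiogenesis/stroma/immune programs, consensus-cohort proportions
#' 95 desert / 75 excluded / 176 inflamed, log-normal expression noise,
#' subtype-ordered progression-free survival (medians 66 inflamed / 47
#' excluded / 35 desert months) with roughly 30% independent censoring,
#' and a triplicate qPCR read-out with stable reference genes.
#'
#' The subtype effect pattern, in log2 units of size `delta`: desert
#' shifts immune genes by -delta and stroma by -delta/2; excluded shifts
#' stroma by +delta and angiogenesis by +delta/2; inflamed shifts immune
#' by +delta while its stroma program is heterogeneous (zero mean shift,
#' doubled program-factor variance).
#'
#' @param n_desert,n_excluded,n_inflamed Samples per subtype.
#' @param n_angio,n_stroma,n_immune Signature genes per program
#'   (13/13/14, a 40-gene signature).
#' @param n_background Genes with no subtype effect (default 300).
#' @param delta Subtype shift in log2 units (default 2).
#' @param rho Within-program gene correlation parameter (default 0.5);
#'   see [generate_expression()] for how it is realized.
#' @param resid_sd Residual sd in log2 units (default 1).
#' @param baseline_range Range of per-gene baseline log2 means (default
#'   `c(3, 10)`).
#' @param surv_medians Named survival medians in months
#'   (desert/excluded/inflamed).
#' @param censor_target Expected censoring fraction (default 0.3).
#' @param ct_intercept,ct_slope,ct_noise_sd Ct model: `Ct = a - b * log2
#'   expression + N(0, sd)` (defaults 35, 1, 0.3).
#' @param n_replicates qPCR replicates (default 3).
#' @param ref_sd Biological sd of reference-gene log2 expression (default
#'   0.25; no subtype effect).
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_desert = 95, n_excluded = 75, n_inflamed = 176,
                             n_angio = 13, n_stroma = 13, n_immune = 14,
                             n_background = 300, delta = 2, rho = 0.5,
                             resid_sd = 1, baseline_range = c(3, 10),
                             surv_medians = c(desert = 35, excluded = 47,
                                              inflamed = 66),
                             censor_target = 0.3,
                             ct_intercept = 35, ct_slope = 1,
                             ct_noise_sd = 0.3, n_replicates = 3,
                             ref_sd = 0.25) {
  cfg <- list(n_per_subtype = c(desert = n_desert, excluded = n_excluded,
                                inflamed = n_inflamed),
              n_program = c(angiogenesis = n_angio, stroma = n_stroma,
                            immune = n_immune),
              n_background = n_background, delta = delta, rho = rho,
              resid_sd = resid_sd, baseline_range = baseline_range,
              surv_medians = surv_medians[SUBTYPES],
              censor_target = censor_target,
              ct_intercept = ct_intercept, ct_slope = ct_slope,
              ct_noise_sd = ct_noise_sd, n_replicates = n_replicates,
              ref_sd = ref_sd)
  if (any(cfg$n_per_subtype <= 0) || any(cfg$n_program <= 0)) {
    stop("subtype and program sizes must be positive")
  }
  if (cfg$delta < 0) stop("delta must be >= 0")
  if (cfg$rho < 0 || cfg$rho >= 1) stop("rho must be in [0, 1)")
  if (cfg$resid_sd <= 0) stop("resid_sd must be positive")
  if (any(!is.finite(cfg$surv_medians)) || any(cfg$surv_medians <= 0)) {
    stop("survival medians must be positive for all three subtypes")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

# per-subtype mean shift (log2) of each program
program_shift <- function(subtype, program, delta) {
  switch(subtype,
    desert = switch(program, immune = -delta, stroma = -delta / 2, 0),
    excluded = switch(program, stroma = delta, angiogenesis = delta / 2, 0),
    inflamed = switch(program, immune = delta, 0))
}

# Variance of the shared per-sample program-activity factor. Genes of one
# program co-vary because they share the subtype shifts; rho sets the
# shared variance rho/(1-rho)*resid^2 that would give within-program
# correlation rho in an unstructured cohort, and the factor supplies only
# what the subtype blocks do not already provide (at the default effect
# size the blocks exceed it, so no extra noise is injected; at delta = 0
# the cohort exhibits correlation rho exactly).
solve_factor_var <- function(cfg) {
  w <- cfg$n_per_subtype / sum(cfg$n_per_subtype)
  shift_var <- vapply(names(cfg$n_program), function(p) {
    s <- vapply(SUBTYPES, program_shift, numeric(1), program = p,
                delta = cfg$delta)
    sum(w * s^2) - sum(w * s)^2
  }, numeric(1))
  target <- cfg$rho / (1 - cfg$rho) * cfg$resid_sd^2
  max(0, target - mean(shift_var))
}

#' Generate a subtype-structured expression cohort
#'
#' Draws log2 expression as baseline + subtype program shift + residual
#' noise and returns the matrix on the raw (`2^x`) scale together with the
#' true labels and the signature table. Genes of one program co-vary
#' because they share the subtype shifts; `rho` sets the shared
#' program-activity variance (`rho/(1-rho) * resid_sd^2`) that a shared
#' per-sample factor supplies whenever the block structure alone falls
#' short of it (at the default effect size the blocks exceed it; at
#' `delta = 0` the cohort exhibits within-program correlation `rho`
#' exactly). Stroma genes of inflamed samples are drawn with doubled
#' residual variance to mimic stromal heterogeneity. Background genes
#' carry no subtype effect, enabling exact false-positive accounting in
#' marker-selection tests.
#'
#' @param cfg A `synthetic_config`.
#' @param seed Integer seed; all output is reproducible from it.
#' @return List: `expression` (genes x samples, raw scale), `labels`
#'   (`subtype_labeling`, provenance `"simulated"`), `signature` (gene
#'   category table covering the signature genes only), and
#'   `background_genes` (ids of the no-effect genes).
#' @export
generate_expression <- function(cfg = synthetic_config(), seed = 1) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed)
  programs <- rep(names(cfg$n_program), cfg$n_program)
  sig_genes <- sprintf("%s%02d", toupper(substr(programs, 1, 2)),
                       unlist(lapply(cfg$n_program, seq_len)))
  sig_genes <- paste0("SIG_", sig_genes)
  bg_genes <- sprintf("BG_%03d", seq_len(cfg$n_background))
  genes <- c(sig_genes, bg_genes)
  subtypes <- rep(SUBTYPES, cfg$n_per_subtype)
  n <- length(subtypes)
  samples <- sprintf("S%03d", seq_len(n))

  # baselines are gene-intrinsic: fixed given the config (own RNG stream),
  # so independently seeded cohorts share the same gene universe and a
  # model trained on one cohort transfers to another
  baseline <- local({
    set.seed(8191L)
    stats::runif(length(genes), cfg$baseline_range[1], cfg$baseline_range[2])
  })
  set.seed(seed)
  x <- matrix(0, length(genes), n, dimnames = list(genes, samples))
  fac_var <- solve_factor_var(cfg)
  fac <- sapply(names(cfg$n_program),
                function(p) stats::rnorm(n, 0, sqrt(fac_var)))
  for (gi in seq_along(genes)) {
    g_prog <- if (gi <= length(programs)) programs[gi] else NA
    if (!is.na(g_prog)) {
      shift <- vapply(subtypes, program_shift, numeric(1), program = g_prog,
                      delta = cfg$delta)
      # inflamed stroma is heterogeneous: doubled residual variance
      rsd <- cfg$resid_sd *
        ifelse(g_prog == "stroma" & subtypes == "inflamed", sqrt(2), 1)
      eff <- fac[, g_prog] + rsd * stats::rnorm(n)
    } else {
      shift <- 0
      eff <- cfg$resid_sd * stats::rnorm(n)
    }
    x[gi, ] <- baseline[gi] + shift + eff
  }
  labels <- data.frame(sample_id = samples, label = subtypes,
                       provenance = "simulated", stringsAsFactors = FALSE)
  class(labels) <- c("subtype_labeling", "data.frame")
  signature <- data.frame(gene_id = sig_genes, category = programs,
                          stringsAsFactors = FALSE)
  list(expression = 2^x, labels = labels, signature = signature,
       background_genes = bg_genes)
}

#' Simulate a qPCR read-out of an expression matrix
#'
#' Generates triplicate Ct values per (sample, gene) from the linear model
#' `Ct = a - b * log2(expression) + N(0, noise_sd)` and appends two stable
#' reference genes (RPL13A, GAPDH) whose log2 expression is drawn with sd
#' `ref_sd` around fixed baselines, independent of subtype. Efficiencies
#' default to 2 (100%).
#'
#' @param expr Raw-scale expression matrix (genes x samples).
#' @param genes Genes to assay (must be present in `expr`).
#' @param cfg A `synthetic_config`.
#' @param seed Integer seed.
#' @return A `ct_table` with attribute `reference_genes`.
#' @export
generate_qpcr <- function(expr, genes, cfg = synthetic_config(), seed = 1) {
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) {
    stop("genes absent from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  set.seed(seed + 1000L)
  samples <- colnames(expr)
  refs <- c(RPL13A = 8, GAPDH = 9.5)            # baseline log2 expression
  ref_expr <- t(sapply(names(refs), function(r) {
    refs[[r]] + stats::rnorm(length(samples), 0, cfg$ref_sd)
  }))
  colnames(ref_expr) <- samples
  log2_expr <- rbind(log2(expr[genes, , drop = FALSE]), ref_expr)
  all_genes <- rownames(log2_expr)
  grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                      gene_id = all_genes, sample_id = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- cfg$ct_intercept -
    cfg$ct_slope * log2_expr[cbind(grid$gene_id, grid$sample_id)]
  grid$ct <- mu + stats::rnorm(nrow(grid), 0, cfg$ct_noise_sd)
  grid$ct <- pmin(pmax(grid$ct, 1e-6), 40)
  grid$efficiency <- 2
  out <- as_ct_table(grid[, c("sample_id", "gene_id", "replicate", "ct",
                              "efficiency")])
  attr(out, "reference_genes") <- names(refs)
  out
}

#' Simulate subtype-dependent survival
#'
#' Exponential event times with the configured per-subtype medians and
#' independent uniform censoring on `(0, c_max)`, where `c_max` is solved
#' so the expected censoring fraction matches `censor_target` for the
#' label mix at hand.
#'
#' @param labels A `subtype_labeling` (samples with real subtype labels).
#' @param cfg A `synthetic_config`.
#' @param seed Integer seed.
#' @return Data frame: `sample_id`, `time_months`, `event`, `group`.
#' @export
generate_survival <- function(labels, cfg = synthetic_config(), seed = 1) {
  keep <- labels$label %in% SUBTYPES
  labels <- labels[keep, , drop = FALSE]
  if (!nrow(labels)) stop("no labeled samples")
  set.seed(seed + 2000L)
  rates <- log(2) / cfg$surv_medians[labels$label]
  # expected censoring with C ~ U(0, cmax): mean over samples of
  # (1 - exp(-rate * cmax)) / (rate * cmax)
  cens_frac <- function(cmax) mean((1 - exp(-rates * cmax)) / (rates * cmax))
  cmax <- stats::uniroot(function(cm) cens_frac(cm) - cfg$censor_target,
                         lower = 1e-3, upper = 1e5)$root
  t_event <- stats::rexp(nrow(labels), rate = rates)
  t_cens <- stats::runif(nrow(labels), 0, cmax)
  data.frame(sample_id = labels$sample_id,
             time_months = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             group = labels$label, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort
#'
#' Expression + truth labels + signature, a paired qPCR read-out of the
#' seven published classifier genes when they are present (otherwise of
#' `qpcr_genes`), and survival times.
#'
#' @param cfg A `synthetic_config`.
#' @param seed Integer seed.
#' @param qpcr_genes Genes to assay by qPCR; default: the 40 signature
#'   genes are RNA-seq-only and the qPCR panel is chosen at validation
#'   time, so this defaults to `NULL` (no Ct table).
#' @return List: `expression`, `labels`, `signature`, `background_genes`,
#'   `survival`, and `ct` (if requested).
#' @export
generate_cohort <- function(cfg = synthetic_config(), seed = 1,
                            qpcr_genes = NULL) {
  ex <- generate_expression(cfg, seed)
  surv <- generate_survival(ex$labels, cfg, seed)
  ct <- if (!is.null(qpcr_genes)) generate_qpcr(ex$expression, qpcr_genes,
                                                cfg, seed)
  c(ex, list(survival = surv, ct = ct))
}
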