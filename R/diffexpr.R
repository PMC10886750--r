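#' Gene-wise group-means model fit
#'
#' Fits, for every gene, the least-squares means model with one coefficient
#' per subtype and no intercept (design `~ 0 + subtype`). With this design
#' the coefficients are the per-group sample means and the residual degrees
#' of freedom are `n - 3`.
#'
#' @param expr Expression matrix on the modeling (log2) scale, genes in
#'   rows.
#' @param labels A `subtype_labeling`; only samples with a real subtype
#'   label are used, and every subtype needs at least 2 samples.
#' @return List of class `gene_fit`: `coefficients` (genes x 3 matrix of
#'   group means), `sigma2` (residual variances), `df_resid`, `n_group`,
#'   `xtx_inv_diag` (diagonal of \eqn{(X'X)^{-1}}, here `1/n_g`).
#' @export
fit_gene_models <- function(expr, labels) {
  keep <- labels$label %in% SUBTYPES
  labels <- labels[keep, , drop = FALSE]
  expr <- expr[, labels$sample_id, drop = FALSE]
  grp <- factor(labels$label, levels = SUBTYPES)
  n_group <- table(grp)
  if (any(n_group < 2)) {
    stop("each subtype needs >= 2 samples; got ",
         paste(n_group, collapse = "/"))
  }
  n <- ncol(expr)
  # means model: closed-form fit, vectorized over genes
  ind <- stats::model.matrix(~ 0 + grp)            # n x 3 indicator
  colnames(ind) <- levels(grp)
  means <- expr %*% ind %*% diag(1 / as.numeric(n_group))
  colnames(means) <- levels(grp)
  fitted <- means %*% t(ind)
  rss <- rowSums((expr - fitted)^2)
  df_resid <- n - nlevels(grp)
  out <- list(coefficients = means, sigma2 = rss / df_resid,
              df_resid = df_resid,
              n_group = stats::setNames(as.numeric(n_group), levels(grp)),
              xtx_inv_diag = 1 / as.numeric(n_group))
  class(out) <- "gene_fit"
  out
}

# Newton inversion of the trigamma function (for prior-df estimation)
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Empirical-Bayes moderation of residual variances
#'
#' Models the gene-wise residual variances as draws from a scaled-F
#' hierarchy \eqn{s^2 \sim s_0^2 F(d, d_0)} and estimates the prior degrees
#' of freedom `d0` and prior variance `s0^2` by matching the mean and
#' variance of `log(s^2)` (digamma/trigamma moment inversion). Posterior
#' variances shrink each gene toward the prior:
#' `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)`. When the spread of
#' `log(s^2)` is no larger than its sampling noise, `d0 = Inf` and all
#' posterior variances equal `s0^2`.
#'
#' @param s2 Non-negative residual variances (>= 10 genes).
#' @param df_resid Residual degrees of freedom shared by all genes.
#' @return List of class `variance_moderation`: `df_prior`, `var_prior`,
#'   `var_post`.
#' @export
moderate_variances <- function(s2, df_resid) {
  if (length(s2) < 10) stop("need >= 10 genes to estimate the prior")
  if (any(s2 < 0)) stop("negative variances")
  if (all(s2 == 0)) stop("degenerate variances: all residual variances are 0")
  # zero variances cannot enter the log-moment fit; exact fits are mapped to
  # the smallest positive variance for estimation only
  s2_work <- pmax(s2, min(s2[s2 > 0]) * 1e-8)
  z <- log(s2_work)
  e <- z - digamma(df_resid / 2) + log(df_resid / 2)
  ebar <- mean(e)
  evar <- stats::var(z) - trigamma(df_resid / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(ebar + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior <- exp(ebar)
  }
  var_post <- if (is.infinite(df_prior)) {
    rep(var_prior, length(s2))
  } else {
    (df_prior * var_prior + df_resid * s2) / (df_prior + df_resid)
  }
  out <- list(df_prior = df_prior, var_prior = var_prior, var_post = var_post)
  class(out) <- "variance_moderation"
  out
}

#' Moderated contrast test
#'
#' Tests a linear contrast of subtype means per gene with the moderated t
#' statistic `t = c'b / sqrt(s2_post * c'(X'X)^-1 c)` on
#' `df_prior + df_resid` degrees of freedom (standard normal when the prior
#' df is infinite). Contrast weights must sum to zero; one-vs-rest
#' contrasts such as `c(1, -0.5, -0.5)` compare a subtype to the average of
#' the other two.
#'
#' @param fit A `gene_fit` from [fit_gene_models()].
#' @param moderated A `variance_moderation` from [moderate_variances()], or
#'   `NULL` for the unmoderated ordinary t-test. A moderation object with
#'   `df_prior = 0` and `var_post = fit$sigma2` likewise reproduces the
#'   ordinary test.
#' @param contrast Numeric weights over the subtypes, in the order
#'   desert/excluded/inflamed (names honored if present), summing to 0.
#' @return Data frame: `gene_id`, `effect`, `t_mod`, `p`, `df_total`.
#' @export
contrast_test <- function(fit, moderated, contrast) {
  stopifnot(inherits(fit, "gene_fit"))
  if (!is.null(names(contrast))) {
    contrast <- contrast[colnames(fit$coefficients)]
  }
  if (length(contrast) != ncol(fit$coefficients)) {
    stop("contrast length must match number of subtypes")
  }
  if (abs(sum(contrast)) > 1e-8) stop("contrast weights must sum to 0")
  if (is.null(moderated)) {
    var_post <- fit$sigma2
    df_prior <- 0
  } else {
    var_post <- moderated$var_post
    df_prior <- moderated$df_prior
  }
  effect <- as.numeric(fit$coefficients %*% contrast)
  cvc <- sum(contrast^2 * fit$xtx_inv_diag)
  se <- sqrt(var_post * cvc)
  t_mod <- effect / se
  t_mod[se == 0] <- 0
  df_total <- df_prior + fit$df_resid
  p <- if (is.infinite(df_total)) {
    2 * stats::pnorm(-abs(t_mod))
  } else {
    2 * stats::pt(-abs(t_mod), df = df_total)
  }
  data.frame(gene_id = rownames(fit$coefficients), effect = effect,
              t_mod = t_mod, p = p, df_total = df_total,
              row.names = NULL, stringsAsFactors = FALSE)
}

#' One-vs-rest moderated tests for all three subtypes
#'
#' Runs [fit_gene_models()], [moderate_variances()] and [contrast_test()]
#' with the three one-vs-rest contrasts (subtype minus the average of the
#' other two). Expression is modeled on the `log2(x + 1)` scale by default.
#'
#' @param expr Raw-scale expression matrix, genes in rows.
#' @param labels A `subtype_labeling`.
#' @param log2_transform Model on `log2(x + 1)` (default `TRUE`).
#' @return List of class `de_result` with one data frame per subtype
#'   contrast plus the `fit` and `moderated` components.
#' @export
de_analysis <- function(expr, labels, log2_transform = TRUE) {
  x <- if (log2_transform) log2p1(expr) else expr
  fit <- fit_gene_models(x, labels)
  mod <- moderate_variances(fit$sigma2, fit$df_resid)
  contrasts <- list(
    desert = c(desert = 1, excluded = -0.5, inflamed = -0.5),
    excluded = c(desert = -0.5, excluded = 1, inflamed = -0.5),
    inflamed = c(desert = -0.5, excluded = -0.5, inflamed = 1)
  )
  tables <- lapply(contrasts, function(cc) contrast_test(fit, mod, cc))
  out <- list(tables = tables, fit = fit, moderated = mod)
  class(out) <- "de_result"
  out
}

#' Top subtype-representative genes
#'
#' For each subtype's one-vs-rest contrast, returns the `per_subtype` genes
#' with the smallest p-values; ties are broken by larger `|t_mod|`, then
#' lexicographic gene id, so rankings are deterministic. The sign of the
#' effect is kept (desert markers are typically down-regulated immune
#' genes).
#'
#' @param de A `de_result` from [de_analysis()].
#' @param per_subtype Number of genes per subtype (default 10).
#' @return Named list of data frames (`gene_id`, `effect`, `t_mod`, `p`,
#'   `rank`).
#' @export
select_top_genes <- function(de, per_subtype = 10) {
  stopifnot(per_subtype >= 1)
  lapply(de$tables, function(tab) {
    if (per_subtype > nrow(tab)) stop("per_subtype exceeds gene count")
    o <- order(tab$p, -abs(tab$t_mod), tab$gene_id)
    top <- tab[o[seq_len(per_subtype)], , drop = FALSE]
    top$rank <- seq_len(per_subtype)
    rownames(top) <- NULL
    top
  })
}
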