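#' Empirical ROC curve and AUC
#'
#' Computes the empirical ROC over all distinct score thresholds (rule:
#' predict positive when `score >= threshold`) and the area under it by the
#' trapezoid rule, which for an empirical ROC equals the Mann-Whitney
#' statistic `U / (n1 * n0)` with tied pairs counted 1/2.
#'
#' @param scores Numeric scores, higher meaning more positive-like.
#' @param truth Logical or 0/1 vector; both classes must occur.
#' @return List of class `roc_curve`: `roc` (data frame `threshold`,
#'   `sensitivity`, `specificity`) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  # Mann-Whitney via midranks: ties counted 1/2
  r <- rank(scores)
  auc <- (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  cc <- class_counts(scores, truth)
  thr <- c(cc$u, Inf)
  sens <- c(cc$pos_ge, 0) / n1
  spec <- 1 - c(cc$neg_ge, 0) / n0
  out <- list(roc = data.frame(threshold = thr, sensitivity = sens,
                               specificity = spec), auc = auc)
  class(out) <- "roc_curve"
  out
}

# for each unique score u[i] (ascending): counts of positives / negatives
# with score >= u[i], via reverse cumulated per-value counts
class_counts <- function(scores, truth) {
  u <- sort(unique(scores))
  idx <- match(scores, u)
  pos <- tabulate(idx[truth], nbins = length(u))
  neg <- tabulate(idx[!truth], nbins = length(u))
  list(u = u,
       pos_ge = rev(cumsum(rev(pos))),
       neg_ge = rev(cumsum(rev(neg))))
}

#' Youden-optimal cutoff
#'
#' Scans the midpoints between consecutive distinct sorted scores (plus
#' -Inf and +Inf) and returns the cutoff maximizing Youden's
#' `J = sensitivity + specificity - 1` under the rule
#' `score >= cutoff -> positive`. Ties go to the smallest such cutoff.
#'
#' @inheritParams roc_auc
#' @return List with `cutoff` and `j`.
#' @export
youden_cutoff <- function(scores, truth) {
  truth <- as.logical(truth)
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  if (!any(truth) || all(truth)) stop("both classes must be present")
  cc <- class_counts(scores, truth)
  u <- cc$u
  # cutoff between u[i-1] and u[i] predicts positive exactly for score >= u[i]
  cand <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  j <- c(cc$pos_ge / sum(truth) - cc$neg_ge / sum(!truth), 0)
  best <- which.max(j)                        # which.max takes the first = smallest cutoff
  list(cutoff = cand[best], j = j[best])
}

#' Wilson score confidence interval for a proportion
#'
#' @param x Successes.
#' @param n Trials.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  mid <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  c(lower = (mid - half) / den, upper = (mid + half) / den)
}

cui_grade <- function(cui) {
  if (!is.finite(cui)) return(NA_character_)
  if (cui >= 0.81) "excellent" else if (cui >= 0.64) "good" else
    if (cui >= 0.49) "fair" else if (cui >= 0.36) "poor" else "very poor"
}

accuracy_grade <- function(acc) {
  if (!is.finite(acc)) return(NA_character_)
  if (acc >= 0.85) "excellent" else if (acc >= 0.70) "good" else
    if (acc >= 0.55) "fair" else "poor"
}

#' Binary classification performance report
#'
#' Confusion counts plus sensitivity, specificity, accuracy, PPV and NPV
#' with 95% Wilson score intervals, Youden's J, and the clinical utility
#' indices `cui_pos = sensitivity * PPV` and `cui_neg = specificity * NPV`
#' with their conventional qualitative grades (>= 0.81 excellent, >= 0.64
#' good, >= 0.49 fair, >= 0.36 poor, else very poor; accuracy >= 0.85
#' excellent, >= 0.70 good, >= 0.55 fair, else poor). Metrics with an empty
#' margin are reported as `NA` (undefined), never as 0.
#'
#' @param pred Predicted classes (logical, 0/1, or labels).
#' @param truth True classes, same coding; both classes must occur.
#' @param positive_class Value of `pred`/`truth` counted as positive
#'   (default `TRUE`).
#' @return Object of class `performance_report`.
#' @export
evaluate_binary <- function(pred, truth, positive_class = TRUE) {
  stopifnot(length(pred) == length(truth))
  p <- pred == positive_class
  t <- truth == positive_class
  if (!any(t) || all(t)) stop("both classes must be present in truth")
  tp <- sum(p & t); fn <- sum(!p & t); fp <- sum(p & !t); tn <- sum(!p & !t)
  n <- length(p)
  prop <- function(x, m) if (m > 0) x / m else NA_real_
  ci <- function(x, m) if (m > 0) wilson_ci(x, m) else c(lower = NA_real_, upper = NA_real_)
  sens <- prop(tp, tp + fn); spec <- prop(tn, tn + fp)
  ppv <- prop(tp, tp + fp); npv <- prop(tn, tn + fn)
  acc <- (tp + tn) / n
  out <- list(
    counts = c(tp = tp, fn = fn, fp = fp, tn = tn, n = n),
    sensitivity = c(estimate = sens, ci(tp, tp + fn)),
    specificity = c(estimate = spec, ci(tn, tn + fp)),
    accuracy = c(estimate = acc, ci(tp + tn, n)),
    ppv = c(estimate = ppv, ci(tp, tp + fp)),
    npv = c(estimate = npv, ci(tn, tn + fn)),
    youden_j = sens + spec - 1,
    cui_pos = sens * ppv,
    cui_neg = spec * npv,
    grades = c(accuracy = accuracy_grade(acc),
               cui_pos = cui_grade(sens * ppv),
               cui_neg = cui_grade(spec * npv))
  )
  class(out) <- "performance_report"
  out
}

#' Build a performance report from stated rates and class sizes
#'
#' Reconstructs the confusion table implied by a sensitivity, a specificity
#' and the two class sizes (counts are rounded to the nearest integer) and
#' evaluates it; useful for checking published operating characteristics
#' whose underlying predictions are not available.
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @param n_pos,n_neg Class sizes.
#' @return A `performance_report`.
#' @export
report_from_rates <- function(sensitivity, specificity, n_pos, n_neg) {
  tp <- round(sensitivity * n_pos)
  tn <- round(specificity * n_neg)
  pred <- c(rep(TRUE, tp), rep(FALSE, n_pos - tp),
            rep(TRUE, n_neg - tn), rep(FALSE, tn))
  truth <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
  evaluate_binary(pred, truth)
}

#' @export
print.performance_report <- function(x, ...) {
  cat("Binary performance report (n =", x$counts[["n"]], ")\n")
  cat(sprintf("  confusion: TP %d  FN %d  FP %d  TN %d\n",
              x$counts[["tp"]], x$counts[["fn"]],
              x$counts[["fp"]], x$counts[["tn"]]))
  fmt <- function(nm, v) {
    sprintf("  %-12s %5.1f%% (CI %.1f-%.1f%%)", nm, 100 * v[["estimate"]],
            100 * v[["lower"]], 100 * v[["upper"]])
  }
  cat(fmt("sensitivity", x$sensitivity), "\n")
  cat(fmt("specificity", x$specificity), "\n")
  cat(fmt("accuracy", x$accuracy), sprintf("[%s]", x$grades[["accuracy"]]), "\n")
  cat(fmt("PPV", x$ppv), "\n")
  cat(fmt("NPV", x$npv), "\n")
  cat(sprintf("  Youden J     %.3f\n", x$youden_j))
  cat(sprintf("  CUI+ (se*ppv) %.3f [%s]   CUI- (sp*npv) %.3f [%s]\n",
              x$cui_pos, x$grades[["cui_pos"]],
              x$cui_neg, x$grades[["cui_neg"]]))
  invisible(x)
}
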