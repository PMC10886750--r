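#' Kaplan-Meier curve for one group
#'
#' Product-limit estimate of the survival function with its risk table,
#' plus the median survival time (smallest time at which the curve reaches
#' 0.5 or below; `NA` when the median is not reached, as is common in
#' short-follow-up cohorts).
#'
#' @param time Positive follow-up times (months).
#' @param event Event indicator (1 = death/progression, 0 = censored).
#' @return List of class `km_curve`: `curve` (data frame `time`,
#'   `at_risk`, `surv`), `median`, `n`, `events`.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) >= 1, all(time > 0), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  curve <- data.frame(time = fit$time, at_risk = fit$n.risk, surv = fit$surv)
  reached <- curve$surv <= 0.5 + 1e-12
  med <- if (any(reached)) min(curve$time[reached]) else NA_real_
  out <- list(curve = curve, median = med, n = length(time),
              events = sum(event))
  class(out) <- "km_curve"
  out
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s\n",
              x$n, x$events,
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Log-rank test across subtype groups
#'
#' Standard log-rank test (hypergeometric variance at each distinct event
#' time) on 2 or more groups; the statistic is chi-square with
#' `groups - 1` degrees of freedom.
#'
#' @param time,event As in [km_curve()].
#' @param group Group labels (>= 2 distinct values).
#' @return List: `chisq`, `df`, `p`, `n_groups`.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2) stop("log-rank test needs >= 2 groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n_groups = nlevels(group))
}

#' Subtype survival comparison
#'
#' Per-group Kaplan-Meier curves and medians plus the overall log-rank
#' test; with three groups the pairwise tests are reported both unadjusted
#' and Holm-adjusted.
#'
#' @param data Data frame with columns `time_months`, `event`, `group`.
#' @return List of class `survival_report`: `curves` (named list of
#'   `km_curve`), `logrank`, `pairwise` (or `NULL` for 2 groups).
#' @export
compare_survival <- function(data) {
  stopifnot(all(c("time_months", "event", "group") %in% names(data)))
  groups <- sort(unique(as.character(data$group)))
  curves <- lapply(groups, function(g) {
    d <- data[data$group == g, , drop = FALSE]
    km_curve(d$time_months, d$event)
  })
  names(curves) <- groups
  lr <- logrank_test(data$time_months, data$event, data$group)
  pairwise <- NULL
  if (length(groups) > 2) {
    prs <- utils::combn(groups, 2, simplify = FALSE)
    p <- vapply(prs, function(pr) {
      d <- data[data$group %in% pr, , drop = FALSE]
      logrank_test(d$time_months, d$event, d$group)$p
    }, numeric(1))
    pairwise <- data.frame(
      group1 = vapply(prs, `[`, character(1), 1),
      group2 = vapply(prs, `[`, character(1), 2),
      p = p, p_holm = stats::p.adjust(p, "holm"),
      stringsAsFactors = FALSE)
  }
  out <- list(curves = curves, logrank = lr, pairwise = pairwise)
  class(out) <- "survival_report"
  out
}

#' @export
print.survival_report <- function(x, ...) {
  cat("Survival comparison\n")
  for (g in names(x$curves)) {
    k <- x$curves[[g]]
    cat(sprintf("  %-10s n = %3d, events = %3d, median = %s months\n", g,
                k$n, k$events,
                if (is.na(k$median)) "not reached" else format(round(k$median, 1))))
  }
  cat(sprintf("  log-rank chi-square = %.2f on %d df, p = %.3g\n",
              x$logrank$chisq, x$logrank$df, x$logrank$p))
  if (!is.null(x$pairwise)) {
    cat("  pairwise (Holm-adjusted):\n")
    for (i in seq_len(nrow(x$pairwise))) {
      cat(sprintf("    %s vs %s: p = %.3g (adj %.3g)\n",
                  x$pairwise$group1[i], x$pairwise$group2[i],
                  x$pairwise$p[i], x$pairwise$p_holm[i]))
    }
  }
  invisible(x)
}
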