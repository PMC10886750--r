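#' Modified z-score of a numeric vector
#'
#' Robust standardization `0.6745 * (x - median(x)) / MAD(x)` with the raw
#' (unscaled) median absolute deviation. When the MAD is zero the mean
#' absolute deviation takes over with constant 0.7979
#' (`0.7979 * (x - median) / meanAD`); if that is also zero the vector is
#' constant and all zeros are returned. The constants make the score
#' comparable to an ordinary z-score under normality.
#'
#' @param x Finite numeric vector, length >= 2.
#' @return Numeric vector of modified z-scores.
#' @export
modified_zscore <- function(x) {
  if (length(x) < 2) stop("need at least 2 values")
  if (!all(is.finite(x))) stop("non-finite values in input")
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 > 0) return(0.6745 * (x - med) / mad0)
  meanad <- mean(abs(x - med))
  if (meanad > 0) return(0.7979 * (x - med) / meanad)
  rep(0, length(x))
}

#' Robust per-gene location and scale
#'
#' Median, raw MAD and mean absolute deviation for each gene row; these are
#' the reference statistics frozen into a trained classifier so that new
#' samples can be scored against the training cohort.
#'
#' @param m Numeric matrix, genes in rows, no missing values.
#' @return Data frame with columns `gene_id`, `center` (median), `mad`,
#'   `meanad`.
#' @export
gene_reference_stats <- function(m) {
  stopifnot(is.matrix(m), !anyNA(m))
  med <- apply(m, 1L, stats::median)
  mad0 <- apply(abs(m - med), 1L, stats::median)
  meanad <- rowMeans(abs(m - med))
  data.frame(gene_id = rownames(m), center = unname(med), mad = unname(mad0),
             meanad = unname(meanad), stringsAsFactors = FALSE)
}

#' Modified z-score matrix
#'
#' Applies [modified_zscore()] to each gene row independently and stores the
#' per-gene reference statistics alongside the matrix (attribute
#' `"reference_stats"`) for later single-sample scoring.
#'
#' @param m Numeric matrix, genes in rows, no missing values, all finite.
#' @return Numeric matrix of modified z-scores with attribute
#'   `reference_stats` (see [gene_reference_stats()]).
#' @export
zscore_matrix <- function(m) {
  stopifnot(is.matrix(m))
  if (ncol(m) < 2) stop("need at least 2 samples")
  z <- t(apply(m, 1L, modified_zscore))
  dimnames(z) <- dimnames(m)
  attr(z, "reference_stats") <- gene_reference_stats(m)
  z
}

#' Score samples against frozen reference statistics
#'
#' Computes modified z-scores of `m` using per-gene medians and MADs from a
#' reference (training) cohort rather than from `m` itself, so that a single
#' new sample can be placed on the training scale.
#'
#' @param m Numeric matrix, genes in rows (a subset of the reference genes).
#' @param stats Data frame as returned by [gene_reference_stats()].
#' @return Matrix of z-scores with the same dimensions as `m`.
#' @export
apply_reference_zscore <- function(m, stats) {
  stopifnot(is.matrix(m), is.data.frame(stats))
  idx <- match(rownames(m), stats$gene_id)
  if (anyNA(idx)) {
    stop("genes absent from reference stats: ",
         paste(rownames(m)[is.na(idx)], collapse = ", "))
  }
  center <- stats$center[idx]
  madv <- stats$mad[idx]
  meanadv <- stats$meanad[idx]
  scale <- ifelse(madv > 0, madv / 0.6745,
                  ifelse(meanadv > 0, meanadv / 0.7979, Inf))
  z <- (m - center) / scale
  z[!is.finite(z)] <- 0
  dimnames(z) <- dimnames(m)
  z
}

# log2(x + 1): the scale on which expression is modeled and z-scored
log2p1 <- function(m) log2(m + 1)
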