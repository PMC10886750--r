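#' Read a long-format qPCR Ct table
#'
#' Columns: `sample_id`, `gene_id`, `replicate`, `ct`, and optionally
#' `efficiency` (fold amplification per cycle, defaulting to 2 = 100%).
#' The token `"Undetermined"` (case-insensitive) or an empty cell marks a
#' failed replicate and is kept as `NA`, never imputed.
#'
#' @param path TSV path.
#' @param default_efficiency Efficiency for genes lacking a column/value.
#' @return Data frame of class `ct_table`.
#' @export
read_ct_table <- function(path, default_efficiency = 2) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "gene_id", "replicate", "ct")
  if (!all(need %in% names(df))) {
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  }
  if (is.character(df$ct)) {
    df$ct[tolower(trimws(df$ct)) %in% c("undetermined", "")] <- NA
    df$ct <- as.numeric(df$ct)
  }
  if (is.null(df$efficiency)) df$efficiency <- default_efficiency
  df$efficiency[is.na(df$efficiency)] <- default_efficiency
  as_ct_table(df)
}

#' Construct / validate a Ct table
#'
#' @param df Data frame with columns `sample_id`, `gene_id`, `replicate`,
#'   `ct` (`NA` = undetermined), `efficiency`.
#' @return The validated data frame with class `ct_table`.
#' @export
as_ct_table <- function(df) {
  ok <- is.na(df$ct) | (df$ct > 0 & df$ct <= 40)
  if (!all(ok)) stop("Ct values must lie in (0, 40] or be undetermined")
  if (any(df$efficiency <= 1 | df$efficiency > 2.2)) {
    stop("amplification efficiencies must lie in (1, 2.2]")
  }
  class(df) <- unique(c("ct_table", class(df)))
  df
}

#' Collapse technical replicates to a consensus Ct
#'
#' The consensus Ct of each (sample, gene) is the median of its determined
#' replicates — robust to a single failed well. The replicate spread
#' (max - min) is reported and spreads above `flag_spread` cycles flagged.
#' A pair whose replicates are all undetermined is kept with `NA` Ct and
#' flagged `missing`.
#'
#' @param ct A `ct_table`.
#' @param flag_spread Spread threshold in cycles (default 0.5); reporting
#'   only, no value is altered.
#' @return Data frame: `sample_id`, `gene_id`, `ct`, `efficiency`,
#'   `n_reps`, `spread`, `flag` (`""`, `"spread"` or `"missing"`).
#' @export
aggregate_replicates <- function(ct, flag_spread = 0.5) {
  stopifnot(inherits(ct, "ct_table") || is.data.frame(ct))
  key <- interaction(ct$sample_id, ct$gene_id, drop = TRUE)
  rows <- split(seq_len(nrow(ct)), key)
  out <- do.call(rbind, lapply(rows, function(i) {
    v <- ct$ct[i]
    det <- v[!is.na(v)]
    data.frame(
      sample_id = ct$sample_id[i[1]], gene_id = ct$gene_id[i[1]],
      ct = if (length(det)) stats::median(det) else NA_real_,
      efficiency = ct$efficiency[i[1]],
      n_reps = length(det),
      spread = if (length(det) > 1) max(det) - min(det) else 0,
      stringsAsFactors = FALSE)
  }))
  out$flag <- ifelse(out$n_reps == 0, "missing",
                     ifelse(out$spread > flag_spread, "spread", ""))
  rownames(out) <- NULL
  out
}

#' Efficiency-corrected relative expression
#'
#' Converts consensus Ct values into relative gene expression with
#' efficiency correction: each gene's quantity is `E_g^(-Ct_g)` and is
#' divided by the geometric mean of the reference-gene quantities of the
#' same sample. With all efficiencies equal to 2 this reduces to
#' `2^(mean(Ct_ref) - Ct_g)`.
#'
#' @param consensus Output of [aggregate_replicates()].
#' @param reference_genes Character vector of reference gene ids (default
#'   `c("RPL13A", "GAPDH")`); every sample must have a determined Ct for
#'   each.
#' @return Numeric matrix of relative expression, genes in rows, samples
#'   in columns (reference genes excluded). Missing target Cts propagate
#'   as `NA`.
#' @export
relative_expression <- function(consensus,
                                reference_genes = c("RPL13A", "GAPDH")) {
  samples <- unique(consensus$sample_id)
  genes <- setdiff(unique(consensus$gene_id), reference_genes)
  logq <- function(rows) -rows$ct * log2(rows$efficiency)  # log2 quantity
  out <- matrix(NA_real_, length(genes), length(samples),
                dimnames = list(genes, samples))
  for (s in samples) {
    cs <- consensus[consensus$sample_id == s, , drop = FALSE]
    ref <- cs[cs$gene_id %in% reference_genes, , drop = FALSE]
    if (!setequal(intersect(ref$gene_id, reference_genes), reference_genes) ||
        anyNA(ref$ct)) {
      stop("sample ", s, " lacks a determined Ct for a reference gene")
    }
    ref_log <- mean(logq(ref))                  # geometric mean of quantities
    tg <- cs[cs$gene_id %in% genes, , drop = FALSE]
    out[tg$gene_id, s] <- 2^(logq(tg) - ref_log)
  }
  out
}

#' Modified z-scores of qPCR relative expression
#'
#' Z-scores each gene's log2 relative expression across the cohort —
#' relative quantities are multiplicative, so the log scale matches the
#' RNA-seq z-scoring — yielding a matrix directly consumable by
#' [classify_samples()].
#'
#' @param rel Relative expression matrix from [relative_expression()].
#' @return Modified z-score matrix with `reference_stats` attribute.
#' @export
qpcr_to_z <- function(rel) {
  if (anyNA(rel)) stop("missing relative expression; cannot z-score")
  zscore_matrix(log2(rel))
}
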