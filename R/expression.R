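#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects the first column to hold gene identifiers and the header row to
#' hold sample identifiers; cells are numeric, with empty cells or the token
#' `"NA"` treated as missing. Duplicate gene or sample identifiers are an
#' error, as all downstream stages index by name.
#'
#' @param path Path to a tab-separated text file.
#' @param genes_in_rows If `FALSE`, the file is transposed on read (samples
#'   in rows).
#' @return A numeric matrix with genes in rows and samples in columns.
#' @seealso [write_expression()], [drop_incomplete_genes()], [cv_filter()]
#' @export
read_expression <- function(path, genes_in_rows = TRUE) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          na.strings = c("NA", ""), stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("expression table needs an id column plus data columns")
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!genes_in_rows) m <- t(m)
  if (anyDuplicated(rownames(m))) stop("duplicate gene identifiers in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample identifiers in ", path)
  m
}

#' Write an expression matrix to TSV
#'
#' Values are written with full double precision so a write/read round trip
#' preserves them to at least 12 significant digits.
#'
#' @param m Numeric matrix, genes in rows.
#' @param path Output path.
#' @param id_column Name of the identifier column in the header.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, id_column = "gene_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(rownames(m), format(m, digits = 17, trim = TRUE,
                                       scientific = NA),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_column, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Drop genes with missing values
#'
#' Removes every gene row containing at least one missing entry; the sample
#' axis is untouched. The identifiers of removed genes are attached as the
#' `"dropped"` attribute so the filtering can be audited.
#'
#' @param m Numeric matrix, genes in rows.
#' @return The filtered matrix, with attribute `dropped` (character vector).
#' @export
drop_incomplete_genes <- function(m) {
  stopifnot(is.matrix(m))
  keep <- stats::complete.cases(m)
  if (!any(keep)) stop("empty matrix: every gene has missing values")
  out <- m[keep, , drop = FALSE]
  attr(out, "dropped") <- rownames(m)[!keep]
  out
}

#' Per-gene coefficient of variation
#'
#' CV in percent, `100 * sd/mean`, with the sample (n-1) standard deviation,
#' computed on the values as given (no log transform). Genes with mean 0 get
#' `NA`.
#'
#' @param m Numeric matrix without missing values, genes in rows.
#' @return Named numeric vector of CVs (percent).
#' @export
gene_cv <- function(m) {
  stopifnot(is.matrix(m), !anyNA(m))
  if (ncol(m) < 2) stop("CV undefined with fewer than 2 samples")
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  cv <- 100 * sdv / mu
  cv[mu == 0] <- NA_real_
  names(cv) <- rownames(m)
  cv
}

#' Filter genes by dispersion
#'
#' Retains genes whose coefficient of variation is at least `threshold_pct`
#' percent; low-dispersion genes carry little subtype signal and inflate the
#' downstream gene lists. Genes with mean 0 are removed. A per-gene report
#' of the removed genes with their CVs is attached as attribute
#' `"filter_report"`.
#'
#' @param m Numeric matrix without missing values, genes in rows.
#' @param threshold_pct Minimum CV in percent (default 5).
#' @return Filtered matrix with attribute `filter_report`, a data frame with
#'   columns `gene_id`, `reason`, `cv_pct`.
#' @export
cv_filter <- function(m, threshold_pct = 5) {
  stopifnot(threshold_pct >= 0)
  cv <- gene_cv(m)
  keep <- !is.na(cv) & cv >= threshold_pct
  if (!any(keep)) stop("empty matrix: no gene passes the CV filter")
  out <- m[keep, , drop = FALSE]
  rem <- !keep
  attr(out, "filter_report") <- data.frame(
    gene_id = rownames(m)[rem],
    reason = rep("low_cv", sum(rem)),
    cv_pct = unname(cv[rem]),
    stringsAsFactors = FALSE
  )
  out
}

#' Missing-value and dispersion preprocessing in one call
#'
#' Applies [drop_incomplete_genes()] then [cv_filter()], merging the two
#' removal reports into one `filter_report` attribute
#' (`reason` is `"missing"` or `"low_cv"`).
#'
#' @inheritParams cv_filter
#' @return Filtered matrix with combined `filter_report` attribute.
#' @export
preprocess_expression <- function(m, threshold_pct = 5) {
  m1 <- drop_incomplete_genes(m)
  dropped <- attr(m1, "dropped")
  m2 <- cv_filter(m1, threshold_pct)
  rep_cv <- attr(m2, "filter_report")
  rep_all <- rbind(
    if (length(dropped))
      data.frame(gene_id = dropped, reason = "missing", cv_pct = NA_real_,
                 stringsAsFactors = FALSE),
    rep_cv
  )
  attr(m2, "dropped") <- NULL
  attr(m2, "filter_report") <- rep_all
  m2
}
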