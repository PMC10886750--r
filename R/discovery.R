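SUBTYPES <- c("desert", "excluded", "inflamed")

# category -> subtype mapping: the program that dominates each state
CATEGORY_SUBTYPE <- c(angiogenesis = "desert", stroma = "excluded",
                      immune = "inflamed")

#' Read / validate a gene category signature
#'
#' The signature maps each gene to one of the three microenvironment
#' programs: `angiogenesis`, `stroma`, `immune`. Each gene belongs to
#' exactly one category and every category must be represented.
#'
#' @param x Either a path to a two-column TSV (`gene_id`, `category`) or a
#'   data frame with those columns.
#' @return Data frame with columns `gene_id`, `category`.
#' @export
read_signature <- function(x) {
  df <- if (is.character(x)) {
    if (!file.exists(x)) stop("signature file not found: ", x)
    utils::read.delim(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  } else as.data.frame(x, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "category") %in% names(df))) {
    stop("signature needs columns gene_id, category")
  }
  df <- df[, c("gene_id", "category")]
  bad <- setdiff(unique(df$category), names(CATEGORY_SUBTYPE))
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$gene_id)) stop("duplicate genes in signature")
  missing_cat <- setdiff(names(CATEGORY_SUBTYPE), unique(df$category))
  if (length(missing_cat)) {
    stop("signature lacks categories: ", paste(missing_cat, collapse = ", "))
  }
  df
}

# k-means++ seeding (Arthur & Vassilvitskii): spread initial centers by
# sampling proportional to squared distance from the chosen set
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers[1L], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      centers[j] <- sample.int(n, 1L)
    } else {
      centers[j] <- sample.int(n, 1L, prob = d2)
    }
    dj <- rowSums((x - matrix(x[centers[j], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  x[centers, , drop = FALSE]
}

# best-of-restarts k-means with k-means++ seeding; x = samples in rows
kmeans_pp <- function(x, k, restarts = 50, iter.max = 100) {
  if (nrow(x) < k) stop("fewer samples than clusters")
  if (nrow(x) == k) {             # one point per cluster; stats::kmeans refuses k = n
    return(list(cluster = stats::setNames(seq_len(k), rownames(x)),
                centers = x, tot.withinss = 0,
                withinss = rep(0, k), size = rep(1L, k)))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    cen <- kmeanspp_centers(x, k)
    # duplicate seeded centers can arise with tied points; jitter to distinct rows
    if (anyDuplicated(cen)) cen <- cen + stats::rnorm(length(cen), 0, 1e-8)
    fit <- suppressWarnings(stats::kmeans(x, centers = cen, iter.max = iter.max))
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' Elbow and silhouette curves for choosing k
#'
#' Runs k-means (Euclidean, k-means++ seeding, best of `restarts` starts) on
#' samples described by their signature-gene z-scores for each `k` in
#' `1..k_max`, recording the distortion (total within-cluster sum of
#' squares) and, for `k >= 2`, the mean silhouette width.
#'
#' @param z Z-score matrix, genes in rows, samples in columns.
#' @param k_max Largest k to evaluate (>= 2).
#' @param seed Integer seed controlling all restarts.
#' @param restarts Random restarts per k (default 50).
#' @return Object of class `k_selection_curve`: data frame with columns `k`,
#'   `distortion`, `silhouette` (`NA` at k = 1).
#' @export
k_selection_curves <- function(z, k_max = 10, seed = 1, restarts = 50) {
  stopifnot(k_max >= 2)
  x <- t(z)                                    # samples as points
  if (nrow(x) < k_max) stop("fewer samples than k_max")
  set.seed(seed)
  d <- stats::dist(x)
  res <- data.frame(k = seq_len(k_max), distortion = NA_real_,
                    silhouette = NA_real_)
  for (k in seq_len(k_max)) {
    if (k == 1L) {
      ctr <- colMeans(x)
      res$distortion[1L] <- sum(sweep(x, 2L, ctr)^2)
      next
    }
    fit <- kmeans_pp(x, k, restarts = restarts)
    res$distortion[k] <- fit$tot.withinss
    sil <- cluster::silhouette(fit$cluster, d)
    # all-singleton clusterings have no defined widths; score them 0
    res$silhouette[k] <- if (is.matrix(sil)) mean(sil[, "sil_width"]) else 0
  }
  class(res) <- c("k_selection_curve", "data.frame")
  res
}

#' Pick the number of clusters from selection curves
#'
#' Returns the k maximizing the mean silhouette width. The distortion-elbow
#' candidate (k with the largest second forward difference of distortion) is
#' also computed; when the two disagree the silhouette choice wins and the
#' disagreement is reported as a message.
#'
#' @param curve A `k_selection_curve` from [k_selection_curves()].
#' @return Integer k.
#' @export
choose_k <- function(curve) {
  stopifnot(inherits(curve, "k_selection_curve") || is.data.frame(curve))
  if (max(curve$k) < 3) stop("curve must cover k >= 3")
  ks <- curve$k[!is.na(curve$silhouette)]
  sil <- curve$silhouette[!is.na(curve$silhouette)]
  k_sil <- ks[which.max(sil)]
  d <- curve$distortion[order(curve$k)]
  if (length(d) >= 3) {
    d2 <- d[seq_len(length(d) - 2L)] - 2 * d[seq_len(length(d) - 2L) + 1L] +
      d[seq_len(length(d) - 2L) + 2L]
    k_elbow <- curve$k[which.max(d2) + 1L]
    if (k_elbow != k_sil) {
      message("elbow suggests k = ", k_elbow, ", silhouette k = ", k_sil,
              "; using silhouette")
    }
  }
  as.integer(k_sil)
}

#' Rule-based subtype assignment from category scores
#'
#' For each sample, the angiogenesis, stroma and immune scores are the mean
#' modified z-scores over the signature genes of each category; the sample
#' is assigned to the subtype whose hallmark program scores highest
#' (angiogenesis -> desert, stroma -> excluded, immune -> inflamed). Exact
#' ties yield `unassigned` rather than an arbitrary pick.
#'
#' @param z Z-score matrix containing every signature gene.
#' @param signature Gene category table (see [read_signature()]).
#' @return Data frame of class `subtype_labeling`: columns `sample_id`,
#'   `label`, `provenance` (`"rule"`), plus the three category score
#'   columns.
#' @export
rule_assign <- function(z, signature) {
  signature <- read_signature(signature)
  missing <- setdiff(signature$gene_id, rownames(z))
  if (length(missing)) {
    stop("signature genes absent from matrix: ",
         paste(missing, collapse = ", "))
  }
  cats <- names(CATEGORY_SUBTYPE)
  scores <- sapply(cats, function(cc) {
    g <- signature$gene_id[signature$category == cc]
    colMeans(z[g, , drop = FALSE])
  })
  top <- apply(scores, 1L, max)
  n_top <- rowSums(scores == top)
  lab <- unname(CATEGORY_SUBTYPE[cats[max.col(scores, ties.method = "first")]])
  lab[n_top > 1L] <- "unassigned"
  out <- data.frame(sample_id = colnames(z), label = lab, provenance = "rule",
                    angiogenesis = scores[, "angiogenesis"],
                    stroma = scores[, "stroma"], immune = scores[, "immune"],
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("subtype_labeling", "data.frame")
  out
}

#' Translate k-means clusters into subtype names
#'
#' Finds, among the six bijections between the three cluster ids and the
#' three subtypes, the one maximizing agreement with a rule-based labeling,
#' and returns the k-means partition relabeled accordingly.
#'
#' @param clusters Named integer vector (sample -> cluster id, 3 clusters).
#' @param rules A `subtype_labeling` from [rule_assign()] on the same
#'   samples.
#' @return Data frame of class `subtype_labeling` with provenance
#'   `"kmeans"`; attribute `agreement` holds the matched-sample count.
#' @export
map_clusters_to_subtypes <- function(clusters, rules) {
  if (!setequal(names(clusters), rules$sample_id)) {
    stop("cluster and rule labelings cover different samples")
  }
  ids <- sort(unique(clusters))
  if (length(ids) != 3L) stop("expected 3 clusters, got ", length(ids))
  rule_lab <- rules$label[match(names(clusters), rules$sample_id)]
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  agree <- vapply(perms, function(p) {
    lab <- SUBTYPES[p][match(clusters, ids)]
    sum(lab == rule_lab)
  }, numeric(1))
  if (sum(agree == max(agree)) > 1L) {
    warning("cluster-to-subtype mapping tie; using first optimal permutation")
  }
  best <- perms[[which.max(agree)]]
  out <- data.frame(sample_id = names(clusters),
                    label = SUBTYPES[best][match(clusters, ids)],
                    provenance = "kmeans", row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "agreement") <- max(agree)
  class(out) <- c("subtype_labeling", "data.frame")
  out
}

#' Consensus of two subtype labelings
#'
#' Keeps a sample's label only when both labelings agree on a real subtype;
#' every other sample becomes `unassigned`. The retained fraction is
#' attached as attribute `retained`.
#'
#' @param a,b `subtype_labeling` data frames over the same samples.
#' @return A `subtype_labeling` with provenance `"consensus"`.
#' @export
consensus_labels <- function(a, b) {
  if (!setequal(a$sample_id, b$sample_id)) stop("mismatched sample sets")
  bl <- b$label[match(a$sample_id, b$sample_id)]
  lab <- ifelse(a$label == bl & a$label != "unassigned", a$label, "unassigned")
  out <- data.frame(sample_id = a$sample_id, label = lab,
                    provenance = "consensus", row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "retained") <- mean(lab != "unassigned")
  class(out) <- c("subtype_labeling", "data.frame")
  out
}

#' Consensus subtype discovery on a cohort
#'
#' Convenience wrapper running the discovery stage end to end: restrict the
#' z-matrix to the signature genes, compute k-selection curves, run k-means
#' at k = 3, assign rule-based labels, map clusters to subtypes and form the
#' consensus.
#'
#' @param z Z-score matrix (all signature genes present).
#' @param signature Gene category table.
#' @param k_max,seed,restarts Passed to [k_selection_curves()].
#' @return List with elements `labels` (consensus `subtype_labeling`),
#'   `rule`, `kmeans`, `curve`, `k`, `agreement`, `retained`.
#' @export
discover_subtypes <- function(z, signature, k_max = 10, seed = 1,
                              restarts = 50) {
  signature <- read_signature(signature)
  zs <- z[signature$gene_id, , drop = FALSE]
  curve <- k_selection_curves(zs, k_max = k_max, seed = seed,
                              restarts = restarts)
  k <- choose_k(curve)
  set.seed(seed + 1L)
  km <- kmeans_pp(t(zs), 3L, restarts = restarts)
  rules <- rule_assign(zs, signature)
  kmap <- map_clusters_to_subtypes(stats::setNames(km$cluster, colnames(zs)),
                                   rules)
  cons <- consensus_labels(rules, kmap)
  list(labels = cons, rule = rules, kmeans = kmap, curve = curve, k = k,
       agreement = attr(kmap, "agreement"), retained = attr(cons, "retained"))
}

#' Read / write subtype labels as TSV
#'
#' @param x A `subtype_labeling` data frame (for writing) or a path (for
#'   reading).
#' @param path Output path.
#' @return The labeling (read) or the path, invisibly (write).
#' @export
write_labels <- function(x, path) {
  utils::write.table(x[, c("sample_id", "label", "provenance")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(x) {
  df <- utils::read.delim(x, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("labels need columns sample_id, label")
  }
  bad <- setdiff(unique(df$label), c(SUBTYPES, "unassigned"))
  if (length(bad)) stop("unknown labels: ", paste(bad, collapse = ", "))
  if (is.null(df$provenance)) df$provenance <- "histology"
  class(df) <- c("subtype_labeling", "data.frame")
  df
}
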