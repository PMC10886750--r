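# small in-code fixtures shared across test files

# tiny expression matrix with named genes/samples
expr_matrix <- function(nrow, ncol, data, genes = paste0("g", seq_len(nrow)),
                        samples = paste0("s", seq_len(ncol))) {
  matrix(data, nrow, ncol, dimnames = list(genes, samples))
}

# labeling data frame in the package's format
make_labels <- function(sample_ids, labels, provenance = "simulated") {
  df <- data.frame(sample_id = sample_ids, label = labels,
                   provenance = provenance, stringsAsFactors = FALSE)
  class(df) <- c("subtype_labeling", "data.frame")
  df
}

# three-category signature over given gene ids (in category blocks)
make_signature <- function(angio, stroma, immune) {
  data.frame(gene_id = c(angio, stroma, immune),
             category = rep(c("angiogenesis", "stroma", "immune"),
                            c(length(angio), length(stroma), length(immune))),
             stringsAsFactors = FALSE)
}

# z-matrix whose per-sample category means are exactly as requested
# (each category holds 2 identical genes)
z_from_category_scores <- function(scores) {
  # scores: matrix samples x 3 (angio, stroma, immune)
  z <- rbind(A1 = scores[, 1], A2 = scores[, 1],
             S1 = scores[, 2], S2 = scores[, 2],
             I1 = scores[, 3], I2 = scores[, 3])
  colnames(z) <- rownames(scores)
  z
}

cat_signature <- make_signature(c("A1", "A2"), c("S1", "S2"), c("I1", "I2"))

# brute-force AUC: count concordant (pos, neg) pairs, ties 1/2
auc_oracle <- function(scores, truth) {
  pos <- scores[as.logical(truth)]
  neg <- scores[!as.logical(truth)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# brute-force Youden: evaluate J over every threshold between sorted values
youden_oracle <- function(scores, truth) {
  truth <- as.logical(truth)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (u[-length(u)] + u[-1]) / 2, Inf)
  j <- sapply(cand, function(t) {
    mean(scores[truth] >= t) + mean(scores[!truth] < t) - 1
  })
  max(j)
}

# brute-force log-rank chi-square for two groups (hypergeometric variance)
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  stopifnot(length(unique(g)) == 2)
  tt <- sort(unique(time[event == 1]))
  o_minus_e <- 0
  v <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}
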