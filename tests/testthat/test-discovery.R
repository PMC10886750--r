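make_blobs <- function(n_per = 30, centers, sd = 1, seed = 1) {
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
  }))
  rownames(x) <- paste0("s", seq_len(nrow(x)))
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  t(x)   # features (genes) in rows, as a z-matrix would be
}

test_that("silhouette peaks at 3 for three well-separated blobs", {
  centers <- rbind(c(0, 0, 0), c(15, 0, 0), c(0, 15, 0))
  z <- make_blobs(25, centers, sd = 1, seed = 5)
  curve <- k_selection_curves(z, k_max = 6, seed = 1, restarts = 10)
  expect_equal(curve$k[which.max(curve$silhouette)], 3)
  expect_equal(choose_k(curve), 3L)
  # distortion is non-increasing in k
  expect_true(all(diff(curve$distortion) <= 1e-8))
})

test_that("a single Gaussian blob yields no strong silhouette", {
  z <- make_blobs(80, rbind(c(0, 0, 0, 0)), sd = 1, seed = 6)
  curve <- k_selection_curves(z, k_max = 6, seed = 2, restarts = 10)
  expect_true(all(curve$silhouette[-1] < 0.5, na.rm = TRUE))
  expect_true(all(diff(curve$distortion) <= 1e-8))
})

test_that("k equal to the sample count gives zero distortion", {
  z <- expr_matrix(2, 6, c(1:6, 6:1) * 1.0)
  curve <- k_selection_curves(z, k_max = 6, seed = 3, restarts = 5)
  expect_equal(curve$distortion[6], 0, tolerance = 1e-10)
  expect_error(k_selection_curves(z, k_max = 7, seed = 1), "fewer samples")
})

test_that("choose_k takes the silhouette argmax", {
  curve <- data.frame(k = 1:4, distortion = c(100, 60, 30, 25),
                      silhouette = c(NA, 0.3, 0.7, 0.4))
  class(curve) <- c("k_selection_curve", "data.frame")
  expect_equal(suppressMessages(choose_k(curve)), 3L)
  curve$silhouette <- c(NA, 0.6, 0.5, 0.2)
  expect_equal(suppressMessages(choose_k(curve)), 2L)
})

test_that("rule assignment follows the category-subtype mapping with tie rule", {
  scores <- rbind(
    s1 = c(1.2, -0.1, -0.8),    # angiogenesis top -> desert
    s2 = c(0.0, 1.5, 0.2),      # stroma top -> excluded
    s3 = c(-0.3, 0.1, 2.0),     # immune top -> inflamed
    s4 = c(0.5, 0.5, -1.0)      # exact tie -> unassigned
  )
  lab <- rule_assign(z_from_category_scores(scores), cat_signature)
  expect_equal(lab$label, c("desert", "excluded", "inflamed", "unassigned"))
  expect_equal(lab$angiogenesis, unname(scores[, 1]))

  z <- z_from_category_scores(scores)
  expect_error(rule_assign(z[-1, ], cat_signature), "A1")
})

test_that("rule assignment is invariant to gene and sample order", {
  set.seed(7)
  scores <- matrix(rnorm(30), 10, 3,
                   dimnames = list(paste0("s", 1:10), NULL))
  z <- z_from_category_scores(scores)
  a <- rule_assign(z, cat_signature)
  perm_g <- sample(nrow(z)); perm_s <- sample(ncol(z))
  b <- rule_assign(z[perm_g, perm_s], cat_signature[sample(6), ])
  expect_equal(b$label[match(a$sample_id, b$sample_id)], a$label)
})

test_that("cluster-subtype mapping recovers permutations and flags scale", {
  rules <- make_labels(paste0("s", 1:9),
                       rep(c("desert", "excluded", "inflamed"), each = 3),
                       "rule")
  clusters <- setNames(rep(c(2L, 3L, 1L), each = 3), rules$sample_id)
  mapped <- map_clusters_to_subtypes(clusters, rules)
  expect_equal(mapped$label, rules$label)
  expect_equal(attr(mapped, "agreement"), 9)
  expect_error(map_clusters_to_subtypes(clusters[1:3], rules),
               "different samples")
  expect_error(
    map_clusters_to_subtypes(
      setNames(rep(c(1L, 2L), c(5, 4)), rules$sample_id), rules),
    "expected 3 clusters")
  expect_error(
    map_clusters_to_subtypes(setNames(rep(1:2, c(5, 4)), rules$sample_id),
                             rules), "expected 3 clusters")
})

test_that("random labels vs balanced clusters give near-chance best agreement", {
  # best-of-six-permutations agreement is slightly above n/3 by selection
  set.seed(8)
  agree <- replicate(40, {
    cl <- setNames(rep(1:3, each = 100), paste0("s", 1:300))
    rules <- make_labels(names(cl),
                         sample(c("desert", "excluded", "inflamed"), 300, TRUE),
                         "rule")
    suppressWarnings(attr(map_clusters_to_subtypes(cl, rules), "agreement"))
  })
  expect_gt(mean(agree) / 300, 1 / 3)
  expect_lt(mean(agree) / 300, 0.42)
})

test_that("consensus keeps agreeing real labels and is symmetric", {
  a <- make_labels(paste0("s", 1:4),
                   c("desert", "excluded", "inflamed", "unassigned"), "rule")
  b <- make_labels(paste0("s", 1:4),
                   c("desert", "inflamed", "inflamed", "unassigned"), "kmeans")
  cons <- consensus_labels(a, b)
  expect_equal(cons$label, c("desert", "unassigned", "inflamed", "unassigned"))
  expect_equal(attr(cons, "retained"), 0.5)
  expect_equal(consensus_labels(b, a)$label, cons$label)

  expect_equal(unique(consensus_labels(a, a)$label[a$label != "unassigned"] ==
                        a$label[a$label != "unassigned"]), TRUE)
  disjoint <- make_labels(paste0("s", 1:4),
                          c("excluded", "desert", "desert", "desert"), "kmeans")
  expect_true(all(consensus_labels(a, disjoint)$label == "unassigned"))
  expect_error(consensus_labels(a, b[1:2, ]), "mismatched")
})

test_that("signature validation rejects malformed tables", {
  expect_error(read_signature(data.frame(gene_id = "g", category = "other")),
               "unknown categories")
  expect_error(read_signature(data.frame(gene_id = c("a", "b"),
                                         category = c("immune", "immune"))),
               "lacks categories")
  expect_error(read_signature(data.frame(gene_id = c("a", "a", "b", "c"),
                                         category = c("immune", "immune",
                                                      "stroma",
                                                      "angiogenesis"))),
               "duplicate")
})
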