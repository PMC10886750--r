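test_that("configuration validation rejects degenerate settings", {
  expect_error(synthetic_config(n_desert = 0), "positive")
  expect_error(synthetic_config(delta = -1), "delta")
  expect_error(synthetic_config(rho = 1), "rho")
  expect_error(synthetic_config(resid_sd = 0), "resid_sd")
  expect_error(synthetic_config(surv_medians = c(desert = 35, excluded = 47,
                                                 inflamed = Inf)),
               "survival medians")
})

test_that("generation is bit-reproducible from the seed", {
  cfg <- synthetic_config(n_background = 30)
  a <- generate_expression(cfg, seed = 7)
  b <- generate_expression(cfg, seed = 7)
  expect_identical(a$expression, b$expression)
  expect_identical(a$labels, b$labels)
  c <- generate_expression(cfg, seed = 8)
  expect_false(identical(a$expression, c$expression))

  ct1 <- generate_qpcr(a$expression, a$signature$gene_id[1:3], cfg, seed = 7)
  ct2 <- generate_qpcr(b$expression, b$signature$gene_id[1:3], cfg, seed = 7)
  expect_identical(ct1, ct2)
  s1 <- generate_survival(a$labels, cfg, seed = 7)
  s2 <- generate_survival(a$labels, cfg, seed = 7)
  expect_identical(s1, s2)
})

test_that("cohort structure matches the configuration", {
  cfg <- synthetic_config()
  co <- generate_expression(cfg, seed = 1)
  expect_equal(dim(co$expression), c(40 + 300, 346))
  expect_equal(unname(table(co$labels$label)[c("desert", "excluded",
                                               "inflamed")]),
               c(95, 75, 176), ignore_attr = TRUE)
  expect_equal(unname(table(co$signature$category)[c("angiogenesis",
                                                     "immune", "stroma")]),
               c(13, 14, 13), ignore_attr = TRUE)
  expect_true(all(co$expression > 0))
  # signature genes shifted as configured: immune block separates subtypes
  lx <- log2(co$expression)
  immune <- co$signature$gene_id[co$signature$category == "immune"]
  lab <- co$labels$label
  im_means <- tapply(colMeans(lx[immune, ]), lab, mean)
  expect_gt(im_means[["inflamed"]] - im_means[["desert"]], 2 * cfg$delta * 0.8)
})

test_that("a null cohort exhibits the configured within-program correlation", {
  cfg <- synthetic_config(delta = 0, n_background = 0)
  co <- generate_expression(cfg, seed = 2)
  lx <- log2(co$expression)
  corr <- sapply(split(co$signature$gene_id, co$signature$category),
                 function(g) {
                   cm <- cor(t(lx[g, ]))
                   mean(cm[lower.tri(cm)])
                 })
  expect_equal(unname(mean(corr)), 0.5, tolerance = 0.08)
})

test_that("null effects destroy separability, default effects restore it", {
  # delta = 0 with default rho: program structure remains but carries no
  # subtype signal -> scores are uninformative, consensus labels are at chance
  null_cfg <- synthetic_config(delta = 0, n_background = 50)
  aucs <- acc_null <- c()
  for (s in 1:3) {
    co <- generate_expression(null_cfg, seed = s)
    z <- zscore_matrix(log2(co$expression + 1))
    zs <- z[co$signature$gene_id, ]
    immune <- co$signature$gene_id[co$signature$category == "immune"]
    aucs <- c(aucs, roc_auc(colMeans(zs[immune, ]),
                            co$labels$label == "inflamed")$auc)
    rules <- rule_assign(zs, co$signature)
    acc_null <- c(acc_null, mean(rules$label == co$labels$label))
  }
  expect_lt(mean(abs(aucs - 0.5)), 0.05)
  expect_lt(mean(acc_null), 0.5)

  # fully unstructured null (rho = 0 as well): consensus becomes unstable
  retained <- c()
  for (s in 1:3) {
    co <- generate_expression(synthetic_config(delta = 0, rho = 0,
                                               n_background = 50), seed = s)
    z <- zscore_matrix(log2(co$expression + 1))
    zs <- z[co$signature$gene_id, ]
    rules <- rule_assign(zs, co$signature)
    set.seed(s)
    km <- melsubtype:::kmeans_pp(t(zs), 3, restarts = 15)
    kmap <- suppressWarnings(
      map_clusters_to_subtypes(setNames(km$cluster, colnames(zs)), rules))
    retained <- c(retained, attr(consensus_labels(rules, kmap), "retained"))
  }
  expect_lt(mean(retained), 0.6)

  cfg <- synthetic_config(n_background = 50)
  acc <- sapply(1:3, function(s) {
    co <- generate_expression(cfg, seed = s)
    z <- zscore_matrix(log2(co$expression + 1))
    r <- rule_assign(z[co$signature$gene_id, ], co$signature)
    mean(r$label == co$labels$label)
  })
  expect_gte(mean(acc), 0.9)
})

test_that("background genes carry no subtype effect", {
  cfg <- synthetic_config(n_background = 200)
  co <- generate_expression(cfg, seed = 3)
  de <- de_analysis(co$expression, co$labels)
  bg <- de$tables$inflamed$gene_id %in% co$background_genes
  # p-values of background genes are uniform-ish: ~5% below 0.05
  expect_lt(mean(de$tables$inflamed$p[bg] < 0.05), 0.1)
  top <- select_top_genes(de, per_subtype = 10)
  expect_equal(sum(unlist(lapply(top, `[[`, "gene_id")) %in%
                     co$background_genes), 0)
})

test_that("simulated Ct values decrease with expression and stay in range", {
  cfg <- synthetic_config(n_background = 10)
  co <- generate_expression(cfg, seed = 4)
  genes <- co$signature$gene_id[1:4]
  ct <- generate_qpcr(co$expression, genes, cfg, seed = 4)
  expect_true(all(ct$ct > 0 & ct$ct <= 40))
  expect_equal(sum(ct$gene_id %in% c("RPL13A", "GAPDH")),
               2 * 3 * ncol(co$expression))
  agg <- aggregate_replicates(ct)
  for (g in genes) {
    rows <- agg[agg$gene_id == g, ]
    expr <- log2(co$expression[g, rows$sample_id])
    expect_lt(cor(expr, rows$ct), -0.9)
  }
  expect_error(generate_qpcr(co$expression, "NOPE", cfg, seed = 1), "NOPE")
})

test_that("survival generator hits the censoring target and group ordering", {
  cfg <- synthetic_config()
  lab <- make_labels(sprintf("S%03d", 1:346),
                     rep(c("desert", "excluded", "inflamed"),
                         c(95, 75, 176)))
  cens <- meds <- NULL
  inf_top <- c()
  for (s in 1:10) {
    sv <- generate_survival(lab, cfg, seed = s)
    expect_true(all(sv$time_months > 0))
    cens <- c(cens, 1 - mean(sv$event))
    km <- sapply(split(sv, sv$group),
                 function(d) km_curve(d$time_months, d$event)$median)
    meds <- rbind(meds, km)
    inf_top <- c(inf_top, km[["inflamed"]] > km[["desert"]])
  }
  expect_lt(abs(mean(cens) - 0.3), 0.05)
  expect_true(all(inf_top))
  m <- colMeans(meds)
  expect_true(m[["inflamed"]] > m[["excluded"]] &&
                m[["excluded"]] > m[["desert"]])
})
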