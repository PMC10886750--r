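balanced_labels <- function(n_per = 10) {
  make_labels(paste0("s", seq_len(3 * n_per)),
              rep(c("desert", "excluded", "inflamed"), each = n_per))
}

test_that("group-means model recovers exact fits and sample means", {
  lab <- make_labels(paste0("s", 1:6),
                     rep(c("desert", "excluded", "inflamed"), each = 2))
  x <- rbind(g1 = c(1, 1, 2, 2, 3, 3))
  colnames(x) <- lab$sample_id
  fit <- fit_gene_models(x, lab)
  expect_equal(unname(fit$coefficients[1, ]), c(1, 2, 3))
  expect_equal(unname(fit$sigma2), 0)
  expect_equal(fit$df_resid, 3)

  set.seed(1)
  lab2 <- balanced_labels(7)
  x2 <- expr_matrix(50, 21, rnorm(1050), samples = lab2$sample_id)
  fit2 <- fit_gene_models(x2, lab2)
  grp <- rep(c("desert", "excluded", "inflamed"), each = 7)
  for (g in c("desert", "excluded", "inflamed")) {
    expect_equal(unname(fit2$coefficients[, g]),
                 unname(rowMeans(x2[, grp == g])), tolerance = 1e-12)
  }
})

test_that("least-squares fit matches a normal-equations oracle", {
  set.seed(2)
  lab <- make_labels(paste0("s", 1:20),
                     sample(rep(c("desert", "excluded", "inflamed"),
                                c(8, 5, 7))))
  x <- expr_matrix(200, 20, rnorm(4000), samples = lab$sample_id)
  fit <- fit_gene_models(x, lab)
  X <- model.matrix(~ 0 + factor(lab$label,
                                 c("desert", "excluded", "inflamed")))
  beta <- t(solve(t(X) %*% X, t(X) %*% t(x)))
  expect_equal(unname(fit$coefficients), unname(beta), tolerance = 1e-10)
  resid <- t(x) - X %*% t(beta)
  expect_equal(unname(fit$sigma2), unname(colSums(resid^2) / (20 - 3)),
               tolerance = 1e-10)
})

test_that("fit requires two samples per subtype", {
  lab <- make_labels(paste0("s", 1:5),
                     c("desert", "desert", "excluded", "excluded", "inflamed"))
  x <- expr_matrix(3, 5, rnorm(15), samples = lab$sample_id)
  expect_error(fit_gene_models(x, lab), ">= 2 samples")
})

test_that("moment matching recovers the variance prior", {
  df <- 27
  d0 <- 4; s0 <- 1
  est <- sapply(1:10, function(s) {
    set.seed(s)
    s2 <- s0 * (rchisq(1e4, df) / df) / (rchisq(1e4, d0) / d0)
    m <- moderate_variances(s2, df)
    c(m$df_prior, m$var_prior)
  })
  expect_lt(abs(mean(est[1, ]) - d0) / d0, 0.2)
  expect_lt(abs(mean(est[2, ]) - s0) / s0, 0.1)
})

test_that("posterior variances shrink toward the prior and stay bounded", {
  set.seed(3)
  s2 <- rchisq(500, 5)
  m <- moderate_variances(s2, df_resid = 10)
  lo <- pmin(s2, m$var_prior); hi <- pmax(s2, m$var_prior)
  pos <- s2 > 0 & abs(s2 - m$var_prior) > 1e-12
  expect_true(all(m$var_post[pos] > lo[pos] & m$var_post[pos] < hi[pos]))
  # weighted-average form is invariant to gene relabeling
  perm <- sample(500)
  m2 <- moderate_variances(s2[perm], df_resid = 10)
  expect_equal(m2$var_post, m$var_post[perm], tolerance = 1e-9)
})

test_that("constant variances trigger the infinite-prior branch", {
  m <- moderate_variances(rep(2, 50), df_resid = 8)
  expect_true(is.infinite(m$df_prior))
  expect_equal(unique(m$var_post), m$var_prior)
  expect_error(moderate_variances(rep(0, 50), 8), "degenerate")
})

test_that("moderated contrast reduces to the ordinary t-test without a prior", {
  set.seed(4)
  lab <- balanced_labels(6)
  x <- expr_matrix(80, 18, rnorm(1440), samples = lab$sample_id)
  fit <- fit_gene_models(x, lab)
  ct0 <- contrast_test(fit, NULL, c(1, -0.5, -0.5))
  # ordinary t by hand for a few genes
  grp <- factor(lab$label, c("desert", "excluded", "inflamed"))
  for (g in c(1, 40, 80)) {
    lmfit <- lm(x[g, ] ~ 0 + grp)
    est <- sum(coef(lmfit) * c(1, -0.5, -0.5))
    se <- sqrt(sum(c(1, -0.5, -0.5)^2 / table(grp)) * sigma(lmfit)^2)
    expect_equal(ct0$t_mod[g], est / se, tolerance = 1e-10)
  }
  # an explicit zero-df prior gives the same statistics
  mod0 <- structure(list(df_prior = 0, var_prior = 1, var_post = fit$sigma2),
                    class = "variance_moderation")
  expect_equal(contrast_test(fit, mod0, c(1, -0.5, -0.5))$t_mod, ct0$t_mod)
})

test_that("contrast sanity: equal means give t = 0 and weights must sum to 0", {
  lab <- balanced_labels(3)
  x <- rbind(g1 = rep(c(5, 5, 5), each = 3) + rep(c(-0.1, 0, 0.1), 3))
  colnames(x) <- lab$sample_id
  fit <- fit_gene_models(x, lab)
  ct <- contrast_test(fit, NULL, c(1, -0.5, -0.5))
  expect_equal(ct$t_mod, 0, tolerance = 1e-12)
  expect_equal(ct$p, 1, tolerance = 1e-12)
  expect_error(contrast_test(fit, NULL, c(1, -0.5, 0)), "sum to 0")
})

test_that("moderated and ordinary t agree in sign, |t| ordering follows shrinkage", {
  set.seed(5)
  lab <- balanced_labels(5)
  x <- expr_matrix(120, 15, rnorm(1800), samples = lab$sample_id)
  fit <- fit_gene_models(x, lab)
  mod <- moderate_variances(fit$sigma2, fit$df_resid)
  tm <- contrast_test(fit, mod, c(1, -0.5, -0.5))$t_mod
  t0 <- contrast_test(fit, NULL, c(1, -0.5, -0.5))$t_mod
  expect_true(all(sign(tm) == sign(t0) | t0 == 0))
  # |t_mod| / |t| = sqrt(s2 / s2_post) exactly
  expect_equal(tm^2 * mod$var_post, t0^2 * fit$sigma2, tolerance = 1e-9)
})

test_that("moderated statistics agree with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(6)
  lab <- balanced_labels(8)
  # heteroskedastic gene variances so the prior df is finite
  sds <- sqrt(rchisq(300, 4) / 4)
  x <- expr_matrix(300, 24, rnorm(300 * 24) * rep(sds, 24),
                   samples = lab$sample_id)
  fit <- fit_gene_models(x, lab)
  mod <- moderate_variances(fit$sigma2, fit$df_resid)
  ct <- contrast_test(fit, mod, c(1, -0.5, -0.5))

  design <- model.matrix(~ 0 + factor(lab$label,
                                      c("desert", "excluded", "inflamed")))
  colnames(design) <- c("desert", "excluded", "inflamed")
  eb <- limma::eBayes(limma::contrasts.fit(limma::lmFit(x, design),
                                           c(1, -0.5, -0.5)))
  expect_equal(mod$df_prior, eb$df.prior, tolerance = 0.05)
  expect_equal(mod$var_prior, eb$s2.prior, tolerance = 0.02)
  expect_equal(ct$t_mod, unname(eb$t[, 1]), tolerance = 0.01)
})

test_that("planted inflamed markers fill the inflamed top list", {
  cfg <- synthetic_config(n_immune = 10, delta = 3)
  for (s in 1:3) {
    co <- generate_expression(cfg, seed = s)
    de <- de_analysis(co$expression, co$labels)
    top <- select_top_genes(de, per_subtype = 10)
    immune <- co$signature$gene_id[co$signature$category == "immune"]
    expect_gte(sum(top$inflamed$gene_id %in% immune), 9)
  }
})

test_that("top-gene ranking is deterministic under ties", {
  tab <- data.frame(gene_id = c("b", "a", "c"),
                    effect = c(1, -1, 2),
                    t_mod = c(2, -2, 5),
                    p = c(0.5, 0.5, 0.001),
                    df_total = 10)
  de <- structure(list(tables = list(desert = tab)), class = "de_result")
  top <- select_top_genes(de, per_subtype = 3)$desert
  # smallest p first; tie on p broken by |t| (equal) then gene id
  expect_equal(top$gene_id, c("c", "a", "b"))
  expect_error(select_top_genes(de, per_subtype = 4), "exceeds gene count")
})
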