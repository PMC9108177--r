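# BH adjustment, moderated t-tests, consensus clustering and PCA views.

test_that("bh_adjust implements the step-up rule exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.4, 5)), rep(0.4, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(10, {
    for (i in 1:20) {
      p <- runif(sample(1:40, 1))
      expect_equal(bh_adjust(p), oracle_bh(p))
      expect_equal(bh_adjust(p), p.adjust(p, "BH")) # cross-check
      perm <- sample(seq_along(p))
      expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm]) # order-invariant
    }
  })
})

two_group_expr <- function(ng = 200, n1 = 5, n2 = 5, delta = NULL, seed = 1) {
  withr::with_seed(seed, {
    if (is.null(delta)) delta <- rep(0, ng)
    x <- cbind(matrix(rnorm(ng * n1, delta), ng, n1),
               matrix(rnorm(ng * n2, 0), ng, n2))
    dimnames(x) <- list(sprintf("g%03d", 1:ng), sprintf("s%02d", 1:(n1 + n2)))
    list(x = expr_matrix(x, "log2"),
         labels = factor(rep(c("A", "B"), c(n1, n2))))
  })
}

test_that("moderated t reduces to the ordinary pooled t when d0 = 0", {
  fx <- two_group_expr(seed = 3)
  out <- moderated_t(fx$x, fx$labels, prior_df = 0)
  ord_t <- apply(fx$x, 1, function(v) {
    t.test(v[fx$labels == "A"], v[fx$labels == "B"], var.equal = TRUE)$statistic
  })
  expect_equal(out$t_mod, unname(ord_t), tolerance = 1e-10)
})

test_that("identical group means give a zero moderated statistic", {
  x <- matrix(rep(c(1, 2, 5), each = 6), 3, 6, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), sprintf("s%d", 1:6)))
  x[2, ] <- c(1, 2, 3, 1, 2, 3) # same values per group, zero mean diff
  out <- moderated_t(expr_matrix(x, "log2"), rep(c("A", "B"), each = 3))
  expect_equal(out$mean_diff, rep(0, 3))
  expect_equal(out$t_mod, rep(0, 3))
  expect_equal(out$p_value[1], 1) # zero variance, zero diff convention
})

test_that("moderated t agrees with the limma empirical-Bayes reference", {
  skip_if_not_installed("limma")
  # heteroscedastic truth: gene variances drawn from a scaled inverse
  # chi-square so the prior df is finite and estimable
  withr::with_seed(7, {
    ng <- 500
    sd_g <- sqrt(1 * 4 / rchisq(ng, df = 4))
    delta <- c(rep(1, 50), rep(0, ng - 50))
    x <- cbind(matrix(rnorm(ng * 5, delta, sd_g), ng, 5),
               matrix(rnorm(ng * 5, 0, sd_g), ng, 5))
    dimnames(x) <- list(sprintf("g%03d", 1:ng), sprintf("s%02d", 1:10))
  })
  labels <- factor(rep(c("A", "B"), each = 5))
  mine <- moderated_t(expr_matrix(x, "log2"), labels)
  design <- stats::model.matrix(~ labels)
  ebayes <- limma::eBayes(limma::lmFit(x, design))
  ref_t <- -ebayes$t[, 2] # limma's coefficient is B minus A
  expect_gt(cor(mine$t_mod, ref_t), 0.999)
  expect_equal(attr(mine, "d0"), ebayes$df.prior, tolerance = 0.1)
  expect_equal(attr(mine, "s0_2"), ebayes$s2.prior, tolerance = 0.1)
})

test_that("variance shrinkage improves effect ordering at small n", {
  withr::with_seed(17, {
    delta <- rnorm(2000)
    x <- cbind(matrix(rnorm(2000 * 3, delta), 2000, 3),
               matrix(rnorm(2000 * 3), 2000, 3))
    dimnames(x) <- list(sprintf("g%04d", 1:2000), sprintf("s%d", 1:6))
  })
  labels <- rep(c("A", "B"), each = 3)
  m <- moderated_t(expr_matrix(x, "log2"), labels)
  o <- moderated_t(expr_matrix(x, "log2"), labels, prior_df = 0)
  expect_gte(cor(m$t_mod, delta, method = "spearman"),
             cor(o$t_mod, delta, method = "spearman"))
})

test_that("consensus clustering recovers well-separated planted subtypes", {
  coh <- cached_cohort("sep3", mid_config(seed = 37, subtype_effect = 3))
  rpm <- cohort_erna_rpm(coh)
  x <- expr_matrix(log2(rpm[coh$truth$ir_ernas, ] + 1), "log2")
  cc <- consensus_cluster(x, k_range = 2:4, reps = 100, seed = 2)
  expect_equal(cc$chosen_k, 2)
  expect_equal(adjusted_rand(cc$chosen_labels,
                             coh$truth$subtype[names(cc$chosen_labels)]), 1)
  # similarity-matrix invariants
  cm <- cc$consensus[["2"]]
  expect_equal(cm, t(cm))
  expect_true(all(diag(cm) == 1))
  expect_true(all(cm >= 0 & cm <= 1))
  # bit-reproducible under the seed
  cc2 <- consensus_cluster(x, k_range = 2:4, reps = 100, seed = 2)
  expect_identical(cc$consensus, cc2$consensus)
  expect_identical(cc$chosen_labels, cc2$chosen_labels)
})

test_that("a degenerate consensus run equals one direct k-medoids pass", {
  coh <- cached_cohort("tiny_io", tiny_config(seed = 12))
  rpm <- cohort_erna_rpm(coh)
  x <- expr_matrix(log2(rpm[coh$truth$active_ernas, ] + 1), "log2")
  cc <- consensus_cluster(x, k_range = 2, reps = 1, subsample = 1.0, seed = 1)
  z <- ernascape:::standardize_rows(x)
  direct <- cluster::pam(as.dist(1 - cor(z)), k = 2, diss = TRUE,
                         cluster.only = TRUE)
  expect_equal(adjusted_rand(cc$labels[["2"]], direct), 1)
})

test_that("PCA views have deterministic orientation and exact reconstruction", {
  # rank-1 data: PC1 carries all variance
  withr::with_seed(21, {
    u <- rnorm(8); v <- rnorm(5)
    x <- outer(u, v)
    dimnames(x) <- list(sprintf("f%d", 1:8), sprintf("s%d", 1:5))
  })
  pv <- pca_view(expr_matrix(x, "log2"), n_components = 2)
  expect_equal(pv$var_explained[1], 1, tolerance = 1e-10)

  withr::with_seed(22, {
    xn <- x + matrix(rnorm(40, 0, 0.1), 8, 5)
    dimnames(xn) <- dimnames(x)
  })
  full <- pca_view(expr_matrix(xn, "log2"), n_components = 5)
  # full-rank scores times loadings reproduce the standardized data
  recon <- as.matrix(full$scores[, -1]) %*% t(full$loadings)
  expect_equal(recon, t(ernascape:::standardize_rows(xn)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # orientation: the largest loading of each component is positive
  for (j in 1:2) {
    expect_gt(full$loadings[which.max(abs(full$loadings[, j])), j], 0)
  }
  expect_error(pca_view(expr_matrix(x, "log2"), n_components = 9), "exceeds")
})

test_that("PC1 separates planted subtypes at the default effect size", {
  coh <- ref_cohort()
  gl <- cohort_gene_log2(coh)
  pv <- pca_view(gl[coh$truth$signature_genes$gene_id, ], n_components = 2)
  sub <- coh$truth$subtype[pv$scores$sample_id]
  pc1 <- pv$scores$PC1
  gap <- abs(mean(pc1[sub == "active"]) - mean(pc1[sub == "resistant"]))
  pooled <- sqrt((var(pc1[sub == "active"]) + var(pc1[sub == "resistant"])) / 2)
  expect_gt(gap, 2 * pooled)
})
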