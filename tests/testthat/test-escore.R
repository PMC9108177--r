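# Signature selection, set partition, E-score computation and the
# maximally selected cutpoint.

test_that("signature selection recovers planted genes and passes through on 'all'", {
  coh <- cached_cohort("mid_default", mid_config(seed = 43, n_samples = 400))
  gl <- cohort_gene_log2(coh)
  labels <- coh$truth$subtype
  deg <- moderated_t(gl, factor(labels[colnames(gl)]))
  sel <- suppressMessages(select_signature(deg, gl, coh$clinical, labels,
                                           seed = 11))
  planted <- coh$truth$signature_genes$gene_id
  expect_gte(mean(planted %in% sel), 0.8)

  all_mode <- suppressMessages(select_signature(deg, gl, coh$clinical, labels,
                                                importance_rule = "all"))
  prog <- suppressMessages(prognostic_filter(
    gl[deg$gene_id[deg$adj_p < 0.05], , drop = FALSE], coh$clinical))
  expect_setequal(as.character(all_mode), prog$feature_id)
})

test_that("noise genes are selected only rarely", {
  coh <- cached_cohort("mid_default", mid_config(seed = 43, n_samples = 400))
  gl0 <- cohort_gene_log2(coh)
  withr::with_seed(44, {
    noise <- matrix(rnorm(300 * ncol(gl0), 5, 1), 300, ncol(gl0),
                    dimnames = list(sprintf("noise%03d", 1:300), colnames(gl0)))
  })
  gl <- expr_matrix(rbind(unclass(gl0), noise), "log2")
  # present the noise genes as if they were DEGs; the prognostic filter
  # and forest must still reject nearly all of them
  deg <- tibble::tibble(gene_id = c(coh$truth$signature_genes$gene_id,
                                    rownames(noise)),
                        adj_p = 0)
  sel <- suppressMessages(select_signature(deg, gl, coh$clinical,
                                           coh$truth$subtype, seed = 13))
  expect_lte(mean(rownames(noise) %in% sel), 0.05)
})

test_that("set partition follows the correlation sign and flips with the coding", {
  withr::with_seed(3, {
    n <- 40
    labels <- setNames(rep(c("active", "resistant"), each = n / 2),
                       sprintf("s%02d", 1:n))
    ind <- as.numeric(labels == "active")
    x <- rbind(up_in_active = ind * 2 + rnorm(n, 0, 0.1),
               up_in_resistant = -ind * 2 + rnorm(n, 0, 0.1),
               flat = rep(3, n))
    colnames(x) <- names(labels)
  })
  expect_warning(partition_sets(expr_matrix(x, "log2"), rownames(x), labels),
                 "excluded")
  sets <- suppressWarnings(
    partition_sets(expr_matrix(x, "log2"), rownames(x), labels))
  expect_equal(sets$set_A, "up_in_active")
  expect_equal(sets$set_B, "up_in_resistant")
  flipped <- suppressWarnings(
    partition_sets(expr_matrix(x, "log2"), rownames(x), labels,
                   active_level = "resistant"))
  expect_equal(flipped$set_A, sets$set_B)
  expect_equal(flipped$set_B, sets$set_A)
})

test_that("the E-score reduces, duplicates and separates as specified", {
  coh <- ref_cohort()
  gl <- cohort_gene_log2(coh)
  labels <- coh$truth$subtype
  sig <- coh$truth$signature_genes$gene_id
  sets <- partition_sets(gl, sig, labels)
  expect_true(length(sets$set_A) > 0 && length(sets$set_B) > 0)

  esc <- compute_escore(gl, sets, mode = "difference")
  sub <- labels[esc$sample_id]
  gap <- mean(esc$e_score[sub == "active"]) - mean(esc$e_score[sub == "resistant"])
  pooled <- sqrt((var(esc$e_score[sub == "active"]) +
                    var(esc$e_score[sub == "resistant"])) / 2)
  expect_gt(gap, 1 * pooled) # oriented toward the active (coded-1) subtype

  # a one-set signature reduces to that set's PC1
  only_a <- structure(list(set_A = sets$set_A, set_B = character(0),
                           indicator_coding = "active"),
                      class = "signature_sets")
  esc_a <- compute_escore(gl, only_a)
  expect_equal(esc_a$e_score, esc_a$pc1_a)
  expect_equal(esc_a$pc1_b, rep(0, nrow(esc_a)))

  # duplicating every sample leaves per-sample scores identical
  dup <- cbind(unclass(gl), unclass(gl))
  colnames(dup) <- c(colnames(gl), paste0(colnames(gl), "_dup"))
  esc_dup <- compute_escore(expr_matrix(dup, "log2"), sets)
  half <- nrow(esc_dup) / 2
  expect_equal(esc_dup$e_score[seq_len(half)],
               esc_dup$e_score[half + seq_len(half)], tolerance = 1e-9)

  # sample order invariance
  perm <- sample(colnames(gl))
  esc_perm <- compute_escore(gl[, perm], sets, mode = "difference")
  expect_equal(esc_perm$e_score[match(esc$sample_id, esc_perm$sample_id)],
               esc$e_score, tolerance = 1e-9)
})

test_that("the optimal cutpoint matches an exhaustive scan", {
  withr::with_seed(21, {
    n <- 150
    scores <- rnorm(n)
    clin <- make_clinical(n, lp = -0.8 * scores, censor = 90)
  })
  cut <- optimal_cutpoint(scores, clin)
  orc <- oracle_cutpoint(scores, clin$time, clin$event)
  expect_equal(cut$cutpoint, orc$cutpoint)
  expect_equal(abs(cut$statistic), abs(orc$statistic), tolerance = 1e-9)
})

test_that("clearly separated score clouds split along the cloud boundary", {
  withr::with_seed(25, {
    cloud <- rep(c("short", "long"), each = 40)
    scores <- c(rnorm(40, 0), rnorm(40, 10)) # no overlap in practice
    t_ev <- ifelse(cloud == "short", rexp(80, 1 / 6), rexp(80, 1 / 60)) + 1.01
    clin <- tibble::tibble(sample_id = sprintf("p%02d", 1:80),
                           time = t_ev, event = 1L)
  })
  cut <- optimal_cutpoint(scores, clin)
  # the induced high/low grouping recovers cloud membership (the optimal
  # cut may trade 1-2 boundary-tail samples on their survival noise)
  agreement <- mean((cut$groups$group == "high") == (cloud == "long"))
  expect_gte(agreement, 76 / 80)
})

test_that("cutpoint selection inflates the naive statistic under the null", {
  withr::with_seed(29, {
    n <- 80
    clin <- make_clinical(n, censor = 70)
    base_scores <- rnorm(n)
  })
  reps <- 200
  max_stat <- numeric(reps)
  naive_p <- numeric(reps)
  withr::with_seed(30, {
    for (r in seq_len(reps)) {
      s <- sample(base_scores)
      cut <- optimal_cutpoint(s, clin)
      max_stat[r] <- abs(cut$statistic)
      naive_p[r] <- cut$naive_p
    }
  })
  perm_p <- vapply(seq_len(reps), function(r) {
    mean(max_stat[-r] >= max_stat[r])
  }, numeric(1))
  expect_gte(mean(naive_p < perm_p), 0.9)
})

test_that("the full scoring chain is deterministic under a fixed seed", {
  coh <- cached_cohort("mid_default", mid_config(seed = 43, n_samples = 400))
  gl <- cohort_gene_log2(coh)
  labels <- coh$truth$subtype
  run_once <- function() {
    deg <- moderated_t(gl, factor(labels[colnames(gl)]))
    sel <- suppressMessages(select_signature(deg, gl, coh$clinical, labels,
                                             seed = 77))
    sets <- partition_sets(gl, sel, labels)
    esc <- compute_escore(gl, sets)
    cut <- suppressMessages(optimal_cutpoint(esc, coh$clinical))
    list(sel = as.character(sel), score = esc$e_score,
         cutpoint = cut$cutpoint, groups = cut$groups$group)
  }
  expect_identical(run_once(), run_once())
})
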