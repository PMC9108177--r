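# eRNA-gene pairing and pair-table summaries.

make_pair_fixture <- function(n = 30, seed = 5) {
  withr::with_seed(seed, {
    samples <- sprintf("s%02d", 1:n)
    e <- matrix(rnorm(3 * n), 3, n, dimnames = list(c("e1", "e2", "e3"), samples))
    g <- rbind(e[1, ] + rnorm(n, 0, 0.1),  # strongly co-expressed with e1
               matrix(rnorm(2 * n), 2, n))
    rownames(g) <- c("gA", "gB", "gC"); colnames(g) <- samples
    regions <- tibble::tibble(erna_id = c("e1", "e2", "e3"), chrom = "chr1",
                              start = c(0, 2e6, 5e6), end = c(3e3, 2e6 + 3e3, 5e6 + 3e3),
                              midpoint = c(1500, 2e6 + 1500, 5e6 + 1500))
    genes <- tibble::tibble(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                            strand = "+",
                            tss = c(5000, 1500 + 1e6 + 1, 5e6 + 8e5),
                            tes = c(9000, 1500 + 1e6 + 5000, 5e6 + 9e5),
                            exons = list(tibble::tibble(), tibble::tibble(),
                                         tibble::tibble()))
    list(e = expr_matrix(e, "RPM"), g = expr_matrix(g, "log2"),
         regions = regions, genes = genes)
  })
}

test_that("pairing keeps identical profiles and enforces the 1 Mb bound", {
  fx <- make_pair_fixture()
  # gene identical to the eRNA: rho = 1, retained
  g2 <- fx$g; g2["gA", ] <- fx$e["e1", ]
  pr <- pair_genes(fx$e, expr_matrix(g2, "log2"), fx$regions, fx$genes)
  expect_true(any(pr$erna_id == "e1" & pr$gene_id == "gA" & abs(pr$rho - 1) < 1e-9))
  # gB sits exactly 1,000,001 bp from e1's midpoint: never a candidate
  all_pairs <- pair_genes(fx$e, fx$g, fx$regions, fx$genes, keep_all = TRUE)
  expect_false(any(all_pairs$erna_id == "e1" & all_pairs$gene_id == "gB"))
  expect_true(all(all_pairs$distance <= 1e6))
  expect_true(all(all_pairs$fdr >= all_pairs$p_value))
  expect_true(all(all_pairs$gene_rank >= 1))
})

test_that("pairing equals the brute-force oracle and recovers planted pairs", {
  coh <- ref_cohort()
  ann <- coh$annotation
  retained <- suppressWarnings(filter_enhancers(ann$enhancers, ann$genes))
  regions <- derive_regions(retained)
  rpm <- cohort_erna_rpm(coh)
  act <- suppressMessages(call_active(rpm[regions$erna_id, , drop = FALSE]))
  arpm <- rpm[act$erna_id[act$active], , drop = FALSE]
  gl <- cohort_gene_log2(coh)

  pr <- pair_genes(arpm, gl, regions, ann$genes)
  truth <- paste(coh$truth$pairs$erna_id, coh$truth$pairs$gene_id)
  expect_gte(mean(truth %in% paste(pr$erna_id, pr$gene_id)), 0.9)

  # exact agreement with the all-pairs cor.test oracle on a subset
  sub_regions <- regions[regions$erna_id %in% head(rownames(arpm), 15), ]
  orc <- oracle_pairs(arpm, gl, sub_regions, ann$genes)
  mine <- pair_genes(arpm[head(rownames(arpm), 15), , drop = FALSE],
                     gl, sub_regions, ann$genes)
  expect_setequal(paste(mine$erna_id, mine$gene_id),
                  paste(orc$erna_id, orc$gene_id))
  m <- mine[order(mine$erna_id, mine$gene_id), ]
  o <- orc[order(orc$erna_id, orc$gene_id), ]
  expect_equal(unname(m$rho), unname(o$rho), tolerance = 1e-8)
  expect_equal(unname(m$distance), unname(o$distance))
})

test_that("pairing is invariant to sample and feature order", {
  fx <- make_pair_fixture(seed = 8)
  base <- pair_genes(fx$e, fx$g, fx$regions, fx$genes, keep_all = TRUE)
  perm_s <- sample(colnames(fx$e))
  perm_f <- sample(rownames(fx$e))
  shuffled <- pair_genes(
    fx$e[perm_f, perm_s], fx$g[, perm_s],
    fx$regions[sample(1:3), ], fx$genes, keep_all = TRUE)
  key <- function(x) x[order(x$erna_id, x$gene_id),
                       c("erna_id", "gene_id", "distance", "rho", "p_value", "fdr")]
  expect_equal(key(shuffled), key(base), tolerance = 1e-12)
})

test_that("the printed single-eRNA gene percentage arises from the tally", {
  # 4,459 genes of which 2,664 pair with exactly one eRNA -> 59.74%
  genes <- sprintf("g%04d", 1:4459)
  single <- genes[1:2664]
  multi <- genes[2665:4459]
  pairs <- tibble::tibble(
    erna_id = c(sprintf("e%04d", seq_along(single)),
                rep(sprintf("m%04d", seq_along(multi)), each = 2)),
    gene_id = c(single, rep(multi, each = 2)),
    rho = 0.5, gene_rank = 1L)
  s <- summarize_pairs(pairs)
  expect_equal(s$single_partner$pct[s$single_partner$entity == "gene"], 59.74)
  expect_equal(s$single_partner$total[s$single_partner$entity == "gene"], 4459)
})

test_that("pair summaries handle boundary and null cases", {
  one_each <- tibble::tibble(erna_id = c("e1", "e2"), gene_id = c("g1", "g2"),
                             rho = c(0.4, -0.5), gene_rank = c(1L, 1L))
  s <- summarize_pairs(one_each)
  expect_equal(s$single_partner$pct, c(100, 100))
  expect_equal(s$rho_by_rank$mean_abs_rho, 0.45)

  empty <- summarize_pairs(one_each[0, ])
  expect_equal(empty$single_partner$total, c(0L, 0L))
  expect_equal(nrow(empty$genes_per_erna), 0)

  # identical expression distributions in the two groups: rank-sum p = 1
  expr <- expr_matrix(matrix(c(1, 7, 1, 7), 4, 4,
                             dimnames = list(c("g1", "g2", "g3", "g4"),
                                             sprintf("s%d", 1:4))), "log2")
  activity <- tibble::tibble(erna_id = c("e1", "e2", "e3", "e4"),
                             max_rpm = c(2, 2, 0.1, 0.1),
                             active = c(TRUE, TRUE, FALSE, FALSE))
  nearest <- tibble::tibble(erna_id = activity$erna_id,
                            gene_id = c("g1", "g2", "g3", "g4"))
  s2 <- summarize_pairs(one_each, activity = activity, gene_expr = expr,
                        nearest = nearest)
  expect_equal(s2$activity_expression$ranksum_p[1], 1)
})
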