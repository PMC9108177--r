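# Shared simulated cohorts, cached so several test files can reuse them.

.cohort_cache <- new.env(parent = emptyenv())

# Compact configuration used where full cohort scale is unnecessary.
tiny_config <- function(seed = 1L, ...) {
  defaults <- list(n_samples = 60, n_genes = 60, n_enhancers = 30,
                   chrom_length = 2e7, n_immune_sets = 3, markers_per_set = 5,
                   n_pairs = 3, n_ir_ernas = 4, n_signature_genes = 8,
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Mid-size configuration for recovery checks.
mid_config <- function(seed = 1L, ...) {
  defaults <- list(n_samples = 200, n_genes = 250, n_enhancers = 120,
                   chrom_length = 3e7, n_immune_sets = 8, markers_per_set = 8,
                   n_pairs = 20, n_ir_ernas = 20, n_signature_genes = 30,
                   seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

cached_cohort <- function(key, config) {
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- suppressMessages(simulate_cohort(config))
  }
  .cohort_cache[[key]]
}

# Default reference cohort (the study conditions).
ref_cohort <- function() cached_cohort("ref", sim_config(seed = 101L))

# Library sizes and derived matrices for a cohort.
cohort_lib <- function(coh) colSums(coh$gene_counts) + colSums(coh$erna_counts)

cohort_gene_log2 <- function(coh) {
  lib <- cohort_lib(coh)
  expr_matrix(log2(sweep(coh$gene_counts, 2, lib / 1e6, "/") + 1), "log2")
}

cohort_erna_rpm <- function(coh) {
  suppressWarnings(rpm_normalize(coh$erna_counts, cohort_lib(coh)))
}

# Simple synthetic clinical table with exponential survival.
make_clinical <- function(n, rate = 1 / 24, censor = NULL, seed = NULL,
                          lp = rep(0, n)) {
  gen <- function() {
    t_ev <- rexp(n, rate * exp(lp))
    if (is.null(censor)) {
      time <- t_ev; event <- rep(1L, n)
    } else {
      t_c <- runif(n, 0, censor)
      time <- pmin(t_ev, t_c); event <- as.integer(t_ev <= t_c)
    }
    tibble::tibble(sample_id = sprintf("p%03d", seq_len(n)),
                   time = pmax(time, 1.01), event = event)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
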