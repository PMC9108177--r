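# Enhancer-gene pairing by genomic proximity plus rank correlation, and
# descriptive summaries of the resulting pair table.

# Exact permutation null of Spearman's rho for untied ranks, cached per n.
perm_rho_env <- new.env(parent = emptyenv())
perm_rho_null <- function(n) {
  key <- as.character(n)
  if (!is.null(perm_rho_env[[key]])) return(perm_rho_env[[key]])
  perms <- permutations_of(n)
  base <- seq_len(n)
  denom <- n * (n^2 - 1)
  rho <- apply(perms, 1L, function(p) 1 - 6 * sum((base - p)^2) / denom)
  perm_rho_env[[key]] <- rho
  rho
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (i in seq_len(n)) {
    block <- cbind(rep(i, nrow(sub)), ifelse(sub >= i, sub + 1L, sub))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# Two-sided p for Spearman rho: exact permutation null when n <= 9 and the
# ranks are untied, t approximation otherwise.
spearman_p <- function(rho, n, tied = TRUE) {
  if (n <= 9 && !tied) {
    null <- perm_rho_null(n)
    return(map_dbl(rho, function(r) mean(abs(null) >= abs(r) - 1e-12)))
  }
  r <- pmin(pmax(rho, -1), 1)
  t_stat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(t_stat), df = n - 2)
  p[abs(r) >= 1 - 1e-12] <- 0
  p
}

# Row-standardized rank matrix (samples in columns); constant rows -> NA.
rank_standardize <- function(x) {
  rk <- t(apply(x, 1L, rank, ties.method = "average"))
  if (nrow(x) == 1L) rk <- matrix(rk, 1L, ncol(x), dimnames = dimnames(x))
  mu <- rowMeans(rk)
  s <- sqrt(rowSums((rk - mu)^2))
  z <- (rk - mu) / ifelse(s == 0, NA_real_, s)
  attr(z, "tied") <- apply(x, 1L, function(v) anyDuplicated(v) > 0L)
  z
}

#' Pair eRNAs with genes by proximity and co-expression
#'
#' Candidate pairs are all (eRNA, gene) combinations on the same chromosome
#' with `|gene TSS - eRNA midpoint| <= max_distance`. Spearman correlation
#' and its p-value are computed over the shared samples of the two
#' matrices, the Benjamini-Hochberg FDR is taken across all candidate
#' pairs jointly (or per eRNA via `fdr_scope`), and pairs with
#' `|rho| > rho_min` and `fdr < fdr_max` are returned. `gene_rank` orders
#' each eRNA's candidate genes by distance (1 = closest; ties broken by
#' gene id).
#'
#' @param erna_rpm eRNA expression matrix (any unit; correlations are
#'   rank-based).
#' @param gene_expr Gene expression matrix sharing >= 3 samples with
#'   `erna_rpm`.
#' @param regions eRNA region tibble from [derive_regions()].
#' @param genes Gene model tibble.
#' @param max_distance Maximum TSS-to-midpoint distance in bp (default
#'   1 Mb).
#' @param rho_min Retain pairs with `|rho|` strictly above this (default
#'   0.3).
#' @param fdr_max Retain pairs with FDR strictly below this (default 0.05).
#' @param method `"spearman"` (default) or `"pearson"` for the correlation
#'   used in pairing.
#' @param fdr_scope `"global"` (default) pools all candidate pairs for the
#'   BH adjustment; `"per_erna"` adjusts within each eRNA's candidates.
#' @param keep_all Return all candidate pairs (with a `retained` flag)
#'   instead of only the retained ones.
#' @return Tibble with `erna_id`, `gene_id`, `chrom`, `distance`, `rho`,
#'   `p_value`, `fdr`, `gene_rank`, sorted by eRNA then distance.
#' @export
pair_genes <- function(erna_rpm, gene_expr, regions, genes,
                       max_distance = 1e6, rho_min = 0.3, fdr_max = 0.05,
                       method = c("spearman", "pearson"),
                       fdr_scope = c("global", "per_erna"),
                       keep_all = FALSE) {
  method <- match.arg(method)
  fdr_scope <- match.arg(fdr_scope)
  common <- shared_samples(erna_rpm, gene_expr, min_n = 3L)
  n <- length(common)

  reg <- filter(as_tibble(regions), .data$erna_id %in% rownames(erna_rpm))
  gen <- filter(as_tibble(genes), .data$gene_id %in% rownames(gene_expr))
  cand <- bind_rows(map(split(seq_len(nrow(reg)), reg$chrom), function(idx) {
    ch <- reg$chrom[idx[1]]
    g <- gen[gen$chrom == ch, ]
    if (!nrow(g)) return(NULL)
    bind_rows(map(idx, function(i) {
      d <- abs(g$tss - reg$midpoint[i])
      hit <- which(d <= max_distance)
      if (!length(hit)) return(NULL)
      tibble(erna_id = reg$erna_id[i], gene_id = g$gene_id[hit],
             chrom = ch, distance = d[hit])
    }))
  }))
  if (is.null(cand) || !nrow(cand)) {
    out <- tibble(erna_id = character(), gene_id = character(),
                  chrom = character(), distance = numeric(), rho = numeric(),
                  p_value = numeric(), fdr = numeric(), gene_rank = integer())
    return(out)
  }

  e_mat <- erna_rpm[unique(cand$erna_id), common, drop = FALSE]
  g_mat <- gene_expr[unique(cand$gene_id), common, drop = FALSE]
  if (method == "spearman") {
    ze <- rank_standardize(e_mat); zg <- rank_standardize(g_mat)
    tied_e <- attr(ze, "tied"); tied_g <- attr(zg, "tied")
  } else {
    std <- function(m) {
      mu <- rowMeans(m); s <- sqrt(rowSums((m - mu)^2))
      (m - mu) / ifelse(s == 0, NA_real_, s)
    }
    ze <- std(e_mat); zg <- std(g_mat)
    tied_e <- rep(TRUE, nrow(e_mat)); tied_g <- rep(TRUE, nrow(g_mat))
    names(tied_e) <- rownames(e_mat); names(tied_g) <- rownames(g_mat)
  }
  ei <- match(cand$erna_id, rownames(e_mat))
  gi <- match(cand$gene_id, rownames(g_mat))
  cand$rho <- unname(rowSums(ze[ei, , drop = FALSE] * zg[gi, , drop = FALSE]))
  tied <- tied_e[ei] | tied_g[gi]
  if (method == "spearman") {
    cand$p_value <- NA_real_
    ok <- !is.na(cand$rho)
    cand$p_value[ok & !tied] <- spearman_p(cand$rho[ok & !tied], n, tied = FALSE)
    cand$p_value[ok & tied] <- spearman_p(cand$rho[ok & tied], n, tied = TRUE)
  } else {
    cand$p_value <- ifelse(is.na(cand$rho), NA_real_,
                           spearman_p(cand$rho, n, tied = TRUE))
  }
  # constant features give undefined correlation; treat as non-signal
  cand$rho[is.na(cand$rho)] <- 0
  cand$p_value[is.na(cand$p_value)] <- 1

  cand <- cand |>
    arrange(.data$erna_id, .data$distance, .data$gene_id) |>
    group_by(.data$erna_id) |>
    mutate(gene_rank = row_number()) |>
    ungroup()
  if (fdr_scope == "global") {
    cand$fdr <- bh_adjust(cand$p_value)
  } else {
    cand <- cand |>
      group_by(.data$erna_id) |>
      mutate(fdr = bh_adjust(.data$p_value)) |>
      ungroup()
  }
  cand$retained <- abs(cand$rho) > rho_min & cand$fdr < fdr_max
  if (keep_all) cand else select(filter(cand, .data$retained), -"retained")
}

#' Summarize an eRNA-gene pair table
#'
#' Computes the degree distributions of the pairing graph (genes per eRNA,
#' eRNAs per gene), the percentage of eRNAs/genes with exactly one partner
#' (rounded to 2 decimals), the mean absolute correlation by distance rank
#' (closest through 4th-closest gene), and optionally a Wilcoxon rank-sum
#' comparison of nearest-gene expression between active and inactive eRNAs.
#'
#' @param pairs Pair tibble from [pair_genes()].
#' @param activity Optional activity tibble from [call_active()].
#' @param gene_expr Optional gene expression matrix for the rank-sum
#'   comparison.
#' @param nearest Optional tibble (`erna_id`, `gene_id`) mapping every eRNA
#'   to its nearest gene; required for the rank-sum comparison.
#' @return A list with `genes_per_erna`, `ernas_per_gene`, `single_partner`
#'   (pct with exactly one partner), `rho_by_rank`, and optionally
#'   `activity_expression` (group means and rank-sum p-value).
#' @export
summarize_pairs <- function(pairs, activity = NULL, gene_expr = NULL,
                            nearest = NULL) {
  pairs <- as_tibble(pairs)
  if (!nrow(pairs)) {
    return(list(
      genes_per_erna = tibble(n_partners = integer(), n = integer()),
      ernas_per_gene = tibble(n_partners = integer(), n = integer()),
      single_partner = tibble(entity = c("erna", "gene"), total = c(0L, 0L),
                              n_single = c(0L, 0L), pct = c(NA_real_, NA_real_)),
      rho_by_rank = tibble(gene_rank = integer(), mean_abs_rho = numeric(),
                           n = integer())
    ))
  }
  deg_e <- count(pairs, .data$erna_id, name = "n_partners")
  deg_g <- count(pairs, .data$gene_id, name = "n_partners")
  hist_e <- count(deg_e, .data$n_partners, name = "n")
  hist_g <- count(deg_g, .data$n_partners, name = "n")
  single <- tibble(
    entity = c("erna", "gene"),
    total = c(nrow(deg_e), nrow(deg_g)),
    n_single = c(sum(deg_e$n_partners == 1L), sum(deg_g$n_partners == 1L))
  )
  single$pct <- round(100 * single$n_single / single$total, 2)
  rho_by_rank <- pairs |>
    filter(.data$gene_rank <= 4L) |>
    group_by(.data$gene_rank) |>
    summarise(mean_abs_rho = mean(abs(.data$rho)), n = n(), .groups = "drop")
  out <- list(genes_per_erna = hist_e, ernas_per_gene = hist_g,
              single_partner = single, rho_by_rank = rho_by_rank)
  if (!is.null(activity) && !is.null(gene_expr) && !is.null(nearest)) {
    nn <- left_join(as_tibble(nearest), activity, by = "erna_id") |>
      filter(.data$gene_id %in% rownames(gene_expr), !is.na(.data$active))
    expr_mean <- rowMeans(gene_expr)[nn$gene_id]
    grp_active <- expr_mean[nn$active]
    grp_inactive <- expr_mean[!nn$active]
    p <- if (length(grp_active) && length(grp_inactive)) {
      if (identical(sort(unname(grp_active)), sort(unname(grp_inactive)))) {
        1 # identical distributions carry no evidence of a difference
      } else {
        stats::wilcox.test(grp_active, grp_inactive, exact = FALSE)$p.value
      }
    } else NA_real_
    out$activity_expression <- tibble(
      group = c("active", "inactive"),
      n = c(length(grp_active), length(grp_inactive)),
      mean_expr = c(mean(grp_active), mean(grp_inactive)),
      ranksum_p = p
    )
  }
  out
}

#' Nearest gene for each eRNA region
#'
#' @param regions eRNA region tibble from [derive_regions()].
#' @param genes Gene model tibble.
#' @return Tibble (`erna_id`, `gene_id`, `distance`) with the closest TSS
#'   on the same chromosome (ties broken by gene id).
#' @export
nearest_genes <- function(regions, genes) {
  reg <- as_tibble(regions); gen <- as_tibble(genes)
  bind_rows(map(seq_len(nrow(reg)), function(i) {
    g <- gen[gen$chrom == reg$chrom[i], ]
    if (!nrow(g)) return(NULL)
    d <- abs(g$tss - reg$midpoint[i])
    o <- order(d, g$gene_id)
    tibble(erna_id = reg$erna_id[i], gene_id = g$gene_id[o[1]], distance = d[o[1]])
  }))
}
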