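# Consensus clustering into immune subtypes, empirical-Bayes moderated
# t-tests, Benjamini-Hochberg adjustment, and PCA views.

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-invariant implementation of the BH step-up rule with enforced
#' monotonicity.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("p must be numeric")
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  adj_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# Newton inversion of the trigamma function (for the prior-df estimate).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-8) break
  }
  x
}

#' Moderated two-group t-tests with empirical-Bayes variance shrinkage
#'
#' Per gene, the two-sample mean difference and pooled residual variance
#' `s^2` (with `d = n1 + n2 - 2` df) are computed; a scaled-F model for
#' the marginal distribution of `log s^2` yields prior df `d0` and prior
#' variance `s0^2` by method-of-moments (digamma/trigamma matching). The
#' posterior variance `s2_post = (d0 s0^2 + d s^2) / (d0 + d)` replaces
#' `s^2` in the t statistic, which gains `d0` degrees of freedom. With
#' `prior_df = 0` the statistic reduces exactly to the ordinary pooled
#' t-test; with `prior_df = Inf` all genes share `s0^2`.
#'
#' @param expr Log2-scale expression matrix (features x samples).
#' @param labels Two-group factor/character vector aligned with the
#'   columns of `expr` (each group needs >= 2 samples). The reported
#'   `mean_diff` is group 1 minus group 2 in level order.
#' @param prior_df Optional override of the estimated prior df `d0`.
#' @return A tibble with `gene_id`, `mean_diff`, `s2`, `s2_post`, `t_mod`,
#'   `p_value`, `adj_p` (BH), carrying the shared `d0` and `s0_2` as
#'   attributes. Genes with zero variance and zero mean difference get
#'   `p = 1` by convention.
#' @export
moderated_t <- function(expr, labels, prior_df = NULL) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) abort("labels must define exactly two groups")
  if (length(labels) != ncol(expr)) abort("labels must align with expr columns")
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) abort("each group needs at least 2 samples")
  d <- n1 + n2 - 2

  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m2 <- rowMeans(expr[, !g1, drop = FALSE])
  v1 <- apply(expr[, g1, drop = FALSE], 1L, var)
  v2 <- apply(expr[, !g1, drop = FALSE], 1L, var)
  mean_diff <- m1 - m2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / d

  pos <- s2 > 0
  z <- log(s2[pos])
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- var(e) - trigamma(d / 2)
  if (sum(pos) < 2 || !is.finite(evar)) {
    d0 <- Inf
    s0_2 <- if (sum(pos)) exp(mean(e)) else 1
  } else if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  } else {
    warn("variance underdispersion: prior df set to Inf (complete shrinkage)")
    d0 <- Inf
    s0_2 <- exp(mean(e))
  }
  if (!is.null(prior_df)) d0 <- prior_df

  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2)) else (d0 * s0_2 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, mean_diff / se, ifelse(mean_diff == 0, 0, Inf * sign(mean_diff)))
  df_total <- d0 + d
  p <- if (is.infinite(df_total)) 2 * pnorm(-abs(t_mod)) else 2 * pt(-abs(t_mod), df = df_total)
  degenerate <- s2 == 0 & mean_diff == 0
  t_mod[degenerate] <- 0
  p[degenerate] <- 1

  out <- tibble(gene_id = rownames(expr), mean_diff = unname(mean_diff),
                s2 = unname(s2), s2_post = unname(s2_post),
                t_mod = unname(t_mod), p_value = unname(p),
                adj_p = bh_adjust(unname(p)))
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  attr(out, "df_total") <- df_total
  out
}

#' Consensus clustering of samples by subsampled k-medoids
#'
#' For each candidate `k`, samples are repeatedly subsampled and
#' partitioned by k-medoids (PAM) under correlation distance
#' (`1 - Pearson`); the consensus matrix records, for every sample pair,
#' the fraction of co-subsampled runs in which the pair co-clustered.
#' Final labels come from Ward hierarchical clustering of
#' `1 - consensus` cut at `k`. The number of clusters is chosen by
#' minimizing the proportion of ambiguous clustering (PAC: consensus
#' entries strictly between 0.1 and 0.9), with ties broken toward the
#' smaller `k`; the classic change-in-CDF-area diagnostics are also
#' reported (`cdf_area`, `delta_area`). Randomness enters only through
#' the subsampling; PAM uses its deterministic build/swap steps.
#'
#' @param expr Expression matrix (features x samples); rows are z-scored
#'   internally.
#' @param k_range Candidate cluster counts (default `2:6`).
#' @param reps Subsampling iterations per `k` (default 1000).
#' @param subsample Fraction of samples drawn per iteration (default 0.8).
#' @param seed Integer seed for the subsampling stream.
#' @param linkage Linkage for the final hierarchical step (default
#'   `"ward.D"`).
#' @param pac_limits Consensus interval whose occupancy defines PAC
#'   (default `c(0.1, 0.9)`).
#' @return An object of class `consensus_result` with elements
#'   `consensus` (per-k matrices), `labels` (per-k), `cdf_area`,
#'   `delta_area`, `pac`, `chosen_k`, and the chosen labels; see
#'   [tidy()], [glance()], [autoplot()].
#' @export
consensus_cluster <- function(expr, k_range = 2:6, reps = 1000,
                              subsample = 0.8, seed = 1L,
                              linkage = "ward.D", pac_limits = c(0.1, 0.9)) {
  n <- ncol(expr)
  if (n < 2 * max(k_range)) {
    abort(sprintf("need at least %d samples for k up to %d", 2 * max(k_range), max(k_range)))
  }
  z <- standardize_rows(expr)
  D <- 1 - stats::cor(z)
  samples <- colnames(expr)
  m <- ceiling(subsample * n)

  with_preserved_seed(seed, function() {
    consensus <- list(); labels <- list()
    for (k in k_range) {
      co <- matrix(0, n, n); tog <- matrix(0, n, n)
      for (r in seq_len(reps)) {
        idx <- sort(sample.int(n, m))
        cl <- cluster::pam(as.dist(D[idx, idx]), k = k, diss = TRUE,
                           cluster.only = TRUE)
        same <- outer(cl, cl, "==") * 1
        co[idx, idx] <- co[idx, idx] + same
        tog[idx, idx] <- tog[idx, idx] + 1
      }
      if (any(tog == 0)) {
        abort("some sample pair was never co-subsampled; increase reps")
      }
      cm <- co / tog
      diag(cm) <- 1
      dimnames(cm) <- list(samples, samples)
      hc <- hclust(as.dist(1 - cm), method = linkage)
      lab <- cutree(hc, k = k)
      consensus[[as.character(k)]] <- cm
      labels[[as.character(k)]] <- lab
    }
    area <- map_dbl(consensus, function(cm) {
      v <- sort(cm[upper.tri(cm)])
      cdf <- ecdf(v)
      xs <- sort(unique(v))
      if (length(xs) < 2) return(0)
      sum(diff(xs) * cdf(xs[-length(xs)]))
    })
    delta <- numeric(length(k_range))
    delta[1] <- area[1]
    if (length(k_range) > 1) {
      delta[-1] <- diff(area) / head(area, -1)
    }
    names(delta) <- names(area)
    pac <- map_dbl(consensus, function(cm) {
      v <- cm[upper.tri(cm)]
      mean(v > pac_limits[1] & v < pac_limits[2])
    })
    chosen_k <- k_range[which.min(pac)] # which.min takes the first minimum
    structure(list(
      k_range = k_range, consensus = consensus, labels = labels,
      cdf_area = area, delta_area = delta, pac = pac, chosen_k = chosen_k,
      chosen_labels = labels[[as.character(chosen_k)]],
      params = list(reps = reps, subsample = subsample, seed = seed,
                    linkage = linkage, pac_limits = pac_limits)
    ), class = "consensus_result")
  })
}

#' @method tidy consensus_result
#' @export
tidy.consensus_result <- function(x, k = x$chosen_k, ...) {
  lab <- x$labels[[as.character(k)]]
  tibble(sample_id = names(lab), cluster = unname(lab), k = k)
}

#' @method glance consensus_result
#' @export
glance.consensus_result <- function(x, ...) {
  tibble(chosen_k = x$chosen_k,
         k = x$k_range,
         cdf_area = unname(x$cdf_area),
         delta_area = unname(x$delta_area),
         pac = unname(x$pac))
}

#' @method print consensus_result
#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("Consensus clustering over k = %s (reps = %d, subsample = %.2f)\n",
              paste(range(x$k_range), collapse = ".."),
              x$params$reps, x$params$subsample))
  cat(sprintf("chosen k = %d; cluster sizes: %s\n", x$chosen_k,
              paste(table(x$chosen_labels), collapse = ", ")))
  invisible(x)
}

#' @method autoplot consensus_result
#' @export
autoplot.consensus_result <- function(object, k = object$chosen_k, ...) {
  cm <- object$consensus[[as.character(k)]]
  ord <- order(object$labels[[as.character(k)]])
  df <- as_tibble(as.data.frame.table(cm[ord, ord], stringsAsFactors = FALSE))
  names(df) <- c("sample_i", "sample_j", "consensus")
  df$sample_i <- factor(df$sample_i, levels = colnames(cm)[ord])
  df$sample_j <- factor(df$sample_j, levels = colnames(cm)[ord])
  ggplot2::ggplot(df, ggplot2::aes(.data$sample_i, .data$sample_j,
                                   fill = .data$consensus)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#08306b", limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "consensus",
                  title = sprintf("Consensus matrix (k = %d)", k)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' PCA view of samples
#'
#' Features are z-scored, samples are projected onto the leading principal
#' components, and each component is oriented so its largest-magnitude
#' loading is positive (a deterministic sign convention).
#'
#' @param expr Expression matrix (features x samples).
#' @param n_components Number of components (must not exceed
#'   `min(dim(expr))`).
#' @return A list of class `pca_view`: `scores` tibble (sample_id, PC1,
#'   ...), `loadings` matrix, `var_explained` fractions.
#' @export
pca_view <- function(expr, n_components = 2) {
  if (n_components > min(dim(expr))) {
    abort("n_components exceeds the matrix rank bound")
  }
  z <- standardize_rows(expr)
  pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
  k <- n_components
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(
    scores = bind_cols(tibble(sample_id = colnames(expr)), as_tibble(scores)),
    loadings = load,
    var_explained = ve[seq_len(k)]
  ), class = "pca_view")
}

#' @method autoplot pca_view
#' @export
autoplot.pca_view <- function(object, colour = NULL, ...) {
  df <- object$scores
  if (!is.null(colour)) df$group <- colour[df$sample_id]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(colour)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  } else {
    p + ggplot2::geom_point()
  }
}
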