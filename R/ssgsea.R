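# Single-sample gene set enrichment (ssGSEA) and ESTIMATE-style summary
# scores.

#' Single-sample gene set enrichment scores
#'
#' For each sample, genes are ranked by expression (average ranks for
#' ties). Walking down the list in decreasing expression order, the
#' enrichment score is the sum, over all list positions, of the difference
#' between the weighted in-set empirical CDF (gene weights = rank^`alpha`)
#' and the unweighted out-of-set empirical CDF. Within-sample ties in
#' expression are walked in feature-name order so scores are deterministic.
#' Being rank-based, scores are invariant to any strictly monotone
#' transform of a sample's expression values.
#'
#' @param expr Expression matrix (features x samples), any unit.
#' @param sets Named list of gene-id vectors; members absent from `expr`
#'   are dropped (with a note). A set with no members present scores `NA`.
#' @param alpha Rank-weighting exponent (default 0.25).
#' @param normalize Divide all scores by the range (max - min) of the
#'   computed score matrix (default `TRUE`).
#' @return Numeric matrix, samples in rows, sets in columns.
#' @export
ssgsea <- function(expr, sets, alpha = 0.25, normalize = TRUE) {
  sets <- validate_gene_sets(sets)
  feats <- rownames(expr)
  n_feat <- length(feats)
  kept <- lapply(sets, intersect, y = feats)
  n_dropped <- sum(lengths(sets) - lengths(kept))
  if (n_dropped > 0) {
    inform(sprintf("%d set member(s) absent from the expression matrix", n_dropped))
  }
  full <- lengths(kept) == n_feat
  if (any(full)) {
    abort(sprintf("set '%s' covers all features; out-of-set ECDF undefined",
                  names(sets)[full][1]))
  }
  scores <- matrix(NA_real_, ncol(expr), length(sets),
                   dimnames = list(colnames(expr), names(sets)))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    rk <- rank(x, ties.method = "average")
    ord <- order(-x, feats) # decreasing expression, ties by feature name
    w <- rk[ord]^alpha
    for (s in seq_along(kept)) {
      members <- kept[[s]]
      if (!length(members)) next
      in_set <- feats[ord] %in% members
      w_in <- w * in_set
      ecdf_in <- cumsum(w_in) / sum(w_in)
      ecdf_out <- cumsum(!in_set) / (n_feat - length(members))
      scores[j, s] <- sum(ecdf_in - ecdf_out)
    }
  }
  if (normalize) {
    rng <- range(scores, na.rm = TRUE)
    if (diff(rng) > 0) scores <- scores / diff(rng)
  }
  scores
}

#' ESTIMATE-style stromal, immune and purity scores
#'
#' Stromal and immune scores are unnormalized ssGSEA enrichment sums of
#' the two signatures; the ESTIMATE score is their sum. Tumor purity uses
#' the published transformation `cos(a + b * estimate)`, whose constants
#' were derived on a specific expression platform, so the purity formula
#' is opt-in and disabled by default on other data.
#'
#' @param expr Expression matrix (features x samples).
#' @param stromal_set,immune_set Character vectors of signature gene ids.
#' @param purity_formula Apply the cosine purity transformation?
#' @param purity_constants Named vector `c(a, b)` of the transformation
#'   constants.
#' @param alpha ssGSEA exponent passed through.
#' @return Tibble with `sample_id`, `stromal_score`, `immune_score`,
#'   `estimate_score`, `tumor_purity` (NA unless `purity_formula`).
#' @export
estimate_scores <- function(expr, stromal_set, immune_set,
                            purity_formula = FALSE,
                            purity_constants = c(a = 0.6049872018, b = 0.0001467884),
                            alpha = 0.25) {
  ss <- ssgsea(expr, list(stromal = stromal_set, immune = immune_set),
               alpha = alpha, normalize = FALSE)
  if (anyNA(ss)) abort("stromal/immune signature could not be resolved against expr")
  out <- tibble(
    sample_id = rownames(ss),
    stromal_score = ss[, "stromal"],
    immune_score = ss[, "immune"],
    estimate_score = ss[, "stromal"] + ss[, "immune"]
  )
  if (purity_formula) {
    if (is.null(purity_constants) || !all(c("a", "b") %in% names(purity_constants))) {
      abort("purity requested but purity_constants are disabled")
    }
    p <- cos(purity_constants[["a"]] + purity_constants[["b"]] * out$estimate_score)
    out$tumor_purity <- pmin(pmax(p, 0), 1)
  } else {
    out$tumor_purity <- NA_real_
  }
  out
}
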