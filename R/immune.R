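# Immune-related eRNA identification and the univariate-Cox prognostic
# feature filter.

#' Identify immune-related eRNAs (ir-eRNAs)
#'
#' An eRNA is immune-related when its expression has
#' `|Spearman rho| > rho_min` with `p < p_max` for at least one immune
#' cell type's abundance score. P-values are unadjusted by default (the
#' convention for this screen); `adjust = TRUE` applies a BH correction
#' across all (eRNA, cell type) tests as a sensitivity mode.
#'
#' @param erna_rpm eRNA expression matrix (features x samples); Spearman
#'   makes the unit immaterial.
#' @param cell_scores Sample x cell-type score matrix as returned by
#'   [ssgsea()].
#' @param rho_min Absolute-correlation threshold (strict, default 0.3).
#' @param p_max P-value threshold (strict, default 0.05).
#' @param adjust Apply BH across all tests before thresholding.
#' @return Tibble with `erna_id`, `best_cell_type` (largest `|rho|`),
#'   `rho`, `p_value` (of the best cell type), `is_ir`. Constant eRNA rows
#'   are excluded with a warning.
#' @export
identify_ir_ernas <- function(erna_rpm, cell_scores, rho_min = 0.3,
                              p_max = 0.05, adjust = FALSE) {
  cs <- t(as.matrix(cell_scores)) # cell types x samples
  common <- shared_samples(erna_rpm, cs, min_n = 3L)
  n <- length(common)
  e <- erna_rpm[, common, drop = FALSE]
  cs <- cs[, common, drop = FALSE]

  ze <- rank_standardize(e)
  zc <- rank_standardize(cs)
  tied_e <- attr(ze, "tied")
  const_e <- rowSums(!is.na(ze)) == 0L
  if (any(const_e)) {
    warn(sprintf("%d constant eRNA row(s) excluded (correlation undefined)",
                 sum(const_e)))
    ze <- ze[!const_e, , drop = FALSE]
    tied_e <- tied_e[!const_e]
  }
  if (!nrow(ze)) abort("no non-constant eRNAs to test")
  rho <- ze %*% t(zc) # eRNAs x cell types
  tied <- outer(tied_e, attr(zc, "tied"), `|`)
  p <- matrix(spearman_p(as.vector(rho), n, tied = TRUE), nrow(rho), ncol(rho),
              dimnames = dimnames(rho))
  if (n <= 9) {
    untied <- !tied
    if (any(untied)) {
      p[untied] <- spearman_p(rho[untied], n, tied = FALSE)
    }
  }
  if (adjust) p[] <- bh_adjust(as.vector(p))

  best <- apply(abs(rho), 1L, which.max)
  idx <- cbind(seq_len(nrow(rho)), best)
  tibble(
    erna_id = rownames(rho),
    best_cell_type = colnames(rho)[best],
    rho = rho[idx],
    p_value = p[idx],
    is_ir = apply(abs(rho) > rho_min & p < p_max, 1L, any)
  )
}

#' Univariate-Cox prognostic feature filter
#'
#' Fits a univariate Cox proportional-hazards model per feature on its
#' standardized expression (so hazard ratios are per standard deviation)
#' and retains features with `p < p_max` and an effect size outside the
#' (`hr_lo`, `hr_hi`) indifference band.
#'
#' @param expr Expression matrix (features x samples).
#' @param clinical Clinical tibble (`sample_id`, `time`, `event`); the
#'   short-survivor exclusion is applied, and at least 10 events are
#'   required.
#' @param p_max P-value gate (default 0.01).
#' @param hr_lo,hr_hi Hazard-ratio indifference band (defaults 0.9 / 1.1):
#'   retained features need `HR < hr_lo` or `HR > hr_hi`.
#' @param standardize Z-score each feature before fitting (default TRUE).
#' @param keep_all Return all features with a `retained` flag instead of
#'   the retained subset.
#' @return Tibble with `feature_id`, `beta`, `hr`, `ci_low`, `ci_high`,
#'   `p_value` (and `retained` when `keep_all`).
#' @export
prognostic_filter <- function(expr, clinical, p_max = 0.01,
                              hr_lo = 0.9, hr_hi = 1.1,
                              standardize = TRUE, keep_all = FALSE) {
  clinical <- apply_exclusions(clinical)
  common <- intersect(colnames(expr), clinical$sample_id)
  clinical <- clinical[match(common, clinical$sample_id), ]
  if (sum(clinical$event) < 10) {
    abort(sprintf("need >= 10 events for stable fits, found %d", sum(clinical$event)))
  }
  x <- expr[, common, drop = FALSE]
  srv <- survival::Surv(clinical$time, clinical$event)
  rows <- map(rownames(x), function(f) {
    v <- x[f, ]
    s <- sd(v)
    if (s == 0) {
      warn(sprintf("feature %s is constant; skipped", f))
      return(NULL)
    }
    z <- if (standardize) (v - mean(v)) / s else v
    fit <- survival::coxph(srv ~ z)
    sm <- summary(fit)
    tibble(feature_id = f,
           beta = unname(stats::coef(fit)),
           hr = unname(sm$conf.int[1, "exp(coef)"]),
           ci_low = unname(sm$conf.int[1, "lower .95"]),
           ci_high = unname(sm$conf.int[1, "upper .95"]),
           p_value = unname(sm$coefficients[1, "Pr(>|z|)"]))
  })
  out <- bind_rows(rows)
  out$retained <- out$p_value < p_max & (out$hr > hr_hi | out$hr < hr_lo)
  if (keep_all) out else select(filter(out, .data$retained), -"retained")
}
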