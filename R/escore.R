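# The E-score: signature gene selection (prognostic filter + random
# forest), correlation-sign partition into sets A/B, per-set PC1 scoring,
# and the maximally selected log-rank cutpoint.

#' Select signature genes for the E-score
#'
#' Stage 1 keeps differentially expressed genes (`adj_p < deg_adj_p`) that
#' pass the univariate-Cox prognostic filter. Stage 2 fits a random forest
#' classifying the immune subtype label from the stage-1 genes and keeps
#' genes by permutation importance: positive importance (default), all
#' stage-1 genes (`importance_rule = "all"`), or the top fraction when
#' `importance_rule` is a number in (0, 1].
#'
#' @param deg_table Output of [moderated_t()].
#' @param expr Log2 expression matrix (features x samples).
#' @param clinical Clinical tibble.
#' @param labels Subtype labels named by sample id (two levels).
#' @param deg_adj_p DEG gate on the BH-adjusted p (default 0.05).
#' @param cox_p,hr_lo,hr_hi Prognostic filter gates (defaults 0.01,
#'   0.9, 1.1).
#' @param rf_trees Random-forest size (default 500).
#' @param importance_rule `"positive"`, `"all"`, or a top fraction.
#' @param seed Seed for the forest.
#' @return Character vector of selected gene ids with the importance table
#'   attached as attribute `"importance"`.
#' @export
select_signature <- function(deg_table, expr, clinical, labels,
                             deg_adj_p = 0.05, cox_p = 0.01,
                             hr_lo = 0.9, hr_hi = 1.1,
                             rf_trees = 500, importance_rule = "positive",
                             seed = 1L) {
  degs <- deg_table$gene_id[deg_table$adj_p < deg_adj_p]
  degs <- intersect(degs, rownames(expr))
  if (!length(degs)) abort("no DEGs pass the adjusted-p gate")
  prog <- prognostic_filter(expr[degs, , drop = FALSE], clinical,
                            p_max = cox_p, hr_lo = hr_lo, hr_hi = hr_hi)
  if (!nrow(prog)) abort("no prognostic DEGs")
  stage1 <- prog$feature_id
  if (identical(importance_rule, "all")) {
    return(structure(stage1, importance = NULL))
  }
  common <- intersect(colnames(expr), names(labels))
  x <- t(expr[stage1, common, drop = FALSE])
  y <- factor(labels[common])
  rf <- with_preserved_seed(seed, function() {
    randomForest::randomForest(x = x, y = y, ntree = rf_trees,
                               importance = TRUE)
  })
  imp <- randomForest::importance(rf, type = 1)[, 1]
  imp_tbl <- tibble(gene_id = stage1, importance = unname(imp[stage1]))
  selected <- if (is.numeric(importance_rule)) {
    if (importance_rule <= 0 || importance_rule > 1) {
      abort("numeric importance_rule must be a fraction in (0, 1]")
    }
    k <- max(1L, ceiling(importance_rule * length(stage1)))
    imp_tbl$gene_id[order(-imp_tbl$importance)][seq_len(k)]
  } else if (identical(importance_rule, "positive")) {
    imp_tbl$gene_id[imp_tbl$importance > 0]
  } else {
    abort("importance_rule must be 'positive', 'all', or a fraction")
  }
  if (!length(selected)) abort("no genes with positive importance")
  structure(selected, importance = imp_tbl)
}

#' Partition signature genes into sets A and B
#'
#' Each gene's Pearson correlation with the 0/1 subtype indicator
#' (`active_level` coded 1) decides its set: positive correlation goes to
#' set A, negative to set B; zero or undefined correlations are excluded
#' with a warning. Flipping the indicator coding swaps A and B exactly.
#'
#' @param expr Expression matrix (features x samples).
#' @param selected Signature gene ids.
#' @param labels Subtype labels named by sample id.
#' @param active_level Label coded as 1 (default `"active"`).
#' @return List of class `signature_sets`: `set_A`, `set_B`,
#'   `indicator_coding`.
#' @export
partition_sets <- function(expr, selected, labels, active_level = "active") {
  common <- intersect(colnames(expr), names(labels))
  ind <- as.numeric(labels[common] == active_level)
  if (all(ind == 0) || all(ind == 1)) abort("both subtypes must be present")
  selected <- intersect(selected, rownames(expr))
  r <- map_dbl(selected, function(g) {
    v <- expr[g, common]
    if (sd(v) == 0) NA_real_ else cor(v, ind)
  })
  drop <- is.na(r) | r == 0
  if (any(drop)) {
    warn(sprintf("%d gene(s) with zero/undefined indicator correlation excluded",
                 sum(drop)))
  }
  set_a <- selected[!drop & r > 0]
  set_b <- selected[!drop & r < 0]
  if (!length(set_a) || !length(set_b)) {
    warn("all genes landed in one set; scoring proceeds with the non-empty set")
  }
  structure(list(set_A = set_a, set_B = set_b,
                 indicator_coding = active_level),
            class = "signature_sets")
}

#' Compute the E-score
#'
#' Expression of each signature set is z-scored per gene; the first
#' principal component of each set is extracted and oriented so that it
#' correlates positively with the set's mean expression (PCA signs are
#' otherwise arbitrary). The E-score is `PC1_A + PC1_B` (`mode = "sum"`,
#' the headline definition) or `PC1_A - PC1_B` (`mode = "difference"`, a
#' sensitivity variant for when the two oppositely-correlated sets would
#' cancel). A set with a single gene uses that standardized gene as its
#' PC1; an empty set contributes 0.
#'
#' @param expr Expression matrix (features x samples).
#' @param sets A `signature_sets` object from [partition_sets()].
#' @param mode `"sum"` (default) or `"difference"`.
#' @return Tibble of class `escore_result`: `sample_id`, `pc1_a`,
#'   `pc1_b`, `e_score`.
#' @export
compute_escore <- function(expr, sets, mode = c("sum", "difference")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sets, "signature_sets"))
  set_pc1 <- function(ids) {
    ids <- intersect(ids, rownames(expr))
    if (!length(ids)) return(rep(0, ncol(expr)))
    z <- standardize_rows(expr[ids, , drop = FALSE])
    if (length(ids) == 1L) {
      inform("signature set with a single gene: PC1 is that standardized gene")
      return(as.numeric(z))
    }
    pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
    pc1 <- unname(pc$x[, 1])
    if (cor(pc1, colMeans(z)) < 0) pc1 <- -pc1
    pc1
  }
  pc1_a <- set_pc1(sets$set_A)
  pc1_b <- set_pc1(sets$set_B)
  e <- if (mode == "sum") pc1_a + pc1_b else pc1_a - pc1_b
  out <- tibble(sample_id = colnames(expr), pc1_a = pc1_a, pc1_b = pc1_b,
                e_score = e)
  class(out) <- c("escore_result", class(out))
  attr(out, "mode") <- mode
  attr(out, "sets") <- sets
  out
}

#' Maximally selected log-rank cutpoint
#'
#' Evaluates every candidate cutpoint (midpoints between consecutive
#' distinct score values whose smaller induced group keeps at least
#' `minprop` of the samples) and returns the one maximizing the absolute
#' standardized log-rank statistic between the induced high/low groups.
#' Exact ties are broken toward the median score. The reported naive
#' p-value ignores the selection over cutpoints and is anti-conservative;
#' it is included for reference only.
#'
#' @param scores Numeric scores (an [compute_escore()] tibble is also
#'   accepted), named by or aligned with `clinical` sample ids.
#' @param clinical Clinical tibble (>= 10 events after exclusion).
#' @param minprop Minimum proportion per group (default 0.1).
#' @return List of class `cutpoint_result`: `cutpoint`, `statistic`
#'   (standardized log-rank), `naive_p`, and `groups` tibble
#'   (`sample_id`, `score`, `group` in high/low).
#' @export
optimal_cutpoint <- function(scores, clinical, minprop = 0.1) {
  if (inherits(scores, "escore_result") || is.data.frame(scores)) {
    scores <- setNames(scores$e_score, scores$sample_id)
  }
  clinical <- apply_exclusions(clinical)
  common <- intersect(clinical$sample_id,
                      if (is.null(names(scores))) clinical$sample_id else names(scores))
  clinical <- clinical[match(common, clinical$sample_id), ]
  s <- if (is.null(names(scores))) scores else scores[common]
  if (sum(clinical$event) < 10) abort("need >= 10 events")
  if (length(unique(s)) < 2) abort("scores are constant")
  us <- sort(unique(s))
  cands <- (head(us, -1) + tail(us, -1)) / 2
  n <- length(s)
  grp_sizes <- map_int(cands, function(cc) sum(s > cc))
  ok <- pmin(grp_sizes, n - grp_sizes) / n >= minprop
  if (!any(ok)) abort("no candidate cutpoint satisfies minprop")
  cands <- cands[ok]
  stat <- map_dbl(cands, function(cc) {
    g <- factor(ifelse(s > cc, "high", "low"))
    sd <- survival::survdiff(survival::Surv(clinical$time, clinical$event) ~ g)
    (sd$obs[1] - sd$exp[1]) / sqrt(sd$var[1, 1])
  })
  best <- which(abs(stat) >= max(abs(stat)) - 1e-12)
  if (length(best) > 1) {
    best <- best[which.min(abs(cands[best] - median(s)))]
  }
  cut <- cands[best]
  z <- stat[best]
  structure(list(
    cutpoint = cut, statistic = z,
    naive_p = 2 * pnorm(-abs(z)),
    groups = tibble(sample_id = clinical$sample_id, score = unname(s),
                    group = ifelse(s > cut, "high", "low"))
  ), class = "cutpoint_result")
}

#' @method print cutpoint_result
#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("Optimal cutpoint %.4g (standardized log-rank %.3f)\n",
              x$cutpoint, x$statistic))
  print(table(x$groups$group))
  invisible(x)
}

#' @method tidy cutpoint_result
#' @export
tidy.cutpoint_result <- function(x, ...) x$groups

#' @method glance cutpoint_result
#' @export
glance.cutpoint_result <- function(x, ...) {
  tibble(cutpoint = x$cutpoint, statistic = x$statistic, naive_p = x$naive_p,
         n_high = sum(x$groups$group == "high"),
         n_low = sum(x$groups$group == "low"))
}

#' @method autoplot escore_result
#' @export
autoplot.escore_result <- function(object, group = NULL, ...) {
  df <- object
  df$group <- if (is.null(group)) "all" else group[df$sample_id]
  ggplot2::ggplot(df, ggplot2::aes(.data$group, .data$e_score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4) +
    ggplot2::labs(x = NULL, y = "E-score") +
    ggplot2::theme_minimal()
}
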