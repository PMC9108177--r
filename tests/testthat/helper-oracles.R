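# Brute-force reference implementations, kept deliberately literal and
# independent of the package's internals.

# All-pairs interval filter: remove an enhancer iff it overlaps (>= 1 bp,
# half-open) any exon, gene body, or +/- ext window around a TSS/TES.
oracle_filter <- function(enhancers, genes, ext = 1000) {
  overlaps <- function(s1, e1, s2, e2) s1 < e2 && s2 < e1
  keep <- logical(nrow(enhancers))
  for (i in seq_len(nrow(enhancers))) {
    s <- enhancers$start[i]; e <- enhancers$end[i]; ch <- enhancers$chrom[i]
    hit <- FALSE
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != ch) next
      lo <- min(genes$tss[j], genes$tes[j]); hi <- max(genes$tss[j], genes$tes[j])
      if (overlaps(s, e, lo, hi + 1)) { hit <- TRUE; break }
      if (overlaps(s, e, genes$tss[j] - ext, genes$tss[j] + 1 + ext)) { hit <- TRUE; break }
      if (overlaps(s, e, genes$tes[j] - ext, genes$tes[j] + 1 + ext)) { hit <- TRUE; break }
      ex <- genes$exons[[j]]
      if (nrow(ex) && any(mapply(function(a, b) overlaps(s, e, a, b), ex$start, ex$end))) {
        hit <- TRUE; break
      }
    }
    keep[i] <- !hit
  }
  enhancers[keep, ]
}

# All-pairs eRNA-gene pairing with per-pair cor.test.
oracle_pairs <- function(erna, gene_expr, regions, genes, max_d = 1e6,
                         rho_min = 0.3, fdr_max = 0.05) {
  rows <- list()
  for (i in seq_len(nrow(regions))) {
    if (!(regions$erna_id[i] %in% rownames(erna))) next
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] != regions$chrom[i]) next
      if (!(genes$gene_id[j] %in% rownames(gene_expr))) next
      d <- abs(genes$tss[j] - regions$midpoint[i])
      if (d > max_d) next
      ct <- suppressWarnings(stats::cor.test(
        erna[regions$erna_id[i], ], gene_expr[genes$gene_id[j], ],
        method = "spearman", exact = FALSE))
      rows[[length(rows) + 1]] <- data.frame(
        erna_id = regions$erna_id[i], gene_id = genes$gene_id[j],
        distance = d, rho = unname(ct$estimate), p = ct$p.value)
    }
  }
  tab <- do.call(rbind, rows)
  tab$rho[is.na(tab$rho)] <- 0
  tab$p[is.na(tab$p)] <- 1
  tab$fdr <- stats::p.adjust(tab$p, method = "BH")
  tab[abs(tab$rho) > rho_min & tab$fdr < fdr_max, ]
}

oracle_active <- function(rpm, thr = 1) {
  out <- logical(nrow(rpm))
  for (i in seq_len(nrow(rpm))) {
    mx <- -Inf
    for (j in seq_len(ncol(rpm))) if (rpm[i, j] > mx) mx <- rpm[i, j]
    out[i] <- mx >= thr
  }
  stats::setNames(out, rownames(rpm))
}

# Literal per-sample running-sum ssGSEA (same tie order as the package:
# decreasing expression, ties by feature name).
oracle_ssgsea <- function(expr, sets, alpha = 0.25) {
  feats <- rownames(expr)
  out <- matrix(NA_real_, ncol(expr), length(sets),
                dimnames = list(colnames(expr), names(sets)))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    rk <- rank(x, ties.method = "average")
    ord <- order(-x, feats)
    for (s in seq_along(sets)) {
      members <- intersect(sets[[s]], feats)
      if (!length(members)) next
      num_in <- 0; num_out <- 0; total <- 0
      w_sum <- sum(rk[members]^alpha)
      n_out <- length(feats) - length(members)
      for (pos in ord) {
        if (feats[pos] %in% members) {
          num_in <- num_in + rk[pos]^alpha
        } else {
          num_out <- num_out + 1
        }
        total <- total + (num_in / w_sum - num_out / n_out)
      }
      out[j, s] <- total
    }
  }
  out
}

# Literal BH step-up: adj of the i-th order statistic is
# min_{j >= i} m * p_(j) / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

# O(n^2) concordance: pair usable when the earlier observed time is an
# event (equal times: event vs censored counts, event before censoring;
# both events at the same time are not usable).
oracle_harrell <- function(scores, time, event, tie_policy = 0.5) {
  conc <- 0; tied <- 0; usable <- 0
  n <- length(scores)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) {
        if (event[i] + event[j] != 1) next
        first <- if (event[i] == 1) i else j
      } else {
        first <- if (time[i] < time[j]) i else j
        if (event[first] != 1) next
      }
      second <- if (first == i) j else i
      usable <- usable + 1
      if (scores[first] > scores[second]) conc <- conc + 1
      else if (scores[first] == scores[second]) tied <- tied + 1
    }
  }
  (conc + tie_policy * tied) / usable
}

# Two-group log-rank by explicit O/E/V tabulation over pooled event times.
oracle_logrank_z <- function(time, event, in_group1) {
  ev_times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & in_group1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in_group1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E) / sqrt(V)
}

oracle_km <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ev_times, surv = NA_real_)
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

oracle_cutpoint <- function(scores, time, event, minprop = 0.1) {
  us <- sort(unique(scores))
  cands <- (head(us, -1) + tail(us, -1)) / 2
  n <- length(scores)
  best <- NULL; best_z <- 0
  for (cc in cands) {
    hi <- scores > cc
    if (min(sum(hi), n - sum(hi)) / n < minprop) next
    z <- oracle_logrank_z(time, event, hi)
    if (is.null(best) || abs(z) > abs(best_z)) { best_z <- z; best <- cc }
  }
  list(cutpoint = best, statistic = best_z)
}

# Plain rank-sum AUC (probability a case outscores a control, ties 0.5).
ranksum_auc <- function(case_scores, control_scores) {
  tot <- 0
  for (a in case_scores) {
    for (b in control_scores) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(case_scores) * length(control_scores))
}
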