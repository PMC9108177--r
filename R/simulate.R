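# Synthetic AML-like cohort generator with planted ground truth: enhancer and
# gene annotation on one chromosome, Poisson counts over log-normal rates,
# two latent immune subtypes, planted eRNA-gene pairs, immune-correlated
# eRNAs, and exponential proportional-hazards survival.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort generator. Defaults describe
#' the reference cohort used throughout the package's validation suite:
#' 300 samples, a 50 Mb chromosome, two immune subtypes at a 50/50 split
#' with a 2-unit log2 marker shift, 30 planted enhancer-gene pairs at a
#' target Spearman correlation of 0.8, 30 immune-related eRNAs at loading
#' 0.7, and exponential survival with a subtype log hazard ratio of 0.7
#' under 30% uniform censoring.
#'
#' @param n_samples,n_genes,n_enhancers Cohort dimensions.
#' @param chrom_length Chromosome length in bp used for feature placement.
#' @param overlap_fraction Fraction of enhancers deliberately placed inside
#'   gene bodies or within 1 kb of a TSS/TES, to exercise the exclusion
#'   filter.
#' @param frac_active_ernas Fraction of non-overlapping enhancers that are
#'   transcribed at all; the rest produce zero counts.
#' @param n_pairs Number of planted eRNA-gene co-expression links (within
#'   1 Mb).
#' @param pair_rho Target Spearman correlation of planted pairs.
#' @param n_immune_sets,markers_per_set Immune cell marker sets emitted as a
#'   GMT collection.
#' @param n_ir_ernas Number of eRNAs loaded on the latent immune factor.
#' @param ir_loading Loading of ir-eRNAs on the immune factor (log2 scale).
#' @param n_signature_genes Genes differentially expressed between subtypes
#'   (half up in each subtype).
#' @param subtype_split Fraction of samples in the immune-active subtype.
#' @param subtype_effect Log2 fold-change of marker/signature genes between
#'   subtypes.
#' @param noise_sd Log2-scale biological noise standard deviation.
#' @param baseline_scale Baseline mean survival (months) of the exponential
#'   model.
#' @param true_logHR_subtype Log hazard ratio of the immune-resistant
#'   subtype.
#' @param true_logHR_age Log hazard ratio per year of age (centered).
#' @param censor_rate Target fraction of censored samples (independent
#'   uniform censoring).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 300, n_genes = 400, n_enhancers = 200,
                       chrom_length = 5e7, overlap_fraction = 0.2,
                       frac_active_ernas = 0.6, n_pairs = 30, pair_rho = 0.8,
                       n_immune_sets = 23, markers_per_set = 8,
                       n_ir_ernas = 30, ir_loading = 0.7,
                       n_signature_genes = 40,
                       subtype_split = 0.5, subtype_effect = 2,
                       noise_sd = 0.5,
                       baseline_scale = 24, true_logHR_subtype = 0.7,
                       true_logHR_age = 0.03, censor_rate = 0.3,
                       seed = 1L) {
  cfg <- list(
    n_samples = n_samples, n_genes = n_genes, n_enhancers = n_enhancers,
    chrom_length = chrom_length, overlap_fraction = overlap_fraction,
    frac_active_ernas = frac_active_ernas, n_pairs = n_pairs,
    pair_rho = pair_rho, n_immune_sets = n_immune_sets,
    markers_per_set = markers_per_set, n_ir_ernas = n_ir_ernas,
    ir_loading = ir_loading, n_signature_genes = n_signature_genes,
    subtype_split = subtype_split, subtype_effect = subtype_effect,
    noise_sd = noise_sd, baseline_scale = baseline_scale,
    true_logHR_subtype = true_logHR_subtype, true_logHR_age = true_logHR_age,
    censor_rate = censor_rate, seed = as.integer(seed)
  )
  for (nm in c("n_samples", "n_genes", "chrom_length")) {
    assert_scalar_number(cfg[[nm]], nm, lo = 1)
  }
  assert_scalar_number(cfg$n_enhancers, "n_enhancers", lo = 0)
  assert_scalar_number(cfg$subtype_split, "subtype_split", lo = 1e-9, hi = 1 - 1e-9)
  assert_scalar_number(cfg$censor_rate, "censor_rate", lo = 0, hi = 1 - 1e-9)
  assert_scalar_number(cfg$pair_rho, "pair_rho", lo = 1e-9, hi = 1 - 1e-9)
  assert_scalar_number(cfg$overlap_fraction, "overlap_fraction", lo = 0, hi = 1)
  structure(cfg, class = "sim_config")
}

# Place `n` non-overlapping intervals of the given widths on [0, L).
place_nonoverlapping <- function(n, widths, L, forbidden = NULL, max_tries = 200L) {
  starts <- numeric(0); ends <- numeric(0)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      s <- floor(runif(1, 0, L - widths[i]))
      e <- s + widths[i]
      clash <- any(s < ends & e > starts)
      if (!is.null(forbidden) && nrow(forbidden)) {
        clash <- clash || any(s < forbidden$end & e > forbidden$start)
      }
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) abort("could not place features without overlap; increase chrom_length")
    starts <- c(starts, s); ends <- c(ends, e)
  }
  tibble(start = starts, end = ends)
}

#' Simulate gene and enhancer annotation
#'
#' Genes (with exons) are placed uniformly and without mutual overlap on a
#' single chromosome. A fraction `overlap_fraction` of enhancers is planted
#' inside gene bodies or within 1 kb of a TSS/TES so the exclusion filter
#' has true positives to remove; the rest are intergenic with at least 1 kb
#' clearance. The `planted_overlap` column records which is which.
#'
#' @param config A [sim_config()].
#' @return A list with `genes` (gene model tibble) and `enhancers`
#'   (interval tibble with a `planted_overlap` flag).
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_preserved_seed(derive_seed(config$seed, "annotation"), function() {
    L <- config$chrom_length
    gene_w <- floor(runif(config$n_genes, 5000, 20000))
    if (sum(gene_w) + 4000 * config$n_genes > L) {
      abort("chrom_length too small for the requested genes; increase chrom_length")
    }
    pos <- place_nonoverlapping(config$n_genes, gene_w + 4000, L)
    # 2 kb padding on each side keeps intergenic placement feasible
    gstart <- pos$start + 2000
    gend <- gstart + gene_w
    strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
    gene_id <- sprintf("gene%04d", seq_len(config$n_genes))
    exons <- map(seq_len(config$n_genes), function(i) {
      k <- sample(1:3, 1)
      cuts <- sort(floor(runif(2 * k, gstart[i], gend[i])))
      ex <- tibble(start = cuts[seq(1, 2 * k, 2)], end = cuts[seq(2, 2 * k, 2)])
      ex <- filter(ex, .data$end > .data$start)
      if (!nrow(ex)) ex <- tibble(start = gstart[i], end = gend[i])
      mutate(ex, id = sprintf("%s:exon%d", gene_id[i], row_number()))
    })
    genes <- tibble(
      gene_id = gene_id, chrom = "chr1", strand = strand,
      tss = ifelse(strand == "+", gstart, gend - 1),
      tes = ifelse(strand == "+", gend - 1, gstart),
      exons = exons
    )
    enhancers <- tibble(chrom = character(), start = numeric(), end = numeric(),
                        id = character(), planted_overlap = logical())
    if (config$n_enhancers > 0) {
      n_bad <- round(config$overlap_fraction * config$n_enhancers)
      n_good <- config$n_enhancers - n_bad
      widths <- floor(runif(config$n_enhancers, 200, 600))
      # exclusion zones: gene body plus 1 kb around TSS/TES (= body +/- 1 kb)
      zone <- tibble(start = pmin(genes$tss, genes$tes) - 1000,
                     end = pmax(genes$tss, genes$tes) + 1 + 1000)
      starts <- numeric(config$n_enhancers)
      for (i in seq_len(n_bad)) {
        g <- sample.int(config$n_genes, 1)
        lo <- pmin(genes$tss[g], genes$tes[g]); hi <- pmax(genes$tss[g], genes$tes[g])
        starts[i] <- floor(runif(1, max(0, lo - 500), hi - widths[i] / 2))
      }
      if (n_good > 0) {
        placed <- place_nonoverlapping(n_good, widths[n_bad + seq_len(n_good)], L,
                                       forbidden = zone)
        starts[n_bad + seq_len(n_good)] <- placed$start
      }
      enhancers <- tibble(
        chrom = "chr1", start = starts, end = starts + widths,
        id = sprintf("enh%04d", seq_len(config$n_enhancers)),
        planted_overlap = c(rep(TRUE, n_bad), rep(FALSE, n_good))
      )
      ord <- order(enhancers$start)
      enhancers <- enhancers[ord, ]
      enhancers$id <- sprintf("enh%04d", seq_len(config$n_enhancers))
    }
    list(genes = genes, enhancers = enhancers)
  })
}

# Solve the uniform-censoring horizon tau so that the expected censored
# fraction over the cohort's hazard rates equals `target`.
censor_horizon <- function(rates, target) {
  if (target <= 0) return(Inf)
  p_cens <- function(tau) mean((1 - exp(-rates * tau)) / (rates * tau)) - target
  uniroot(p_cens, lower = 1e-6, upper = 1e8, tol = 1e-10)$root
}

#' Simulate a full cohort over a synthetic annotation
#'
#' Generates Poisson counts with log-normal rates and 1-3x library-size
#' variation, two latent immune subtypes (`active` vs `resistant`), immune
#' marker sets elevated in the resistant subtype, planted eRNA-gene
#' correlation pairs within 1 Mb, eRNAs loaded on the immune factor
#' (planted ir-eRNAs), and exponential proportional-hazards survival with
#' uniform censoring calibrated to the target censoring rate.
#'
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_annotation()] (regenerated from
#'   `config` when omitted).
#' @return A list of class `erna_cohort`: `erna_counts` and `gene_counts`
#'   (unit-tagged count matrices), `gene_sets` (named list), `clinical`
#'   (tibble), `truth` (planted ground truth), `annotation`, `config`.
#' @export
simulate_cohort <- function(config, annotation = simulate_annotation(config)) {
  stopifnot(inherits(config, "sim_config"))
  genes <- annotation$genes
  enh <- annotation$enhancers
  with_preserved_seed(derive_seed(config$seed, "cohort"), function() {
    n <- config$n_samples
    samples <- sprintf("s%03d", seq_len(n))
    lib_factor <- runif(n, 1, 3)

    # subtypes and latent immune factor
    n_active <- round(config$subtype_split * n)
    subtype <- rep("resistant", n)
    subtype[sample.int(n, n_active)] <- "active"
    resistant <- as.numeric(subtype == "resistant")
    u_immune <- rnorm(n)
    # immune axes: the subtype shift scales with the effect size while the
    # shared within-subtype latent is damped, so a zero effect leaves only
    # weak unstructured variation. Marker genes carry more within-subtype
    # immune variation (0.4) than eRNAs (0.15), whose residual noise
    # already dominates their profiles.
    f_immune <- config$subtype_effect * resistant + 0.4 * u_immune
    f_erna <- config$subtype_effect * resistant + 0.15 * u_immune

    # gene roles
    n_marker <- config$n_immune_sets * config$markers_per_set
    need <- n_marker + config$n_signature_genes + config$n_pairs
    if (need > config$n_genes) {
      abort(sprintf("n_genes (%d) too small for %d marker + %d signature + %d pair genes",
                    config$n_genes, n_marker, config$n_signature_genes, config$n_pairs))
    }
    gid <- genes$gene_id
    marker_ids <- gid[seq_len(n_marker)]
    sig_ids <- gid[n_marker + seq_len(config$n_signature_genes)]

    # eligible enhancers: non-overlapping ones survive the exclusion filter
    good_enh <- filter(enh, !.data$planted_overlap)
    n_act_erna <- round(config$frac_active_ernas * nrow(good_enh))
    if (n_act_erna < config$n_pairs + config$n_ir_ernas) {
      abort("too few active eRNAs for the requested planted pairs and ir-eRNAs")
    }
    active_ids <- sample(good_enh$id, n_act_erna)

    # planted pairs: active eRNAs with a gene TSS within 1 Mb, excluding
    # marker/signature genes so planted effects stay separable
    free_gene <- genes[!(genes$gene_id %in% c(marker_ids, sig_ids)), ]
    cand_enh <- filter(good_enh, .data$id %in% active_ids)
    mid <- floor((cand_enh$start + cand_enh$end) / 2)
    cand <- bind_rows(map(seq_len(nrow(cand_enh)), function(i) {
      hit <- which(abs(free_gene$tss - mid[i]) <= 1e6)
      if (!length(hit)) return(NULL)
      tibble(erna_id = cand_enh$id[i], gene_id = free_gene$gene_id[hit])
    }))
    if (is.null(cand) || nrow(cand) < config$n_pairs) {
      abort("fewer feasible enhancer-gene combinations within 1 Mb than n_pairs")
    }
    # one pair per eRNA and per gene
    cand <- cand[sample.int(nrow(cand)), ]
    cand <- cand[!duplicated(cand$erna_id) & !duplicated(cand$gene_id), ]
    if (nrow(cand) < config$n_pairs) abort("could not plant n_pairs disjoint pairs")
    pairs <- head(cand, config$n_pairs)

    ir_ids <- sample(setdiff(active_ids, pairs$erna_id), config$n_ir_ernas)

    # latent shared factors for pairs, calibrated for the target Spearman rho
    r_latent <- 2 * sin(pi * config$pair_rho / 6)
    lambda <- config$noise_sd * sqrt(r_latent / (1 - r_latent))
    w_pair <- matrix(rnorm(config$n_pairs * n), config$n_pairs, n)

    # gene log2 rates
    base_g <- rnorm(config$n_genes, 9, 1.5)
    names(base_g) <- gid
    # markers and signature genes sit lower so their subtype fold-changes
    # do not dominate per-sample library sizes
    base_g[marker_ids] <- rnorm(n_marker, 6, 1)
    base_g[sig_ids] <- rnorm(config$n_signature_genes, 7, 1)
    base_g[pairs$gene_id] <- rnorm(config$n_pairs, 8, 0.5)
    logr_g <- matrix(base_g, config$n_genes, n, dimnames = list(gid, samples))
    logr_g <- logr_g + matrix(rnorm(length(logr_g), 0, config$noise_sd),
                              config$n_genes, n)
    # immune marker genes ride the immune factor (log2 FC = subtype_effect)
    set_names <- c("Activated_dendritic_cell", "Macrophage", "Regulatory_T_cell",
                   "MDSC", "Activated_CD8_T_cell", "Activated_CD4_T_cell")
    if (config$n_immune_sets > length(set_names)) {
      set_names <- c(set_names, sprintf("immune_cell_%02d",
                                        seq_len(config$n_immune_sets - length(set_names))))
    }
    set_names <- set_names[seq_len(config$n_immune_sets)]
    gene_sets <- list()
    for (ci in seq_len(config$n_immune_sets)) {
      members <- marker_ids[(ci - 1) * config$markers_per_set + seq_len(config$markers_per_set)]
      gene_sets[[set_names[ci]]] <- members
      v_c <- rnorm(n, 0, 0.3) # per-cell-type wiggle
      logr_g[members, ] <- logr_g[members, ] +
        matrix(f_immune + v_c, length(members), n, byrow = TRUE)
    }
    # signature genes: half up in resistant, half up in active
    half <- config$n_signature_genes %/% 2
    sig_up_resistant <- sig_ids[seq_len(half)]
    sig_up_active <- sig_ids[(half + 1):config$n_signature_genes]
    logr_g[sig_up_resistant, ] <- logr_g[sig_up_resistant, ] +
      matrix(resistant * config$subtype_effect, length(sig_up_resistant), n, byrow = TRUE)
    logr_g[sig_up_active, ] <- logr_g[sig_up_active, ] +
      matrix((1 - resistant) * config$subtype_effect, length(sig_up_active), n, byrow = TRUE)
    # pair genes share the latent factor with their eRNA
    logr_g[pairs$gene_id, ] <- logr_g[pairs$gene_id, ] + lambda * w_pair

    # eRNA log2 rates; non-active enhancers are untranscribed (zero counts)
    eid <- enh$id
    logr_e <- matrix(-Inf, nrow(enh), n, dimnames = list(eid, samples))
    base_e <- rnorm(length(active_ids), 6, 0.8)
    logr_e[active_ids, ] <- base_e +
      matrix(rnorm(length(active_ids) * n, 0, config$noise_sd), length(active_ids), n)
    logr_e[pairs$erna_id, ] <- logr_e[pairs$erna_id, ] + lambda * w_pair
    # ir-eRNAs load on the immune factor with alternating sign, mirroring
    # eRNAs that track either immune-rich or immune-poor states; mixed
    # signs also make sample profiles pattern-distinct, not just shifted
    ir_sign <- rep(c(1, -1), length.out = length(ir_ids))
    logr_e[ir_ids, ] <- logr_e[ir_ids, ] +
      (config$ir_loading * ir_sign) %o% f_erna

    rate_g <- 2^logr_g * matrix(lib_factor, config$n_genes, n, byrow = TRUE)
    rate_e <- ifelse(is.finite(logr_e), 2^logr_e, 0) *
      matrix(lib_factor, nrow(enh), n, byrow = TRUE)
    gene_counts <- matrix(rpois(length(rate_g), rate_g), config$n_genes, n,
                          dimnames = dimnames(rate_g))
    erna_counts <- matrix(rpois(length(rate_e), rate_e), nrow(enh), n,
                          dimnames = dimnames(rate_e))

    # survival: exponential PH with uniform censoring hitting censor_rate
    age <- round(rnorm(n, 55, 12))
    lp <- config$true_logHR_subtype * resistant + config$true_logHR_age * (age - 55)
    rate_surv <- exp(lp) / config$baseline_scale
    t_event <- rexp(n, rate_surv)
    if (config$censor_rate > 0) {
      tau <- censor_horizon(rate_surv, config$censor_rate)
      t_cens <- runif(n, 0, tau)
    } else {
      t_cens <- rep(Inf, n)
    }
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
    clinical <- validate_clinical(tibble(
      sample_id = samples, time = time, event = event, age = age
    ))

    truth <- list(
      subtype = setNames(subtype, samples),
      pairs = pairs,
      ir_ernas = sort(ir_ids),
      active_ernas = sort(active_ids),
      signature_genes = tibble(
        gene_id = sig_ids,
        direction = c(rep("up_in_resistant", length(sig_up_resistant)),
                      rep("up_in_active", length(sig_up_active)))
      ),
      marker_genes = marker_ids,
      true_lp = setNames(lp, samples)
    )

    structure(list(
      erna_counts = expr_matrix(erna_counts, "counts"),
      gene_counts = expr_matrix(gene_counts, "counts"),
      gene_sets = gene_sets,
      clinical = clinical,
      truth = truth,
      annotation = annotation,
      config = config
    ), class = "erna_cohort")
  })
}

#' Write a simulated cohort to a directory
#'
#' Emits the cohort in the pipeline's external formats: `enhancers.bed`,
#' `genes.gtf`, `immune_sets.gmt`, `erna_counts.tsv`, `gene_counts.tsv`,
#' `clinical.tsv` and `ground_truth.json`.
#'
#' @param cohort An `erna_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "erna_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_bed(select(cohort$annotation$enhancers, "chrom", "start", "end", "id"),
            file.path(dir, "enhancers.bed"))
  write_gtf(cohort$annotation$genes, file.path(dir, "genes.gtf"))
  write_gmt(cohort$gene_sets, file.path(dir, "immune_sets.gmt"))
  write_matrix(cohort$erna_counts, file.path(dir, "erna_counts.tsv"))
  write_matrix(cohort$gene_counts, file.path(dir, "gene_counts.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  truth <- cohort$truth
  truth$pairs <- as.list(truth$pairs)
  truth$signature_genes <- as.list(truth$signature_genes)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
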