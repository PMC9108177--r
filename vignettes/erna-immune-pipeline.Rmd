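---
title: "Methods: eRNA landscapes, immune subtypes and the E-score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eRNA landscapes, immune subtypes and the E-score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models, conventions and numerical choices
behind `ernascape`, in the order the pipeline runs them, and spells out
what the synthetic validation cohorts do and do not establish about real
data.

## Coordinates and formats

All interval arithmetic is done in 0-based half-open coordinates. BED is
read unchanged; GTF (1-based, closed) is converted at the boundary, with
the transcription start site defined as the strand-aware 5' end (`tss =
start − 1` on `+`, `tss = end − 1` on `-`, both 0-based). "Overlap" always
means at least one shared base under half-open semantics — the simplest
definition that can be tested exactly. Gene position for all distance
computations is the TSS, since enhancer–promoter distance is the
biologically relevant quantity. Clinical tables carry survival time in
months and an 0/1 event flag; rows with time under one month are flagged
and dropped before any model fit, the usual guard against registration
artifacts dominating short-follow-up cohorts. Missing covariates are
permitted and dropped case-wise, with a logged count.

## eRNA quantification

Enhancers are removed when they touch any exon, any gene body, or the
±1 kb windows around a TSS or TES, so that residual transcription cannot
be attributed to promoters, terminators or intragenic elements. The
candidate eRNA region is the 3 kb window centered on the enhancer midpoint
`floor((start + end) / 2)`; windows that would cross the chromosome origin
are shifted to start at zero and flagged, keeping a constant width so all
regions are comparable units of signal. RPM normalization divides by the
per-sample total of the full counts matrix when one is supplied; when only
the eRNA submatrix is available its own column totals are used with a
warning, because an eRNA-only denominator understates sequencing depth.
Activity calling is `max RPM >= 1` across samples, an inclusive threshold.

## Pairing and correlation conventions

Candidate enhancer–gene pairs live within 1 Mb (TSS to region midpoint) on
the same chromosome. Spearman correlation is computed over the shared
samples of the two matrices; p-values use the t approximation on the rank
correlation, replaced by the exact permutation null (computed once per
sample size from the untied-rank distribution) when n ≤ 9 and ranks are
untied. The Benjamini–Hochberg adjustment pools **all** candidate pairs —
the alternative, adjusting within each eRNA, is available via
`fdr_scope = "per_erna"` but treats eRNAs with many neighbors more
leniently for no biological reason. Distance ties in the per-eRNA gene
rank break lexicographically by gene id so outputs are deterministic.
Pearson correlation is exposed as an option for descriptive summaries;
pairing defaults to Spearman.

## Immune profiling

ssGSEA ranks genes within each sample (average ranks on ties; ties are
walked in feature-name order so scores are reproducible) and accumulates,
down the expression-sorted list, the difference between the
rank-weight-`alpha` in-set ECDF and the unweighted out-of-set ECDF;
`alpha = 0.25` is the community default for this statistic. When
`normalize = TRUE` all scores are divided by the range (max − min) of the
computed score matrix, making scores comparable across sets and samples
but dependent on the score matrix as a whole; the stromal/immune/ESTIMATE
sums use unnormalized scores. The tumor-purity transformation
`cos(a + b × estimate)` is opt-in because its published constants were
fitted on a specific expression platform and are meaningless on other
scales.

ir-eRNA p-values are deliberately **not** multiplicity-adjusted — this
screen is defined by per-test thresholds (|rho| > 0.3, p < 0.05); a BH
mode exists as a sensitivity analysis. eRNA expression enters on the RPM
scale; Spearman's rank invariance makes any monotone rescaling
immaterial, which a property test verifies.

The prognostic filter standardizes each feature before its univariate Cox
fit so the hazard-ratio gate (HR > 1.1 or < 0.9) reads "per standard
deviation" identically for every feature; without standardization the
gate would be a per-unit criterion whose stringency depends on each
feature's scale.

## Subtype discovery

Consensus clustering subsamples 80% of samples (1000 times by default; the
validation suite uses 100–200, which already stabilizes the consensus
matrix at these cohort sizes), partitions each subsample by k-medoids
(PAM, deterministic build/swap) under 1 − Pearson distance, and records
co-clustering frequencies; final labels come from Ward (`ward.D`)
hierarchical clustering of 1 − consensus. Randomness enters only through
subsampling, so a seed makes runs bit-reproducible.

The number of clusters is chosen by minimizing PAC, the proportion of
consensus entries strictly between 0.1 and 0.9, with ties toward the
smaller k. The classic proportional-increase-in-CDF-area rule is computed
and reported, but it was not usable as a selector: on cleanly separated
two-cluster data, splitting a clean block still inflates the CDF area
enough that the rule prefers larger k. PAC directly measures what
consensus clustering is supposed to deliver — unambiguous co-clustering —
and selects k = 2 on such data while leaving null data visibly ambiguous.

Moderated t-tests shrink per-gene pooled variances toward a common prior
via the scaled-F marginal model for `log s²`: the prior degrees of freedom
`d0` solve a trigamma matching equation (Newton inversion) and the prior
variance follows from the digamma identity. `prior_df = 0` recovers the
ordinary pooled t exactly and `prior_df = Inf` gives complete shrinkage;
under-dispersed variance sets fall back to complete shrinkage with a
warning. The DEG gate is BH-adjusted p < 0.05 with no fold-change
criterion. PCA views z-score features and orient every component so its
largest-magnitude loading is positive, a deterministic sign convention.

## The E-score

Signature construction runs in two stages: the prognostic Cox gate over
the DEGs, then a random-forest classifier of the subtype label whose
permutation importance prunes redundant genes (positive importance by
default; a top-fraction rule and a pass-through mode exist). The forest's
response is the subtype label rather than survival: the score is meant to
quantify the immune pattern, and its prognostic value is then assessed
downstream rather than built in twice.

Genes are partitioned by the sign of their Pearson correlation with the
0/1 subtype indicator (immune-active coded 1): positive to set A, negative
to set B. Each set's expression block is z-scored per gene and reduced to
its first principal component, oriented to correlate positively with the
set's mean expression — PCA signs are otherwise arbitrary and would flip
the score between runs. The headline score is the sum `PC1.A + PC1.B`; a
`"difference"` mode is provided because the two sets correlate with the
subtype in opposite directions, so their oriented PC1s can partially
cancel in the sum. In the sum mode the score's overall sign is therefore
data-dependent (whichever set dominates), and the pipeline orients the
final score so that high E-score tracks the immune-active subtype — the
better-prognosis pattern — before cutpointing.

The cutpoint maximizes the absolute standardized log-rank statistic over
all midpoints between consecutive distinct scores whose smaller induced
group keeps at least `minprop = 0.1` of the cohort; without a floor the
maximum degenerates at the extremes. Ties break toward the median score.
The naive p-value attached to the selected maximum ignores the selection
and is anti-conservative — a Monte-Carlo property test demonstrates the
inflation — so it is reported for reference only.

## Survival machinery

Cox models use the Efron tie correction (better than Breslow under heavy
tying; identical without ties, which a no-ties equivalence test exploits)
with Wald intervals, matching standard forest-plot output. Harrell's C
counts usable pairs under right censoring with half credit for score
ties. The time-dependent ROC uses the cumulative-case/dynamic-control
formulation with inverse-probability-of-censoring weights from the
Kaplan–Meier estimate of the censoring distribution, integrating the
weighted ROC by trapezoid; without censoring it reduces exactly to the
rank-sum AUC. A smoothed variant exists in the literature; the unsmoothed
estimator was chosen for determinism and exact reduction properties.

The nomogram rescales each covariate's contribution `beta x` to points,
with 100 points for the largest effect range over the observed covariate
ranges and the zero-point anchored at each covariate's minimal-risk end,
so points are non-negative by construction. Predicted survival is
`S0(t)^exp(lp)` with the Breslow baseline. Calibration bins samples by
predicted survival (quantile bins; heavily tied predictions collapse
bins), compares against the within-bin Kaplan–Meier estimate and attaches
bootstrap percentile intervals.

## The synthetic cohorts

`simulate_cohort()` generates Poisson counts over log-normal rates on a
single synthetic chromosome, with library-size factors varying threefold
so RPM/CPM normalization is exercised non-trivially. It plants exactly the
structures the analysis assumes:

- a configurable fraction of enhancers placed inside gene bodies or
  within 1 kb of a TSS/TES (exclusion-filter true positives), the rest
  intergenic;
- eRNA–gene pairs within 1 Mb sharing a latent factor whose loading is
  calibrated through the Gaussian-rank identity `r = 2 sin(pi rho / 6)` so
  the realized Spearman correlation hits the target;
- two immune subtypes at a configurable split, with marker gene sets
  elevated by `subtype_effect` log2 units in the resistant subtype plus a
  damped shared latent immune factor for within-subtype variation;
- ir-eRNAs loading on that immune axis with alternating sign — eRNAs
  tracking immune-rich and immune-poor states — which also makes subtype
  profiles pattern-distinct rather than uniformly shifted (a uniform
  shift would be invisible to correlation distance, which centers each
  sample's profile);
- exponential proportional-hazards survival (`logHR = 0.7` for the
  resistant subtype, a small age effect) with Uniform(0, tau) censoring,
  tau solved numerically so the expected censored fraction matches the
  target.

Untranscribed enhancers yield exactly zero counts; real data would show
low-level background instead, so activity calling on real cohorts is a
harder problem than these tests exercise. Other simplifications: one
chromosome, no batch effects, no overdispersion beyond the log-normal
layer, marker sets that do not overlap, and an exponential (memoryless)
baseline chosen for analytic tractability of the recovery tests. Passing
the planted-structure suite therefore shows the machinery is correct and
calibrated under its own assumptions — not that those assumptions hold in
any particular AML cohort.

## Problem sizes and reproducibility

The validation suite runs cohorts of 60–400 samples with a few hundred
features, consensus clustering at 80–200 subsamples, and Monte-Carlo
loops of 200–500 replicates; null calibration checks use 150-sample
cohorts where the log-rank test's asymptotics are already accurate.
The API defaults keep the conventional values (1000 consensus
iterations, 500 forest trees). All randomness descends from explicit
seeds; the pipeline derives one sub-stream per stage from the global seed
by a deterministic string hash, so inserting a stage does not shift the
streams of the others, and `manifest.json` records parameters, derived
seeds and md5 hashes of every output table.

## Known limitations

The enhancer filter treats annotation as authoritative and has no notion
of unannotated transcription. The ir-eRNA screen inherits the usual
caveat that library-size composition effects can couple eRNA RPM values
to immune content; rank-based statistics soften but do not remove this.
Consensus clustering assumes the immune axis is the dominant structure
among prognostic ir-eRNAs. The E-score's sum form can lose contrast when
sets A and B are balanced — the difference mode exists for exactly that
case. Nomogram points assume linear covariate effects, and the
calibration bootstrap resamples within bins, ignoring binning
variability.
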