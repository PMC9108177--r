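# ernascape

Enhancer RNAs (eRNAs) are short non-coding transcripts produced at active
enhancers. Because they are strongly cell-type- and state-specific, their
expression profiles can stratify tumors in ways bulk mRNA profiles blur.
`ernascape` implements an eRNA-centered analysis of the acute myeloid
leukemia (AML) bone-marrow immune microenvironment as a reusable, tested R
pipeline: from enhancer intervals and read-count matrices to immune
subtypes, an eRNA-derived prognostic score, and a survival nomogram. It is
aimed at computational biologists working with bulk RNA-seq of leukemia (or
any tumor) cohorts who want the whole chain — or any single stage — as
plain R functions returning tibbles.

## What the pipeline computes

1. **eRNA quantification.** Enhancer loci (BED) are filtered against gene
   annotation (GTF): any enhancer overlapping an exon, a gene body, or a
   ±1 kb window around a TSS/TES is removed. The 3 kb window centered on
   each surviving enhancer's midpoint is the candidate eRNA region. Counts
   over these regions are normalized to reads per million
   (RPM = count × 10⁶ / library size), and an eRNA is *active* if its RPM
   reaches 1 in at least one sample.
2. **Enhancer–gene pairing.** Candidate pairs are all (eRNA, gene)
   combinations with |TSS − midpoint| ≤ 1 Mb; pairs with Spearman
   |ρ| > 0.3 and Benjamini–Hochberg FDR < 0.05 across all candidates are
   reported, with per-eRNA distance ranks.
3. **Immune profiling.** Per-sample immune-cell abundance is scored by
   single-sample gene set enrichment (ssGSEA, rank weight exponent 0.25)
   over marker gene sets (GMT), with ESTIMATE-style stromal/immune/purity
   summaries. eRNAs with |ρ| > 0.3 and p < 0.05 against at least one cell
   type are *immune-related* (ir-eRNAs); univariate Cox regression
   (p < 0.01, HR > 1.1 or < 0.9, per SD) marks prognostic features.
4. **Immune subtypes.** Consensus clustering (1000 subsamples of 80%,
   k-medoids on 1 − Pearson distance, Ward linkage on the consensus
   matrix) of prognostic ir-eRNA expression splits samples into
   immune-resistant (high suppressive-cell infiltration) and immune-active
   subtypes.
5. **E-score.** Moderated-t DEGs between subtypes (BH-adjusted p < 0.05)
   are filtered by the prognostic Cox gate, reduced by random-forest
   importance, and partitioned by the sign of their correlation with the
   subtype indicator into gene sets A and B. The E-score of a sample is
   `PC1.A + PC1.B`, the sum of the first principal components of the two
   set-wise standardized expression blocks; patients are split at the
   maximally selected log-rank cutpoint.
6. **Survival modelling.** Kaplan–Meier curves and log-rank tests for the
   high/low E-score groups; univariate and multivariate Cox models;
   Harrell's C; time-dependent (cumulative/dynamic, IPCW-weighted) ROC
   AUC; a 0–100-point nomogram over the multivariate fit with calibration
   curves.

A synthetic-cohort generator (`sim_config()`, `simulate_cohort()`) plants
every structure the analysis assumes — eRNA–gene correlation within 1 Mb,
two latent immune subtypes, immune-correlated eRNAs, proportional-hazards
survival — so each stage can be validated against known ground truth.

## A worked example

```r
library(ernascape)

cohort <- simulate_cohort(sim_config(seed = 1))   # 300-sample AML-like cohort
res <- run_pipeline(cohort, "run1", pipeline_config(reps = 200, seed = 1))

res$cluster$consensus
#> Consensus clustering over k = 2..6 (reps = 200, subsample = 0.80)
#> chosen k = 2; cluster sizes: 152, 148

res$surv$logrank
#> # A tibble: 1 × 3
#>   statistic    df  p_value
#>       <dbl> <int>    <dbl>
#> 1      12.4     1 0.000423

res$surv$c_index
#> # A tibble: 1 × 5
#>   c_index     se ci_low ci_high n_pairs
#>     <dbl>  <dbl>  <dbl>   <dbl>   <dbl>
#> 1   0.575 0.0245  0.527   0.623   28202
```

The chosen k = 2 recovers the two planted immune subtypes (adjusted Rand
index 0.97 against ground truth on this seed); the log-rank p-value says
the high-E-score group survives significantly longer than the low group;
the concordance index quantifies how well the continuous E-score ranks
survival (0.5 = random; the planted subtype hazard ratio of e^0.7 ≈ 2
bounds it near 0.6). Every stage's table is also written to the run
directory (`pairs.tsv`, `ir_ernas.tsv`, `deg_table.tsv`,
`escore_groups.tsv`, ...) together with `manifest.json` recording all
parameters, derived seeds and output hashes; re-running the same
configuration reproduces identical hashes.

Result objects have `tidy()`, `glance()` and `autoplot()` methods
(consensus heatmaps, forest plots, KM curves via `plot_km()`, nomogram and
calibration plots).

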