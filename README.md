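# chromstrat

Chromatin-accessibility stratification of tumour ATAC-seq cohorts.

Bulk expression subtyping can miss tumour subgroups whose difference is
regulatory rather than transcriptional. In ER-positive breast cancer, a
subgroup shows reduced chromatin accessibility at oestrogen-responsive
elements (EREs) and FOXA1-bound CREs while ER and FOXA1 themselves stay
expressed. chromstrat implements the full analysis needed to expose such
structure from ATAC-seq alone, for computational biologists working with
tumour cohorts:

- **Peak harmonization** — per-sample summits are extended to fixed
  501-bp peaks, blacklist-filtered, deduplicated by greedy *iterative
  overlap removal*, put on a per-sample *score-per-million* (SPM) scale
  `spm_i = score_i / (Σ_j score_j / 10^6)`, and merged across samples
  with SPM ≥ 5 and support ≥ 2 into a reproducible CRE set.
- **Counting & QC** — Tn5-corrected insertions (+4/−5 bp), half-open
  counting into peaks, `log2`-CPM (prior 5) + quantile normalization,
  TSS-enrichment scores (flank-normalized, 51-bp smoothed, pass ≥ 5),
  fragment-length histograms and the nucleosome-free (< 100 bp) re-run.
- **CRE annotation** — promoter (|summit−TSS| ≤ 1 kb) vs distal classes,
  overlap with TME cell-type reference CREs, *distal cancer CREs*
  (distal ∧ no TME overlap), and mean-accessibility TME deconvolution
  with Wilcoxon comparisons.
- **Classification** — common CREs (median ≥ 3, var ≤ 0.5), top 50,000
  variable CREs, Ward (`ward.D2`) tumour clustering at k = 3, k-means
  CRE modules at k = 5, PCA.
- **Differential analysis** — TMM + negative-binomial quasi-likelihood
  F-tests (edgeR), DAR/DEG calls at |log2FC| > 1 and FDR < 0.01 (BH).
- **Motif scores** — PWM scanning with an exact dynamic-programming
  threshold (per-position null probability 1e-4), GC/accessibility-matched
  background peaks, and chromVAR-style deviation z-scores
  `z = ((X−E)/E − mean_bg) / sd_bg`, compared between clusters by
  Student's t.
- **Survival** — surrogate marker score (mean of z-standardized marker
  expression), cutoff 0.4 split, Kaplan–Meier product-limit curves and
  the log-rank test.

A synthetic-cohort generator (`generate_cohort()`) plants all of this
structure — three tumour groups, ERE/FOXA1-motif regions reduced 0.4× in
one group with *unchanged* ER expression, immune-high TME gradients, a
nucleosomal fragment-length mixture, TSS-enriched insertions, and a
436-sample validation cohort with 45 marker-high tumours at hazard ratio
3 — so the whole pipeline is testable end to end without patient data.

## Worked example

```r
library(chromstrat)

config <- cohort_config(
  n_samples_per_group = 4, genome_length = 1e6, n_chroms = 2,
  n_true_regions = 800, fragments_per_sample = 60000,
  n_validation = 200, n_high_validation = 24, seed = 42
)
cohort <- generate_cohort(config)
result <- run_pipeline(cohort, pipeline_params(seed = 1))
result
#> <chromstrat_pipeline>
#>   12 samples, 800 merged peaks (120 promoter / 680 distal, 584 distal cancer CREs)
#>   clusters: CA-A=4, CA-B=4, CA-C=4
#>   DARs: 0 up / 105 down; markers: 18; ERE t-test p = 2.93e-07
#>   marker-score log-rank p = 1.94e-05
```

All 800 planted regions came back as merged peaks; the 120 planted
promoter regions and the TME overlaps were filtered to 584 distal cancer
CREs; and the three planted tumour groups were recovered exactly:

```r
tidy(result$clusters)
#> # A tibble: 12 x 2
#>    sample_id cluster
#>  1 S01_A     CA-A
#>  5 S05_B     CA-B
#>  9 S09_C     CA-C
#>  ...

adjusted_rand_index(
  dplyr::left_join(cohort$truth$groups, result$clusters$labels,
                   by = "sample_id")$cluster,
  cohort$truth$groups$group
)
#> [1] 1
```

The planted ERE-accessibility reduction in group B is detected as a
lower ERE motif score (105 A-specific DARs, ERE t-test p = 2.9e-07)
while ER "expression" is unchanged, and the marker-score split of the
validation cohort carries the planted survival effect:

```r
result$ere_test
#> # A tibble: 1 x 2
#>   statistic     p_value
#> 1      24.7 0.000000293

head(tidy(result$survival$km))
#> # A tibble: 6 x 6
#>   group   time n_risk n_event n_censor  surv
#> 1 low   0.0280    176       1        0 0.994
#> 2 low   0.0500    175       1        0 0.989
#> ...
```

`autoplot(result$survival$km)`, `autoplot(result$deviations, groups =
result$clusters$labels)`, `plot_volcano(result$dars)`,
`plot_fragment_lengths(result$fragment_lengths)` and
`plot_tss_profile(result$qc)` give the standard figures.

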