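# proxpress

Spatial neighborhood-enrichment analysis of the tumor immune
microenvironment (TIME) from multiplexed single-cell imaging, built for
cohorts of hormone-receptor-positive breast tumors classified by their
response to presurgical endocrine deprivation. The package is aimed at
analysts working with segmented cyclic-immunofluorescence (CycIF) cell
tables — one row per cell with coordinates, area and marker intensities —
who want to ask: *which immune markers press on the cancer cells of
resistant tumors more than on those of sensitive tumors?*

## The statistic

For cancer cell *i* in a sample, the **proximal pressure** of marker *m*
is the upper percentile of that marker's expression over all cells in the
cell's proximity constraint:

```
P_i(m) = Q_0.9 { x_j(m) : 0 < d_ij <= r },     r = k * d_hat
```

where `d_ij` is the centroid distance, `d_hat` is the cancer-cell
diameter estimated as the median area-equivalent diameter
`2 * sqrt(area / pi)` over all cancer cells (median nearest-neighbor
spacing when areas are missing), and `k` is the proximity constraint in
cell diameters (default 2, the "pressure area"). Percentiles use linear
interpolation between order statistics; empty neighborhoods yield missing
values, never zeros. Per sample the summary is the median of the
per-cell pressures; across samples each marker's summaries are z-scored
and compared between response groups (two-sided Wilcoxon rank-sum,
Benjamini–Hochberg across markers).

Around the core statistic the package provides the full pipeline:

- per-sample `log1p` z-score normalization of marker intensities
  (`normalize_markers`) and Gaussian-mixture gating of cancer cells from
  epithelial markers (`gate_cancer_cells`, "and/or" policies);
- the endocrine-response classifier — on-treatment Ki67 ≤ 2.7% sensitive,
  ≥ 7.4% resistant, in between intermediate (`classify_response`) — and
  the Ki67 labeling index `ln(AQUA + 0.01)` (`ki67_index`), plus
  configurable gene-signature scoring (`signature_score`);
- negative-probe limit of quantification, LOQ filtering and Q3
  normalization for segment-level spatial-transcriptomics count matrices
  (`compute_loq`, `filter_by_loq`, `q3_normalize`);
- shared kernels: `rank_sum_test`, `bh_fdr`, `roc_auc`;
- a synthetic-tissue generator with planted, recoverable ground truth
  (`sim_config`, `generate_tissue`, `generate_cohort`,
  `generate_counts`) so every stage is verifiable without patient data.

## Worked example

Simulate a ten-sample cohort in which resistant tumors attract CD8+
T cells five-fold more strongly than sensitive tumors, then run the full
pipeline (gate → normalize → pressure → compare):

```r
library(proxpress)
cfg <- sim_config(n_samples_per_group = 5, seed = 42)
run <- run_pipeline(cfg)
run
#> Pipeline run: 10 samples, 3650 cells (1503 gated cancer)
#> Group comparison of per-sample median proximal pressure (resistant vs sensitive)
#>  marker n_sensitive n_resistant statistic  p_value direction untestable     fdr
#>     CD8           5           5        25 0.007937        up      FALSE 0.03968
#>    CD20           5           5         9 0.547619      down      FALSE 0.68452
#>    CD68           5           5         6 0.222222      down      FALSE 0.51587
#>   FOXP3           5           5        12 1.000000      down      FALSE 1.00000
#>     CD4           5           5        18 0.309524        up      FALSE 0.51587
```

Only the planted CD8 signal survives FDR control (`fdr = 0.040`), with
the resistant-direction effect (`direction = up`); the statistic is the
Mann–Whitney U of resistant versus sensitive per-sample medians (5 vs 5
samples, so U = 25 is complete separation, exact p = 2/252). The
per-sample table underneath holds the medians and cohort z-scores:

```r
head(run$profile$samples[run$profile$samples$marker == "CD8", ], 4)
#>    sample_id marker n_cancer n_empty median_pressure          z
#> 1     sens01    CD8      150       7       0.2017354 -0.8959656
#> 6     sens02    CD8      151       4       0.2323719 -0.7276798
#> 11    sens03    CD8      151       4       0.1835561 -0.9958241
#> 16    sens04    CD8      150       8       0.2247057 -0.7697904
```

Pressures here are on the per-sample z-scored intensity scale, so a
median of ~0.2 means the 90th-percentile CD8 signal near cancer cells
sits a fifth of a standard deviation above the sample average. The
clinical formulas are one-liners:

```r
ki67_index(c(0, 0.99, 12.3))
#> [1] -4.6052  0.0000  2.5104
classify_response(c(2.7, 5.0, 7.4))
#> [1] "sensitive"    "intermediate" "resistant"
```

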