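---
title: "Proximal pressure: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proximal pressure: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxpress)
```

## The problem

Multiplexed immunofluorescence gives, per tissue core, a table of
segmented cells with centroid coordinates and tens of marker
intensities. In hormone-receptor-positive breast cancer treated with
short presurgical estrogen deprivation, tumors that keep proliferating
(on-treatment Ki67 at or above 7.4%) behave differently from those that
shut down (Ki67 at or below 2.7%), and a natural question is whether the
immune cells pressing on the cancer cells differ between the two groups.
`proxpress` quantifies that pressure cell by cell and carries the result
through a grouped cohort comparison, with a synthetic-tissue generator
providing ground truth for verification.

## The pressure statistic

For each cancer cell the neighborhood is every other cell — of any
class, including other cancer cells — whose centroid lies within
`radius_in_diameters` times the estimated cancer-cell diameter; the
boundary is included and the index cell excluded. The proximal pressure
of a marker is the 90th percentile of that marker's expression over the
neighborhood.

Conventions worth stating explicitly, because each was a genuine choice:

* **Radius.** Descriptions of the pressure area alternate between "one
  cell diameter around each cancer cell" and "a two-cell radius". We
  read "one diameter *around*" a cell of diameter $d$ as centroid
  distance $\le 2d$ (the cell's own radius plus one diameter on each
  side collapses to the same thing for centroids), which coincides with
  the two-cell-radius phrasing; `radius_in_diameters` defaults to 2 and
  either literal reading is available by passing 1 or another value.
* **Diameter.** With areas present, the median over cancer cells of the
  area-equivalent circular diameter $2\sqrt{A/\pi}$; without areas, the
  median nearest-neighbor distance among cancer cells. A sample with a
  single cancer cell and no areas is reported unusable rather than
  guessed at.
* **Percentile.** Linear interpolation between order statistics (the
  type-7 convention): the 90th percentile of $\{1,\dots,10\}$ is 9.1,
  not the nearest-rank 10. Fixed once so runs are comparable.
* **Empty neighborhoods** produce missing values and are counted per
  sample; substituting zeros would fabricate low pressure where there is
  simply no neighbor.
* **Aggregation.** Per sample and marker the summary is the median over
  non-missing per-cell pressures. Cohort z-scores of the summaries use
  the population ($n$) denominator, so that with $\ge 2$ samples the
  scores have mean 0 and variance exactly 1. When patients contribute
  several cores the default scores across samples;
  `collapse_by_patient()` re-aggregates to one value per patient first,
  since either reading of "cohort" is defensible.
* **Comparison.** Two-sided Wilcoxon rank-sum on per-sample summaries
  (exact when the smaller group has $\le 10$ tie-free observations,
  mid-rank normal approximation with continuity correction otherwise),
  Benjamini–Hochberg across markers, effect direction the sign of the
  resistant-minus-sensitive median difference. For 8-vs-8 tie-free
  groups the corrected approximation tracks the exact two-sided p to
  within 0.011 everywhere and within 0.01 throughout the tail where
  decisions are made; the worst case sits at central U around
  $p \approx 0.44$. A marker with no usable
  summaries in one group is reported untestable instead of dropped.

The neighbor search is grid-bucketed (bins of side `radius`, 3 × 3
lookup); unit and acceptance tests hold it to within $10^{-9}$ of an
exhaustive $O(n^2)$ reference on random tables, and a field-covering
radius reduces every cell's pressure to the global 90th percentile over
all other cells, which is checked as a limit case.

## Cell typing

Cancer cells are gated from epithelial markers (E-cadherin, pan-CK) with
an "and/or" policy: positive for at least one marker (`any`, default) or
for all (`all`). Per sample and marker a two-component Gaussian mixture
is fit by EM to the log of the strictly positive intensities, seeded at
the 25th/75th percentiles so the fit is deterministic; the threshold is
the equal-posterior crossing between the component means, and a cell
exactly at threshold is called non-cancer (a conservative denominator
for pressure). Pure `log` rather than `log1p` is used here so that
rescaling a marker rescales the threshold covariantly and leaves labels
unchanged — an invariance the tests exercise — with zero intensities
below any threshold by construction. Degenerate fits (collapsed
components, fewer than 20 positive cells) fall back to the
75th-percentile threshold and are flagged in the gating report.

Marker normalization for the pressure stage is per-sample, per-marker
`log1p` z-scoring. The original assays were scaled against internal
control tissues that a reanalysis cannot access; per-sample z-scoring is
the package's stand-in and preserves the rank structure the percentile
statistic consumes. Markers constant within a sample are centered only
and flagged. Pressure itself runs on whatever scale it is given, so
pre-normalized inputs can use `mode = "raw"`.

## Clinical formulas and signatures

`ki67_index()` is the printed formula `ln(AQUA + 0.01)`, strictly
increasing and exactly invertible. `classify_response()` uses closed
boundaries — 2.7 is sensitive, 7.4 is resistant — per the printed
$\le$/$\ge$ criteria, and partitions $[0, 100]$ monotonically.
`signature_score()` defaults to the two-gene cytolytic set
(GZMA, PRF1) under a geometric mean with pseudocount 0.01; the gene set
and method (`geomean`, cohort `meanz`) are configurable because the
CD8-activation gene list behind the published score is not enumerated —
the package records that openness rather than guessing a list.

## Segment-level normalization

For compartment count matrices with negative probes, the limit of
quantification is "the geometric mean plus 2 SDs of the negative
probes". That phrase is ambiguous about the SD scale, so both readings
are implemented: the default `geometric` mode,
$\mathrm{LOQ} = \mathrm{geoMean} \times \mathrm{geoSD}^2$, and the
literal `arithmetic` mode, $\bar n + 2\,\mathrm{sd}(n)$. Standard
deviations use the population ($n$) denominator — with two probes at 1
and 100 the geometric mode then gives
$10 \times 10^2 = 1000$ exactly. Zeros receive a 0.5 pseudocount before
logs; a segment whose probes are all zero is flagged unquantifiable.
Genes are retained when above the segment LOQ in at least a fraction
`min_segment_fraction` of quantifiable segments (default 0.1, an
artifact choice — the original QC thresholds inside the vendor suite are
not printed); negative probes are never retained.

Q3 normalization divides each segment by
$Q3_s / \mathrm{target}$ with the target the geometric mean of the
retained segments' 75th percentiles (the platform convention, keeping
values on the count scale). After normalization every retained segment's
Q3 equals the target to $10^{-9}$ and renormalizing is a no-op. One
subtlety: under the geometric-mean target, multiplying a single
segment's counts by $k$ shifts *every* normalized value by the common
factor $k^{1/S}$ — exact single-segment scale invariance is impossible
with a data-driven target. Passing a fixed numeric `target` restores the
exact invariance; the tests cover both behaviors.

## What the generator emulates — and what it does not

`generate_tissue()` builds one core: cancer cells from a Thomas-like
cluster process (default 150 cells in 5 nests of spread 60 on a
1000 × 1000 field, roughly a dense TMA core at micrometre scale), and
each immune population as a mixture of a uniform component and an
attracted component whose density decays exponentially with distance to
the nearest cancer cell. The kernel scale is one synthetic cell diameter
($2\sqrt{\bar A/\pi} \approx 16$ for the default 200-unit² areas), the
single interpretable parameter; the mixing weight is
$\lambda/(1+\lambda)$, so $\lambda = 0$ is exactly uniform and the
attracted fraction saturates as $\lambda$ grows. The attracted component
is drawn by rejection sampling, which is exact for that density.
Intensities are lognormal: each class's defining marker at
$\mu_{\log} = 6$, everything else at the background $\mu_{\log} = 3$,
both with $\sigma_{\log} = 0.5$ — a six-sigma separation chosen so that
gating, a downstream consumer, has genuine bimodality to find.
`generate_cohort()` plants the group signal by multiplying selected
populations' $\lambda$ in resistant samples (default: CD8 × 5) and draws
on-treatment Ki67 uniformly from [0.5, 2.7] (sensitive) and [7.4, 25]
(resistant), so every synthetic sample falls unambiguously inside the
printed classification bands. `generate_counts()` plants an
expressed/unexpressed gene split with segment-specific scale factors;
unexpressed genes sit slightly below the negative-probe mean so the
planted split is separable by a probe-derived LOQ at realistic probe
counts. All randomness flows from the configuration seed (per-sample
offsets), and identical configurations reproduce byte-identical tables.

The generator deliberately does not emulate pixel-level images,
segmentation or registration error, autofluorescence, spatially varying
background, correlated marker panels, multi-nest phenotype gradients, or
patient-level heterogeneity beyond the group effect. Passing tests
therefore demonstrate that the algorithms recover signals of the planted
form, not that real tissue satisfies the model; on real data the gating
and normalization stages absorb much, but not all, of what is missing
here.

## Validation problem sizes

The shipped checks use cohorts the package can rerun quickly: detection
power for the five-fold CD8 effect is estimated over 100 replicate
cohorts of 20 samples per group (observed: essentially every cohort
significant at BH < 0.05 with the resistant direction), and null
calibration over 200 replicate cohorts of 6 per group with all
multipliers at 1 (observed rejection ≈ 5%; the exact rank-sum test is
slightly conservative at these group sizes, which is a property of the
test, not a defect). The exhaustive-reference comparisons use random
tables of up to 2,000 cells. These sizes are the package's validation
choices and scale linearly if larger studies are simulated.

## Known limitations

* The pressure statistic is a hard-radius percentile; kernel-weighted or
  graph-neighborhood variants are out of scope by design.
* Immune phenotypes are not gated into subtypes — pressure consumes
  continuous normalized intensities, matching the original analysis; a
  gating tree for CD4/CD8/FOXP3 calls would be a separate layer.
* The multiplicity procedure is Benjamini–Hochberg throughout; no other
  FDR variant is offered.
* `meanz` signature scores need a cohort; single-sample inputs must use
  the geometric mean.
* The EM gate assumes an approximately bimodal log-intensity
  distribution per sample; heavily skewed unimodal samples fall back to
  a quantile threshold, which is blunt (and flagged as such).
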