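---
title: "Anchor-gene transcriptome analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-gene transcriptome analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorscope)
```

## The analysis in one paragraph

`anchorscope` characterises the transcriptomic context of one anchor gene
(the motivating application is *RUNX3* in CD14+ monocytes from the MESA and
CEDAR cohorts) by running the same four stages in two independent cohorts
and merging only at the end: median-filter and log-transform the intensity
matrices; correlate every gene with the anchor and meta-rank by the
cross-cohort mean r; select predictive genes with a tuned
extremely-randomized forest and intersect high-importance genes across
cohorts; and apply DRAIMI — bootstrap ranking of transcript ratios that
differ between the upper and bottom anchor deciles, followed by scoring of
protein–protein-interaction (PPI) pivot genes. Keeping the cohorts separate
until the merge trades some sensitivity for a lower false-positive rate:
only effects that replicate appear near the top of any merged table.

## Preprocessing

Microarray intensity matrices are assumed non-negative, complete (no
missing values), and already summarised to one row per gene symbol;
duplicated symbols are rejected rather than collapsed, because probe-level
collapsing rules vary by platform and belong upstream.

* **Median filter.** A gene is kept when its per-gene median intensity over
  samples passes a threshold. Two modes exist because the two cohort
  conventions differ: `strictly_greater` ("median greater than zero") and
  `at_least` ("a threshold of 1, reached by ..."). The median of an even
  sample count is the mean of the two central order statistics
  (`stats::median`). The filter is idempotent, and an empty result is a
  warning rather than an error so the caller decides how to fail.
* **Offset + log.** Every value v becomes `log_base(v + offset)`. The
  offset default is 1, which maps zero intensity to zero on the log scale
  — the most common microarray convention when no offset is stated — and
  the base default is 2 (expression fold changes are conventionally read in
  log2 units). Both are configurable; a non-positive `v + offset` is a hard
  error naming the gene and sample.

## Anchor correlation and cross-cohort meta-ranking

Pearson r is computed on the log scale; the two-sided p-value comes from
`t = r sqrt((n-2)/(1-r^2))` on `n - 2` degrees of freedom (identically
`stats::cor.test`). A perfect `|r| = 1` is assigned p = 0 exactly instead
of propagating a division by zero. The FDR family is all non-anchor genes
within one cohort — matching per-cohort adjusted-p columns — and the
procedure is Benjamini–Hochberg (`stats::p.adjust`), the default meaning of
"FDR" in transcriptomics. The meta-statistic is the plain arithmetic mean
`r_mean = (r_A + r_B)/2` over the inner join of the two filtered gene sets;
no weighting by cohort size is applied because the statistic is used for
ranking consistency, not for estimating a pooled effect.

Report files round to 2 decimals, half away from zero; all chained
computation keeps full precision. (Rounding-to-even would disagree with
half-away printed values on exact halves such as 0.565; the implementation
also guards the half-away rule against binary representation error, since
0.565 × 100 is 56.4999… in floating point.) Ranking ties are broken by gene
symbol so output files are reproducible byte for byte.

## Random-forest feature selection

The forest predicts the anchor's log expression from all other genes with
`ranger`, using extremely-randomized split thresholds (`splitrule =
"extratrees"`), 101 trees, and a grid over mtry (5–50 in steps of 5) and
minimum node size (2 or 3), tuned by repeated k-fold cross-validation
(10-fold × 5 repeats by default) selecting by RMSE, with R² and mean
absolute error reported alongside. Fold assignments are drawn once per
repeat and shared across the whole grid so every candidate sees identical
splits; each forest receives a deterministic seed derived from the
configuration seed, making the entire tuning path reproducible. The best
configuration is refit on all samples and impurity (variance-reduction)
importance is extracted from that final refit — the alternative, averaging
importance over CV resamples, is noisier and was not used. Importances are
rescaled so the maximum equals 100, the convention that makes per-cohort
tables comparable; the cross-cohort intersection keeps genes strictly above
a threshold (40 or 70 in the shipped workflow) in both cohorts.

Desk-scale runs in the test-suite and the acceptance script use a reduced
grid (a single mtry, node size 2, 5-fold × 1 repeat) on 200 genes ×
300 samples; what those runs assert — recovery of planted predictors in
the top of the importance table — is a property of the forest and the
importance scaling, not of the width of the tuning grid, which remains at
its full default for real analyses.

## DRAIMI

On the log scale a transcript ratio is a difference, so for genes a and b
the per-sample statistic is `d_s = x_a,s − x_b,s`.

1. **Groups.** Upper and bottom anchor deciles: group size
   `floor(f · n)` with `f = 0.10` by default, minimum 1, ties at a
   boundary broken by sample-id order, groups always disjoint. The anchor
   is excluded from the ratio gene set by default since its own deciles
   define the groups (a flag restores it).
2. **Per-pair statistic.** Absolute Welch two-sample t on the d values,
   chosen for robustness to unequal group variances; the statistic is a
   small pluggable function, so a different two-sample statistic can be
   swapped in without touching the bootstrap. A 0/0 (both groups constant
   and equal) is defined as t = 0; a nonzero difference with zero pooled
   variance ranks as infinite.
3. **Consistency.** Within-group bootstrap (resampling samples with
   replacement, group sizes preserved, `n_bootstrap = 100` by default):
   the fraction of replicates in which the pair's |t| ranks within
   `per_bootstrap_k` (default 1000, equal to the final top-K) of all pairs.
   Pairs are ranked by consistency, then |t|, then pair lexicographic
   order — every tie-break is documented and deterministic.
4. **Pivot scoring.** For each PPI node g with degree ≥ 1, `hits(g)` counts
   top-K ratios (a, b) with g ∉ {a, b} and both edges {g,a}, {g,b} present;
   the intermediary ratio is `hits / degree` with degree taken in the full
   loaded graph (a flag restricts it to the analysed gene set). Zero-degree
   nodes are excluded (division undefined); zero-hit nodes are kept with
   score 0. Requiring the pivot to be distinct from both ratio members
   follows from the idea of an intermediary: a node bridging two *other*
   gene products. Note that `hits/degree` is only empirically small — a
   node can in principle bridge more top pairs than it has neighbours
   (hits is bounded by K, not by degree), so scores above 1 are possible
   on dense toy graphs even though real networks with K = 1000 stay far
   below 1.
5. **Merge.** Inner join of per-cohort pivot tables, ranked by the mean
   intermediary ratio, printed to 2 decimals half away from zero.

The PPI network is read from a STRING-style 3-column TSV (node, node,
integer confidence 0–1000) keyed by gene symbol; mapping protein
identifiers to symbols is assumed done upstream, which keeps the package
fully offline. The default confidence cutoff is 700, STRING's
"high confidence" convention, since the original cutoff is not recorded.

## The synthetic generator: what it emulates, what it does not

`synthetic_spec()` describes two cohorts (default sizes mirror the
motivating study's 1202 and 281 samples when run at paper scale; tests use
60–500 samples and 40–200 genes to stay fast) with three planted
structures on a log-scale Gaussian intensity model:

* **Correlates**: `x = r z + sqrt(1 − r²) ε` against the standardized
  latent anchor signal z, then rescaled by a per-gene location and scale
  drawn from `base_mean` (default 6–10 log2 units, typical microarray
  range) and `base_sd` (0.5–1.5). Intensities are `2^value − offset`
  clipped at zero, so the standard preprocessing recovers the planted
  log-scale structure exactly (clipping is a ~7-standard-deviation event at
  these means and never triggers in practice).
* **Ratio pairs**: the pair's log difference shifts by the configured
  amount between upper and lower latent-anchor deciles. The shift is
  split ±shift/4 across both members and both deciles, so the planted
  pair moves by the full shift while any pair sharing a single member
  moves by half — keeping the planted pair the strongest differential
  ratio. Deciles are computed on the latent anchor signal and the shift
  is applied after correlate planting, so the two structures do not
  interact.
* **Pivots**: wired to both members of each assigned ratio pair
  (confidence 999); background edges appear independently with a
  configurable probability. With zero background, a planted pivot's truth
  score is exactly (assigned pairs) / (distinct pair members).

The global seed expands into per-cohort, per-gene and per-graph substreams
(a small deterministic string hash), so adding one planted entity does not
perturb any unrelated draw. Planted effect magnitudes (r ∈ {0.75, 0.5,
−0.55}, ratio shift 3 log2 units) are calibration choices representative
of the strongest effects the motivating study reports, not estimates of
any real cohort's correlation structure. The generator deliberately omits
probe-level artifacts, batch effects, covariates (age/sex/smoking), and
heavy-tailed noise: passing tests demonstrate that the algorithms recover
what they are defined to recover, not that real monocyte data meet these
assumptions.

## Sizes, tolerances, degenerate inputs

* Test-suite problem sizes: 40–200 genes, 60–500 samples, bootstrap 30–100
  replicates, toy PPI graphs ≤ 15 nodes with exhaustive brute-force
  cross-checks (≥ 200 instances).
* Planted r = 0.7 at n = 1000 is required to be recovered within ±0.05;
  the planting error is also checked to shrink from n = 100 to n = 1000.
* Degenerate inputs: zero-variance genes are an explicit error in the
  correlation scan (an undefined correlation should not silently become
  NA); an empty median-filter result warns and returns; an empty
  cross-cohort intersection warns and returns an empty table; an empty
  PPI file warns and yields an empty graph.
* End-to-end determinism is tested at the pipeline level: identical
  configuration and seed produce byte-identical output TSVs.

## Known limitations

* One row = one gene: multi-probe handling must happen upstream.
* No covariate adjustment, partial correlation, or rank-based correlation.
* Permutation importance and SHAP are out of scope; impurity importance is
  biased toward high-variance predictors, which is acceptable here because
  predictors share a common scale after log transformation.
* The bootstrap consistency criterion and replicate count are method
  parameters, not estimated quantities; conclusions about a pair's
  stability are conditional on them.
* The pivot score divides by full-graph degree, so genes with very large
  interaction neighbourhoods need many bridged ratios to rank highly;
  restricting the denominator to the analysed gene set is available but
  changes the score's interpretation.
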