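---
title: "Methods: nucleus morphometry and image-based prognosis in histomorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nucleus morphometry and image-based prognosis in histomorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histomorph)
```

# Overview

`histomorph` implements an interpretable computational-pathology workflow
for H&E-stained tumour tissue, aimed at gastric adenocarcinoma but not
specific to it. From RGB image tiles it measures per-nucleus morphometry,
summarizes each patient into a fixed 150-dimensional feature vector, and
feeds that vector into three analyses:

1. **Genotype–phenotype association** — every feature is compared between
   mutated and wild-type patients for each frequently mutated gene
   (Mann-Whitney U, Benjamini-Hochberg FDR, fold change of medians).
2. **Prognosis** — a risk index from leave-one-out cross-validated
   lasso-penalized Cox regression with a univariate log-rank pre-filter;
   patients are split at the median risk index and the split is tested by
   log-rank and compared against dichotomized clinical factors in
   univariable and multivariable Cox models.
3. **Transcriptome integration** — features that the prognostic model
   selects consistently are correlated (Spearman) with gene expression,
   and the top correlated genes are tested for gene-set
   over-representation with a hypergeometric test.

Because real whole-slide cohorts are large and access-controlled, the
package ships a first-class synthetic-data module that generates
ground-truthed tiles, cohorts with planted mutation/survival effects, and
expression matrices. All statistical guarantees quoted below are verified
against these generators in the test suite.

# Image processing

## Stain normalization

`normalize_stain()` works in optical-density (OD) space,
$OD = -\log(I/255)$. Tissue pixels (summed OD above 0.15) are decomposed
into two stain components: the top two eigenvectors of the *uncentered* OD
second-moment matrix span the stain plane (stain mixtures are nonnegative
combinations through the origin, so the first eigenvector points along the
mean OD direction and stain angles do not wrap), and the stain vectors are
taken at the 1st/99th percentiles of the angular distribution within that
plane. Per-pixel concentrations are obtained by least squares, clipped at
zero, rescaled so that each stain's 99th-percentile concentration matches
the reference maximum, and re-rendered in the reference basis
(`stain_reference()`, Ruifrok–Johnston H&E vectors). This is a standard
stain-vector-estimation normalization; it preserves concentration ranks
per stain, which is all the downstream morphometry needs. Near-blank
tiles (fewer than 50 tissue pixels) are returned unchanged with a warning
flag rather than normalized against noise.

## Segmentation

`segment_nuclei()` realizes hierarchical multilevel thresholding with
standard, testable components:

* the tile is projected onto the dominant-stain OD direction
  (hematoxylin-like channel);
* a first Otsu threshold separates stained foreground from background;
* a second Otsu *within* the foreground separates dark nuclei from dimmer
  cytoplasm/stroma — but only when the foreground is genuinely bimodal.
  The guard is the Otsu objective itself: the maximized between-class
  variance as a fraction of total variance is ≈ 0.64 for unimodal
  Gaussian-like data and approaches 1 for well-separated modes; the
  second level (and the first, which protects blank or noise-only tiles)
  is applied only above a score of 0.75 (`seg_params()$second_level_score`);
* binary regions are hole-filled, touching nuclei are split by watershed
  on the distance transform (EBImage), and regions under
  `min_area = 30` px² are discarded (appropriate near 0.5 µm/pixel).

Detections with area strictly above the per-image 95th percentile
(nearest-rank definition) are removed by `filter_large_nuclei()`; such
outliers are typically tissue folds or merged clumps. The percentile is
computed per image rather than from a single designated reference image —
per-image adapts to staining variation — and the function takes the
percentile as an argument so either policy is available.

Coordinates are 1-based (row, col) pixel positions, the R convention;
areas are pixel counts.

# Cell-level features

Each retained nucleus carries ten features: `area`, `major`, `minor`
(full axis lengths of the ellipse with the region's second central
moments — the moment fit is deterministic and matches EBImage's moment
features to 1e-6), `ratio` (major/minor, ≥ 1; degenerate single-pixel
regions clamp the minor axis to 1 px and are flagged), `rMean`, `gMean`,
`bMean` (mean channel intensities, 0–255), and `distMean`, `distMax`,
`distMin` — summaries of the Euclidean centroid distances to the
nucleus's neighbours in the Delaunay triangulation of all centroids in
the tile (`deldir`). Two centroids fall back to a single edge; collinear
sets connect as a path; a failed triangulation retries once after a
deterministic 1e-6-px jitter. Isolated nodes get missing distance
features and are excluded from distance-feature aggregation only. Long
boundary (hull) edges are not pruned by default; a maximum-edge-length
option would be the natural extension but the distance summaries are
robust to the few long hull edges in practice.

Distances are in pixels; no micron conversion is applied unless the
caller rescales, which keeps ×20/×40 material explicit rather than
silently mixed.

# Patient-level aggregation

All slides of a patient are pooled into one cell table. For each of the
ten cell-level features the patient receives a 10-bin histogram
(proportions, summing to 1) plus five raw-value statistics, giving the
150 canonical features of `feature_names()` (e.g. `area_bin1` …
`area_bin10`, `area_mean`, `area_std`, `area_skewness`, `area_kurtosis`,
`area_entropy`).

The histogram bins must be identical for every patient to make the
proportions comparable. `fit_bin_scheme()` derives them once, on a
reference cohort: 10 equal-width bins spanning the nearest-rank
[P1, P99] of the pooled cell values, so extreme outliers cannot stretch
the bin width. The scheme is serialized to JSON (edges stored as `%.17g`
strings, because plain JSON doubles lose the final bits) and reused
verbatim by later cohorts. Cell values outside the range clamp into the
first/last bin. Conventions for the statistics, chosen once and
documented here because several definitions circulate: standard deviation
is the population form (divide by *n*); skewness is the moment
coefficient $g_1 = m_3/m_2^{3/2}$; kurtosis is $m_4/m_2^2$ (non-excess, a
normal gives 3); entropy is the Shannon entropy of the 10 bin proportions
with natural log ($0\ln 0 \equiv 0$, maximum $\ln 10 \approx 2.303$).
Statistics are computed on the raw pooled values, not on the binned
histogram.

# Mutation–morphology association

Genes mutated in **strictly more than** 15% of patients are tested
(`select_frequent_genes()`). For each gene × feature pair,
`mann_whitney_two_sided()` compares the feature between mutated and
wild-type patients: exact p-values from the null U distribution when the
combined sample is ≤ 12 without ties, otherwise the normal approximation
with tie and continuity corrections. Fold change is the ratio of the
mutated-group median to the wild-type median (missing when the wild-type
median is 0 — an infinity would poison downstream plots). FDR correction
is Benjamini-Hochberg; the family is **all gene × feature tests jointly**
by default, with a per-gene family behind `fdr_family = "per_gene"` —
the joint family is the conservative reading when the family definition
is not otherwise fixed. Gene–patient groups with fewer than 2 members are
flagged untestable and excluded from the FDR family.

# Prognostic model

The risk index is built under strict leave-one-out cross-validation
(`loocv_risk_indices()`); for each held-out patient:

1. **Screen.** Every feature is dichotomized at its *training-set*
   median (ties to the "≥ median" group) and tested by two-group
   log-rank; features with p < 0.05 are retained. No multiplicity
   correction is applied at this screening step — the goal is to keep
   trending features; see the calibration caveat below for what the
   LOOCV wrapper does and does not protect against.
2. **Fit.** The retained features are z-scored by training mean/SD and a
   lasso Cox path is fitted with `glmnet`; the penalty is chosen by
   10-fold cross-validated partial-likelihood deviance at the deviance
   minimum (a "1-SE" rule is available via `lambda_rule = "1se"`).
   Standardization matters because the 150 features mix proportions
   in [0, 1] with pixel-scale statistics; an unstandardized L1 penalty
   would effectively never select the proportions. With exactly one
   retained feature there is nothing for the lasso to select between, so
   an unpenalized Cox fit is used; with none, the fold emits an empty
   model and risk 0.
3. **Predict.** The held-out risk index is the inner product of the
   held-out patient's training-standardized features with the fold's
   coefficients.

The inner CV fold assignment for fold *i* derives from `seed + i`, so the
whole procedure is deterministic. Patients with non-positive follow-up
are dropped with a warning (they break the partial likelihood). After all
folds, patients split at the median risk index; ties at the median go to
the low-risk group (a declared convention — some published pipelines put
them high; the choice only matters for exactly-tied indices). The log-rank
test implementation is the package's own single-pass version (vectorized
across features, exact agreement with `survival::survdiff` is enforced in
tests) because screening 150 features × *n* folds makes `survdiff`'s
per-call overhead the bottleneck.

`summarize_selection()` reports, per feature, in how many folds it
received a nonzero coefficient and its mean coefficient *over the
selecting folds only* (the averaging convention; never-selected folds do
not drag the mean toward zero). `cox_regression()` fits univariable and
multivariable proportional-hazards models on dichotomized factors
(stage I+II vs III+IV, G1+G2 vs G3, MSS vs MSI-L+MSI-H via
`dichotomize_clinical()`), first level = reference, Wald hazard ratios
with 95% CIs.

# Expression integration

For each consistently selected feature (default: nonzero in ≥ 80% of
folds), `spearman_profile()` computes the rank correlation against every
gene (rank-then-Pearson, average ranks, pairwise NA dropping).
`select_top_genes()` keeps genes with |ρ| ≥ 0.3 — the boundary is
inclusive, with a strict-inequality flag — ranked by |ρ| and capped at
100. If fewer than 10 genes qualify, enrichment is skipped for that
feature: over-representation statistics on one or two genes are
uninformative, and 10 is the configurable default for "enough to bother".
`hypergeometric_enrichment()` tests one-sided over-representation against
user-supplied GMT gene sets, with the expression matrix's gene list as
the default universe — that is the sampling frame the correlations were
computed on, and an offline tool cannot reproduce a web service's
internal background.

# Synthetic data: what it emulates and what it does not

`generate_tile()` renders lognormal-area, lognormal-elongation (clipped
≥ 1) ellipses at uniform orientations on a near-white background, with a
hard-core minimum centroid separation enforced by rejection sampling
(capped at 10,000 attempts per nucleus — exceeding the cap raises an
"overcrowded tile" error rather than looping forever), Gaussian pixel
noise (SD 3 grey levels), and a guarantee that rendered ellipses never
touch, so the label mask has exactly the requested number of connected
components. Ground truth (centroids, areas, axes) is returned alongside.
This validates segmentation geometry and the morphometry chain; it does
**not** emulate chromatin texture, nucleus clumping/overlap, cytoplasmic
staining gradients, or batch effects — so passing segmentation tests here
demonstrates correctness of the algorithmic chain, not clinical-grade
performance on real slides.

`generate_cohort()` draws the 150 patient-level features i.i.d. Gaussian
(mean 10, SD 2 — arbitrary units; the Gaussian surrogate ignores the
simplex constraint that real histogram bins obey, which none of the rank-
or regression-based downstream statistics rely on). Mutations are
Bernoulli per gene; mutated patients shift the affected feature by the
stated effect size in pooled-SD units. Survival is exponential
proportional hazards on the z-scored features with independent
exponential censoring; the defaults (baseline hazard 0.02/month,
censoring 0.035/month) give roughly 35–40% observed deaths and a median
follow-up near a year, typical of a gastric-adenocarcinoma cohort, and
times are in months. `generate_expression()` maps the driving feature's
ranks to normal scores and mixes in Gaussian noise at the weight
$r = 2\sin(\pi\rho_s/6)$ that yields the target Spearman correlation
under the bivariate-normal copula; targets of ±1 use the noiseless
monotone transform so the realized rank correlation is exactly ±1.
Undriven genes are independent noise.

All generators restore the caller's RNG state, and identical specs with
identical seeds are bit-reproducible.

# Numerical and testing notes

* Nearest-rank percentiles (`nearest_rank_percentile()`) are used
  wherever a percentile feeds a hard decision (size filter, bin ranges):
  they always return observed values, which makes small worked examples
  exact.
* The exact Mann-Whitney p uses `stats::pwilcox`; tests verify it against
  full enumeration of labelings. BH q-values come from `stats::p.adjust`
  and are verified against a brute-force sort/scale/cummin oracle.
* The hypergeometric enrichment p-value is discrete and therefore
  super-uniform under the null; calibration tests assert
  $P(p \le \alpha) \le \alpha$ (plus Monte-Carlo margin) rather than a
  Kolmogorov-Smirnov match to the continuous uniform, which discreteness
  alone would fail.
* Simulation sizes in the test suite: null calibration of the screen and
  the association stage uses 100 cohorts of n = 200; the LOOCV
  selection-bias audit uses 50 cohorts of n = 100; planted-signal
  recovery uses n = 300 with 25 seeds (10 for the full LOOCV power run,
  whose per-seed cost is dominated by 300 inner cross-validations).
  These sizes give binomial standard errors comfortably inside the
  asserted bounds.
* The LOOCV leakage guard re-runs a fold's entire training pipeline on
  the data with the held-out row removed and asserts bit-identical
  coefficients, penalty, and standardization parameters — the held-out
  patient is provably unused.

## Calibration caveat: the pooled test on out-of-fold risk indices

Out-of-fold prediction guarantees that no patient's own survival enters
their own risk index, and the test suite proves this bit-exactly (the
leakage guard). It does **not** make the final log-rank test of the
median split well calibrated. The fold models share n − 1 of n patients,
so the screen and the lasso converge on essentially the same
chance-significant features in every fold, fitted to almost exactly the
patients being tested; removing one patient per fold removes only a 1/n
share of that optimism. This is the documented anti-conservatism of
significance tests on "pre-validated" predictors. The package's own
null-cohort audit (n = 100, 50 seeds) measures the effect directly: the
split reaches p < 0.05 in roughly a third of null seeds rather than the
nominal ≤ 10%, with a bimodal p distribution (seeds whose screens retain
chance features give extreme p-values; seeds whose screens retain
nothing give none). The risk index is therefore useful as a *predictor*
— planted-signal cohorts are recovered with near-perfect selection and
stratification — but the pooled split p-value on the same cohort the
models were built from overstates significance and should be read as
descriptive, or validated on an external cohort.

# Known limitations

* The stain normalization is a stain-vector estimation method, not a
  structure-preserving decomposition; heavily necrotic or
  single-stain-dominant tiles fall back to a single-stain path.
* Watershed under-segments genuinely overlapping nuclei; the synthetic
  generator does not produce overlaps, so this failure mode is untested
  by design and should be expected on dense real tissue.
* The Cox machinery assumes proportional hazards and right censoring;
  no competing-risk or time-varying support.
* Enrichment results depend entirely on the supplied GMT collection; the
  package ships only a toy collection in its demo.
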