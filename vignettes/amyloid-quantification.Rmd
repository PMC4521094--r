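---
title: "Amyloid-PET quantification, cut-off harmonization and mixture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Amyloid-PET quantification, cut-off harmonization and mixture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amypet)
```

## The scientific problem

Amyloid PET tracers such as [11C]PIB and [18F]Florbetapir bind fibrillar
amyloid-beta, and regional uptake ratios are used to decide whether a scan
is "amyloid positive". Three analytical problems recur in this setting and
are what `amypet` implements:

1. **Quantification.** Voxel uptake is scaled by a reference region
   (cerebellum) into standardized uptake value ratios (SUVR), averaged over
   bilateral grey-matter ROIs, and summarised by a composite neocortical
   ratio (CCTXR) over the frontal, parietal and lateral-temporal cortices.
2. **Cut-off derivation and harmonization.** A positivity cut-off is the
   ROC point closest to (0, 1) for discriminating controls from AD
   patients. Because each tracer has its own dynamic range, a cut-off
   derived for one tracer is mapped onto another through the linear
   relation between the tracers' regional mean SUVRs
   (`y = 1.13x - 0.28` maps a PIB cut-off of 1.42 to 1.32 on the
   Florbetapir scale).
3. **Mixture structure.** In some age strata the CCTXR distribution is not
   one population: a two-component Gaussian mixture, fitted by EM and
   compared against a single normal by BIC, separates low- and
   high-amyloid subpopulations and lets their demographics (notably ApoE4
   carriage) be compared.

Because the original scan data are access-controlled, the package ships a
**synthetic generator** for both labeled uptake volumes (phantoms) and
cohort tables whose distributional structure is calibrated to the published
group-level results. Every downstream stage is exercised and tested against
this generator.

## The synthetic cohort: what it emulates and what it does not

`default_strata()` encodes the six diagnosis-by-age strata at their
published sizes and CCTXR distributions:

| stratum | n | CCTXR distribution |
|---|---|---|
| younger HC (55-75 y) | 123 | mixture: 1.23 ± 0.08 (w 110/123) and 1.52 ± 0.08 (w 13/123) |
| older HC (76-93 y) | 123 | normal 1.26 ± 0.16 |
| younger MCI | 171 | normal 1.36 ± 0.19 |
| older MCI | 171 | normal 1.35 ± 0.20 |
| younger AD | 69 | normal 1.48 ± 0.17 |
| older AD | 69 | mixture: 1.08 ± 0.13 (w 15/69) and 1.48 ± 0.13 (w 54/69) |

Regional SUVRs are linear transforms of the subject's CCTXR
(`default_roi_model()`), anchored so each ROI's younger-HC and younger-AD
group means reproduce the published regional means. Each ROI's residual SD
is set to its published younger-HC SD; with the putamen's steep slope this
gives it the smallest noise-to-slope ratio and so the top discrimination
rank, matching the published AUC table — whose cortical neighbours are
nearly tied, which is why rank checks in the tests are
majority-over-seeds properties. The total generated ROI variance somewhat
exceeds the published marginal variance, a deliberate conservative
simplification. Intra-subject correlation of
the regional residuals is a single shared parameter (`regional_cor`,
default 0.3): the published analyses do not constrain it, so it is exposed
rather than asserted.

Design choices worth knowing:

* **ApoE4.** The published analyses report ApoE4 main effects but no
  mechanism. The config carries an additive CCTXR shift for carriers, but
  its default is 0: a nonzero shift would move each stratum's CCTXR
  distribution away from the calibrated mixture, and the generator treats
  the published mixtures as the ground truth to reproduce (the test suite
  checks the generated distributions against the configured mixture CDF at
  Kolmogorov-Smirnov distance < 0.02). The ApoE4-amyloid association is
  instead produced by component-dependent carrier probabilities, calibrated
  to the published subgroup rates (69% vs 26% in younger HC; 74% vs 7% in
  older AD). Consequence: in strata modelled as a single normal, ApoE4 is
  unrelated to CCTXR, so ANOVA ApoE4 main effects on synthetic data are
  weaker than the published ones. That is a deliberate trade-off in favour
  of distributional calibration.
* **Ages** are uniform within the group bounds 55-75 and 76-93 years. The
  published age split is quoted inconsistently in places ("76-83" in one
  methods sentence); the 76-93 bound used by the cohort tables and
  abstract is adopted.
* **Truncation.** CCTXR draws at or below zero are redrawn; regional
  values whose linear predictor plus residual lands at or below zero are
  resampled from the residual's zero-truncated normal (inverse CDF), since
  for extreme low CCTXR the predictor itself can be negative and naive
  redrawing would not terminate. Both are counted in the `n_truncated`
  attribute; under the default calibration fewer than 0.1% of draws are
  affected.
* **Latent truth.** Each subject's mixture component is stored
  (`true_component`) for recovery scoring only; no analysis stage reads it.

The phantom generator lays regions out as z-axis slabs (bilateral ROIs
split at the x midline), assigns each region its configured uptake ratio
times the reference value, then adds Gaussian noise and an optional
separable Gaussian blur (`smoothing_fwhm_mm`) emulating spill-over between
compartments — the mechanism by which white-matter signal inflates
adjacent grey-matter SUVR. What the phantoms do *not* emulate: scanner
point-spread anisotropy, spatial-normalisation error, anatomical shape,
or partial-volume effects beyond the blur. Passing phantom tests therefore
demonstrate the correctness of the quantification arithmetic, not
robustness to real-scan artefacts.

## Quantification conventions

* The reference statistic is configurable per tracer: median (the
  cerebellar-GM convention used for PIB) or mean (the whole-cerebellum
  convention used for Florbetapir). `evaluate_reference_regions()`
  reproduces the benchmark that motivated the whole-cerebellum choice:
  lower healthy-control coefficient of variation and larger HC-vs-AD
  Cohen's d.
* Bilateral ROI values are means over the **voxel union** of the left and
  right labels, so unequal hemispheric volumes weight by voxel count.
* The published description of the composite is a "weighted average" of
  the frontal, parietal and basal/lateral temporal regions without printed
  weights. `compute_cctxr()` defaults to ROI voxel-count weights, which
  makes the composite identical to the voxel-level mean over the union of
  the composite regions; the weights are exposed for other conventions.
  The "basal/lateral temporal" region maps to the atlas's temporal-lobe
  ROI.

## ROC cut-offs

The threshold grid is the set of midpoints between adjacent distinct
pooled scores plus infinite sentinels, so every attainable operating point
appears exactly once and the reported optimum is attained on the grid.
Positivity is strictly `score > cutoff` (a value exactly at the cut-off is
negative). The optimum minimises the Euclidean distance to (0, 1); ties
prefer higher sensitivity, then the lower threshold. The AUC is the
Mann-Whitney probability with ties counted one half; its 95% CI uses the
DeLong placement-value estimator (the original report prints CIs without
naming a method; DeLong is the standard choice and a stratified bootstrap
is available behind `ci_method = "bootstrap"`). Cross-tracer
harmonization fits ordinary least squares of tracer-B on tracer-A ROI
means and applies the line to the cut-off; `convert_cutoff()` reports full
precision plus a half-even 2-decimal display value, applied only at
report time.

## Mixture analysis

`fit_gaussian_mixture()` is a standard univariate EM with:

* restarts: median split, one k-means partition, then random pairs of data
  points (20 starts by default — enough that the best restart is stable
  across seeds for the sample sizes here);
* convergence at log-likelihood gain < 1e-8 or 500 iterations;
* a variance floor of 1e-4 times the sample variance, preventing a
  component collapsing onto one point;
* components reported in ascending mean order (the canonical order used
  for the low/high amyloid labels).

Model choice between K = 1 and K = 2 uses BIC (the original analysis says
only that one model was "more likely"; BIC is the documented stand-in and
the tie breaks toward the smaller K). Hard assignment uses the larger
responsibility, ties to the high component. Normality is tested with the
Kolmogorov-Smirnov statistic under estimated parameters and a seeded
Monte-Carlo (Lilliefors-corrected) null of at least 2,000-10,000
replicates, rather than the naive KS p-value which is conservative when
parameters are estimated.

Numerical notes: the EM log-likelihood is non-decreasing by construction
(asserted per iteration in the tests, with a 1e-9 numerical allowance);
on samples of n <= 12 the converged likelihood is checked against a dense
grid-search oracle; identical-valued samples refuse K = 2 and return a
degenerate K = 1 fit with a warning.

## Cohort statistics

* Matching is greedy nearest-neighbour without replacement in seeded
  random order, exact on the categorical variables (sex) and minimal
  scaled squared distance on the continuous ones (age, MMSE) — the
  original description says only "randomly matched", so the greedy scheme
  is a documented choice with balance diagnostics (standardized mean
  differences) in the output.
* Two-way ANOVA uses type III sums of squares with sum-to-zero contrasts
  (the SPSS convention), so unbalanced cells are handled as in the
  original analysis; an empty cell downgrades to the additive model with a
  warning. On balanced designs type III equals sequential sums of squares,
  which the tests verify.
* Chi-squared tests are Pearson without continuity correction by default
  (Yates behind a flag); Spearman's rho uses midranks with an exact
  p-value for n <= 12 without ties; Cohen's d uses the n-1 pooled SD;
  kappa uses marginal-product expected agreement.

## Problem sizes in the tests and acceptance script

The test suite and `scripts/acceptance.R` simulate at the published
stratum sizes (n = 69-171 per stratum; 726 subjects per full cohort) and
average stochastic recoveries over 100 seeds; distribution-calibration
checks use 10,000 draws per stratum, ANOVA calibration 2,000 null
replicates, and direction checks 100 generated cohorts. These sizes were
chosen to keep Monte-Carlo error well inside the tolerances being
asserted.

## Known limitations

* The regional model is linear in CCTXR with a single shared residual
  correlation — adequate for ordering and discrimination structure, but
  not a generative model of real regional covariance.
* The published real-data cut-offs (1.42 PIB, 1.34 Florbetapir) are
  properties of the original scans; synthetic ROC cut-offs approximate
  but do not reproduce them, and the package makes no claim to.
* Phantoms validate arithmetic, not image processing: spatial
  normalisation, segmentation and partial-volume correction are out of
  scope.
* The bundled cross-tracer regional-mean table is synthetic: its rank
  structure (and hence the Spearman correlations) is calibrated to the
  published values, but its absolute values are constructed.

## A worked example

```{r, eval = FALSE}
library(amypet)

co <- generate_cohort(cohort_config(seed = 1))

# age-group ROC and optimal cut-offs
sub <- co[co$age_group == "younger" & co$diagnosis %in% c("HC", "AD"), ]
rc <- roc_curve(sub$cctxr, sub$diagnosis)
optimal_cutoff(rc)

# harmonize a PIB-scale cut-off to the Florbetapir scale
convert_cutoff(linear_map(1.13, -0.28), 1.42)

# mixture decomposition of the younger-HC stratum
v <- co$cctxr[co$diagnosis == "HC" & co$age_group == "younger"]
sel <- select_model(fit_gaussian_mixture(v, K = 1),
                    fit_gaussian_mixture(v, K = 2, seed = 2))
sel$chosen
```
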