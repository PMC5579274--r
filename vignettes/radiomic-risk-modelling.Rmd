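---
title: "Radiomic risk modelling with radrisk: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radiomic risk modelling with radrisk: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radrisk)
```

## Overview

`radrisk` implements a complete radiomics workflow for 3D oncologic PET/CT
imaging: a battery of 1615 quantitative features per imaging modality
extracted from a tumour region of interest (ROI), and outcome models built
with learning strategies adjusted for the heavy class imbalance that is
typical of tumour-failure endpoints (event rates of 10–20%). Every stage is
exercisable on synthetic phantoms and cohorts with known ground truth, so
the statistical machinery can be validated without patient data.

The pipeline is:

1. **Extraction** — isotropic resampling, within-ROI gray-level
   quantization, four 3D texture matrices, and 10 intensity + 5 shape + 40×40
   texture features per scan (`extract_battery()`).
2. **Univariate screening** — Spearman association of each feature with a
   binary endpoint, Benjamini–Hochberg control at a 10% false discovery rate
   (`run_univariate()`).
3. **Model construction** — Gain-based reduction to 25 candidate features,
   0.632+ bootstrap forward selection over model orders 1–10, and a final
   logistic model whose coefficients are averaged over 100 imbalance-adjusted
   bootstrap fits (`run_train()`).
4. **Clinical combination** — partition-ensemble random forests mixing the
   selected radiomic variables with age, tumour site and staging variables,
   with minority-class weight tuning by stratified sub-sampling
   (`train_forest()`, `tune_weight()`, `select_staging()`).
5. **Evaluation** — ROC metrics at a 0.5 probability threshold, DeLong
   comparisons, Harrell's concordance index against time-to-event data, and
   Kaplan–Meier log-rank stratification into two (threshold 0.5) or three
   (thresholds 1/3 and 2/3) risk groups (`run_evaluate()`).

## Image processing conventions

**Resampling.** Texture analysis requires an isotropic grid; the ROI (with a
one-voxel pad, so border texture neighbourhoods survive) is resampled to
isotropic voxel sizes of 1–5 mm. The output grid is anchored at the input
volume's origin, which makes the identity case exact: a volume already at
the target spacing is reproduced bit-for-bit on the overlapping nodes.
Intensities are interpolated with a tricubic Keys kernel (exactly
interpolating, reproduces linear ramps); the binary mask is interpolated
linearly and re-thresholded at 0.5. The kernel is a convention, not a
derived quantity, so `extraction_config(interp = "linear")` switches to
trilinear throughout.

**Quantization.** Both algorithms operate on ROI voxels only, per scan.
*Uniform* divides the ROI intensity range into equal-width bins
(`level = min(n_gray, floor(n_gray·(x−min)/(max−min)) + 1)`, so the maximum
closes the top bin); *EqualProbability* places bin edges at empirical
quantiles k/n_gray, equalizing the level histogram to within one count when
intensities are distinct. Degenerate rules: a constant ROI maps entirely to
level 1; heavy ties may leave levels empty but counts always sum to the ROI
size. Both algorithms depend on intensities only through ranks over an
affine scale, so quantization is invariant under increasing affine intensity
transforms — a property the test suite asserts.

**Texture matrices.** GLCM, GLRLM, GLSZM and NGTDM are each built **once per
scan**, merging the 13 unique directions of 3D space (26-connectivity)
rather than keeping per-direction matrices. The 6 face, 12 edge and 8 corner
neighbours sit at physical distances 1, √2 and √3 voxels; to account for
these discretization length differences, co-occurrence pairs and NGTDM
neighbourhood averages are weighted by inverse Euclidean distance, and GLRLM
run lengths accumulate the geometric step length per diagonal step before
rounding to an integer run-length column. The exact functional form of a
distance correction is an open design point; inverse-distance weighting was
chosen because it equalizes per-unit-length sampling density, and
`distance_weight = FALSE` selects the unweighted variant so the choice is
auditable. All four builders are verified against exhaustive brute-force
oracles on every ROI up to 4×4×4 in the test suite.

**Feature lists.** The 40 texture features are: 9 GLCM (energy, contrast,
entropy, homogeneity, correlation, sum-average, variance, dissimilarity,
autocorrelation), 13 GLRLM (SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE,
SRHGE, LRLGE, LRHGE, GLV, RLV), 13 GLSZM (SZE, LZE, GLN, ZSN, ZP, LGZE,
HGZE, SZLGE, SZHGE, LZLGE, LZHGE, GLV, ZSV) and 5 NGTDM (coarseness,
busyness, contrast, complexity, strength). Degenerate rules: a single-level
ROI has entropy 0 and correlation 0 (zero marginal variance); the NGTDM
coarseness and strength denominators carry an ε = 1e-9 guard; run-length
percentage uses the distance-weighted voxel-run coverage as its denominator
so it remains exact under the diagonal length correction.

**Intensity features** are computed at native resolution: population
variance/skewness/kurtosis (zero for constant or single-voxel ROIs), SUVmax,
SUVmean, SUVpeak (mean over in-ROI voxels within a 1 cm³ sphere centred on
the hottest voxel — a common convention where no standard is fixed), the
area under the cumulative intensity–volume histogram (midpoint rule over
n_bins = 100 thresholds spanning the ROI range; defined as 1 for a constant
ROI), total lesion glycolysis (SUVmean × volume in cm³), the percentage of
the ROI below 50% of its maximum ("inactive volume"; the threshold fraction
is a config parameter), and the generalized effective total uptake
`V·mean(xᵃ)^(1/a)` with exponent a = 1 by default, at which it reduces to
TLG. The same formulas are applied to CT volumes in Hounsfield units.

**Shape features.** Volume (cm³); size (maximum distance between ROI voxel
centers); solidity (ROI voxel count over the voxel count of the rasterized
convex hull — rasterizing keeps solidity ≤ 1 exactly for digital shapes,
which the polyhedral hull volume of voxel centers does not); eccentricity
(√(1 − λmin/λmax) of the second moments, which include the voxel
self-moment spacing²/12 so a single voxel is isotropic and a one-voxel rod
stays strictly below 1); and compactness V/(√π·A^{3/2}), maximal at 1/(6π)
for a sphere. The surface area A is estimated as the integral of the
gradient magnitude of the Gaussian-smoothed mask indicator (σ = 1.5 voxels):
unlike the voxel-face (staircase) count, which overestimates a sphere's area
by roughly 50% and never converges, this estimator approaches the smooth
boundary area — the test suite checks a digital ball of radius 10 voxels
against the analytic sphere within 10%.

## Statistical machinery

**MIC.** The maximal information coefficient is the redundancy measure in
feature-set reduction. It is implemented as the bounded grid search with
`B(n) = n^0.6`: one axis is equipartitioned into i rows, the other's
partition into at most j columns is optimized by dynamic programming over
equal-frequency superclump candidate boundaries (clump factor 5), both
orientations are searched, and the maximal mutual information normalized by
`log2(min(i, j))` is returned. The DP step matters: a pure
equipartition-only variant underestimates MIC for non-monotone functional
relationships (e.g. y = x²).

**Gain-based reduction.** The first feature maximizes the absolute Spearman
correlation with the outcome; each subsequent feature maximizes
`0.5·|r_s| + 0.5·(1 − max_{s∈S} MIC(f, s))`. The mixing weight 0.5 balances
predictive power and non-redundancy equally and is configurable. The
redundancy of a candidate against the selected set is aggregated with the
**maximum** MIC: the maximum guarantees that an exact duplicate of any
selected feature (MIC = 1) is maximally penalized regardless of how many
features are already selected, whereas the mean dilutes that penalty as the
set grows. The mean variant remains selectable.

**0.632+ bootstrap AUC.** Prediction performance during selection is
`(1−w)·AUC_app + w·AUC'_oob` with `AUC'_oob = max(AUC_oob, 0.5)`,
overfitting rate `R = (AUC_app − AUC'_oob)/(AUC_app − 0.5)` clipped to
[0, 1], and `w = 0.632/(1 − 0.368·R)`; 0.5 is the no-information AUC. Every
fit — apparent and per-bootstrap — is an imbalance-adjusted partition
ensemble, and bootstraps are stratified by class so both classes are always
represented (a deliberate deviation from the naive bootstrap that avoids
degenerate single-class fits at 10–15% event rates).

**Imbalance adjustment.** A training sample with N⁻ majority and N⁺
minority instances is split into `P = round(N⁻/N⁺)` (half-up — consistent
with the worked 168/32 → 5 example) balanced partitions: minority instances
are copied into every partition, majority instances are distributed without
replacement into parts of size ⌊N⁻/P⌋ or ⌈N⁻/P⌉. Logistic ensembles average
partition coefficients; forests grow one tree per partition. Minority
weights w ∈ {0.5, …, 2.0} resample the minority within each partition to
`round(w·N⁺)` — without replacement when undersampling, duplication of every
instance before sampling the remainder when oversampling, so no rare event
is ever lost. The weight is interpreted as a per-partition count multiplier
(rather than a loss reweighting inside tree training), which keeps the
ensemble layout auditable and serializable.

**Model order.** The forward pass produces nested models of orders 1–10;
the chosen order is the smallest whose 0.632+ estimate is within one
standard error of the maximum (the classical parsimony rule), with a manual
override mirroring inspection-based choice.

**Final models.** Logistic coefficients are averaged across 100 stratified
bootstrap samples (each itself a partition-ensemble average); prediction is
the logistic transform of the averaged linear combination. Zero-variance
features receive coefficient 0 with a warning; separation-induced
divergence falls back to a tiny-ridge (λ = 1e-4) penalized fit.

**Forests.** Trees are CART-style (Gini impurity, `mtry = ⌈√p⌉`, unlimited
depth, minimum node size 1) on a one-hot encoding of categorical clinical
variables; these hyperparameters are unstated in the underlying methodology
and are exposed as arguments. The forest probability of event is the exact
fraction of trees voting for the event class, and the forest size equals
the sum of partition counts over bootstraps — both properties are unit
tested. Risk groups: two-group mode assigns probabilities strictly above
0.5 to the high-risk group; three-group mode uses left-closed intervals at
1/3 and 2/3, with probability 1 assigned to the high-risk group (the
half-open top interval would otherwise leave it unassignable).

**Survival analysis** uses the `survival` package: Cox linear predictors
(storing the training-set median as the two-group threshold for test-set
stratification), Harrell's concordance with score ties counting 1/2, and
log-rank tests with pairwise (unadjusted) comparisons in three-group mode.
Spearman p-values follow `cor.test` (exact for small untied samples, t
approximation otherwise); DeLong comparisons use `pROC`.

## The synthetic generators

`make_phantom()` emulates an FDG-PET (or CT) tumour as Gaussian-smoothed
white noise inside an ellipsoidal ROI: the correlation length (mm) is the
single heterogeneity knob, and mean/variance set the intensity scale
(defaults: 24³ grid at 1 mm, semi-axes 8–10 mm, SUV-like mean 5, variance
2, correlation length 2 mm). Checkerboard and necrotic-core presets support
feature sanity checks. What it does **not** emulate: PET partial-volume
effects, spatially correlated acquisition noise, irregular tumour margins,
multi-component ROIs, or any SUV calibration physics. Passing tests on
phantoms therefore validate the *computational* pipeline, not clinical
performance on real images.

`make_cohort()` generates cohorts with a known generative model: standard
normal features, a calibrated-intercept logistic event model, exponential
event times whose hazard scales with the linear risk, and early censoring
of non-events by an independent exponential. Defaults emulate the training
conditions the methodology targets: 194 subjects, 15% events, follow-up
horizon 60 months, three informative features with standardized
coefficients (1.5, 1.2, 1.0) among 27 noise features. These defaults were
fixed once, from the structure of the problem (a ~0.87 Bayes-optimal AUC,
i.e. a realistic moderately-strong radiomic signature), and are the
conditions under which the recovery and imbalance-benefit properties are
tested. "Strong signal" checks (out-of-sample AUC ≥ 0.85 for the forest)
use coefficients (3, 2.5, 2), the regime where each informative feature
alone separates at univariate AUC ≈ 0.85.

## Problem sizes in the test suite and acceptance script

Monte-Carlo checks run at sizes chosen to give stable averages at
interactive runtimes: texture-matrix oracle equivalence on 100 random ROIs
up to 4×4×4; the imbalance-benefit comparison on 25 cohorts (n = 200, 12%
events) in the test suite and 10 in the acceptance script; selection
recovery on 25 and 10 seeds respectively, with forward selection over
orders 1–5 at 10 bootstrap samples per candidate (selection at the full 100
bootstraps behaves identically on these cohorts but is reserved for real
analyses). The full 1615-feature battery is validated on 16³ phantoms,
where it runs in well under a second.

## Known limitations

- The Gain equation's exact published form, the distance-correction
  formula, and the inactive-volume/gETU constants are not fully specified
  in the public record of the methodology; all four are implemented as
  documented, configurable conventions (see above) rather than guesses
  frozen in code.
- NGTDM summed differences are arithmetic on gray-level labels, so they are
  not equivariant under arbitrary relabelings (only order-preserving ones);
  the occurrence probabilities are.
- Wavelet/filtered-image features, per-direction texture matrices,
  competing-risks analysis and time-dependent AUC are out of scope.
- DICOM RT-structure handling is limited to a convenience NIfTI reader;
  contour rasterization and registration must happen upstream.
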