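---
title: "Quantifying pulmonary perfusion compartments from dual-energy CT iodine maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulmonary perfusion compartments from dual-energy CT iodine maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dectperf)
```

## The problem

Acute pulmonary embolism (APE) and chronic thromboembolic pulmonary
hypertension (CTEPH) both produce wedge-shaped perfusion defects on CT
pulmonary angiography, and distinguishing them matters: treatment differs
fundamentally (anticoagulation versus endarterectomy/balloon angioplasty),
and CTEPH is frequently missed at first presentation. Detector-based
dual-energy CT reconstructs voxelwise iodine density (ID, mg/mL), a
surrogate for pulmonary blood volume, alongside the anatomical images from
a single acquisition. `dectperf` implements a quantitative pipeline over
such iodine-density maps: compartment segmentation anchored to blood-pool
reference densities, first-order histogram features with reference
normalization, and the diagnostic-performance statistics that turn those
features into classifiers.

The physiological idea behind the headline marker is that CTEPH defects are
not bloodless: over months to years, systemic bronchopulmonary collaterals
(which can supply a substantial share of pulmonary blood flow) partially
reperfuse the obstructed territories. Acute emboli have had no time to
recruit collaterals, so defect iodine density stays lower. Normalizing the
mean defect density to the left atrium — which blood reaches through either
route — yields `ID_mean,LA`, higher in CTEPH than in APE.

## Compartment model

Given an iodine volume, a lung mask, and mean reference densities measured
in circular ROIs over the main pulmonary artery (MPA) and left atrium (LA),
every lung voxel is labelled by two thresholds:

* **malperfused**: `ID < 0.05 * ID_MPA`
* **normally perfused**: `0.05 * ID_MPA <= ID < 0.5 * ID_LA`
* **vessel**: `ID >= 0.5 * ID_LA`

The wording "less than 5%" / "more than 50%" leaves the measure-zero
boundary voxels unassigned; we resolve both boundaries upward (a voxel
exactly at a threshold joins the upper compartment), which makes the three
intervals a partition of the lung mask — an invariant the test suite checks
on random phantoms. The pair of references is rejected as degenerate when
`0.05 * ID_MPA >= 0.5 * ID_LA`. Compartment fractions are reported as
percentages of lung *voxels* (isotropic spacing within a case is assumed);
the vessel remainder is always reported explicitly, so the three fractions
sum to 100 by construction and the denominator convention is transparent.

## Histogram features and normalization

Per compartment we compute mean and maximum density plus moment skewness
`g1 = m3 / m2^{3/2}` and *excess* kurtosis `g2 = m4 / m2^2 - 3`. Two
deliberate choices:

* **Excess scale for kurtosis.** Malperfused compartments are
  threshold-bounded and near-uniform; their kurtosis sits near the uniform
  law's −1.2, which is only expressible on the excess scale. Reported
  reference values for malperfused lung (≈ −1.1) confirm this reading.
* **Population (biased) moment estimators.** Real compartments contain
  10^4–10^6 voxels, where `g1`/`g2` and their small-sample-corrected
  variants coincide; declaring the population form makes oracle tests exact.
  A compartment with fewer than 2 voxels or zero variance reports missing
  higher moments — 0/0 has no defensible value, and zero would fake
  normality.

Mean and maximum are then normalized four ways: by the MPA reference
(feeding-vessel normalization, `ID_mean,MPA`, `ID_max,MPA`) and by the LA
reference (`ID_mean,LA`, `ID_max,LA`), the latter capturing collateral
supply. Two cap properties follow directly from the segmentation rule and
hold on every input: malperfused `ID_max,MPA <= 0.05` and normal
`ID_max,LA <= 0.5`.

## The phantom generator

No imaging data accompanies the study this package operationalizes, so the
voxel-level generator is a first-class, tested component, not a fixture. It
emulates exactly the features the analysis is sensitive to:

* **Geometry**: two ellipsoidal half-lungs with a mediastinal gap; spherical
  MPA/LA reference regions clipped away from the lung. Defaults: 40×56×56
  voxels at 4 mm.
* **Ventro-dorsal gradient**: parenchymal density rises linearly along +y
  from a ventral-edge baseline of 1.3 mg/mL at 0.03 per cm — a
  dorsal/ventral ratio near 1.5 over an adult lung, the gravity-dependent
  pattern seen in supine patients, and a lung-average density near
  1.6 mg/mL consistent with normally perfused lung at the default
  references (ID_MPA 12.6, ID_LA 10.1 mg/mL, the APE group means).
* **Defects**: solid cones with apex near the hilum opening toward the
  pleura (segmental vascular territories are described only qualitatively
  as "wedge-shaped"; a cone is the simplest shape with that anatomy),
  clipped to the lung. In-defect density is
  `local_baseline * (defect_multiplier + collateral_fraction)`.
  `defect_multiplier = 0.17` reproduces malperfused `ID_mean,MPA ≈ 0.022`;
  the CTEPH preset adds `collateral_fraction = 0.1` — deliberately below
  the up-to-30% physiological ceiling so that defects stay strictly below
  the 5%-of-MPA threshold even at the dorsal gradient maximum, which the
  constructor enforces at build time for "detectable" phantoms.
* **Noise**: additive Gaussian, truncated at 0 mg/mL (the simplest model
  preserving non-negativity), seeded and bit-reproducible.

What the phantom does *not* model — and therefore what passing tests do not
establish about patient data: CT physics (no spectral decomposition,
reconstruction, or beam hardening), airway/vessel trees, respiratory or
cardiac motion, mask-editing errors, and perfusion heterogeneity beyond the
linear gradient. Morphological features (MPA diameter etc.) are manual
radiologist readings in practice; phantom cases take them from the
feature-level simulator rather than measuring them from the image.

The feature-level simulator draws per-patient features from per-group
normal distributions parameterized by the published group means/SDs (APE
n=57, CTEPH n=52, controls n=22). Positive-support features (diameters,
densities, fractions) use rejection sampling at 0 — at the printed
coefficients of variation the induced truncation bias is below 1% of an SD,
and the redraw count is logged; tests compare against zero-truncated-normal
moments, the sampler's actual law. Bronchial artery diameter is observable
only per the published detection rates (31/57, 46/52, 5/22); undetected
entries are missing, never zero. Within-group correlation between any two
named features is available but defaults to 0: the published tables give
only marginal summaries, and this independence assumption is flagged
wherever the combined-marker AUC is interpreted.

## Diagnostic-performance layer

* **AUC** is the tie-corrected Mann-Whitney estimator computed via midranks
  (ties count 1/2 — the standard convention, unstated in most papers);
  tests pin it to exhaustive pair counting on all datasets up to 20
  subjects. `direction = "lower"` returns exactly `1 - AUC`.
* **DeLong** structural components give the variance of one AUC, a
  normal-approximation 95% CI clipped to [0, 1] (a perfect marker is
  flagged degenerate rather than given a fake interval), and the paired
  two-sided test for correlated AUCs. The CI method for the reference
  values is not documented; DeLong is the parsimonious choice consistent
  with the reported use of the DeLong test. Cross-checked in the suite
  against `pROC` and against bootstrap/Hanley–McNeil bounds.
* **Youden cutoffs** search midpoints between adjacent distinct scores plus
  ±Inf sentinels — with cumulative class counts this is O(n log n) and
  provably attains the brute-force optimum (tested to n = 12 exhaustively).
  Ties in J resolve toward higher sensitivity, then toward calling more
  subjects positive (the rule-out orientation).
* **Predictive values** come from Bayes' rule at a given prevalence, or
  from confusion counts when a concrete set is reported; validation-set
  PPV/NPV use the validation set's own prevalence.
* **Two-marker combination** follows the risk-score tradition of combining
  markers linearly and reporting `A + b*B + c` with the anchor coefficient
  fixed at 1. The default estimator is logistic-fit-then-rescale, which
  reproduces exactly that published form including an intercept; a
  distribution-free alternative maximizes empirical AUC over the direction
  angle. The grid is also the fallback on perfect separation and whenever
  the logistic score's training AUC falls below either single marker, making
  the "combination never loses to its anchor on training data" guarantee
  unconditional. Which estimator the original analysis used cannot be
  determined from the printed coefficients; both are provided and agree
  within 10% on binormal cohorts.
* **Split**: stratified by group (the original randomization procedure is
  underspecified; stratification keeps a 22-patient control group usable in
  a 20% validation set and is declared, not hidden), `round(ratio * n)` per
  stratum, clamped so both sides stay non-empty. The Youden cutoff is
  chosen on the training set and transferred unchanged to validation —
  transfer is implied by the original reporting and adopted globally.

## Problem sizes and numerical choices

The simulation studies in the test suite and acceptance script use 500
replicates of the published cohort sizes (57/52) for the AUC reproduction
targets, 20 seeds for noisy-phantom defect recovery (±3 percentage points
at noise = 10% of baseline), 24×32×32-voxel phantoms for property sweeps
and 40×56×56 for the worked example, and n = 10^5 per class for
closed-form recoveries (binormal AUC, Fisher discriminant, equal-density
Youden point). These sizes put every Monte-Carlo check at least 4 standard
errors away from its pass boundary while keeping the whole suite in the
tens of seconds.

The three headline reproduction targets land where the binormal closed
form Φ(Δμ/√(σ₁²+σ₂²)) predicts: 0.726 for malperfused `ID_mean,LA`
(printed: 0.72), 0.768 for MPA diameter (printed: 0.76), 0.828 for the
published combined score under within-group independence (printed: 0.82).
The published sensitivity/specificity/PPV/NPV and the
ID_skewness train/validation AUCs are sample-specific (they depend on the
actual patients and the actual 80/20 draw) and are exercised qualitatively
by `analysis/03_diagnostic_performance.R`, not asserted numerically.

## Known limitations

* Features are voxel-count based; anisotropic spacing within a case is not
  volume-weighted.
* The independence default understates (or overstates) the combined-marker
  AUC if MPA diameter and defect `ID_mean,LA` are correlated within groups;
  the simulator can impose a correlation, but no published value exists to
  calibrate it.
* The phantom's defect residual perfusion is spatially uniform; real
  collateral reperfusion is heterogeneous, so phantom-derived skewness and
  kurtosis inside defects are narrower-ranged than patient values.
* No automatic lung segmentation or ROI placement: masks are inputs, as in
  the semi-automatic clinical workflow the pipeline mirrors.
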