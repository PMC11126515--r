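# dectperf

Quantitative lung-perfusion analysis for dual-energy CT iodine-density
maps, aimed at a question that routine CT angiography answers poorly: is a
patient's thromboembolic disease **acute pulmonary embolism (APE)** or
**chronic thromboembolic pulmonary hypertension (CTEPH)**? The two look
alike on morphology alone but are treated very differently.

The pipeline implements:

* **Three-compartment segmentation** of the lung from voxelwise iodine
  density (ID, mg/mL) using blood-pool references measured in the main
  pulmonary artery (MPA) and left atrium (LA):
  malperfused `ID < 0.05·ID_MPA`, normally perfused
  `0.05·ID_MPA ≤ ID < 0.5·ID_LA`, vessel `ID ≥ 0.5·ID_LA`.
* **First-order histogram features** per compartment — mean, maximum,
  moment skewness `g1 = m3/m2^{3/2}`, excess kurtosis `g2 = m4/m2² − 3` —
  with the four reference-normalized ratios
  `ID_mean,MPA = mean ID / mean ID_MPA`, `ID_max,MPA`, `ID_mean,LA`,
  `ID_max,LA`. The LA normalization is the biologically loaded one: in
  CTEPH, systemic bronchopulmonary collaterals partially reperfuse the
  defects, raising `ID_mean,LA` relative to acute embolism.
* **Diagnostic performance**: tie-corrected Mann-Whitney AUC, DeLong
  variance/CI and paired test, Youden-index cutoffs with
  sensitivity/specificity/PPV/NPV, stratified 80/20 train-validation
  evaluation with cutoff transfer, and linear two-marker combination
  (`A + b·B + c`, logistic-fit-then-rescale with a distribution-free
  AUC-grid alternative).
* **Synthetic inputs at two scales**, since no patient data are deposited:
  a digital lung phantom (ellipsoidal lungs, ventro-dorsal perfusion
  gradient, wedge-shaped defects with tunable residual and collateral
  perfusion, blood-pool reference regions, seeded noise, full ground
  truth) and a feature-level cohort simulator drawing from the published
  group means/SDs (APE n=57, CTEPH n=52, controls n=22).

I/O: NIfTI-1 for volumes/masks/label maps (`RNifti`), CSV for cohorts,
YAML for study configs, JSON for study reports.

## Worked example

The repository is organised as an analysis workflow; the numbered scripts
under `analysis/` run the full study at desk scale on simulated data.

```sh
Rscript analysis/01_simulate_cohort.R     # cohort at published group sizes
Rscript analysis/02_phantom_study.R       # voxel-level imaging core
Rscript analysis/03_diagnostic_performance.R
```

Step 2 builds phantoms per group and runs the full extraction chain;
segmentation recovers the ground-truth defect fraction and collateral
supply raises defect `ID_mean,LA` in the CTEPH-like phantoms:

```
  APE01     truth defect  18.1%  recovered  18.1%  (err -0.01)
  CTEPH01   truth defect  22.0%  recovered  20.8%  (err -1.19)
  ...
malperfused ID_mean,LA: APE-like 0.0290 vs CTEPH-like 0.0449  (collateral supply raises it by 55%)
```

(The CTEPH recovery error is the collateral effect itself: reperfused
defect voxels sit closer to the 5%-of-MPA threshold, so noise can lift a
fraction of them above it.)

Step 3 evaluates the markers on a stratified 80/20 split of the simulated
cohort and fits the two-marker combinations:

```
  malp_id_mean_la  [CTEPH positive vs APE]
       train AUC 0.71 (0.60-0.82)  val AUC 0.77 (0.55-1.00)  cutoff 0.03203
  mpa_dia          [CTEPH positive vs APE]
       train AUC 0.75 (0.65-0.85)  val AUC 0.72 (0.49-0.95)  cutoff 30.15
  malp_id_skewness [APE+CTEPH positive vs CONTROL]
       train AUC 0.85 (0.78-0.93)  val AUC 0.81 (0.60-1.00)  cutoff -0.1354

two-marker combinations (training set):
  mpa_dia + 264.9 * malp_id_mean_la -40.62
    anchor alone AUC 0.75 -> combined 0.80  (DeLong p = 0.131)
  bronchial_dia + 21.77 * malp_id_mean_la -2.574
    anchor alone AUC 0.84 -> combined 0.91  (DeLong p = 0.092)
```

Reading this: defect `ID_mean,LA` separates CTEPH from APE with moderate
accuracy (higher in CTEPH — collateral reperfusion); adding it to the MPA
diameter raises the training AUC from 0.75 to 0.80 with a combination of
the published `MPA_dia + b·ID_mean,LA + c` form; defect skewness
identifies thromboembolic disease against controls (defect histograms are
more symmetric in disease). Exact numbers vary with the simulation seed —
these are one cohort draw, not population values.

## Package layout

```
R/                 phantom + cohort simulators, NIfTI/CSV/YAML/JSON I/O,
                   segmentation & histogram features, AUC/DeLong/Youden/
                   combination statistics, study orchestration
analysis/          numbered workflow drivers (simulate, phantom study,
                   diagnostic performance)
scripts/           acceptance.R (headline-AUC reproduction)
tests/testthat/    unit, property and acceptance suites with built-in
                   brute-force oracles
vignettes/         methods vignette: model, assumptions, defaults, limits
```
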