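#!/usr/bin/env Rscript

# Step 2 — voxel-level phantom study of the imaging core.
#
# Builds digital lung phantoms for the three groups (controls without
# defects; acute-PE-like with wedge defects and purely residual perfusion;
# CTEPH-like adding systemic collateral supply), runs the full extraction
# chain (reference ROI measurement -> 5%-MPA / 50%-LA threshold
# segmentation -> histogram features -> normalization), and checks that
# (a) segmentation recovers the ground-truth defect fraction and
# (b) collateral supply raises malperfused ID_mean,LA in the CTEPH-like
# phantoms — the physiological signature the feature-level analysis relies
# on. Writes per-phantom features and one example NIfTI set.

suppressPackageStartupMessages(library(dectperf))

seed0 <- 400L
n_per_group <- 3L
dir.create("results/phantoms", recursive = TRUE, showWarnings = FALSE)

records <- list()
cat(sprintf("building %d phantoms per group (grid 40x56x56 @ 4 mm)\n",
            n_per_group))
for (g in c("CONTROL", "APE", "CTEPH")) {
  for (k in seq_len(n_per_group)) {
    p <- phantom_group_params(g, seed = seed0 + 10L * k +
                                match(g, c("CONTROL", "APE", "CTEPH")))
    case <- build_phantom(p, group = g)
    rec <- extract_patient_features(case, id = sprintf("%s%02d", g, k))
    err <- rec$malp_fraction_pct - case$truth_defect_fraction
    cat(sprintf("  %-9s truth defect %5.1f%%  recovered %5.1f%%  (err %+.2f)\n",
                rec$id, case$truth_defect_fraction, rec$malp_fraction_pct, err))
    attr(rec, "compartment_map") <- NULL
    records[[rec$id]] <- rec
    if (g == "CTEPH" && k == 1L) {
      write_volume(case$volume, "results/phantoms/cteph_example_id.nii.gz")
      write_mask(case$lung_mask, p$spacing_mm,
                 "results/phantoms/cteph_example_lung.nii.gz")
      cmap <- segment_compartments(case$volume, case$lung_mask,
        reference_densities(
          measure_reference_density(case$volume, case$mpa_roi),
          measure_reference_density(case$volume, case$la_roi)))
      write_labels(cmap$labels, p$spacing_mm,
                   "results/phantoms/cteph_example_labels.nii.gz")
    }
  }
}

tab <- do.call(rbind, records)
rownames(tab) <- NULL
write_cohort(tab, "results/phantom_features.csv")

m_ape <- mean(tab$malp_id_mean_la[tab$group == "APE"])
m_cteph <- mean(tab$malp_id_mean_la[tab$group == "CTEPH"])
cat(sprintf("\nmalperfused ID_mean,LA: APE-like %.4f vs CTEPH-like %.4f",
            m_ape, m_cteph))
cat(sprintf("  (collateral supply raises it by %.0f%%)\n",
            100 * (m_cteph / m_ape - 1)))
cat("written: results/phantom_features.csv, results/phantoms/*.nii.gz\n")
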