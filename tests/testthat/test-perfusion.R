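make_volume <- function(values, dims = NULL) {
  if (is.null(dims)) dims <- dim(values)
  iodine_volume(array(values, dim = dims), c(1, 1, 1))
}

test_that("reference density is the arithmetic ROI mean", {
  v <- array(0, dim = c(4, 4, 4))
  roi <- array(FALSE, dim = c(4, 4, 4))
  roi[1, 1, 1:2] <- TRUE
  v[1, 1, 1] <- 10; v[1, 1, 2] <- 14
  expect_equal(measure_reference_density(make_volume(v), roi), 12.0)

  v2 <- array(0, dim = c(4, 4, 4)); roi2 <- array(FALSE, dim = c(4, 4, 4))
  roi2[2, , 1] <- TRUE; v2[roi2] <- 12.6
  expect_equal(measure_reference_density(make_volume(v2), roi2), 12.6)

  expect_error(measure_reference_density(make_volume(v),
                                         array(FALSE, dim = c(4, 4, 4))),
               class = "dectperf_validation_error")
  lung <- array(TRUE, dim = c(4, 4, 4))
  expect_warning(measure_reference_density(make_volume(v), roi, lung),
                 class = "dectperf_roi_overlap")
})

test_that("noisy phantom ROI mean recovers the configured blood-pool density", {
  # MPA region of the default-size phantom carries id_mpa_true + N(0, 0.5)
  p <- phantom_params(noise_sd = 0.5, seed = 77L)
  case <- build_phantom(p)
  n_roi <- sum(case$mpa_roi)
  expect_gte(n_roi, 50L)
  est <- measure_reference_density(case$volume, case$mpa_roi)
  expect_lt(abs(est - p$id_mpa_true), 4 * 0.5 / sqrt(n_roi))
})

test_that("threshold segmentation follows the 5%-MPA / 50%-LA rule with upper-boundary convention", {
  refs <- reference_densities(12.6, 10.1)  # thresholds 0.63 and 5.05 mg/mL
  v <- array(0, dim = c(2, 2, 2))
  lung <- array(TRUE, dim = c(2, 2, 2))
  v[1, 1, 1] <- 0.5   # below 0.63  -> MALPERFUSED
  v[1, 1, 2] <- 3.0   # in between  -> NORMAL
  v[1, 2, 1] <- 6.0   # above 5.05  -> VESSEL
  v[1, 2, 2] <- 0.63  # exactly at the malperfusion threshold -> NORMAL
  v[2, 1, 1] <- 5.05  # exactly at the vessel threshold -> VESSEL
  cmap <- segment_compartments(make_volume(v), lung, refs)
  codes <- compartment_codes()
  expect_identical(cmap$labels[1, 1, 1], codes[["MALPERFUSED"]])
  expect_identical(cmap$labels[1, 1, 2], codes[["NORMAL"]])
  expect_identical(cmap$labels[1, 2, 1], codes[["VESSEL"]])
  expect_identical(cmap$labels[1, 2, 2], codes[["NORMAL"]])
  expect_identical(cmap$labels[2, 1, 1], codes[["VESSEL"]])
  expect_equal(unname(cmap$thresholds), c(0.63, 5.05))
})

test_that("degenerate reference densities are rejected naming both thresholds", {
  err <- expect_error(reference_densities(100, 9),
                      class = "dectperf_degenerate_threshold")
  expect_match(conditionMessage(err), "5")
  expect_match(conditionMessage(err), "4.5")
})

test_that("noiseless phantom segmentation recovers the ground-truth defect mask exactly", {
  p <- tiny_phantom_params(defect_spec = list(tiny_wedge(1), tiny_wedge(3)),
                           noise_sd = 0, defect_multiplier = 0.02,
                           collateral_fraction = 0)
  case <- build_phantom(p)
  refs <- reference_densities(
    measure_reference_density(case$volume, case$mpa_roi),
    measure_reference_density(case$volume, case$la_roi))
  cmap <- segment_compartments(case$volume, case$lung_mask, refs)
  malp <- cmap$labels == compartment_codes()[["MALPERFUSED"]]
  expect_identical(malp, case$truth_defect_mask)
})

test_that("compartment fractions count voxels and always sum to 100", {
  lab <- array(0L, dim = c(10, 10, 10))
  lab[seq_len(700)] <- 2L; lab[701:980] <- 1L; lab[981:1000] <- 3L
  cmap <- structure(list(labels = lab, thresholds = c(0.5, 5),
                         spacing_mm = c(1, 1, 1)), class = "compartment_map")
  fr <- compartment_fractions(cmap)
  expect_equal(unname(fr), c(28.0, 70.0, 2.0))
  for (s in 6:10) {
    case <- build_phantom(random_phantom_params(s))
    rec <- extract_patient_features(case)
    expect_equal(rec$malp_fraction_pct + rec$normal_fraction_pct +
                   rec$vessel_fraction_pct, 100, tolerance = 1e-9)
  }
})

test_that("segmentation partitions the lung and is monotone in the thresholds", {
  case <- build_phantom(random_phantom_params(11))
  refs <- reference_densities(12, 10)
  cmap <- segment_compartments(case$volume, case$lung_mask, refs)
  codes <- compartment_codes()
  expect_true(all((cmap$labels != codes[["OUTSIDE"]]) == case$lung_mask))
  # raising id_mpa never shrinks MALPERFUSED; raising id_la never grows VESSEL
  malp1 <- cmap$labels == codes[["MALPERFUSED"]]
  cmap2 <- segment_compartments(case$volume, case$lung_mask,
                                reference_densities(16, 10))
  expect_true(all((cmap2$labels == codes[["MALPERFUSED"]]) >= malp1))
  ves1 <- cmap$labels == codes[["VESSEL"]]
  cmap3 <- segment_compartments(case$volume, case$lung_mask,
                                reference_densities(12, 14))
  expect_true(all(ves1 >= (cmap3$labels == codes[["VESSEL"]])))
})

test_that("first-order features match direct moment summation and handle degenerate compartments", {
  # symmetric 4-point sample inside a 2x2x1 "lung"
  v <- array(c(1, 2, 3, 4), dim = c(2, 2, 1))
  lung <- array(TRUE, dim = c(2, 2, 1))
  cmap <- segment_compartments(make_volume(v), lung,
                               reference_densities(10, 100))
  feats <- first_order_features(make_volume(v), cmap, "NORMAL")
  expect_equal(feats$id_mean, 2.5)
  expect_equal(feats$id_max, 4)
  expect_equal(feats$id_skewness, 0)

  # 50-voxel random compartment against the summation oracle
  set.seed(12)
  v50 <- array(runif(50, 1, 4), dim = c(50, 1, 1))
  lung50 <- array(TRUE, dim = c(50, 1, 1))
  cm50 <- segment_compartments(make_volume(v50), lung50,
                               reference_densities(10, 100))
  f50 <- first_order_features(make_volume(v50), cm50, "NORMAL")
  oracle <- moments_by_summation(as.vector(v50))
  expect_equal(f50$id_mean, oracle$mean, tolerance = 1e-12)
  expect_equal(f50$id_skewness, oracle$skewness, tolerance = 1e-12)
  expect_equal(f50$id_kurtosis, oracle$kurtosis, tolerance = 1e-12)

  # constant compartment: higher moments are missing, not zero
  vc <- array(2, dim = c(3, 3, 1))
  cmc <- segment_compartments(make_volume(vc), array(TRUE, dim = c(3, 3, 1)),
                              reference_densities(10, 100))
  fc <- first_order_features(make_volume(vc), cmc, "NORMAL")
  expect_true(is.na(fc$id_skewness) && is.na(fc$id_kurtosis))
  expect_equal(fc$id_mean, 2)
})

test_that("uniform densities give excess kurtosis near -1.2", {
  set.seed(99)
  n <- 4e6
  v <- array(runif(n, 0.5, 4.5), dim = c(200, 200, 100))
  lung <- array(TRUE, dim = c(200, 200, 100))
  cmap <- segment_compartments(iodine_volume(v, c(1, 1, 1)), lung,
                               reference_densities(10, 100))
  f <- first_order_features(iodine_volume(v, c(1, 1, 1)), cmap, "NORMAL")
  expect_equal(f$id_kurtosis, -1.2, tolerance = 0.01)
})

test_that("normalization fills the four reference ratios and leaves raw fields alone", {
  refs <- reference_densities(12.6, 10.1)
  raw <- structure(list(compartment = "NORMAL", fraction_pct = 50,
                        n_voxels = 100L, id_mean = 1.64, id_max = 5.0,
                        id_skewness = 0.1, id_kurtosis = -0.5,
                        id_mean_mpa = NA_real_, id_max_mpa = NA_real_,
                        id_mean_la = NA_real_, id_max_la = NA_real_),
                   class = "compartment_features")
  norm <- normalize_features(raw, refs)
  expect_equal(norm$id_mean_mpa, 1.64 / 12.6, tolerance = 1e-12)
  expect_equal(round(norm$id_mean_mpa, 2), 0.13)
  expect_equal(norm$id_max_la, 5.0 / 10.1, tolerance = 1e-12)
  expect_identical(norm$id_mean, raw$id_mean)

  zero <- raw; zero$id_mean <- 0
  nz <- normalize_features(zero, refs)
  expect_equal(nz$id_mean_mpa, 0)
  expect_equal(nz$id_mean_la, 0)
})

test_that("segmentation thresholds cap the normalized maxima by construction", {
  for (s in 12:16) {
    case <- build_phantom(random_phantom_params(s))
    rec <- extract_patient_features(case)
    if (!is.na(rec$malp_id_max_mpa)) expect_lte(rec$malp_id_max_mpa, 0.05)
    if (!is.na(rec$normal_id_max_la)) expect_lte(rec$normal_id_max_la, 0.5)
  }
})

test_that("patient record assembly composes the chain and handles missing compartments", {
  # control phantom without defects and without noise: nothing malperfused
  case <- build_phantom(tiny_phantom_params(noise_sd = 0), group = "CONTROL")
  rec <- extract_patient_features(case, id = "CTRL1")
  expect_equal(rec$malp_fraction_pct, 0)
  expect_true(is.na(rec$malp_id_mean))
  expect_false(is.na(rec$normal_id_mean))

  # collateral flow raises malperfused ID_mean,LA in the CTEPH-like phantom
  base <- list(defect_spec = list(tiny_wedge(1), tiny_wedge(2)),
               noise_sd = 0, defect_multiplier = 0.15)
  rec_ape <- extract_patient_features(
    build_phantom(do.call(tiny_phantom_params, c(base, collateral_fraction = 0))))
  rec_cteph <- extract_patient_features(
    build_phantom(do.call(tiny_phantom_params, c(base, collateral_fraction = 0.1))))
  expect_gt(rec_cteph$malp_id_mean_la, rec_ape$malp_id_mean_la)

  # record survives the CSV round trip unchanged
  rec$group <- "CONTROL"
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(rec, f)
  back <- read_cohort(f)
  for (nm in setdiff(names(rec), c("id", "group", "subtype")))
    expect_identical(back[[nm]], rec[[nm]])
})
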