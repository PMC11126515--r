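#' Compartment label codes
#'
#' Fixed codes used in compartment label maps: `OUTSIDE = 0`,
#' `MALPERFUSED = 1`, `NORMAL = 2`, `VESSEL = 3`.
#'
#' @return named integer vector.
#' @export
compartment_codes <- function() {
  c(OUTSIDE = 0L, MALPERFUSED = 1L, NORMAL = 2L, VESSEL = 3L)
}

#' Blood-pool reference densities
#'
#' Mean iodine densities measured in the main pulmonary artery (MPA) and the
#' left atrium (LA). They define the compartment thresholds: malperfused lung
#' below `0.05 * id_mpa`, vessel compartment at or above `0.5 * id_la`. The
#' pair is degenerate (rejected) when the malperfusion threshold is not
#' strictly below the vessel threshold.
#'
#' @param id_mpa,id_la mean reference densities, mg/mL, both > 0.
#' @return list of class `reference_densities`.
#' @export
reference_densities <- function(id_mpa, id_la) {
  assert_number(id_mpa, "id_mpa", lower = 0, strict_lower = TRUE)
  assert_number(id_la, "id_la", lower = 0, strict_lower = TRUE)
  if (0.05 * id_mpa >= 0.5 * id_la)
    abort_dectperf(sprintf(
      "degenerate thresholds: 0.05*id_mpa = %.4g >= 0.5*id_la = %.4g mg/mL",
      0.05 * id_mpa, 0.5 * id_la), "dectperf_degenerate_threshold")
  structure(list(id_mpa = id_mpa, id_la = id_la),
            class = "reference_densities")
}

#' Mean iodine density over a reference region
#'
#' @param volume an [iodine_volume()].
#' @param roi_mask logical array over the volume domain.
#' @param lung_mask optional lung mask; overlap between ROI and lung is
#'   physiologically implausible and triggers a warning (not an error).
#' @return arithmetic mean density over the ROI voxels, mg/mL.
#' @export
measure_reference_density <- function(volume, roi_mask, lung_mask = NULL) {
  stopifnot(inherits(volume, "iodine_volume"))
  if (!identical(dim(roi_mask), dim(volume$values)))
    abort_dectperf("ROI mask does not match the volume domain",
                   "dectperf_validation_error")
  if (!any(roi_mask))
    abort_dectperf("empty reference ROI", "dectperf_validation_error")
  if (!is.null(lung_mask) && any(roi_mask & lung_mask))
    warn_dectperf("reference ROI overlaps the lung mask",
                  "dectperf_roi_overlap")
  mean(volume$values[roi_mask])
}

#' Three-compartment threshold segmentation of the lung
#'
#' Each lung voxel is labelled by its iodine density `ID` relative to the
#' blood-pool references: `MALPERFUSED` if `ID < 0.05 * id_mpa`, `NORMAL` if
#' `0.05 * id_mpa <= ID < 0.5 * id_la`, `VESSEL` if `ID >= 0.5 * id_la`.
#' Boundary voxels exactly at a threshold go to the upper compartment, which
#' makes the three intervals a partition of the lung mask.
#'
#' @param volume an [iodine_volume()].
#' @param lung_mask logical array.
#' @param refs a [reference_densities()].
#' @return list of class `compartment_map`: `labels` (3D integer array),
#'   `thresholds` (mg/mL), `spacing_mm`.
#' @export
segment_compartments <- function(volume, lung_mask, refs) {
  stopifnot(inherits(volume, "iodine_volume"),
            inherits(refs, "reference_densities"))
  if (!identical(dim(lung_mask), dim(volume$values)))
    abort_dectperf("lung mask does not match the volume domain",
                   "dectperf_validation_error")
  t_malp <- 0.05 * refs$id_mpa
  t_vessel <- 0.5 * refs$id_la
  codes <- compartment_codes()
  labels <- array(codes[["OUTSIDE"]], dim = dim(volume$values))
  v <- volume$values[lung_mask]
  lab <- ifelse(v < t_malp, codes[["MALPERFUSED"]],
                ifelse(v < t_vessel, codes[["NORMAL"]], codes[["VESSEL"]]))
  labels[lung_mask] <- lab
  structure(list(labels = labels,
                 thresholds = c(malperfused = t_malp, vessel = t_vessel),
                 spacing_mm = volume$spacing_mm),
            class = "compartment_map")
}

#' Compartment fractions
#'
#' Percentages of lung voxels in the malperfused, normally perfused and
#' vessel compartments. The vessel remainder is reported explicitly; the
#' three fractions sum to 100.
#'
#' @param cmap a [segment_compartments()] result.
#' @return named numeric vector `(malperfused, normal, vessel)`, percent.
#' @export
compartment_fractions <- function(cmap) {
  stopifnot(inherits(cmap, "compartment_map"))
  codes <- compartment_codes()
  n_lung <- sum(cmap$labels != codes[["OUTSIDE"]])
  if (n_lung == 0L)
    abort_dectperf("empty lung mask", "dectperf_validation_error")
  100 * c(
    malperfused = sum(cmap$labels == codes[["MALPERFUSED"]]),
    normal = sum(cmap$labels == codes[["NORMAL"]]),
    vessel = sum(cmap$labels == codes[["VESSEL"]])
  ) / n_lung
}

#' First-order histogram features of a compartment
#'
#' Computes mean and maximum iodine density plus the moment coefficients of
#' skewness (`g1 = m3 / m2^(3/2)`) and excess kurtosis (`g2 = m4 / m2^2 - 3`)
#' over the voxels of one compartment, using population (biased) moment
#' estimators; at the compartment sizes of real lungs (1e4-1e6 voxels) these
#' coincide with the small-sample-corrected forms. A compartment with fewer
#' than 2 voxels or zero variance reports the variance-based statistics as
#' missing (`NA`), never zero.
#'
#' @param volume an [iodine_volume()].
#' @param cmap a [segment_compartments()] result.
#' @param compartment `"MALPERFUSED"`, `"NORMAL"` or `"VESSEL"`.
#' @return list of class `compartment_features`: `compartment`,
#'   `fraction_pct`, `n_voxels`, `id_mean`, `id_max`, `id_skewness`,
#'   `id_kurtosis` (normalized fields `NA` until [normalize_features()]).
#' @export
first_order_features <- function(volume, cmap,
                                 compartment = c("MALPERFUSED", "NORMAL",
                                                 "VESSEL")) {
  stopifnot(inherits(volume, "iodine_volume"),
            inherits(cmap, "compartment_map"))
  compartment <- match.arg(compartment)
  codes <- compartment_codes()
  sel <- cmap$labels == codes[[compartment]]
  n <- sum(sel)
  if (n == 0L)
    abort_dectperf(sprintf("compartment %s is empty", compartment),
                   "dectperf_empty_compartment")
  v <- volume$values[sel]
  mu <- mean(v)
  skew <- kurt <- NA_real_
  if (n >= 2L) {
    m2 <- mean((v - mu)^2)
    if (m2 > 0) {
      skew <- mean((v - mu)^3) / m2^1.5
      kurt <- mean((v - mu)^4) / m2^2 - 3
    }
  }
  fr <- compartment_fractions(cmap)
  fr_name <- c(MALPERFUSED = "malperfused", NORMAL = "normal",
               VESSEL = "vessel")[[compartment]]
  structure(list(
    compartment = compartment,
    fraction_pct = fr[[fr_name]], n_voxels = n,
    id_mean = mu, id_max = max(v),
    id_skewness = skew, id_kurtosis = kurt,
    id_mean_mpa = NA_real_, id_max_mpa = NA_real_,
    id_mean_la = NA_real_, id_max_la = NA_real_
  ), class = "compartment_features")
}

#' Normalize histogram features to the blood-pool references
#'
#' Fills the four normalized ratios: mean and maximum density divided by the
#' mean MPA density (feeding-vessel normalization) and by the mean LA
#' density (accounts for systemic collateral supply, which reaches the LA
#' but not the MPA). Raw fields are unchanged.
#'
#' @param raw a [first_order_features()] result.
#' @param refs a [reference_densities()].
#' @return `raw` with `id_mean_mpa`, `id_max_mpa`, `id_mean_la`, `id_max_la`
#'   filled.
#' @export
normalize_features <- function(raw, refs) {
  stopifnot(inherits(raw, "compartment_features"),
            inherits(refs, "reference_densities"))
  raw$id_mean_mpa <- raw$id_mean / refs$id_mpa
  raw$id_max_mpa <- raw$id_max / refs$id_mpa
  raw$id_mean_la <- raw$id_mean / refs$id_la
  raw$id_max_la <- raw$id_max / refs$id_la
  raw
}

features_as_columns <- function(feat, prefix) {
  vals <- if (is.null(feat)) {
    rep(NA_real_, 8L)
  } else {
    unlist(feat[c("id_mean", "id_max", "id_skewness", "id_kurtosis",
                  "id_mean_mpa", "id_max_mpa", "id_mean_la", "id_max_la")])
  }
  names(vals) <- paste0(prefix, "_", c(
    "id_mean", "id_max", "id_skewness", "id_kurtosis",
    "id_mean_mpa", "id_max_mpa", "id_mean_la", "id_max_la"))
  as.list(vals)
}

#' Extract the full per-patient feature record from one case
#'
#' Runs the whole voxel-level chain — reference measurement, three-compartment
#' segmentation, compartment fractions, first-order features, reference
#' normalization — for the NORMAL and MALPERFUSED compartments and assembles
#' a one-row data frame in registry column order. An empty malperfused (or
#' normal) compartment yields missing features for that compartment, not an
#' error.
#'
#' @param case a [build_phantom()] result, or `NULL` if the individual
#'   pieces are supplied.
#' @param volume,lung_mask,mpa_roi,la_roi individual inputs, used when
#'   `case` is `NULL`.
#' @param id patient identifier.
#' @param group optional group label.
#' @param morphology optional named list/vector of morphological features
#'   (e.g. `mpa_dia`); appended as columns.
#' @return one-row data frame (patient record); attribute `compartment_map`
#'   carries the label map.
#' @export
extract_patient_features <- function(case = NULL, volume = NULL,
                                     lung_mask = NULL, mpa_roi = NULL,
                                     la_roi = NULL, id = "P001",
                                     group = NA_character_,
                                     morphology = NULL) {
  if (!is.null(case)) {
    stopifnot(inherits(case, "phantom_case"))
    volume <- case$volume; lung_mask <- case$lung_mask
    mpa_roi <- case$mpa_roi; la_roi <- case$la_roi
    if (is.na(group) && !is.na(case$group)) group <- case$group
  }
  if (is.null(volume) || is.null(lung_mask) || is.null(mpa_roi) ||
      is.null(la_roi))
    abort_dectperf("volume, lung mask and both reference ROIs are required",
                   "dectperf_validation_error")
  refs <- reference_densities(
    measure_reference_density(volume, mpa_roi, lung_mask),
    measure_reference_density(volume, la_roi, lung_mask))
  cmap <- segment_compartments(volume, lung_mask, refs)
  fr <- compartment_fractions(cmap)

  get_feats <- function(comp) {
    tryCatch(
      normalize_features(first_order_features(volume, cmap, comp), refs),
      dectperf_error = function(e) {
        if (inherits(e, "dectperf_empty_compartment")) NULL else stop(e)
      })
  }
  normal <- get_feats("NORMAL")
  malp <- get_feats("MALPERFUSED")

  rec <- data.frame(id = id, group = group, subtype = NA_character_,
                    stringsAsFactors = FALSE)
  rec$id_mpa <- refs$id_mpa
  rec$id_la <- refs$id_la
  rec$normal_fraction_pct <- fr[["normal"]]
  rec$malp_fraction_pct <- fr[["malperfused"]]
  rec$vessel_fraction_pct <- fr[["vessel"]]
  rec <- cbind(rec,
               as.data.frame(features_as_columns(normal, "normal")),
               as.data.frame(features_as_columns(malp, "malp")))
  if (!is.null(morphology))
    for (nm in names(morphology)) rec[[nm]] <- as.numeric(morphology[[nm]])
  rec <- rec[, cohort_column_order(names(rec)), drop = FALSE]
  attr(rec, "compartment_map") <- cmap
  rec
}
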