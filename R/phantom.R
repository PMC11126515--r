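#' Wedge-shaped perfusion defect specification
#'
#' Perfusion defects caused by pulmonary emboli follow the segmental vascular
#' anatomy: roughly conical territories whose apex sits near the occluded
#' (hilar) artery and whose base spreads towards the pleura. A defect is
#' modelled as a solid cone, clipped to the lung.
#'
#' @param apex_mm numeric length-3, cone apex in mm coordinates (z, y, x).
#' @param axis numeric length-3 direction (z, y, x) from apex towards the
#'   pleural base; normalised internally.
#' @param angle_deg full opening angle of the cone in degrees, in (0, 180).
#' @param length_mm cone height in mm.
#' @return list of class `wedge_defect`.
#' @export
wedge_defect <- function(apex_mm, axis, angle_deg, length_mm) {
  assert_number(angle_deg, "angle_deg", lower = 0, upper = 180,
                strict_lower = TRUE)
  assert_number(length_mm, "length_mm", lower = 0, strict_lower = TRUE)
  if (length(apex_mm) != 3L || !is.numeric(apex_mm))
    abort_dectperf("`apex_mm` must be numeric length 3",
                   "dectperf_invalid_parameter")
  structure(list(apex_mm = as.numeric(apex_mm),
                 axis = normalize_axis(as.numeric(axis)),
                 angle_deg = angle_deg, length_mm = length_mm),
            class = "wedge_defect")
}

#' Default two-ellipsoid lung geometry
#'
#' Two ellipsoidal half-lungs, mirrored about the midline, leaving a
#' mediastinal gap for the blood-pool reference regions.
#'
#' @param grid_shape voxel counts (z, y, x).
#' @param spacing_mm voxel size (z, y, x) in mm.
#' @return list with per-lung `center_mm` and `radii_mm`.
#' @export
default_lung_geometry <- function(grid_shape, spacing_mm) {
  extent <- grid_shape * spacing_mm
  ctr <- extent / 2
  radii <- c(0.42 * extent[1], 0.40 * extent[2], 0.21 * extent[3])
  offset <- 0.26 * extent[3]
  list(
    left  = list(center_mm = c(ctr[1], ctr[2], ctr[3] - offset), radii_mm = radii),
    right = list(center_mm = c(ctr[1], ctr[2], ctr[3] + offset), radii_mm = radii)
  )
}

#' Parameters of the digital lung perfusion phantom
#'
#' The phantom emulates the salient structure of an iodine-density overlay
#' map: parenchymal iodine density with a linear ventro-dorsal gradient
#' (gravity-dependent pulmonary blood volume in the supine position),
#' sharply defined wedge-shaped hypoperfused defects, elevated residual
#' defect perfusion via systemic (bronchopulmonary) collaterals, and
#' blood-pool reference regions for the main pulmonary artery (MPA) and the
#' left atrium (LA).
#'
#' @param grid_shape integer length-3 voxel counts (z, y, x).
#' @param spacing_mm voxel size (z, y, x), mm.
#' @param lung_geometry as [default_lung_geometry()]; a list of two
#'   ellipsoids, each with `center_mm` and `radii_mm`.
#' @param gradient_slope fractional iodine increase per cm along +y
#'   (ventral to dorsal). Default 0.03/cm gives a dorsal/ventral density
#'   ratio of roughly 1.5 across an adult lung.
#' @param baseline_id parenchymal iodine density at the ventral lung edge,
#'   mg/mL.
#' @param id_mpa_true,id_la_true blood-pool densities (mg/mL) written into
#'   the MPA and LA reference regions. Defaults are the acute-PE group means.
#' @param defect_spec list of [wedge_defect()]s (may be empty).
#' @param defect_multiplier fraction of the local baseline retained inside a
#'   defect, in \[0, 1).
#' @param collateral_fraction additional fraction of local baseline supplied
#'   to defects by systemic collaterals (CTEPH physiology), >= 0.
#' @param noise_sd additive Gaussian noise SD, mg/mL (truncated at 0).
#' @param seed integer RNG seed for the noise.
#' @param detectable if `TRUE` (default), require at build time that every
#'   defect voxel falls strictly below the malperfusion threshold
#'   `0.05 * id_mpa_true` before noise, so ground truth and threshold
#'   segmentation agree by construction.
#' @return validated list of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(40L, 56L, 56L),
                           spacing_mm = c(4, 4, 4),
                           lung_geometry = NULL,
                           gradient_slope = 0.03,
                           baseline_id = 1.3,
                           id_mpa_true = 12.6,
                           id_la_true = 10.1,
                           defect_spec = list(),
                           defect_multiplier = 0.17,
                           collateral_fraction = 0,
                           noise_sd = 0.1,
                           seed = 1L,
                           detectable = TRUE) {
  if (length(grid_shape) != 3L || any(grid_shape < 4) ||
      any(grid_shape != as.integer(grid_shape)))
    abort_dectperf("`grid_shape` must be 3 integers >= 4",
                   "dectperf_invalid_parameter")
  assert_positive_vector(spacing_mm, "spacing_mm", n = 3L)
  assert_number(gradient_slope, "gradient_slope", lower = 0)
  assert_number(baseline_id, "baseline_id", lower = 0, strict_lower = TRUE)
  assert_number(id_mpa_true, "id_mpa_true", lower = 0, strict_lower = TRUE)
  assert_number(id_la_true, "id_la_true", lower = 0, strict_lower = TRUE)
  assert_number(defect_multiplier, "defect_multiplier", lower = 0, upper = 1 - 1e-12)
  assert_number(collateral_fraction, "collateral_fraction", lower = 0)
  assert_number(noise_sd, "noise_sd", lower = 0)
  if (!all(vapply(defect_spec, inherits, logical(1), "wedge_defect")))
    abort_dectperf("`defect_spec` must be a list of wedge_defect objects",
                   "dectperf_invalid_parameter")
  lung_geometry <- lung_geometry %||%
    default_lung_geometry(as.numeric(grid_shape), as.numeric(spacing_mm))
  structure(list(
    grid_shape = as.integer(grid_shape), spacing_mm = as.numeric(spacing_mm),
    lung_geometry = lung_geometry, gradient_slope = gradient_slope,
    baseline_id = baseline_id, id_mpa_true = id_mpa_true,
    id_la_true = id_la_true, defect_spec = defect_spec,
    defect_multiplier = defect_multiplier,
    collateral_fraction = collateral_fraction,
    noise_sd = noise_sd, seed = as.integer(seed), detectable = detectable
  ), class = "phantom_params")
}

# voxel-center coordinate arrays in mm, dims (z, y, x)
coordinate_arrays <- function(grid_shape, spacing_mm) {
  nz <- grid_shape[1]; ny <- grid_shape[2]; nx <- grid_shape[3]
  z <- (seq_len(nz) - 0.5) * spacing_mm[1]
  y <- (seq_len(ny) - 0.5) * spacing_mm[2]
  x <- (seq_len(nx) - 0.5) * spacing_mm[3]
  list(
    z = array(rep(z, times = ny * nx), dim = grid_shape),
    y = array(rep(rep(y, each = nz), times = nx), dim = grid_shape),
    x = array(rep(x, each = nz * ny), dim = grid_shape)
  )
}

ellipsoid_mask <- function(co, center_mm, radii_mm) {
  ((co$z - center_mm[1]) / radii_mm[1])^2 +
    ((co$y - center_mm[2]) / radii_mm[2])^2 +
    ((co$x - center_mm[3]) / radii_mm[3])^2 <= 1
}

sphere_mask <- function(co, center_mm, radius_mm) {
  (co$z - center_mm[1])^2 + (co$y - center_mm[2])^2 +
    (co$x - center_mm[3])^2 <= radius_mm^2
}

cone_mask <- function(co, defect) {
  dz <- co$z - defect$apex_mm[1]
  dy <- co$y - defect$apex_mm[2]
  dx <- co$x - defect$apex_mm[3]
  proj <- dz * defect$axis[1] + dy * defect$axis[2] + dx * defect$axis[3]
  nrm <- sqrt(dz^2 + dy^2 + dx^2)
  cos_half <- cos(defect$angle_deg / 2 * pi / 180)
  proj >= 0 & proj <= defect$length_mm & proj >= nrm * cos_half
}

#' Build a voxel-level lung perfusion phantom
#'
#' Construction rule (before noise): parenchymal voxels carry
#' `baseline_id * (1 + gradient_slope * (y - y_ventral) / 10)` where
#' `y_ventral` is the ventral-most lung coordinate; voxels inside a defect
#' carry `local_baseline * (defect_multiplier + collateral_fraction)`;
#' MPA/LA reference voxels carry `id_mpa_true` / `id_la_true`; everything
#' else is 0. Gaussian noise (SD `noise_sd`, truncated at 0) is then added
#' over the lung and reference regions. Defects extending beyond the lung
#' are clipped to it.
#'
#' @param params a [phantom_params()].
#' @param group optional group label (`"CONTROL"`, `"APE"`, `"CTEPH"`)
#'   carried through to the case.
#' @return list of class `phantom_case` with elements `volume`
#'   ([iodine_volume()]), `lung_mask`, `mpa_roi`, `la_roi`,
#'   `truth_defect_mask` (logical arrays), `truth_defect_fraction`
#'   (% of lung voxels), `group`, and `params`.
#' @export
build_phantom <- function(params, group = NA_character_) {
  stopifnot(inherits(params, "phantom_params"))
  co <- coordinate_arrays(params$grid_shape, params$spacing_mm)

  lung <- Reduce(`|`, lapply(params$lung_geometry, function(g)
    ellipsoid_mask(co, g$center_mm, g$radii_mm)))
  if (!any(lung))
    abort_dectperf("lung geometry produces an empty lung mask",
                   "dectperf_invalid_parameter")

  # mediastinal blood-pool reference regions, clipped away from the lung
  extent <- params$grid_shape * params$spacing_mm
  mpa <- sphere_mask(co, c(0.45, 0.40, 0.50) * extent, 0.080 * min(extent)) & !lung
  la  <- sphere_mask(co, c(0.62, 0.62, 0.50) * extent, 0.085 * min(extent)) & !lung
  la <- la & !mpa
  if (!any(mpa) || !any(la))
    abort_dectperf("reference-region geometry is empty after clipping",
                   "dectperf_invalid_parameter")

  y_ventral <- min(co$y[lung])
  local_baseline <- params$baseline_id *
    (1 + params$gradient_slope * (co$y - y_ventral) / 10)

  defect <- array(FALSE, dim = params$grid_shape)
  for (d in params$defect_spec) defect <- defect | cone_mask(co, d)
  defect <- defect & lung  # clip to lung, not an error

  resid <- params$defect_multiplier + params$collateral_fraction
  if (params$detectable && any(defect)) {
    max_defect_id <- max(local_baseline[defect]) * resid
    thr <- 0.05 * params$id_mpa_true
    if (max_defect_id >= thr)
      abort_dectperf(sprintf(
        paste0("defect density %.4g mg/mL not strictly below the ",
               "malperfusion threshold %.4g mg/mL; lower defect_multiplier/",
               "collateral_fraction or set detectable = FALSE"),
        max_defect_id, thr), "dectperf_invalid_parameter")
  }

  vals <- array(0, dim = params$grid_shape)
  vals[lung] <- local_baseline[lung]
  vals[defect] <- local_baseline[defect] * resid
  vals[mpa] <- params$id_mpa_true
  vals[la] <- params$id_la_true

  if (params$noise_sd > 0) {
    support <- lung | mpa | la
    set.seed(params$seed)
    vals[support] <- pmax(0, vals[support] +
                            stats::rnorm(sum(support), 0, params$noise_sd))
  }

  structure(list(
    volume = iodine_volume(vals, params$spacing_mm),
    lung_mask = lung, mpa_roi = mpa, la_roi = la,
    truth_defect_mask = defect,
    truth_defect_fraction = 100 * sum(defect) / sum(lung),
    group = group, params = params
  ), class = "phantom_case")
}

#' Group-preset phantom parameters
#'
#' Presets for the three study groups: controls have no defects; acute-PE
#' phantoms carry wedge defects with purely residual pulmonary perfusion;
#' CTEPH phantoms add collateral supply (`collateral_fraction = 0.1`),
#' raising iodine density inside the defects without lifting them above the
#' malperfusion threshold.
#'
#' @param group one of `"CONTROL"`, `"APE"`, `"CTEPH"`.
#' @param seed RNG seed passed to [phantom_params()].
#' @param noise_sd noise SD in mg/mL.
#' @param ... further overrides passed to [phantom_params()].
#' @return a [phantom_params()].
#' @export
phantom_group_params <- function(group = c("CONTROL", "APE", "CTEPH"),
                                 seed = 1L, noise_sd = 0.1, ...) {
  group <- match.arg(group)
  grid_shape <- c(40L, 56L, 56L)
  spacing <- c(4, 4, 4)
  extent <- grid_shape * spacing
  # apexes near each hilum, cones opening laterally and dorsally
  defects <- list(
    wedge_defect(c(0.45, 0.45, 0.35) * extent, c(0, 0.5, -0.85), 70, 90),
    wedge_defect(c(0.55, 0.45, 0.65) * extent, c(0, 0.5, 0.85), 70, 90),
    wedge_defect(c(0.35, 0.40, 0.62) * extent, c(-0.3, 0.6, 0.75), 55, 80)
  )
  spec <- switch(group,
                 CONTROL = list(),
                 APE = defects[1:2],
                 CTEPH = defects)
  cf <- if (group == "CTEPH") 0.1 else 0
  phantom_params(grid_shape = grid_shape, spacing_mm = spacing,
                 defect_spec = spec, collateral_fraction = cf,
                 noise_sd = noise_sd, seed = seed, ...)
}
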