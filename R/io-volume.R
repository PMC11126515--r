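#' Iodine-density volume
#'
#' Container for a 3D iodine-density map in mg/mL, the quantitative output of
#' a spectral (dual-energy) CT reconstruction. Axis convention throughout the
#' package: axis 1 is z (craniocaudal), axis 2 is y (ventral to dorsal, so +y
#' points towards the dependent dorsal lung in a supine patient), axis 3 is x
#' (left to right).
#'
#' @param values 3D numeric array of iodine densities, mg/mL. Must be finite
#'   and non-negative.
#' @param spacing_mm numeric length-3 vector of voxel edge lengths in mm,
#'   ordered (z, y, x).
#' @return An object of class `iodine_volume`: a list with elements `values`
#'   and `spacing_mm`.
#' @export
iodine_volume <- function(values, spacing_mm) {
  if (!is.array(values) || length(dim(values)) != 3L)
    abort_dectperf("`values` must be a 3D array",
                   "dectperf_format_error")
  n_bad <- sum(!is.finite(values))
  if (n_bad > 0L)
    abort_dectperf(
      sprintf("iodine volume contains %d non-finite voxel%s",
              n_bad, if (n_bad == 1L) "" else "s"),
      "dectperf_validation_error", n_offending = n_bad)
  n_neg <- sum(values < 0)
  if (n_neg > 0L)
    abort_dectperf(
      sprintf("iodine volume contains %d negative-density voxel%s",
              n_neg, if (n_neg == 1L) "" else "s"),
      "dectperf_validation_error", n_offending = n_neg)
  assert_positive_vector(spacing_mm, "spacing_mm", n = 3L)
  structure(list(values = values, spacing_mm = as.numeric(spacing_mm)),
            class = "iodine_volume")
}

#' @export
print.iodine_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<iodine_volume> %d x %d x %d voxels, spacing %s mm, range [%.3g, %.3g] mg/mL\n",
              d[1], d[2], d[3], paste(signif(x$spacing_mm, 3), collapse = " x "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Write an iodine-density volume as NIfTI-1
#'
#' Volumes are stored in mg/mL as 64-bit floats with no scale slope/intercept,
#' so write/read round-trips are exact.
#'
#' @param volume an [iodine_volume()].
#' @param path output file path; `.nii.gz` recommended.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "iodine_volume"))
  img <- RNifti::asNifti(volume$values)
  RNifti::pixdim(img) <- volume$spacing_mm
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read an iodine-density volume from NIfTI-1
#'
#' @param path NIfTI file.
#' @param strict if `TRUE`, reject volumes whose values are exclusively 0/1:
#'   those are almost certainly masks passed in error, not density maps.
#' @return an [iodine_volume()].
#' @export
read_volume <- function(path, strict = FALSE) {
  if (!file.exists(path))
    abort_dectperf(sprintf("file not found: %s", path), "dectperf_format_error")
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    abort_dectperf(
      sprintf("expected a 3D single-channel volume, got %dD", length(d)),
      "dectperf_format_error")
  values <- array(as.numeric(img), dim = d)
  spacing <- RNifti::pixdim(img)[seq_len(3L)]
  vol <- iodine_volume(values, spacing)
  if (strict && all(values %in% c(0, 1)))
    abort_dectperf(
      "volume contains only values {0,1}; looks like a mask, not an iodine-density map (strict mode)",
      "dectperf_validation_error")
  vol
}

#' Write a binary mask as NIfTI-1 (unsigned 8-bit)
#'
#' @param mask 3D logical (or 0/1) array.
#' @param spacing_mm voxel spacing (z, y, x) in mm.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, spacing_mm, path) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    abort_dectperf("`mask` must be a 3D array", "dectperf_format_error")
  m <- array(as.integer(as.logical(mask)), dim = dim(mask))
  assert_positive_vector(spacing_mm, "spacing_mm", n = 3L)
  img <- RNifti::asNifti(m)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a binary mask from NIfTI-1
#'
#' @param path NIfTI file containing only values 0 and 1.
#' @return 3D logical array with attribute `spacing_mm`.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    abort_dectperf(sprintf("expected a 3D mask, got %dD", length(d)),
                   "dectperf_format_error")
  v <- as.numeric(img)
  if (!all(v %in% c(0, 1)))
    abort_dectperf("mask file contains values other than 0/1",
                   "dectperf_validation_error")
  structure(array(v == 1, dim = d), spacing_mm = RNifti::pixdim(img)[1:3])
}

#' Write / read a compartment label map as NIfTI-1 (unsigned 8-bit)
#'
#' Label codes are fixed: OUTSIDE=0, MALPERFUSED=1, NORMAL=2, VESSEL=3
#' (see [compartment_codes()]).
#'
#' @param labels 3D integer array of label codes.
#' @param spacing_mm voxel spacing (z, y, x) in mm.
#' @param path file path.
#' @return `path` (write) or a 3D integer array with attribute `spacing_mm`
#'   (read).
#' @export
write_labels <- function(labels, spacing_mm, path) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    abort_dectperf("`labels` must be a 3D array", "dectperf_format_error")
  if (!all(labels %in% 0:3))
    abort_dectperf("label codes must be in {0,1,2,3}",
                   "dectperf_validation_error")
  img <- RNifti::asNifti(array(as.integer(labels), dim = dim(labels)))
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    abort_dectperf(sprintf("expected a 3D label map, got %dD", length(d)),
                   "dectperf_format_error")
  v <- as.integer(img)
  if (!all(v %in% 0:3))
    abort_dectperf("label map contains codes outside {0,1,2,3}",
                   "dectperf_validation_error")
  structure(array(v, dim = d), spacing_mm = RNifti::pixdim(img)[1:3])
}
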