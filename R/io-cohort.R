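#' Feature registry
#'
#' Canonical per-patient feature names with units. The registry fixes the
#' column order of cohort CSV files, so write/read/write round-trips are
#' byte-identical. Prefixes: `normal_` and `malp_` refer to the normally
#' perfused and malperfused lung compartments; `_mpa` / `_la` suffixes denote
#' normalization to the mean iodine density of the main pulmonary artery or
#' the left atrium.
#'
#' @return named character vector mapping feature name to unit (`""` for
#'   dimensionless quantities).
#' @export
feature_registry <- function() {
  c(
    # morphology (manually read in clinical practice; simulated here)
    mpa_dia             = "mm",
    aorta_dia           = "mm",
    mpa_aorta_ratio     = "",
    rv_lv_ratio         = "",
    bronchial_dia       = "mm",
    # blood-pool reference densities
    id_mpa              = "mg/mL",
    id_la               = "mg/mL",
    # compartment fractions (% of lung voxels)
    normal_fraction_pct = "%",
    malp_fraction_pct   = "%",
    vessel_fraction_pct = "%",
    # first-order histogram features, normally perfused compartment
    normal_id_mean      = "mg/mL",
    normal_id_max       = "mg/mL",
    normal_id_skewness  = "",
    normal_id_kurtosis  = "",
    normal_id_mean_mpa  = "",
    normal_id_max_mpa   = "",
    normal_id_mean_la   = "",
    normal_id_max_la    = "",
    # first-order histogram features, malperfused compartment
    malp_id_mean        = "mg/mL",
    malp_id_max         = "mg/mL",
    malp_id_skewness    = "",
    malp_id_kurtosis    = "",
    malp_id_mean_mpa    = "",
    malp_id_max_mpa     = "",
    malp_id_mean_la     = "",
    malp_id_max_la      = ""
  )
}

#' @keywords internal
cohort_groups <- function() c("APE", "CTEPH", "CONTROL")

#' @keywords internal
cohort_subtypes <- function() c("cCTEPH", "pCTEPH")

validate_cohort <- function(tab) {
  if (!is.data.frame(tab) || nrow(tab) == 0L)
    abort_dectperf("cohort table must be a non-empty data frame",
                   "dectperf_validation_error")
  if (!all(c("id", "group") %in% names(tab)))
    abort_dectperf("cohort table requires `id` and `group` columns",
                   "dectperf_validation_error")
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup) > 0L)
    abort_dectperf(sprintf("duplicate patient id(s): %s",
                           paste(dup, collapse = ", ")),
                   "dectperf_validation_error")
  bad <- setdiff(unique(tab$group), cohort_groups())
  if (length(bad) > 0L)
    abort_dectperf(sprintf("unknown group label(s): %s",
                           paste(bad, collapse = ", ")),
                   "dectperf_validation_error")
  if ("subtype" %in% names(tab)) {
    has_sub <- !is.na(tab$subtype) & tab$subtype != ""
    if (any(has_sub & !(tab$subtype %in% cohort_subtypes())))
      abort_dectperf("subtype must be cCTEPH or pCTEPH",
                     "dectperf_validation_error")
    if (any(has_sub & tab$group != "CTEPH"))
      abort_dectperf("subtype is only valid for group CTEPH",
                     "dectperf_validation_error")
  }
  invisible(tab)
}

cohort_column_order <- function(nms) {
  meta <- intersect(c("id", "group", "subtype"), nms)
  feats <- intersect(names(feature_registry()), nms)
  extra <- sort(setdiff(nms, c(meta, feats)))
  c(meta, feats, extra)
}

# Fixed float formatting (17 significant digits) guarantees an exact
# value round-trip through text, hence byte-identical rewrite.
format_csv_number <- function(x) {
  out <- character(length(x))
  out[!is.na(x)] <- formatC(x[!is.na(x)], format = "g", digits = 17)
  out[is.na(x)] <- ""
  out
}

#' Write a patient cohort table as CSV
#'
#' Columns are emitted in canonical registry order; missing values become
#' empty fields. Numeric fields use a fixed 17-significant-digit format so
#' that `write -> read -> write` reproduces the file byte for byte.
#'
#' @param tab data frame with at least `id` and `group` columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(tab, path) {
  validate_cohort(tab)
  tab <- tab[, cohort_column_order(names(tab)), drop = FALSE]
  out <- tab
  for (nm in names(out)) {
    if (is.numeric(out[[nm]])) {
      out[[nm]] <- format_csv_number(out[[nm]])
    } else {
      v <- as.character(out[[nm]])
      v[is.na(v)] <- ""
      out[[nm]] <- v
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = ","), con)
  if (nrow(out) > 0L)
    writeLines(do.call(paste, c(unname(as.list(out)), sep = ",")), con)
  invisible(path)
}

#' Read a patient cohort table from CSV
#'
#' Empty fields become `NA` (never zero). Group labels and patient ids are
#' validated; registered feature columns are converted to numeric and carry
#' their units in the `units` attribute of the returned data frame.
#'
#' @param path CSV path as written by [write_cohort()].
#' @return data frame with attribute `units`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    abort_dectperf(sprintf("file not found: %s", path), "dectperf_format_error")
  tab <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, stringsAsFactors = FALSE)
  reg <- feature_registry()
  for (nm in names(tab)) {
    v <- tab[[nm]]
    v[v == ""] <- NA_character_
    if (nm %in% names(reg)) {
      num <- suppressWarnings(as.numeric(v))
      if (any(is.na(num) & !is.na(v)))
        abort_dectperf(sprintf("non-numeric value in feature column `%s`", nm),
                       "dectperf_validation_error")
      tab[[nm]] <- num
    } else {
      tab[[nm]] <- v
    }
  }
  validate_cohort(tab)
  attr(tab, "units") <- reg[intersect(names(reg), names(tab))]
  tab
}
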