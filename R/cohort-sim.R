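#' Default per-group feature distribution parameters
#'
#' Group means and standard deviations of the morphological and perfusion
#' features for the three study groups (acute PE n=57, CTEPH n=52, controls
#' n=22). Features with positive physical support (diameters, densities,
#' fractions, ratios) are flagged `positive`; `detect_rate` gives the
#' per-group probability that an optional feature (bronchial artery
#' diameter) is measurable at all — non-detected entries are missing, never
#' zero.
#'
#' @return named list; each element has `mean` and `sd` (named by group),
#'   logical `positive`, and optional `detect_rate`.
#' @export
default_feature_params <- function() {
  p <- function(ape, cteph, ctrl, positive = TRUE, detect_rate = NULL) {
    out <- list(
      mean = c(APE = ape[1], CTEPH = cteph[1], CONTROL = ctrl[1]),
      sd   = c(APE = ape[2], CTEPH = cteph[2], CONTROL = ctrl[2]),
      positive = positive)
    if (!is.null(detect_rate)) out$detect_rate <- detect_rate
    out
  }
  list(
    mpa_dia            = p(c(28.8, 4.5),    c(34.0, 5.5),    c(26.7, 2.6)),
    mpa_aorta_ratio    = p(c(0.85, 0.14),   c(1.05, 0.22),   c(0.83, 0.10)),
    rv_lv_ratio        = p(c(1.09, 0.36),   c(1.26, 0.43),   c(0.93, 0.13)),
    bronchial_dia      = p(c(1.6, 0.31),    c(2.4, 0.74),    c(1.5, 0.16),
                           detect_rate = c(APE = 31 / 57, CTEPH = 46 / 52,
                                           CONTROL = 5 / 22)),
    id_mpa             = p(c(12.6, 5.2),    c(14.3, 3.9),    c(15.3, 3.8)),
    id_la              = p(c(10.1, 2.8),    c(9.0, 2.3),     c(10.4, 2.9)),
    normal_fraction_pct = p(c(68.6, 17.9),  c(53.6, 20.0),   c(73.1, 18.2)),
    malp_fraction_pct  = p(c(28.3, 18.4),   c(44.1, 20.2),   c(23.9, 18.5)),
    normal_id_mean_mpa = p(c(0.13, 0.04),   c(0.10, 0.02),   c(0.11, 0.03)),
    normal_id_mean_la  = p(c(0.15, 0.03),   c(0.16, 0.04),   c(0.16, 0.05)),
    normal_id_max_mpa  = p(c(0.44, 0.16),   c(0.33, 0.13),   c(0.35, 0.09)),
    malp_id_mean_mpa   = p(c(0.022, 0.005), c(0.023, 0.004), c(0.028, 0.005)),
    malp_id_mean_la    = p(c(0.028, 0.012), c(0.040, 0.016), c(0.046, 0.022)),
    malp_id_max_la     = p(c(0.06, 0.02),   c(0.09, 0.03),   c(0.08, 0.04)),
    malp_id_skewness   = p(c(0.03, 0.48),   c(-0.06, 0.38),  c(-0.57, 0.45),
                           positive = FALSE),
    malp_id_kurtosis   = p(c(-1.1, 0.3),    c(-1.1, 0.2),    c(-0.7, 0.8),
                           positive = FALSE)
  )
}

#' Cohort simulation parameters
#'
#' @param group_sizes named integer vector of patients per group; defaults
#'   to the study sizes (APE 57, CTEPH 52, CONTROL 22).
#' @param feature_params per-feature per-group normal distribution
#'   parameters, as [default_feature_params()].
#' @param correlation optional within-group correlation between exactly two
#'   features: `list(features = c("a","b"), rho = r)` with `r` in \[-1, 1\].
#'   Default `NULL` (all features independent within group; the published
#'   tables give no within-group correlations).
#' @param subtype_split proportion of CTEPH patients labelled central
#'   (`cCTEPH`) vs peripheral (`pCTEPH`); default 14/52 central.
#' @param seed integer RNG seed.
#' @return validated list of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(group_sizes = c(APE = 57L, CTEPH = 52L, CONTROL = 22L),
                              feature_params = default_feature_params(),
                              correlation = NULL,
                              subtype_split = 14 / 52,
                              seed = 1L) {
  if (is.null(names(group_sizes)) ||
      !all(names(group_sizes) %in% cohort_groups()))
    abort_dectperf("`group_sizes` must be named with APE/CTEPH/CONTROL",
                   "dectperf_configuration_error")
  if (any(group_sizes < 0))
    abort_dectperf("group sizes must be >= 0", "dectperf_configuration_error")
  for (nm in names(feature_params)) {
    fp <- feature_params[[nm]]
    if (is.null(fp$mean) || is.null(fp$sd) || any(fp$sd < 0))
      abort_dectperf(sprintf("feature `%s`: mean/sd missing or sd < 0", nm),
                     "dectperf_configuration_error")
  }
  if (!is.null(correlation)) {
    if (length(correlation$features) != 2L ||
        !all(correlation$features %in% names(feature_params)))
      abort_dectperf("correlation$features must name two configured features",
                     "dectperf_configuration_error")
    assert_number(correlation$rho, "correlation$rho", lower = -1, upper = 1)
  }
  assert_number(subtype_split, "subtype_split", lower = 0, upper = 1)
  structure(list(group_sizes = group_sizes, feature_params = feature_params,
                 correlation = correlation, subtype_split = subtype_split,
                 seed = as.integer(seed)),
            class = "cohort_sim_params")
}

# Draw n values from N(mean, sd); for positive-support features, non-positive
# draws are rejected and redrawn. Returns values plus the redraw count.
draw_feature <- function(n, mean, sd, positive) {
  v <- stats::rnorm(n, mean, sd)
  redraws <- 0L
  if (positive && sd > 0) {
    bad <- which(v <= 0)
    while (length(bad) > 0L) {
      redraws <- redraws + length(bad)
      v[bad] <- stats::rnorm(length(bad), mean, sd)
      bad <- bad[v[bad] <= 0]
    }
  }
  list(values = v, redraws = redraws)
}

#' Simulate a feature-level patient cohort
#'
#' Draws one row per patient from the per-group (optionally bivariate)
#' normal distributions configured in `params`. Positive-support features
#' are redrawn on non-positive draws (rejection sampling); the total number
#' of redraws is recorded in the `n_redraws` attribute and reported via a
#' message when non-zero. Reproducible given the seed: groups are sampled in
#' the order APE, CTEPH, CONTROL and features in registry order.
#'
#' @param params a [cohort_sim_params()].
#' @return data frame with columns `id`, `group`, `subtype` and one column
#'   per configured feature; attributes `n_redraws` and `units`.
#' @export
sample_feature_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_sim_params"))
  set.seed(params$seed)
  groups <- intersect(c("APE", "CTEPH", "CONTROL"), names(params$group_sizes))
  feats <- names(params$feature_params)
  corr <- params$correlation
  total_redraws <- 0L
  rows <- list()
  for (g in groups) {
    n <- params$group_sizes[[g]]
    if (n == 0L) next
    df <- data.frame(id = sprintf("%s%03d", g, seq_len(n)),
                     group = g, subtype = NA_character_,
                     stringsAsFactors = FALSE)
    if (g == "CTEPH") {
      n_c <- round(params$subtype_split * n)
      sub <- c(rep("cCTEPH", n_c), rep("pCTEPH", n - n_c))
      df$subtype <- sample(sub)
    }
    corr_pair <- if (!is.null(corr) && corr$rho != 0) corr$features else NULL
    for (f in feats) {
      fp <- params$feature_params[[f]]
      if (!g %in% names(fp$mean))
        abort_dectperf(sprintf("feature `%s` has no parameters for group %s",
                               f, g), "dectperf_configuration_error")
      if (!is.null(corr_pair) && f == corr_pair[2]) next  # drawn with pair[1]
      if (!is.null(corr_pair) && f == corr_pair[1]) {
        fp2 <- params$feature_params[[corr_pair[2]]]
        rho <- corr$rho
        z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
        v1 <- fp$mean[[g]] + fp$sd[[g]] * z1
        v2 <- fp2$mean[[g]] + fp2$sd[[g]] * (rho * z1 + sqrt(1 - rho^2) * z2)
        # joint redraw keeps the correlation structure intact
        bad <- which((fp$positive & v1 <= 0) | (fp2$positive & v2 <= 0))
        while (length(bad) > 0L) {
          total_redraws <- total_redraws + length(bad)
          z1b <- stats::rnorm(length(bad)); z2b <- stats::rnorm(length(bad))
          v1[bad] <- fp$mean[[g]] + fp$sd[[g]] * z1b
          v2[bad] <- fp2$mean[[g]] +
            fp2$sd[[g]] * (rho * z1b + sqrt(1 - rho^2) * z2b)
          bad <- bad[(fp$positive & v1[bad] <= 0) |
                       (fp2$positive & v2[bad] <= 0)]
        }
        df[[f]] <- v1
        df[[corr_pair[2]]] <- v2
        next
      }
      drawn <- draw_feature(n, fp$mean[[g]], fp$sd[[g]],
                            isTRUE(fp$positive))
      v <- drawn$values
      total_redraws <- total_redraws + drawn$redraws
      if (!is.null(fp$detect_rate)) {
        detected <- stats::runif(n) < fp$detect_rate[[g]]
        v[!detected] <- NA_real_
      }
      df[[f]] <- v
    }
    rows[[g]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_cohort(out)
  if (total_redraws > 0L)
    message(sprintf("sample_feature_cohort: %d non-positive draw%s redrawn",
                    total_redraws, if (total_redraws == 1L) "" else "s"))
  attr(out, "n_redraws") <- total_redraws
  reg <- feature_registry()
  attr(out, "units") <- reg[intersect(names(reg), names(out))]
  out
}
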