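#' Study configuration
#'
#' Describes one full desk-scale study run: where the cohort comes from
#' (feature-level simulation, voxel-level phantoms, or a CSV of real
#' per-patient features), which single-marker analyses and two-marker
#' combinations to run, and the split/seed/level settings.
#'
#' @param mode `"feature-simulation"`, `"voxel-phantom"` or `"real-data"`.
#' @param cohort_params a [cohort_sim_params()] (feature-simulation mode;
#'   also used in voxel-phantom mode to sample morphology).
#' @param phantoms list of [phantom_params()] or of
#'   `list(params =, group =, id =)` entries (voxel-phantom mode).
#' @param cohort_path CSV path (real-data mode).
#' @param analyses list of `list(marker =, positive =, negative =,
#'   direction =)` single-marker evaluations.
#' @param combinations list of `list(anchor =, second =, positive =,
#'   negative =, method =)` two-marker combinations.
#' @param ratio training fraction of the 80/20-style split.
#' @param seed integer master seed.
#' @param alpha two-sided type-I level for confidence intervals.
#' @return list of class `study_config`.
#' @export
study_config <- function(mode = c("feature-simulation", "voxel-phantom",
                                  "real-data"),
                         cohort_params = NULL, phantoms = NULL,
                         cohort_path = NULL,
                         analyses = default_analyses(),
                         combinations = default_combinations(),
                         ratio = 0.8, seed = 1L, alpha = 0.05) {
  mode <- match.arg(mode)
  if (mode == "feature-simulation" && is.null(cohort_params))
    cohort_params <- cohort_sim_params(seed = seed)
  if (mode == "voxel-phantom" && is.null(phantoms))
    abort_dectperf("voxel-phantom mode requires `phantoms`",
                   "dectperf_configuration_error")
  if (mode == "real-data" && is.null(cohort_path))
    abort_dectperf("real-data mode requires `cohort_path`",
                   "dectperf_configuration_error")
  assert_number(ratio, "ratio", lower = 0, upper = 1)
  assert_number(alpha, "alpha", lower = 0, upper = 1)
  structure(list(mode = mode, cohort_params = cohort_params,
                 phantoms = phantoms, cohort_path = cohort_path,
                 analyses = analyses, combinations = combinations,
                 ratio = ratio, seed = as.integer(seed), alpha = alpha),
            class = "study_config")
}

#' @rdname study_config
#' @export
default_analyses <- function() {
  list(
    list(marker = "malp_id_mean_la", positive = "CTEPH", negative = "APE",
         direction = "higher"),
    list(marker = "mpa_dia", positive = "CTEPH", negative = "APE",
         direction = "higher"),
    # the disease-detection contrast: both thromboembolic groups pooled
    # against controls (defect histograms are more symmetric in disease)
    list(marker = "malp_id_skewness", positive = c("APE", "CTEPH"),
         negative = "CONTROL", direction = "higher")
  )
}

#' @rdname study_config
#' @export
default_combinations <- function() {
  list(
    list(anchor = "mpa_dia", second = "malp_id_mean_la",
         positive = "CTEPH", negative = "APE", method = "logistic"),
    list(anchor = "bronchial_dia", second = "malp_id_mean_la",
         positive = "CTEPH", negative = "APE", method = "logistic")
  )
}

#' Per-group cohort summary
#'
#' Mean, SD, n and missing count of every numeric feature per group — the
#' "mean ± SD" layout of a clinical characteristics table. A group with a
#' single non-missing value reports a missing SD.
#'
#' @param tab cohort data frame.
#' @return data frame with columns `feature`, `group`, `n`, `n_missing`,
#'   `mean`, `sd`.
#' @export
summarize_cohort <- function(tab) {
  if (nrow(tab) == 0L)
    abort_dectperf("empty cohort", "dectperf_validation_error")
  feats <- names(tab)[vapply(tab, is.numeric, logical(1))]
  groups <- intersect(c("APE", "CTEPH", "CONTROL"), unique(tab$group))
  out <- do.call(rbind, lapply(feats, function(f) {
    do.call(rbind, lapply(groups, function(g) {
      v <- tab[[f]][tab$group == g]
      ok <- !is.na(v)
      data.frame(feature = f, group = g, n = sum(ok), n_missing = sum(!ok),
                 mean = if (any(ok)) mean(v[ok]) else NA_real_,
                 sd = if (sum(ok) >= 2) stats::sd(v[ok]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(config[setdiff(names(config), "phantoms")]), f)
  unname(tools::md5sum(f))
}

performance_as_list <- function(p) {
  p[c("auc", "ci_low", "ci_high", "cutoff", "sensitivity", "specificity",
      "ppv", "npv", "direction", "n_pos", "n_neg", "degenerate")]
}

build_study_cohort <- function(config) {
  switch(config$mode,
    "feature-simulation" = sample_feature_cohort(config$cohort_params),
    "voxel-phantom" = {
      recs <- vector("list", length(config$phantoms))
      morph <- NULL
      if (!is.null(config$cohort_params)) {
        sim <- config$cohort_params
        sim$group_sizes <- c(APE = length(config$phantoms),
                             CTEPH = length(config$phantoms),
                             CONTROL = length(config$phantoms))
        morph <- sample_feature_cohort(sim)
      }
      for (i in seq_along(config$phantoms)) {
        ph <- config$phantoms[[i]]
        params <- if (inherits(ph, "phantom_params")) ph else ph$params
        group <- if (inherits(ph, "phantom_params")) NA_character_ else ph$group
        pid <- if (inherits(ph, "phantom_params")) sprintf("PH%03d", i)
               else ph$id %||% sprintf("PH%03d", i)
        case <- build_phantom(params, group = group)
        mo <- NULL
        if (!is.null(morph) && !is.na(group)) {
          cand <- morph[morph$group == group, , drop = FALSE]
          j <- 1 + (i - 1) %% nrow(cand)
          mo <- as.list(cand[j, c("mpa_dia", "mpa_aorta_ratio",
                                  "rv_lv_ratio", "bronchial_dia")])
        }
        recs[[i]] <- extract_patient_features(case, id = pid, group = group,
                                              morphology = mo)
      }
      cols <- Reduce(union, lapply(recs, names))
      recs <- lapply(recs, function(r) {
        for (nm in setdiff(cols, names(r))) r[[nm]] <- NA_real_
        attr(r, "compartment_map") <- NULL
        r[, cols, drop = FALSE]
      })
      out <- do.call(rbind, recs)
      rownames(out) <- NULL
      out
    },
    "real-data" = read_cohort(config$cohort_path))
}

#' Run the full study
#'
#' Generates or loads the cohort, summarizes it per group, evaluates every
#' configured single marker on a stratified train/validation split (cutoff
#' chosen by Youden's index on the training set and transferred), fits every
#' configured two-marker combination on the training set, and compares the
#' anchor-alone AUC against the combined-score AUC on the same training
#' subjects with the DeLong test. Fully reproducible from config + seed; the
#' report is identical across runs up to its timestamp field.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory; when given, writes
#'   `report.json` and `cohort.csv` (plus per-phantom compartment label maps
#'   in voxel mode when `save_labels = TRUE`).
#' @param save_labels write NIfTI label maps in voxel-phantom mode.
#' @return list of class `study_report`.
#' @export
run_study <- function(config, out_dir = NULL, save_labels = FALSE) {
  stopifnot(inherits(config, "study_config"))
  cohort <- build_study_cohort(config)
  summary <- summarize_cohort(cohort)

  run_analysis <- function(an) {
    sub <- cohort[cohort$group %in% c(an$positive, an$negative), ,
                  drop = FALSE]
    sub <- sub[!is.na(sub[[an$marker]]), , drop = FALSE]
    sp <- split_cohort(sub, ratio = config$ratio, seed = config$seed)
    ev <- evaluate_marker(sp$train, sp$validation, an$marker, an$positive,
                          an$negative, direction = an$direction %||% "higher",
                          alpha = config$alpha)
    list(marker = an$marker, positive = an$positive, negative = an$negative,
         direction = an$direction %||% "higher", cutoff = ev$cutoff,
         n_dropped = ev$n_dropped,
         train = performance_as_list(ev$train),
         validation = performance_as_list(ev$validation))
  }

  run_combination <- function(cb) {
    sub <- cohort[cohort$group %in% c(cb$positive, cb$negative), ,
                  drop = FALSE]
    sub <- sub[!is.na(sub[[cb$anchor]]) & !is.na(sub[[cb$second]]), ,
               drop = FALSE]
    if (nrow(sub) < 4L)
      abort_dectperf(sprintf("too few complete cases for combination %s + %s",
                             cb$anchor, cb$second),
                     "dectperf_validation_error")
    sp <- split_cohort(sub, ratio = config$ratio, seed = config$seed)
    pos_tr <- sp$train$group == cb$positive
    comb <- combine_markers(sp$train[[cb$anchor]], sp$train[[cb$second]],
                            pos_tr, method = cb$method %||% "logistic")
    score_tr <- comb$score(sp$train[[cb$anchor]], sp$train[[cb$second]])
    score_va <- comb$score(sp$validation[[cb$anchor]],
                           sp$validation[[cb$second]])
    yc <- youden_cutoff(score_tr, pos_tr, direction = comb$direction)
    perf_tr <- performance_at_cutoff(score_tr, pos_tr, yc$cutoff,
                                     comb$direction, config$alpha)
    perf_va <- performance_at_cutoff(score_va,
                                     sp$validation$group == cb$positive,
                                     yc$cutoff, comb$direction, config$alpha)
    # anchor alone vs combined, strictly paired on the training subjects
    dl <- delong_compare(sp$train[[cb$anchor]], score_tr, pos_tr,
                         direction_a = "higher",
                         direction_b = comb$direction)
    list(anchor = cb$anchor, second = cb$second, positive = cb$positive,
         negative = cb$negative, method_used = comb$method_used,
         coef_b = comb$coef_b, intercept = comb$intercept,
         direction = comb$direction,
         train = performance_as_list(perf_tr),
         validation = performance_as_list(perf_va),
         delong_anchor_vs_combined = dl[c("auc_a", "auc_b", "z", "p_value")])
  }

  report <- structure(list(
    schema_version = "1.0",
    software_version = as.character(utils::packageVersion("dectperf")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed, mode = config$mode,
    config_hash = config_hash(config),
    cohort_summary = summary,
    analyses = lapply(config$analyses, run_analysis),
    combinations = lapply(config$combinations, run_combination)
  ), class = "study_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    rep_json <- report
    rep_json$cohort_summary <- summary
    jsonlite::write_json(unclass(rep_json),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
    if (save_labels && config$mode == "voxel-phantom") {
      for (i in seq_along(config$phantoms)) {
        ph <- config$phantoms[[i]]
        params <- if (inherits(ph, "phantom_params")) ph else ph$params
        group <- if (inherits(ph, "phantom_params")) NA_character_ else ph$group
        case <- build_phantom(params, group = group)
        rec <- extract_patient_features(case, id = sprintf("PH%03d", i))
        cmap <- attr(rec, "compartment_map")
        write_labels(cmap$labels, cmap$spacing_mm,
                     file.path(out_dir, sprintf("labels_%03d.nii.gz", i)))
      }
    }
  }
  attr(report, "cohort") <- cohort
  report
}

#' Read a study configuration from YAML
#'
#' The YAML mirrors [study_config()] field-for-field; phantom entries mirror
#' [phantom_params()] with `defect_spec` as a list of
#' `{apex_mm, axis, angle_deg, length_mm}` blocks.
#'
#' @param path YAML file.
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_params <- NULL
  if (!is.null(y$cohort_params)) {
    cp <- y$cohort_params
    fp <- default_feature_params()
    if (!is.null(cp$feature_params)) {
      for (nm in names(cp$feature_params)) {
        fp[[nm]] <- utils::modifyList(fp[[nm]] %||% list(positive = TRUE),
                                      cp$feature_params[[nm]])
      }
    }
    cohort_params <- cohort_sim_params(
      group_sizes = unlist(cp$group_sizes) %||%
        c(APE = 57L, CTEPH = 52L, CONTROL = 22L),
      feature_params = fp,
      correlation = cp$correlation,
      seed = cp$seed %||% y$seed %||% 1L)
  }
  phantoms <- NULL
  if (!is.null(y$phantoms)) {
    phantoms <- lapply(y$phantoms, function(ph) {
      spec <- lapply(ph$defect_spec %||% list(), function(d)
        wedge_defect(unlist(d$apex_mm), unlist(d$axis), d$angle_deg,
                     d$length_mm))
      args <- ph[setdiff(names(ph), c("group", "id", "defect_spec"))]
      args$defect_spec <- spec
      list(params = do.call(phantom_params, args),
           group = ph$group %||% NA_character_, id = ph$id)
    })
  }
  study_config(mode = y$mode %||% "feature-simulation",
               cohort_params = cohort_params, phantoms = phantoms,
               cohort_path = y$cohort_path,
               analyses = y$analyses %||% default_analyses(),
               combinations = y$combinations %||% default_combinations(),
               ratio = y$ratio %||% 0.8, seed = y$seed %||% 1L,
               alpha = y$alpha %||% 0.05)
}
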