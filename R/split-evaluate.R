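#' Stratified train/validation split
#'
#' Randomly splits a cohort into a training and a validation set, stratified
#' by group so that every group contributes to both sets. Within each
#' stratum the training size is `round(ratio * n)`, clamped to leave at
#' least one patient on each side. Deterministic given the seed.
#'
#' @param tab cohort data frame (needs `id` plus the stratification column).
#' @param ratio training fraction, default 0.8.
#' @param seed integer RNG seed.
#' @param stratify_by stratification column name, default `"group"`.
#' @return list of class `split_result`: `train`, `validation`, `seed`,
#'   `ratio`.
#' @export
split_cohort <- function(tab, ratio = 0.8, seed = 1L, stratify_by = "group") {
  assert_number(ratio, "ratio", lower = 0, upper = 1)
  if (!stratify_by %in% names(tab))
    abort_dectperf(sprintf("stratification column `%s` not found", stratify_by),
                   "dectperf_configuration_error")
  strata <- sort(unique(tab[[stratify_by]]))
  set.seed(seed)
  train_idx <- integer(0)
  for (s in strata) {
    idx <- which(tab[[stratify_by]] == s)
    n <- length(idx)
    if (n < 2L)
      abort_dectperf(sprintf("stratum `%s` has only %d member(s); need >= 2",
                             s, n), "dectperf_validation_error")
    k <- min(max(round(ratio * n), 1L), n - 1L)
    train_idx <- c(train_idx, sample(idx, k))
  }
  train_idx <- sort(train_idx)
  structure(list(train = tab[train_idx, , drop = FALSE],
                 validation = tab[-train_idx, , drop = FALSE],
                 seed = as.integer(seed), ratio = ratio),
            class = "split_result")
}

new_diagnostic_performance <- function(auc = NA_real_, ci_low = NA_real_,
                                       ci_high = NA_real_, cutoff, sensitivity,
                                       specificity, ppv, npv, direction,
                                       n_pos, n_neg, degenerate = FALSE) {
  structure(list(auc = auc, ci_low = ci_low, ci_high = ci_high,
                 cutoff = cutoff, sensitivity = sensitivity,
                 specificity = specificity, ppv = ppv, npv = npv,
                 direction = direction, n_pos = n_pos, n_neg = n_neg,
                 degenerate = degenerate),
            class = "diagnostic_performance")
}

#' @export
print.diagnostic_performance <- function(x, ...) {
  cat(sprintf(
    "<diagnostic_performance> AUC %.3f (95%%-CI %.3f-%.3f), cutoff %.4g\n",
    x$auc, x$ci_low, x$ci_high, x$cutoff))
  cat(sprintf("  se %.3f  sp %.3f  PPV %.3f  NPV %.3f  (%d pos / %d neg)\n",
              x$sensitivity, x$specificity, x$ppv, x$npv, x$n_pos, x$n_neg))
  invisible(x)
}

# Performance of given scores on one dataset at a fixed cutoff.
performance_at_cutoff <- function(scores, pos, cutoff, direction, alpha) {
  n_pos <- sum(pos); n_neg <- sum(!pos)
  pred <- classify_scores(scores, cutoff, direction)
  se <- if (n_pos > 0) sum(pred & pos) / n_pos else NA_real_
  sp <- if (n_neg > 0) sum(!pred & !pos) / n_neg else NA_real_
  cp <- confusion_predictive(pred, pos)
  auc <- ci_low <- ci_high <- NA_real_
  degenerate <- FALSE
  if (n_pos >= 1 && n_neg >= 1) {
    auc <- auc_mann_whitney(scores, pos, direction = direction)
    if (n_pos >= 2 && n_neg >= 2) {
      ci <- delong_ci(scores, pos, direction = direction, alpha = alpha)
      ci_low <- ci$ci_low; ci_high <- ci$ci_high
      degenerate <- ci$degenerate
    }
  }
  new_diagnostic_performance(auc, ci_low, ci_high, cutoff, se, sp,
                             cp$ppv, cp$npv, direction, n_pos, n_neg,
                             degenerate)
}

#' Train/validation evaluation of one marker
#'
#' The operating cutoff is chosen by Youden's index on the training set and
#' transferred unchanged to the validation set. AUC and its DeLong interval
#' are computed on each set separately; PPV/NPV come from the confusion
#' counts of the set being reported (i.e. at that set's prevalence). Rows
#' missing the marker are dropped and counted. A single-class validation set
#' yields a missing AUC while the cutoff-based measures that remain defined
#' are still reported.
#'
#' @param train,validation cohort data frames.
#' @param marker feature column name.
#' @param positive group label(s) of the positive class; a vector pools
#'   groups (e.g. both disease groups against controls).
#' @param negative optional group label(s) of the negative class; when
#'   given, both sets are filtered to those groups first.
#' @param direction `"higher"` or `"lower"` (is the positive class expected
#'   at higher or lower marker values).
#' @param alpha CI level parameter, default 0.05.
#' @return list of class `marker_evaluation`: `marker`, `train`,
#'   `validation` (both [new_diagnostic_performance()]), `cutoff`,
#'   `n_dropped`.
#' @export
evaluate_marker <- function(train, validation, marker, positive,
                            negative = NULL, direction = "higher",
                            alpha = 0.05) {
  take <- function(tab) {
    if (!marker %in% names(tab))
      abort_dectperf(sprintf("marker `%s` not present", marker),
                     "dectperf_configuration_error")
    if (!is.null(negative))
      tab <- tab[tab$group %in% c(positive, negative), , drop = FALSE]
    keep <- !is.na(tab[[marker]])
    list(scores = tab[[marker]][keep], pos = tab$group[keep] %in% positive,
         dropped = sum(!keep))
  }
  tr <- take(train); va <- take(validation)
  check_two_classes(tr$scores, tr$pos)
  yc <- youden_cutoff(tr$scores, tr$pos, direction = direction)
  perf_train <- performance_at_cutoff(tr$scores, tr$pos, yc$cutoff,
                                      direction, alpha)
  perf_val <- performance_at_cutoff(va$scores, va$pos, yc$cutoff,
                                    direction, alpha)
  structure(list(marker = marker, train = perf_train,
                 validation = perf_val, cutoff = yc$cutoff,
                 n_dropped = tr$dropped + va$dropped),
            class = "marker_evaluation")
}
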