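classify_scores <- function(scores, cutoff, direction = "higher") {
  if (direction == "lower") scores <= cutoff else scores >= cutoff
}

#' Youden-index optimal cutoff
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over candidate
#' thresholds placed midway between adjacent distinct observed scores, plus
#' -Inf/+Inf sentinels (classify-all and classify-none). Subjects are called
#' positive at `score >= cutoff` (direction `"higher"`) or `score <= cutoff`
#' (direction `"lower"`). Ties in J are resolved towards higher sensitivity,
#' then towards the cutoff calling more subjects positive — the rule-out
#' orientation.
#'
#' @inheritParams auc_mann_whitney
#' @return list with `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
youden_cutoff <- function(scores, labels, positive = TRUE,
                          direction = "higher") {
  pos <- as_positive(labels, positive)
  check_two_classes(scores, pos)
  s <- orient_scores(scores, direction)
  m <- as.numeric(sum(pos)); n <- as.numeric(sum(!pos))
  u <- sort(unique(s))
  k <- length(u)
  # candidate c_0 = -Inf (call everyone positive), c_i = midpoint above u[i]
  # for i < k, c_k = +Inf (call no one positive); cumulative class counts
  # give sensitivity/specificity at every candidate in O(n log n)
  cand <- c(-Inf, if (k > 1) (u[-1] + u[-k]) / 2, Inf)
  iu <- match(s, u)
  cnt_pos <- tabulate(iu[pos], nbins = k)
  cnt_neg <- tabulate(iu[!pos], nbins = k)
  se <- (m - c(0, cumsum(cnt_pos))) / m
  sp <- c(0, cumsum(cnt_neg)) / n
  j <- se + sp - 1
  # ties in J resolved towards higher sensitivity, then towards the cutoff
  # calling more subjects positive (lower index): se is non-increasing in
  # the index, so the first index attaining the optimum satisfies both
  idx <- which(j >= max(j) - 1e-12)
  idx <- idx[which.max(se[idx])]
  ci <- cand[idx]
  list(cutoff = if (direction == "lower") -ci else ci,
       sensitivity = se[idx], specificity = sp[idx], j = j[idx])
}

#' Positive and negative predictive value
#'
#' Bayes' rule at a given disease prevalence:
#' `PPV = se*p / (se*p + (1-sp)*(1-p))`,
#' `NPV = sp*(1-p) / ((1-se)*p + sp*(1-p))`.
#' A degenerate denominator (no predicted positives or no predicted
#' negatives in expectation) yields `NA` with a warning.
#'
#' @param sensitivity,specificity proportions in \[0, 1\].
#' @param prevalence disease prevalence in (0, 1).
#' @return list with `ppv`, `npv`.
#' @export
predictive_values <- function(sensitivity, specificity, prevalence) {
  assert_number(sensitivity, "sensitivity", lower = 0, upper = 1)
  assert_number(specificity, "specificity", lower = 0, upper = 1)
  assert_number(prevalence, "prevalence", lower = 0, upper = 1)
  if (prevalence <= 0 || prevalence >= 1)
    abort_dectperf("prevalence must be strictly inside (0, 1)",
                   "dectperf_invalid_parameter")
  p <- prevalence
  den_p <- sensitivity * p + (1 - specificity) * (1 - p)
  den_n <- (1 - sensitivity) * p + specificity * (1 - p)
  ppv <- npv <- NA_real_
  if (den_p > 0) ppv <- sensitivity * p / den_p
  else warn_dectperf("PPV undefined: no predicted positives",
                     "dectperf_degenerate_predictive")
  if (den_n > 0) npv <- specificity * (1 - p) / den_n
  else warn_dectperf("NPV undefined: no predicted negatives",
                     "dectperf_degenerate_predictive")
  list(ppv = ppv, npv = npv)
}

# Empirical PPV/NPV from confusion counts at a fixed cutoff; NA (not 0/0)
# when no subjects are predicted positive resp. negative.
confusion_predictive <- function(pred, pos) {
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  tn <- sum(!pred & !pos); fn <- sum(!pred & pos)
  list(ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}
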