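# Orientation: all AUC-layer functions take a `direction` argument.
# "higher" means larger marker values indicate the positive class;
# "lower" negates the scores internally so the same machinery applies.

orient_scores <- function(scores, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (direction == "lower") -scores else scores
}

check_two_classes <- function(scores, pos) {
  if (anyNA(scores) || anyNA(pos))
    abort_dectperf("scores/labels must not contain missing values",
                   "dectperf_validation_error")
  if (sum(pos) < 1L || sum(!pos) < 1L)
    abort_dectperf("need at least one positive and one negative subject",
                   "dectperf_single_class")
  invisible(NULL)
}

as_positive <- function(labels, positive) {
  if (is.logical(labels) && isTRUE(positive)) labels else labels == positive
}

#' Mann-Whitney AUC
#'
#' Tie-corrected two-sample rank estimator of the area under the empirical
#' ROC curve: the proportion of (positive, negative) pairs in which the
#' positive subject scores higher, with ties counting 1/2. Computed via
#' midranks in O(n log n); equal by construction to exhaustive pair counting
#' and to the trapezoidal area under the empirical ROC.
#'
#' @param scores numeric marker values.
#' @param labels class labels (any type); `positive` selects the positive
#'   class.
#' @param positive value of `labels` denoting a positive (diseased) subject.
#' @param direction `"higher"` if larger scores indicate the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels, positive = TRUE,
                             direction = "higher") {
  pos <- as_positive(labels, positive)
  check_two_classes(scores, pos)
  r <- rank(scores, ties.method = "average")
  m <- as.numeric(sum(pos)); n <- as.numeric(sum(!pos))
  a <- (sum(r[pos]) - m * (m + 1) / 2) / (m * n)
  # negating scores maps the estimator to exactly 1 - AUC (ties included),
  # so the flip is applied to the value rather than to the ranks
  if (match.arg(direction, c("higher", "lower")) == "lower") 1 - a else a
}

# DeLong structural components ("placement values"): for positive i,
# V10_i = mean_j psi(X_i, Y_j); for negative j, V01_j = mean_i psi(X_i, Y_j),
# psi = 1, 1/2, 0 for X>Y, X==Y, X<Y. Midrank identities give them without
# the O(mn) pair sweep.
delong_placements <- function(scores, pos, direction = "higher") {
  s <- orient_scores(scores, direction)
  m <- as.numeric(sum(pos)); n <- as.numeric(sum(!pos))
  r_all <- rank(s, ties.method = "average")
  r_pos <- rank(s[pos], ties.method = "average")
  r_neg <- rank(s[!pos], ties.method = "average")
  v10 <- (r_all[pos] - r_pos) / n
  v01 <- 1 - (r_all[!pos] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10), m = m, n = n)
}

#' DeLong variance and confidence interval for one AUC
#'
#' Nonparametric variance of the Mann-Whitney AUC from the DeLong structural
#' components, with a normal-approximation confidence interval clipped to
#' \[0, 1\]. A perfectly separating marker has zero estimated variance and a
#' degenerate interval, flagged via `degenerate = TRUE`.
#'
#' @inheritParams auc_mann_whitney
#' @param alpha two-sided type-I level for the interval (default 0.05).
#' @return list with `auc`, `se`, `ci_low`, `ci_high`, `degenerate`.
#' @export
delong_ci <- function(scores, labels, positive = TRUE, direction = "higher",
                      alpha = 0.05) {
  pos <- as_positive(labels, positive)
  check_two_classes(scores, pos)
  if (sum(pos) < 2L || sum(!pos) < 2L)
    abort_dectperf("DeLong variance needs >= 2 subjects per class",
                   "dectperf_single_class")
  pl <- delong_placements(scores, pos, direction)
  v <- stats::var(pl$v10) / pl$m + stats::var(pl$v01) / pl$n
  se <- sqrt(v)
  z <- stats::qnorm(1 - alpha / 2)
  list(auc = pl$auc, se = se,
       ci_low = max(0, pl$auc - z * se),
       ci_high = min(1, pl$auc + z * se),
       degenerate = v == 0)
}

#' DeLong test for two correlated AUCs
#'
#' Two-sided z-test on the difference of two AUCs measured on the same
#' subjects, using the covariance of the DeLong structural components.
#' Identical (after orientation) score vectors give `z = 0, p = 1` by
#' definition; zero estimated variance with unequal AUCs is an error.
#'
#' @param scores_a,scores_b paired marker values over identical subjects.
#' @param labels,positive class labels and positive-class value.
#' @param direction_a,direction_b orientation of each marker.
#' @return list with `auc_a`, `auc_b`, `z`, `p_value`, `se_diff`.
#' @export
delong_compare <- function(scores_a, scores_b, labels, positive = TRUE,
                           direction_a = "higher", direction_b = "higher") {
  if (length(scores_a) != length(scores_b))
    abort_dectperf("paired scores must have equal length",
                   "dectperf_validation_error")
  pos <- as_positive(labels, positive)
  check_two_classes(scores_a, pos)
  check_two_classes(scores_b, pos)
  pa <- delong_placements(scores_a, pos, direction_a)
  pb <- delong_placements(scores_b, pos, direction_b)
  sa <- orient_scores(scores_a, direction_a)
  sb <- orient_scores(scores_b, direction_b)
  if (isTRUE(all.equal(sa, sb, tolerance = 0)) || identical(sa, sb))
    return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p_value = 1,
                se_diff = 0))
  v <- stats::var(pa$v10 - pb$v10) / pa$m + stats::var(pa$v01 - pb$v01) / pa$n
  if (v == 0) {
    if (pa$auc == pb$auc)
      return(list(auc_a = pa$auc, auc_b = pb$auc, z = 0, p_value = 1,
                  se_diff = 0))
    abort_dectperf("zero estimated variance with unequal AUCs",
                   "dectperf_degenerate_variance")
  }
  z <- (pa$auc - pb$auc) / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, z = z,
       p_value = 2 * stats::pnorm(-abs(z)), se_diff = sqrt(v))
}
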