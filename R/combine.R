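#' Linear combination of two markers (Pepe-style)
#'
#' Combines two diagnostic markers into a single linear score
#' `A + coef_b * B + intercept`, anchored so marker A's coefficient is
#' exactly 1 — the reporting form of a published two-marker risk score.
#' Two estimators are provided:
#'
#' * `"logistic"` (default): fit a binary logistic model in both markers
#'   and divide the fitted coefficients and intercept by A's coefficient.
#'   Under bivariate-normal markers with equal covariance the fitted
#'   direction converges to the Fisher discriminant `solve(Sigma, delta)`.
#' * `"auc_grid"`: distribution-free search for the `coef_b` maximizing the
#'   empirical (Mann-Whitney) AUC of `A + coef_b * B`, parameterised by the
#'   direction angle so the whole range including `coef_b = 0` and the
#'   pure-B limit is covered. The intercept is set to minus the Youden
#'   cutoff of the un-shifted score, so the decision boundary of the
#'   reported score sits at 0.
#'
#' The logistic route falls back to the grid search (with a notice) on
#' perfect separation and whenever its combined training AUC would fall
#' below either single marker, so the returned combination never loses to
#' its anchor on the training data.
#'
#' @param values_a,values_b complete paired marker values (A is the anchor).
#' @param labels,positive class labels and the positive-class value.
#' @param method `"logistic"` or `"auc_grid"`.
#' @return list of class `marker_combination`: `anchor_coef` (1), `coef_b`,
#'   `intercept`, `direction` of the combined score, `method` requested,
#'   `method_used`, `auc_combined`, `auc_a`, `auc_b`, and `score(a, b)`.
#' @export
combine_markers <- function(values_a, values_b, labels, positive = TRUE,
                            method = c("logistic", "auc_grid")) {
  method <- match.arg(method)
  pos <- as_positive(labels, positive)
  if (anyNA(values_a) || anyNA(values_b))
    abort_dectperf("combine_markers requires complete paired observations",
                   "dectperf_validation_error")
  check_two_classes(values_a, pos)

  auc_a <- auc_mann_whitney(values_a, pos)
  auc_b <- auc_mann_whitney(values_b, pos)
  best_single <- max(auc_a, auc_b, 1 - auc_a, 1 - auc_b)

  fit_logistic <- function() {
    sep_warn <- FALSE
    fit <- withCallingHandlers(
      stats::glm(pos ~ values_a + values_b, family = stats::binomial()),
      warning = function(w) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (sep_warn || !fit$converged) return(NULL)
    cf <- stats::coef(fit)
    if (anyNA(cf)) return(NULL)
    scale_a <- abs(cf[["values_a"]])
    if (scale_a < 1e-10 * max(abs(cf[["values_b"]]), 1))
      abort_dectperf(
        "anchor marker's fitted coefficient is ~0; anchor on marker B instead",
        "dectperf_anchor_swap")
    coef_b <- cf[["values_b"]] / cf[["values_a"]]
    intercept <- cf[["(Intercept)"]] / cf[["values_a"]]
    direction <- if (cf[["values_a"]] > 0) "higher" else "lower"
    score <- values_a + coef_b * values_b + intercept
    list(coef_b = coef_b, intercept = intercept, direction = direction,
         auc = auc_mann_whitney(score, pos, direction = direction),
         method_used = "logistic")
  }

  fit_grid <- function() {
    sd_ratio <- stats::sd(values_a) / max(stats::sd(values_b), 1e-300)
    eval_b <- function(b) auc_mann_whitney(values_a + b * values_b, pos)
    search <- function(thetas) {
      b <- tan(thetas) * sd_ratio
      auc <- vapply(b, eval_b, numeric(1))
      gain <- pmax(auc, 1 - auc)
      # prefer the smallest |coef_b| among ties (parsimony)
      ok <- which(gain >= max(gain) - 1e-12)
      i <- ok[which.min(abs(b[ok]))]
      list(b = b[i], theta = thetas[i], auc = auc[i])
    }
    coarse <- search(seq(-pi / 2 + 0.002, pi / 2 - 0.002, length.out = 721))
    step <- pi / 720
    fine <- search(seq(coarse$theta - step, coarse$theta + step,
                       length.out = 201))
    direction <- if (fine$auc >= 0.5) "higher" else "lower"
    score0 <- values_a + fine$b * values_b
    yc <- youden_cutoff(score0, pos, direction = direction)
    score <- score0 - yc$cutoff
    list(coef_b = fine$b, intercept = -yc$cutoff, direction = direction,
         auc = auc_mann_whitney(score, pos, direction = direction),
         method_used = "auc_grid")
  }

  res <- NULL
  if (method == "logistic") {
    res <- fit_logistic()
    if (is.null(res) || res$auc < best_single - 1e-9) {
      message("combine_markers: logistic fit unusable or beaten by a single ",
              "marker; falling back to AUC grid search")
      res <- fit_grid()
    }
  } else {
    res <- fit_grid()
  }

  structure(list(
    anchor_coef = 1, coef_b = res$coef_b, intercept = res$intercept,
    direction = res$direction, method = method,
    method_used = res$method_used,
    auc_combined = res$auc, auc_a = auc_a, auc_b = auc_b,
    score = function(a, b) a + res$coef_b * b + res$intercept
  ), class = "marker_combination")
}

#' @export
print.marker_combination <- function(x, ...) {
  cat(sprintf("<marker_combination> score = A + %.4g * B + %.4g (%s)\n",
              x$coef_b, x$intercept, x$method_used))
  cat(sprintf("  training AUC: combined %.3f | A alone %.3f | B alone %.3f\n",
              x$auc_combined, x$auc_a, x$auc_b))
  invisible(x)
}
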