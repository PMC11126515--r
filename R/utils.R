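# Internal condition helpers. All package errors carry class "dectperf_error"
# plus a specific subclass so callers (and tests) can branch on error type
# rather than on message text.

abort_dectperf <- function(message, class, call. = FALSE, ...) {
  cond <- errorCondition(message, ..., class = c(class, "dectperf_error"))
  stop(cond)
}

warn_dectperf <- function(message, class, ...) {
  cond <- warningCondition(message, ..., class = c(class, "dectperf_warning"))
  warning(cond)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_dectperf(sprintf("`%s` must be a single finite number", name),
                   "dectperf_invalid_parameter")
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    abort_dectperf(sprintf("`%s` = %g outside allowed range", name, x),
                   "dectperf_invalid_parameter")
  invisible(x)
}

assert_positive_vector <- function(x, name, n = NULL) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    abort_dectperf(sprintf("`%s` must be positive and finite", name),
                   "dectperf_invalid_parameter")
  if (!is.null(n) && length(x) != n)
    abort_dectperf(sprintf("`%s` must have length %d", name, n),
                   "dectperf_invalid_parameter")
  invisible(x)
}

# Unit vector in (z, y, x) mm space; zero vector is a parameter error.
normalize_axis <- function(v) {
  nv <- sqrt(sum(v^2))
  if (!is.finite(nv) || nv == 0)
    abort_dectperf("defect axis must be a non-zero vector",
                   "dectperf_invalid_parameter")
  v / nv
}

`%||%` <- function(a, b) if (is.null(a)) b else a
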