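# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: AUC by exhaustive pair enumeration, Youden by direct
# threshold sweep, moments by explicit summation.

auc_by_pair_counting <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (x in sp) for (y in sn)
    tot <- tot + if (x > y) 1 else if (x == y) 0.5 else 0
  tot / (length(sp) * length(sn))
}

# Best Youden J over every possible decision rule "positive iff s >= t",
# t swept over all observed values, all midpoints and +/-Inf.
youden_by_brute_force <- function(scores, pos) {
  u <- sort(unique(scores))
  cand <- c(-Inf, u, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, Inf)
  best <- -Inf
  for (t in cand) {
    pred <- scores >= t
    j <- sum(pred & pos) / sum(pos) + sum(!pred & !pos) / sum(!pos) - 1
    if (j > best) best <- j
  }
  best
}

# Two-pass population moment computation, one voxel at a time.
moments_by_summation <- function(v) {
  n <- length(v)
  mu <- sum(v) / n
  m2 <- m3 <- m4 <- 0
  for (x in v) {
    d <- x - mu
    m2 <- m2 + d^2; m3 <- m3 + d^3; m4 <- m4 + d^4
  }
  m2 <- m2 / n; m3 <- m3 / n; m4 <- m4 / n
  list(mean = mu, skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3)
}

# Closed-form AUC of a Gaussian marker in two groups.
binormal_auc <- function(mu_pos, sd_pos, mu_neg, sd_neg) {
  pnorm((mu_pos - mu_neg) / sqrt(sd_pos^2 + sd_neg^2))
}

# Hanley-McNeil variance under the exponential model.
hanley_mcneil_var <- function(auc, m, n) {
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  (auc * (1 - auc) + (m - 1) * (q1 - auc^2) + (n - 1) * (q2 - auc^2)) / (m * n)
}
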