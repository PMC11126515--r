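test_that("Mann-Whitney AUC reproduces hand-computed examples", {
  expect_equal(auc_mann_whitney(c(3, 1, 2), c(TRUE, FALSE, FALSE)), 1.0)
  expect_equal(auc_mann_whitney(rep(2, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE)),
               0.5)
  # positives {3,1,2}, negatives {2,0}: 4.5 of 6 pairs
  s <- c(3, 1, 2, 2, 0); l <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(auc_mann_whitney(s, l), 0.75)
  expect_equal(auc_mann_whitney(s, l), auc_by_pair_counting(s, l))
})

test_that("rank-based AUC equals exhaustive pair counting on random small datasets", {
  set.seed(4)
  for (i in 1:40) {
    n <- sample(4:20, 1)
    pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    s <- sample(seq(0, 5, by = 0.5), n, replace = TRUE)  # forces ties
    expect_equal(auc_mann_whitney(s, pos), auc_by_pair_counting(s, pos))
  }
})

test_that("flipping the direction maps AUC to exactly 1 - AUC, ties included", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    s <- sample(seq(0, 3, by = 0.25), n, replace = TRUE)
    a_hi <- auc_mann_whitney(s, pos, direction = "higher")
    a_lo <- auc_mann_whitney(s, pos, direction = "lower")
    expect_identical(a_lo, 1 - a_hi)
  }
})

test_that("single-class input is rejected", {
  expect_error(auc_mann_whitney(1:3, c(TRUE, TRUE, TRUE)),
               class = "dectperf_single_class")
})

test_that("DeLong self-comparison gives z = 0, p = 1", {
  set.seed(2)
  s <- rnorm(30); pos <- rep(c(TRUE, FALSE), 15)
  res <- delong_compare(s, s, pos)
  expect_identical(res$z, 0)
  expect_identical(res$p_value, 1)
})

test_that("perfect marker yields a degenerate CI at [1, 1] and is flagged", {
  s <- c(10, 9, 8, 1, 2, 3); pos <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  ci <- delong_ci(s, pos)
  expect_equal(ci$auc, 1)
  expect_equal(ci$ci_low, 1)
  expect_equal(ci$ci_high, 1)
  expect_true(ci$degenerate)
})

test_that("DeLong AUC standard error is consistent with bootstrap and Hanley-McNeil", {
  set.seed(61)
  m <- 20; n <- 20
  scores <- c(rnorm(m, 1.2, 1), rnorm(n, 0, 1))
  pos <- rep(c(TRUE, FALSE), c(m, n))
  dl <- delong_ci(scores, pos)

  boot <- replicate(2000, {
    ip <- sample.int(m, replace = TRUE)
    ineg <- m + sample.int(n, replace = TRUE)
    auc_mann_whitney(scores[c(ip, ineg)], pos[c(ip, ineg)])
  })
  expect_lt(abs(dl$se - sd(boot)) / sd(boot), 0.15)

  hm <- sqrt(hanley_mcneil_var(dl$auc, m, n))
  expect_lt(abs(dl$se - hm) / hm, 0.20)
})

test_that("DeLong AUC, CI and paired test agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(33)
  n <- 60
  pos <- rep(c(TRUE, FALSE), c(25, 35))
  a <- rnorm(n) + pos * 1.0
  b <- 0.5 * a + rnorm(n) + pos * 0.6
  dl <- delong_ci(a, pos)
  ra <- pROC::roc(pos, a, direction = "<", quiet = TRUE)
  expect_equal(dl$auc, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  ci_ref <- as.numeric(pROC::ci.auc(ra, method = "delong"))
  expect_equal(dl$ci_low, max(0, ci_ref[1]), tolerance = 1e-9)
  expect_equal(dl$ci_high, min(1, ci_ref[3]), tolerance = 1e-9)
  rb <- pROC::roc(pos, b, direction = "<", quiet = TRUE)
  cmp <- delong_compare(a, b, pos)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(cmp$p_value, as.numeric(ref$p.value), tolerance = 1e-9)
})

test_that("Youden search over midpoints reproduces worked examples", {
  # perfectly separated classes: J = 1 midway between the closest pair
  res <- youden_cutoff(c(5, 4, 3, 2, 2, 1),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(res$j, 1)
  expect_equal(res$cutoff, 2.5)
  expect_equal(res$sensitivity, 1)
  expect_equal(res$specificity, 1)
})

test_that("midpoint Youden search attains the brute-force optimum on all small datasets", {
  set.seed(14)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    s <- sample(seq(0, 4, by = 0.5), n, replace = TRUE)
    res <- youden_cutoff(s, pos)
    expect_equal(res$j, youden_by_brute_force(s, pos), tolerance = 1e-12)
  }
})

test_that("Youden cutoff respects the direction convention", {
  s <- c(1, 2, 3, 4); pos <- c(TRUE, TRUE, FALSE, FALSE)  # low = positive
  res <- youden_cutoff(s, pos, direction = "lower")
  expect_equal(res$j, 1)
  expect_equal(res$cutoff, 2.5)
  expect_equal(res$sensitivity, 1)
})

test_that("binormal Youden cutoff converges to the equal-density point of the two normals", {
  # malperfused ID_mean,LA group distributions; the equal-density point of
  # N(0.028, 0.012^2) and N(0.040, 0.016^2) solved numerically is the
  # population-optimal threshold
  f <- function(x) dnorm(x, 0.040, 0.016) - dnorm(x, 0.028, 0.012)
  x_star <- uniroot(f, c(0.03, 0.05))$root
  co <- suppressMessages(sample_feature_cohort(cohort_sim_params(
    group_sizes = c(APE = 100000L, CTEPH = 100000L),
    feature_params = default_feature_params()["malp_id_mean_la"],
    seed = 19L)))
  res <- youden_cutoff(co$malp_id_mean_la, co$group == "CTEPH")
  expect_equal(res$cutoff, x_star, tolerance = 0.002)
})

test_that("predictive values follow Bayes' rule", {
  expect_equal(predictive_values(1, 1, 0.3), list(ppv = 1, npv = 1))
  expect_equal(predictive_values(0.5, 0.5, 0.5), list(ppv = 0.5, npv = 0.5))
  pv <- predictive_values(0.74, 0.64, 52 / 109)
  expect_equal(pv$ppv, 0.652, tolerance = 0.001)
  expect_equal(pv$npv, 0.730, tolerance = 0.001)
  expect_warning(pv0 <- predictive_values(0, 1, 0.5),
                 class = "dectperf_degenerate_predictive")
  expect_true(is.na(pv0$ppv))
})

test_that("an uninformative second marker leaves the combined AUC at the anchor's", {
  set.seed(41)
  n <- 10000
  pos <- rep(c(TRUE, FALSE), each = n / 2)
  a <- rnorm(n) + pos * 1
  b <- rnorm(n)  # independent of the label
  cm <- suppressMessages(combine_markers(a, b, pos))
  expect_lt(abs(cm$auc_combined - cm$auc_a), 0.01)
})

test_that("the combination recovers the Fisher discriminant under bivariate normality", {
  set.seed(52)
  n <- 100000
  sigma <- matrix(c(1, 0.4, 0.4, 0.8), 2)
  delta <- c(0.6, 0.5)
  ch <- chol(sigma)
  zn <- matrix(rnorm(2 * n), ncol = 2) %*% ch
  zp <- sweep(matrix(rnorm(2 * n), ncol = 2) %*% ch, 2, delta, `+`)
  a <- c(zp[, 1], zn[, 1]); b <- c(zp[, 2], zn[, 2])
  pos <- rep(c(TRUE, FALSE), each = n)
  w <- solve(sigma, delta)
  b_expected <- w[2] / w[1]
  cm <- suppressMessages(combine_markers(a, b, pos))
  expect_lt(abs(cm$coef_b - b_expected) / abs(b_expected), 0.05)
})

test_that("logistic and AUC-grid combination agree on the binormal two-marker cohort", {
  co <- suppressMessages(sample_feature_cohort(cohort_sim_params(
    group_sizes = c(APE = 4000L, CTEPH = 4000L),
    feature_params = default_feature_params()[c("mpa_dia", "malp_id_mean_la")],
    seed = 23L)))
  pos <- co$group == "CTEPH"
  cl <- suppressMessages(combine_markers(co$mpa_dia, co$malp_id_mean_la, pos,
                                         method = "logistic"))
  cg <- suppressMessages(combine_markers(co$mpa_dia, co$malp_id_mean_la, pos,
                                         method = "auc_grid"))
  expect_identical(cl$method_used, "logistic")
  expect_identical(cg$method_used, "auc_grid")
  expect_lt(abs(cl$auc_combined - cg$auc_combined) / cg$auc_combined, 0.10)
})

test_that("the combination never loses to its anchor on training data", {
  set.seed(71)
  for (i in 1:10) {
    n <- 60
    pos <- rep(c(TRUE, FALSE), c(25, 35))
    a <- rnorm(n) + pos * runif(1, 0, 1.5)
    b <- rnorm(n) + pos * runif(1, -1, 1)
    cm <- suppressMessages(combine_markers(a, b, pos))
    expect_gte(cm$auc_combined, auc_mann_whitney(a, pos) - 1e-9)
  }
})

test_that("perfect separation falls back to the distribution-free grid search", {
  a <- c(5, 6, 7, 1, 2, 3, 5.5, 6.5, 1.5, 2.5)
  b <- c(1, 2, 1, 2, 1, 2, 1.5, 1.2, 1.8, 1.3)
  pos <- rep(c(TRUE, FALSE), each = 3)
  pos <- c(pos, TRUE, TRUE, FALSE, FALSE)
  expect_message(cm <- combine_markers(a, b, pos), "falling back")
  expect_identical(cm$method_used, "auc_grid")
  expect_equal(cm$auc_combined, 1)
})

test_that("stratified split honours per-stratum sizes and partitions the cohort", {
  co <- suppressMessages(sample_feature_cohort(cohort_sim_params(seed = 3L)))
  sub <- co[co$group %in% c("APE", "CTEPH"), ]
  sp <- split_cohort(sub, ratio = 0.8, seed = 5L)
  expect_equal(sum(sp$train$group == "APE"), 46L)    # round(0.8 * 57)
  expect_equal(sum(sp$train$group == "CTEPH"), 42L)  # round(0.8 * 52)
  expect_setequal(c(sp$train$id, sp$validation$id), sub$id)
  expect_length(intersect(sp$train$id, sp$validation$id), 0)
  expect_identical(split_cohort(sub, ratio = 0.8, seed = 5L)$train$id,
                   sp$train$id)

  ten <- data.frame(id = sprintf("P%02d", 1:10), group = "APE")
  sp10 <- split_cohort(ten, ratio = 0.8, seed = 1L)
  expect_equal(nrow(sp10$train), 8L)
  expect_equal(nrow(sp10$validation), 2L)

  one <- data.frame(id = c("P1", "P2", "P3"), group = c("APE", "APE", "CTEPH"))
  err <- expect_error(split_cohort(one, seed = 1L),
                      class = "dectperf_validation_error")
  expect_match(conditionMessage(err), "CTEPH")
})

test_that("marker evaluation transfers the training cutoff and reports per-set performance", {
  tr <- data.frame(id = sprintf("T%02d", 1:8),
                   group = rep(c("CTEPH", "APE"), each = 4),
                   m = c(5, 6, 7, 8, 1, 2, 3, 4))
  ev <- evaluate_marker(tr, tr, "m", positive = "CTEPH", negative = "APE")
  expect_equal(ev$train$auc, 1)
  expect_equal(ev$validation$auc, 1)
  expect_equal(ev$cutoff, 4.5)
  expect_equal(ev$train$sensitivity, 1)
  expect_equal(ev$train$ppv, 1)

  # direction flip symmetry on the AUC
  ev_lo <- evaluate_marker(tr, tr, "m", positive = "CTEPH", negative = "APE",
                           direction = "lower")
  expect_equal(ev_lo$train$auc, 1 - ev$train$auc)

  # single-class validation: AUC missing, cutoff-based measures survive
  va <- data.frame(id = sprintf("V%02d", 1:3), group = "CTEPH",
                   m = c(5, 3, 9))
  ev2 <- evaluate_marker(tr, va, "m", positive = "CTEPH", negative = "APE")
  expect_true(is.na(ev2$validation$auc))
  expect_equal(ev2$validation$sensitivity, 2 / 3)

  # rows missing the marker are dropped and counted
  tr2 <- tr; tr2$m[1] <- NA
  ev3 <- evaluate_marker(tr2, tr, "m", positive = "CTEPH", negative = "APE")
  expect_equal(ev3$n_dropped, 1L)
})
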