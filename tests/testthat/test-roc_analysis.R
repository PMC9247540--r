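test_that("AUC equals the Mann-Whitney pair statistic on hand-counted data", {
  scores <- c(3, 5, 7, 1, 2, 6)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  roc <- empirical_roc(scores, labels)
  expect_equal(roc$auc, 7 / 9)  # 7 of 9 responder/non-responder pairs ordered correctly

  # perfect separation and complete ties
  expect_equal(empirical_roc(c(5, 6, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(empirical_roc(rep(4, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
})

test_that("empirical AUC matches O(n^2) pair counting on random cohorts", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(6:200, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    scores <- round(rnorm(n, mean = labels), sample(c(0, 1, 3), 1))  # induce ties
    roc <- empirical_roc(scores, labels)
    expect_equal(roc$auc, auc_pair_oracle(scores, labels))
    # curve endpoints and monotonicity
    expect_equal(roc$sens[1], 1); expect_equal(roc$spec[1], 0)
    expect_equal(roc$sens[length(roc$sens)], 0)
    expect_true(all(diff(roc$sens) <= 0) && all(diff(roc$spec) >= 0))
  }
})

test_that("AUC is invariant under strictly monotone transforms and flips with direction", {
  set.seed(8)
  scores <- rnorm(60); labels <- rep(c(TRUE, FALSE), 30)
  a0 <- empirical_roc(scores, labels)$auc
  expect_equal(empirical_roc(exp(scores), labels)$auc, a0)
  expect_equal(empirical_roc(qnorm(pnorm(scores))^3 + 5 * scores, labels)$auc, a0)
  expect_equal(empirical_roc(-scores, labels, direction = "lower")$auc, a0)
  expect_equal(empirical_roc(scores, !labels)$auc, 1 - a0)
})

test_that("missing scores are dropped pairwise and degenerate labels error", {
  scores <- c(3, NA, 7, 1, 2, 6)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  roc <- empirical_roc(scores, labels)
  expect_equal(roc$n_pos, 2L)
  expect_equal(roc$n_dropped, 1L)
  expect_error(empirical_roc(1:5, rep(TRUE, 5)), "degenerate")
})

test_that("DeLong CI collapses at perfect separation and mirrors under direction", {
  scores <- c(10, 11, 12, 1, 2, 3)
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  roc <- empirical_roc(scores, labels)
  expect_equal(delong_ci(roc), c(1, 1))

  set.seed(21)
  s <- rnorm(40); l <- rep(c(TRUE, FALSE), 20)
  ci_hi <- delong_ci(empirical_roc(s, l))
  ci_lo <- delong_ci(empirical_roc(s, l, direction = "lower"))
  expect_equal(ci_lo, c(1 - ci_hi[2], 1 - ci_hi[1]))

  tiny <- empirical_roc(c(2, 1, 3), c(TRUE, FALSE, FALSE))
  expect_error(delong_ci(tiny), "variance-undefined")
})

test_that("DeLong CI width agrees with a bootstrap oracle on binormal data", {
  set.seed(77)
  n <- 200
  labels <- rep(c(TRUE, FALSE), n / 2)
  scores <- rnorm(n) + ifelse(labels, sqrt(2) * qnorm(0.8), 0)
  roc <- empirical_roc(scores, labels)
  ci <- delong_ci(roc)
  boot <- replicate(2000, {
    idx <- sample.int(n, n, replace = TRUE)
    lab <- labels[idx]
    if (!any(lab) || all(lab)) return(NA_real_)
    empirical_roc(scores[idx], lab)$auc
  })
  bci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  expect_lt(abs(diff(ci) - diff(bci)) / diff(bci), 0.10)
})

test_that("DeLong CI covers the true AUC at close to nominal rate", {
  set.seed(500)
  delta <- sqrt(2) * qnorm(0.8)   # equal-variance binormal with AUC 0.8
  covered <- logical(500)
  for (i in seq_len(500)) {
    labels <- c(rep(TRUE, 13), rep(FALSE, 19))
    scores <- rnorm(32) + ifelse(labels, delta, 0)
    ci <- delong_ci(empirical_roc(scores, labels))
    covered[i] <- ci[1] <= 0.8 && 0.8 <= ci[2]
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("paired DeLong test: self-comparison, rank invariance, power", {
  set.seed(14)
  labels <- rep(c(TRUE, FALSE), 25)
  a <- rnorm(50) + labels
  self <- delong_paired_test(a, a, labels)
  expect_equal(self$z, 0); expect_equal(self$p, 1)

  mono <- delong_paired_test(a, exp(a / 2), labels)
  expect_equal(mono$auc_a, mono$auc_b)
  expect_equal(mono$p, 1)

  # independent markers, true AUCs 0.8 vs 0.5, n = 500: near-certain rejection
  set.seed(99)
  rejections <- replicate(200, {
    lab <- rep(c(TRUE, FALSE), 250)
    good <- rnorm(500) + ifelse(lab, sqrt(2) * qnorm(0.8), 0)
    junk <- rnorm(500)
    delong_paired_test(good, junk, lab)$p < 0.05
  })
  expect_gt(mean(rejections), 0.95)

  expect_error(delong_paired_test(c(1, 2, 3), c(1, 2, 3), c(TRUE, FALSE, FALSE)),
               "at least 2")
})

test_that("Youden cutoff maximizes J with ties broken toward sensitivity", {
  # perfectly separated: J = 1 and the cutoff sits between the groups
  res <- youden_best_cutoff(c(10, 12, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(res$youden_j, 1)
  expect_gt(res$cutoff, 2); expect_lt(res$cutoff, 10)

  res <- youden_best_cutoff(1:4, c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$sens, 1); expect_equal(res$spec, 1)
  expect_gt(res$cutoff, 2); expect_lte(res$cutoff, 3)

  # complete ties: no cutoff separates anything, J = 0
  expect_equal(youden_best_cutoff(rep(2, 6), rep(c(TRUE, FALSE), 3))$youden_j, 0)
})

test_that("Youden search agrees with exhaustive midpoint search", {
  set.seed(63)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    scores <- round(rnorm(n, labels), 1)
    got <- youden_best_cutoff(scores, labels)
    want <- youden_exhaustive_oracle(scores, labels)
    expect_equal(got$youden_j, want$j, tolerance = 1e-12)
    expect_equal(got$sens + got$spec - 1, got$youden_j)
  }
})
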