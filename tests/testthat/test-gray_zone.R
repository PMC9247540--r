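make_separated <- function(n_pos = 20, n_neg = 30, gap = c(40, 60),
                           seed = 3) {
  set.seed(seed)
  list(scores = c(runif(n_pos, gap[2], gap[2] + 30),
                  runif(n_neg, gap[1] - 30, gap[1])),
       labels = rep(c(TRUE, FALSE), c(n_pos, n_neg)))
}

test_that("bootstrap zone is deterministic under a seed and lives in the gap", {
  d <- make_separated()
  z1 <- bootstrap_cutoff_zone(d$scores, d$labels, n_boot = 200, seed = 10)
  z2 <- bootstrap_cutoff_zone(d$scores, d$labels, n_boot = 200, seed = 10)
  expect_identical(z1[c("lower", "upper", "boot_cutoffs")],
                   z2[c("lower", "upper", "boot_cutoffs")])
  # every replicate cutoff must fall inside the empty band between groups
  expect_true(all(z1$boot_cutoffs > 40 & z1$boot_cutoffs < 60))
  expect_gte(z1$lower, 40); expect_lte(z1$upper, 60)
  expect_lte(z1$lower, z1$upper)

  z3 <- bootstrap_cutoff_zone(d$scores, d$labels, n_boot = 200, seed = 11)
  expect_false(identical(z1$boot_cutoffs, z3$boot_cutoffs))
})

test_that("bootstrap zone rejects bad inputs and redraws single-class replicates", {
  d <- make_separated()
  expect_error(bootstrap_cutoff_zone(d$scores, d$labels, n_boot = 50), "n_boot")
  expect_error(bootstrap_cutoff_zone(1:5, rep(TRUE, 5)), "degenerate")
  # tiny minority class forces redraws yet still yields n_boot cutoffs
  scores <- c(10, 11, 1, 2, 3, 4, 5, 6)
  labels <- rep(c(TRUE, FALSE), c(2, 6))
  z <- suppressMessages(
    bootstrap_cutoff_zone(scores, labels, n_boot = 200, seed = 5))
  expect_length(z$boot_cutoffs, 200)
})

test_that("triadic zone matches exhaustive Sn/Sp evaluation on small data", {
  scores <- c(10, 20, 30, 40, 50, 60)
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  z <- triadic_zone(scores, labels)
  expect_gt(z$lower, 30); expect_lt(z$upper, 40)
  expect_equal(z$lower, z$upper)  # collapses: separation is perfect

  d <- make_separated()
  z <- triadic_zone(d$scores, d$labels)
  expect_equal(z$upper - z$lower, 0)

  expect_error(triadic_zone(1:4, rep(FALSE, 4)), "degenerate")
})

test_that("triadic zone with overlapping groups brackets the Youden cutoff", {
  set.seed(12)
  scores <- c(rnorm(80, 55, 15), rnorm(120, 35, 15))
  labels <- rep(c(TRUE, FALSE), c(80, 120))
  z <- triadic_zone(scores, labels)
  expect_lt(z$lower, z$upper)
  cut <- youden_best_cutoff(scores, labels)$cutoff
  expect_gte(cut, z$lower); expect_lte(cut, z$upper)
  # fractions are exact cohort proportions summing to one
  expect_equal(sum(z$fractions), 1, tolerance = 1e-9)
  expect_true(all(abs(z$fractions * 200 - round(z$fractions * 200)) < 1e-9))
})

test_that("raising either floor never shrinks the triadic zone", {
  set.seed(6)
  for (rep in 1:10) {
    n <- 80
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(labels) || all(labels)) next
    scores <- rnorm(n, ifelse(labels, 1, 0))
    floors <- c(0.6, 0.75, 0.9, 0.95)
    prev_width <- -Inf
    for (f in floors) {
      z <- triadic_zone(scores, labels, sn_floor = f, sp_floor = f)
      width <- z$upper - z$lower
      expect_gte(width + 1e-12, prev_width)
      prev_width <- width
    }
  }
})

test_that("zero floors give an empty zone on separable data", {
  d <- make_separated()
  z <- triadic_zone(d$scores, d$labels, sn_floor = 0, sp_floor = 0)
  expect_equal(z$upper - z$lower, 0)
})

test_that("combined zone picks the wider component and reports cohort fractions", {
  set.seed(12)
  scores <- c(rnorm(40, 55, 15), rnorm(60, 35, 15))
  labels <- rep(c(TRUE, FALSE), c(40, 60))
  cz <- combined_zone(scores, labels, n_boot = 300, seed = 8)
  bw <- cz$bootstrap$upper - cz$bootstrap$lower
  tw <- cz$triadic$upper - cz$triadic$lower
  if (bw > tw) {
    expect_equal(cz$chosen, "bootstrap")
    expect_equal(c(cz$lower, cz$upper), c(cz$bootstrap$lower, cz$bootstrap$upper))
  } else {
    expect_equal(cz$chosen, "triadic")
    expect_equal(c(cz$lower, cz$upper), c(cz$triadic$lower, cz$triadic$upper))
  }
  expect_equal(sum(cz$fractions), 1, tolerance = 1e-9)
  # inside fraction is a count over n: mirrors a 9-of-32 cohort giving 28.1%
  inside <- sum(scores >= cz$lower & scores <= cz$upper)
  expect_equal(unname(cz$fractions["inside"]), inside / 100)
})

test_that("bootstrap zone width shrinks as the cohort grows", {
  widths <- vapply(c(100, 1000, 10000), function(n) {
    set.seed(42)
    labels <- rep(c(TRUE, FALSE), c(0.4 * n, 0.6 * n))
    scores <- rnorm(n, ifelse(labels, 1.2, 0))
    z <- bootstrap_cutoff_zone(scores, labels, n_boot = 200, seed = 1)
    z$upper - z$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})
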