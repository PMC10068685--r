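test_that("pearson_r reproduces hand-computed values and exact cases", {
  x <- c(1, 2, 3, 5)
  expect_equal(as.numeric(pearson_r(x, 2 * x + 1)), 1)
  expect_equal(as.numeric(pearson_r(x, -3 * x + 2)), -1)

  # 4-point set against the covariance / (sd * sd) formula written out
  x <- c(0, 1, 2, 3); y <- c(1, 3, 2, 5)
  num <- sum((x - mean(x)) * (y - mean(y))) / 3
  den <- sqrt(sum((x - mean(x))^2) / 3) * sqrt(sum((y - mean(y))^2) / 3)
  expect_equal(as.numeric(pearson_r(x, y)), num / den)
})

test_that("pearson_r deletes pairwise and rejects degenerate input", {
  x <- c(1, 2, NA, 4, 5); y <- c(2, NA, 3, 8, 10)
  r <- pearson_r(x, y)
  expect_equal(attr(r, "n"), 3L)
  expect_equal(as.numeric(r), as.numeric(pearson_r(c(1, 4, 5), c(2, 8, 10))))
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant input")
  expect_error(pearson_r(c(1, NA), c(NA, 1)), "fewer than 2")
})

test_that("correlation is affine-invariant with sign from the slope", {
  set.seed(17)
  for (i in 1:5) {
    x <- stats::rnorm(15); y <- stats::rnorm(15)
    r0 <- as.numeric(pearson_r(x, y))
    expect_equal(as.numeric(pearson_r(2.5 * x + 7, y)), r0, tolerance = 1e-12)
    expect_equal(as.numeric(pearson_r(x, -0.3 * y + 1)), -r0, tolerance = 1e-12)
  }
})

test_that("t-based significance has its closed forms and monotonicity", {
  expect_equal(r_significance(0, 10)$p_two_tailed, 1)
  s <- r_significance(0.5, 3)
  expect_equal(s$t, 0.5 * sqrt(1 / 0.75))
  expect_equal(s$p_two_tailed, 2 * stats::pt(-0.5 * sqrt(1 / 0.75), 1))
  expect_equal(s$df, 1)

  d <- r_significance(1, 5)
  expect_true(d$degenerate)
  expect_equal(d$p_two_tailed, 0)
  expect_error(r_significance(0.5, 2), "n must be")

  ps <- vapply(3:30, function(n) r_significance(0.4, n)$p_two_tailed,
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("per-compartment correlations suppress undefined columns", {
  mk <- psmaquant:::make_compartment_scores
  # only one patient has nodal disease -> single pair -> suppressed
  records <- list(
    patient_record(1, mk(10, 4, 2), mk(1, 2, 1), 10, 2),
    patient_record(2, mk(10, NA, 4), mk(9, NA, 0), 10, 6),
    patient_record(3, mk(10, NA, 8), mk(2, NA, 2), 10, 3))
  corr <- correlate_table(build_cohort_table(records))
  expect_true(corr$suppressed[corr$compartment == "nodal"])
  expect_false(corr$suppressed[corr$compartment == "composite"])
})

test_that("a near-constant response column is flagged low-variance", {
  mk <- psmaquant:::make_compartment_scores
  records <- lapply(1:10, function(i) {
    pro_resid <- if (i == 10) 0.5 else 0      # nine of ten at -100%
    patient_record(i, mk(10, 5, NA), mk(10 * pro_resid, 5 * (i / 10), NA),
                   10, i)
  })
  corr <- correlate_table(build_cohort_table(records))
  expect_true(corr$low_variance[corr$compartment == "prostate_bed"])
  expect_false(corr$low_variance[corr$compartment == "nodal"])
})

test_that("baseline burden-PSA correlation recovers a simulated association", {
  spec <- cohort_spec(n_patients = 120,
                      psa_link = psa_link_params(scale = 1, offset = 1,
                                                 exponent = 1, noise_sd = 0.2),
                      seed = 19)
  corr <- correlate_baseline(generate_cohort(spec))
  comp <- corr[corr$compartment == "composite", ]
  expect_false(comp$suppressed)
  expect_gt(comp$r, 0.5)
  expect_lt(comp$p_two_tailed, 0.001)
})
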