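test_that("percent change has the documented closed forms", {
  expect_equal(percent_change(50, 50), 0)
  expect_equal(percent_change(100, 0), -100)
  expect_equal(round_half_away(percent_change(48.7, 91.1)), 87)
  expect_equal(round_half_away(percent_change(69.72, 91.55)), 31)
  expect_true(is.na(percent_change(0, 0)))
  expect_error(percent_change(-1, 2), "non-negative")
})

test_that("forward and backward percent changes compose to identity", {
  set.seed(13)
  a <- stats::runif(20, 0.1, 100)
  b <- stats::runif(20, 0.1, 100)
  p1 <- percent_change(a, b)
  p2 <- percent_change(b, a)
  expect_equal((1 + p1 / 100) * (1 + p2 / 100), rep(1, 20), tolerance = 1e-12)
})

test_that("PSA percent decrease is positive for declines", {
  expect_equal(psa_percent_decrease(10, 0.1), 99)
  expect_equal(psa_percent_decrease(5, 5), 0)
  expect_equal(round_half_away(psa_percent_decrease(8, 2.48)), 69)
  expect_error(psa_percent_decrease(0, 1), "positive")
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_away(c(-99.5, -0.5, 0.5, 13.5, -13.5)),
               c(-100, -1, 1, 14, -14))
  expect_equal(round_half_away(28.12, 1), 28.1)
})

test_that("cohort table propagates missingness and flags new disease", {
  mk <- psmaquant:::make_compartment_scores
  records <- list(
    # no osseous baseline -> osseous cell missing
    patient_record(1, mk(20, 5, NA), mk(0, 0, NA), 10, 1),
    # osseous appears at follow-up over a missing baseline -> new disease
    patient_record(2, mk(20, NA, NA), mk(10, NA, 3), 10, 5),
    # no change anywhere -> all zeros
    patient_record(3, mk(10, 10, 10), mk(10, 10, 10), 4, 4))
  tab <- build_cohort_table(records)
  expect_true(is.na(tab$osseous_pct[1]))
  expect_false(tab$new_disease_osseous[1])
  expect_true(tab$new_disease_osseous[2])
  expect_true(is.na(tab$osseous_pct[2]))     # no percent for new disease
  expect_equal(unlist(tab[3, c("nodal_pct", "osseous_pct", "prostate_pct",
                               "composite_pct", "psa_pct")]),
               c(nodal_pct = 0, osseous_pct = 0, prostate_pct = 0,
                 composite_pct = 0, psa_pct = 0))
  # PSA sign convention: decline is negative in the table
  expect_equal(tab$psa_pct[1], -90)
})

test_that("noise-free simulated cohorts tie imaging and PSA exactly", {
  spec <- cohort_spec(
    n_patients = 25,
    compartment_prevalence = c(prostate_bed = 1, nodal = 1, osseous = 1),
    psa_link = psa_link_params(scale = 2, offset = 0, exponent = 1,
                               noise_sd = 0),
    seed = 31)
  tab <- build_cohort_table(generate_cohort(spec))
  expect_equal(tab$composite_pct, tab$psa_pct, tolerance = 1e-12)
})

test_that("cohort summary handles a single patient and all-missing columns", {
  mk <- psmaquant:::make_compartment_scores
  tab <- build_cohort_table(list(
    patient_record(1, mk(20, NA, NA), mk(5, NA, NA), 10, 2)))
  s <- summarize_cohort(tab)
  pro <- s[s$measure == "prostate_decline", ]
  expect_equal(pro$median, 75)
  expect_equal(pro$min, pro$max)            # degenerate range
  expect_true(is.na(s[s$measure == "nodal_decline", "median"]))
})

test_that("cohort response table CSV round-trips exactly", {
  fx <- load_paper_fixtures()
  f <- tempfile(fileext = ".csv")
  write_cohort_table_csv(fx$table2, f)
  back <- read_cohort_table_csv(f)
  expect_equal(as.data.frame(back), as.data.frame(fx$table2))
  expect_s3_class(back, "cohort_table")
})
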