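test_that("wald interval matches the hand-computed normal approximation", {
  # p +/- 1.96 * sqrt(p(1-p)/n) for 596/2711, worked out by hand:
  # p = 0.21984, se = 0.0079541, half-width = 0.015590
  est <- proportion_ci(596, 2711, method = "wald")
  expect_equal(est$point, 596 / 2711, tolerance = 1e-12)
  expect_equal(est$ci_low, 0.20425, tolerance = 1e-4)
  expect_equal(est$ci_high, 0.23543, tolerance = 1e-4)
})

test_that("wilson interval: boundary behavior and [0, 1] containment", {
  z <- proportion_ci(0, 10)
  expect_identical(z$point, 0)
  expect_identical(z$ci_low, 0)
  expect_gt(z$ci_high, 0)
  one <- proportion_ci(2711, 2711)
  expect_identical(one$point, 1)
  expect_identical(one$ci_high, 1)
  expect_lt(one$ci_low, 1)

  for (n in c(1, 7, 50, 1000)) {
    for (k in unique(round(c(0, n / 3, n / 2, n)))) {
      est <- proportion_ci(k, n)
      expect_gte(est$ci_low, 0)
      expect_lte(est$ci_high, 1)
      expect_lte(est$ci_low, est$point)
      expect_gte(est$ci_high, est$point)
    }
  }
  # width shrinks with the denominator at a fixed point estimate
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    est <- proportion_ci(n / 2, n)
    est$ci_high - est$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  expect_error(proportion_ci(3, 0), "denominator")
  expect_error(proportion_ci(5, 3), "exceeds")
})

test_that("median and quartiles follow the fixed interpolation convention", {
  expect_identical(median_iqr(c(1, 2, 3, 4, 5)),
                   c(median = 3, q1 = 2, q3 = 4))
  expect_identical(median_iqr(5), c(median = 5, q1 = 5, q3 = 5))
  # (n-1)p interpolation, worked out by hand for n = 4
  expect_identical(median_iqr(c(1, 2, 3, 4)),
                   c(median = 2.5, q1 = 1.75, q3 = 3.25))
  expect_error(median_iqr(numeric()), "non-empty")
})

test_that("display percentages are round-half-up of the exact fractions", {
  expect_identical(round_half_up(c(0.5, 1.5, 2.5, -0.5)), c(1, 2, 3, -1))
  corp <- generate_corpus(small_config(), seed = 21)
  tab <- tabulate_reasons(corp, "all_trials")
  expect_identical(tab$pct_outcomes,
                   round_half_up(100 * tab$frac_outcomes))
  expect_identical(tab$pct_trials, round_half_up(100 * tab$frac_trials))
})

test_that("the summary report aggregates review characteristics correctly", {
  pats <- lapply(1:5, function(i) {
    list(registered = TRUE,
         ann = list(O1 = ann_present(TRUE),
                    O2 = if (i <= 2) ann_missing(TRUE, planned = "yes")
                    else ann_present(TRUE)))
  })
  corp <- small_corpus(pats)
  rep <- summarize_corpus(corp, scenarios = "reporting_only")
  expect_identical(rep$review_stats$n_reviews, 1L)
  expect_identical(unname(rep$review_stats$trials_per_review), c(5, 5, 5))
  expect_identical(unname(rep$review_stats$outcomes_per_sof), c(2, 2, 2))
  expect_identical(rep$exclusion$n_excluded_any, 2L)
  expect_identical(rep$evaluable$n_evaluable, 2L)
  expect_identical(rep$waste$reporting_only$n_partial, 2L)
  # a summary regenerated from a round-tripped corpus is identical
  f <- withr::local_tempfile(fileext = ".json")
  write_corpus(corp, f)
  rep2 <- summarize_corpus(read_corpus(f), scenarios = "reporting_only")
  expect_equal(rep2, rep)
})

test_that("the outcome-status matrix export covers evaluable trials deterministically", {
  pats <- list(
    list(registered = TRUE,
         ann = list(O1 = ann_present(TRUE),
                    O2 = ann_missing(TRUE, planned = "yes"),
                    O3 = ann_missing(TRUE, planned = "no"))),
    list(ann = list(O1 = ann_present(), O2 = ann_present(),
                    O3 = ann_missing()))
  )
  jd <- expert_judgment("T01", "O3", "difficult", "easy", "no_cost", "major")
  corp <- small_corpus(pats, n_out = 3L, judgments = jd)
  m <- export_waste_matrix(corp, "reporting_only")
  expect_identical(nrow(m), 6L)  # 2 evaluable trials x 3 positions
  expect_identical(m$status[m$trial_id == "T01" & m$outcome_position == 1L],
                   "present")
  # the selectively reported outcome is avoidable under either scenario
  expect_identical(m$status[m$trial_id == "T01" & m$outcome_position == 2L],
                   "absent_avoidable")
  expect_identical(m$status[m$trial_id == "T01" & m$outcome_position == 3L],
                   "absent")
  expect_identical(m$status[m$trial_id == "T02" & m$outcome_position == 3L],
                   "absent")
  m2 <- export_waste_matrix(corp, "reporting_only")
  expect_identical(m, m2)
  # one distinct row block per evaluable trial
  expect_identical(unique(m$trial_id), c("T01", "T02"))
})
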