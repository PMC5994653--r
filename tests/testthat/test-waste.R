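ip_reason <- function() classify_missing_outcome(ann_missing(TRUE, planned = "no"), TRUE)
sr_reason <- function() classify_missing_outcome(ann_missing(TRUE, planned = "yes"), TRUE)
ir_reason <- function() classify_missing_outcome(ann_missing(FALSE, reported = TRUE), FALSE)
ind_reason <- function() classify_missing_outcome(ann_missing(FALSE), FALSE)
oth_reason <- function() {
  classify_missing_outcome(ann_missing(FALSE, reported = TRUE, zero_event = TRUE),
                           FALSE, "mortality")
}

jd <- function(ft = "easy", fp = "easy", cost = "no_cost", imp = "major") {
  expert_judgment("T1", "O1", ft, fp, cost, imp)
}

test_that("outcome avoidability follows the expert criteria per scenario", {
  # reporting failures are avoidable under either scenario
  for (sc in c("reporting_only", "reporting_plus_planning")) {
    expect_true(is_outcome_avoidable(sr_reason(), scenario = sc)$avoidable)
    expect_true(is_outcome_avoidable(ir_reason(), scenario = sc)$avoidable)
  }
  # inadequate planning: only in the planning scenario, and only when easy
  # for both perspectives, at no/minor cost, and of major importance
  expect_false(is_outcome_avoidable(ip_reason(), jd(),
                                    "reporting_only")$avoidable)
  expect_true(is_outcome_avoidable(ip_reason(), jd(),
                                   "reporting_plus_planning")$avoidable)
  expect_true(is_outcome_avoidable(ip_reason(), jd(cost = "minor"),
                                   "reporting_plus_planning")$avoidable)
  expect_false(is_outcome_avoidable(ip_reason(), jd(cost = "major"),
                                    "reporting_plus_planning")$avoidable)
  expect_false(is_outcome_avoidable(ip_reason(), jd(ft = "moderately_easy"),
                                    "reporting_plus_planning")$avoidable)
  expect_false(is_outcome_avoidable(ip_reason(), jd(fp = "difficult"),
                                    "reporting_plus_planning")$avoidable)
  expect_false(is_outcome_avoidable(ip_reason(), jd(imp = "non_major"),
                                    "reporting_plus_planning")$avoidable)
  # never avoidable
  expect_false(is_outcome_avoidable(ind_reason(),
                                    scenario = "reporting_plus_planning")$avoidable)
  expect_false(is_outcome_avoidable(oth_reason(),
                                    scenario = "reporting_plus_planning")$avoidable)
  # a planned-scenario planning outcome without a judgment is an error
  expect_error(is_outcome_avoidable(ip_reason(), NULL, "reporting_plus_planning"),
               "judgment required")
})

test_that("trial waste level: total requires every assessable outcome avoidable", {
  expect_identical(
    trial_waste_level(list(O1 = sr_reason(), O2 = ir_reason()),
                      scenario = "reporting_only"),
    "total")
  # INDISTINGUISHABLE is assessable but never avoidable: blocks total
  expect_identical(
    trial_waste_level(list(O1 = sr_reason(), O2 = ind_reason()),
                      scenario = "reporting_only"),
    "partial")
  # only OTHER outcomes -> nothing attributable
  expect_identical(
    trial_waste_level(list(O1 = oth_reason()), scenario = "reporting_only"),
    "none")
  # OTHER does not block total under the default policy, but does under "block"
  expect_identical(
    trial_waste_level(list(O1 = sr_reason(), O2 = oth_reason()),
                      scenario = "reporting_only"),
    "total")
  expect_identical(
    trial_waste_level(list(O1 = sr_reason(), O2 = oth_reason()),
                      scenario = "reporting_only", other_policy = "block"),
    "partial")
  # planning scenario flips an all-planning trial from none to total
  j <- jd()
  expect_identical(trial_waste_level(list(O1 = ip_reason()), j,
                                     "reporting_only"), "none")
  expect_identical(trial_waste_level(list(O1 = ip_reason()), j,
                                     "reporting_plus_planning"), "total")
  expect_error(trial_waste_level(list(), scenario = "reporting_only"),
               "non-empty")
})

test_that("corpus-level waste assessment equals the per-trial brute-force recount", {
  for (seed in 1:6) {
    corp <- generate_corpus(small_config(), seed = seed)
    if (length(select_evaluable_trials(corp)) == 0L) next
    for (sc in c("reporting_only", "reporting_plus_planning")) {
      got <- assess_waste(corp, sc)
      want <- oracle_waste(corp, sc)
      expect_identical(got$n_evaluable, want$n_evaluable)
      expect_identical(got$n_partial, as.integer(want$n_partial))
      expect_identical(got$n_total, as.integer(want$n_total))
    }
  }
})

test_that("scenario monotonicity: reporting-only avoidability is a subset of reporting-plus-planning", {
  for (seed in 7:12) {
    corp <- generate_corpus(small_config(), seed = seed)
    if (length(select_evaluable_trials(corp)) == 0L) next
    a <- assess_waste(corp, "reporting_only")
    b <- assess_waste(corp, "reporting_plus_planning")
    expect_lte(a$n_partial, b$n_partial)
    expect_lte(a$n_total, b$n_total)
    # per-outcome subset relation via the exported status matrix
    ma <- export_waste_matrix(corp, "reporting_only")
    mb <- export_waste_matrix(corp, "reporting_plus_planning")
    key <- function(m) paste(m$trial_id, m$outcome_position)
    av_a <- key(ma)[ma$status == "absent_avoidable"]
    av_b <- key(mb)[mb$status == "absent_avoidable"]
    expect_true(all(av_a %in% av_b))
    # total implies partial for every trial
    expect_true(all(b$per_trial$level[b$per_trial$level == "total"] %in%
                      c("total")))
    expect_identical(b$n_partial >= b$n_total, TRUE)
  }
})

test_that("a corpus with no avoidable outcomes yields zero partial and total", {
  corp <- small_corpus(list(
    list(ann = list(O1 = ann_present(), O2 = ann_missing()))
  ))
  w <- assess_waste(corp, "reporting_only")
  expect_identical(w$n_partial, 0L)
  expect_identical(w$n_total, 0L)
  expect_identical(w$n_evaluable, 1L)
})

test_that("judgments attached to non-planning pairs are ignored with a warning", {
  stray <- expert_judgment("T01", "O2", "easy", "easy", "no_cost", "major")
  corp <- small_corpus(list(
    list(registered = TRUE,
         ann = list(O1 = ann_present(TRUE),
                    O2 = ann_missing(TRUE, planned = "yes")))
  ), judgments = stray)
  expect_warning(w <- assess_waste(corp, "reporting_plus_planning"),
                 "ignored")
  expect_identical(w$n_partial, 1L)  # selective reporting still avoidable
})

test_that("a planning-scenario assessment without the required judgment errors", {
  corp <- small_corpus(list(
    list(registered = TRUE,
         ann = list(O1 = ann_present(TRUE),
                    O2 = ann_missing(TRUE, planned = "no")))
  ))
  expect_error(assess_waste(corp, "reporting_plus_planning"),
               "judgment required")
  # the reporting-only scenario needs no judgments
  expect_identical(assess_waste(corp, "reporting_only")$n_partial, 0L)
})
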