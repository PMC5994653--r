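test_that("eligibility filters remove reviews for the documented first failing reason", {
  base <- small_corpus(list(list(ann = list(O1 = ann_present()))), n_out = 1L)
  rv <- base$reviews[[1]]

  withdrawn <- rv; withdrawn$review_id <- "R2"; withdrawn$withdrawn <- TRUE
  withdrawn$trials[[1]]$trial_id <- "T91"
  observational <- rv; observational$review_id <- "R3"
  observational$includes_observational <- TRUE
  observational$trials[[1]]$trial_id <- "T92"
  old <- rv; old$review_id <- "R4"
  old$trials[[1]]$trial_id <- "T93"
  old$trials[[1]]$publication_year <- 2006L
  mixing <- rv; mixing$review_id <- "R5"; mixing$sof_mixes_interventions <- TRUE
  mixing$trials[[1]]$trial_id <- "T94"

  corp <- corpus(list(rv, withdrawn, observational, old, mixing))
  res <- filter_eligible_reviews(corp)
  expect_length(res$corpus$reviews, 1L)
  expect_identical(res$corpus$reviews[[1]]$review_id, "R1")
  log <- res$log
  expect_identical(log$reason[log$review_id == "R2"], "withdrawn")
  expect_identical(log$reason[log$review_id == "R3"], "includes_observational")
  expect_identical(log$reason[log$review_id == "R4"], "all_trials_before_min_year")
  expect_identical(log$reason[log$review_id == "R5"], "sof_mixes_interventions")

  # year threshold is a half-open lower bound: 2007 passes at threshold 2007
  boundary <- rv; boundary$trials[[1]]$publication_year <- 2007L
  expect_true(filter_eligible_reviews(corpus(list(boundary)))$log$eligible)

  # all criteria disabled -> identity
  res_none <- filter_eligible_reviews(corp, eligibility_none())
  expect_length(res_none$corpus$reviews, 5L)
  expect_true(all(res_none$log$eligible))
})

test_that("main-comparison selection: author flag, then outcomes, trials, position", {
  mk_cmp <- function(id, n_out, n_tri, main = FALSE) {
    comparison(id,
               sof_outcomes = lapply(sprintf("%s-O%d", id, seq_len(n_out)),
                                     sof_outcome, categories = "pain"),
               trial_ids = sprintf("%s-T%d", id, seq_len(n_tri)),
               author_designated_main = main)
  }
  # A: 5 outcomes / 10 trials beats B: 3 outcomes / 12 trials (outcomes first)
  rv <- review("R1", comparisons = list(mk_cmp("A", 5, 10), mk_cmp("B", 3, 12)))
  expect_identical(select_main_comparison(rv), "A")
  # author flag overrides the size rule
  rv2 <- review("R1", comparisons = list(mk_cmp("A", 5, 10),
                                         mk_cmp("B", 3, 12, main = TRUE)))
  expect_identical(select_main_comparison(rv2), "B")
  # ties on outcomes and trials -> first-listed
  rv3 <- review("R1", comparisons = list(mk_cmp("X", 4, 6), mk_cmp("Y", 4, 6)))
  expect_identical(select_main_comparison(rv3), "X")
  # outcome tie broken by trials
  rv4 <- review("R1", comparisons = list(mk_cmp("X", 4, 6), mk_cmp("Y", 4, 9)))
  expect_identical(select_main_comparison(rv4), "Y")
  expect_error(select_main_comparison(review("R9", comparisons = list())),
               "no comparisons")
})

test_that("contribution matrices are built cell by cell from meta-analysis membership", {
  corp1 <- small_corpus(list(list(ann = list(O1 = ann_present()))), n_out = 1L)
  cm1 <- build_contribution_matrix(corp1$reviews[[1]])
  expect_identical(dim(cm1$cells), c(1L, 1L))
  expect_true(cm1$cells[1, 1])

  # trial present in 3 of 4 outcome meta-analyses; one outcome empty for all
  pats <- lapply(1:5, function(i) {
    list(ann = list(O1 = ann_present(), O2 = ann_present(),
                    O3 = ann_present(), O4 = ann_missing()))
  })
  pats[[1]]$ann$O3 <- ann_missing()
  corp2 <- small_corpus(pats, n_out = 4L)
  cm2 <- build_contribution_matrix(corp2$reviews[[1]])
  expect_identical(unname(cm2$cells["T01", ]), c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(sum(cm2$cells["T02", ]), 3L)
  expect_identical(unname(colSums(cm2$cells)["O4"]), 0)
})

test_that("exclusion statistics match their definitions on simple corpora", {
  all_in <- small_corpus(lapply(1:3, function(i) {
    list(ann = list(O1 = ann_present(), O2 = ann_present()))
  }))
  es <- exclusion_stats(all_in)
  expect_identical(es$n_excluded_any, 0L)
  expect_identical(es$mean_contribution_fraction, 1)
  expect_identical(es$n_included_all + es$n_excluded_any, es$n_trials)

  half <- small_corpus(list(
    list(ann = list(O1 = ann_present(), O2 = ann_present(),
                    O3 = ann_missing(), O4 = ann_missing()))
  ), n_out = 4L)
  expect_identical(exclusion_stats(half)$mean_contribution_fraction, 0.5)

  expect_error(exclusion_stats(corpus(list())), "no eligible reviews")
})

test_that("exclusion statistics equal a pairwise brute-force recount on generated corpora", {
  for (seed in 1:5) {
    corp <- generate_corpus(small_config(), seed = seed)
    got <- exclusion_stats(corp)
    want <- oracle_exclusion(corp)
    expect_identical(got$n_trials, want$n_trials)
    expect_identical(got$n_included_all, as.integer(want$n_included_all))
    expect_identical(got$n_excluded_any, as.integer(want$n_excluded_any))
    expect_equal(got$mean_contribution_fraction, want$mean_contribution_fraction)
  }
})

test_that("statistics are invariant to trial and outcome order", {
  corp <- generate_corpus(small_config(), seed = 11)
  shuffled <- corp
  for (i in seq_along(shuffled$reviews)) {
    rv <- shuffled$reviews[[i]]
    rv$trials <- rev(rv$trials)
    for (k in seq_along(rv$comparisons)) {
      rv$comparisons[[k]]$sof_outcomes <- rev(rv$comparisons[[k]]$sof_outcomes)
      rv$comparisons[[k]]$meta_analyses <- rev(rv$comparisons[[k]]$meta_analyses)
    }
    shuffled$reviews[[i]] <- rv
  }
  a <- exclusion_stats(corp); b <- exclusion_stats(shuffled)
  expect_identical(a$n_included_all, b$n_included_all)
  expect_identical(a$n_excluded_any, b$n_excluded_any)
  expect_equal(a$mean_contribution_fraction, b$mean_contribution_fraction)
  expect_setequal(select_evaluable_trials(corp), select_evaluable_trials(shuffled))
})

test_that("adding a contribution never lowers the mean fraction or raises the excluded count", {
  corp <- generate_corpus(small_config(), seed = 3)
  before <- exclusion_stats(corp)
  # flip the first missing cell found into a contribution
  done <- FALSE
  for (i in seq_along(corp$reviews)) {
    rv <- corp$reviews[[i]]
    cp <- rv$comparisons[[1]]
    for (j in seq_along(rv$trials)) {
      tr <- rv$trials[[j]]
      for (oid in names(tr$annotations)) {
        if (!tr$annotations[[oid]]$in_meta_analysis && !done) {
          corp$reviews[[i]]$trials[[j]]$annotations[[oid]] <-
            ann_present(tr$registration_found)
          for (k in seq_along(cp$meta_analyses)) {
            if (cp$meta_analyses[[k]]$outcome_id == oid) {
              corp$reviews[[i]]$comparisons[[1]]$meta_analyses[[k]]$contributing_trial_ids <-
                sort(unique(c(cp$meta_analyses[[k]]$contributing_trial_ids,
                              tr$trial_id)))
            }
          }
          done <- TRUE
        }
      }
    }
  }
  expect_true(done)
  after <- exclusion_stats(corp)
  expect_gte(after$mean_contribution_fraction, before$mean_contribution_fraction)
  expect_lte(after$n_excluded_any, before$n_excluded_any)
})

test_that("evaluable-trial selection applies year, accessibility, and language cuts", {
  pats <- list(
    list(year = 2010L, ann = list(O1 = ann_present(), O2 = ann_missing())),
    list(year = 2009L, ann = list(O1 = ann_present(), O2 = ann_missing())),
    list(year = 2012L, accessible = FALSE,
         ann = list(O1 = ann_present(), O2 = ann_missing())),
    list(year = 2012L, language_ok = FALSE,
         ann = list(O1 = ann_present(), O2 = ann_missing())),
    list(year = 2012L, ann = list(O1 = ann_present(), O2 = ann_present()))
  )
  corp <- small_corpus(pats)
  expect_identical(select_evaluable_trials(corp), "T01")
  expect_setequal(select_evaluable_trials(corp, require_accessible = FALSE,
                                          require_language = FALSE),
                  c("T01", "T03", "T04"))
  expect_setequal(select_evaluable_trials(corp, min_year = 2009L),
                  c("T01", "T02"))
})
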