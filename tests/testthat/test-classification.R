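test_that("the decision tree reproduces the published category definitions", {
  # registered, planned, unreported -> selective reporting
  r <- classify_missing_outcome(ann_missing(TRUE, planned = "yes"), TRUE)
  expect_identical(r$category, "SELECTIVE_REPORTING")
  # unregistered, reported but unpoolable -> incomplete reporting
  r <- classify_missing_outcome(ann_missing(FALSE, reported = TRUE), FALSE)
  expect_identical(r$category, "INCOMPLETE_REPORTING")
  # unregistered, unreported, no planning evidence -> indistinguishable
  r <- classify_missing_outcome(ann_missing(FALSE), FALSE)
  expect_identical(r$category, "INDISTINGUISHABLE")
  # registered, unplanned, unreported -> inadequate planning
  r <- classify_missing_outcome(ann_missing(TRUE, planned = "no"), TRUE)
  expect_identical(r$category, "INADEQUATE_PLANNING")
  # unregistered but listed in the publication methods -> selective reporting
  r <- classify_missing_outcome(ann_missing(FALSE, pim = TRUE), FALSE)
  expect_identical(r$category, "SELECTIVE_REPORTING")
  # zero-event overrides planning evidence; subtype follows the category
  a <- ann_missing(TRUE, planned = "yes", reported = TRUE, zero_event = TRUE)
  expect_identical(classify_missing_outcome(a, TRUE, "mortality")$other_subtype,
                   "NO_EVENT")
  expect_identical(classify_missing_outcome(a, TRUE, "adverse_events")$other_subtype,
                   "NO_ADVERSE_EVENT")
  # reported in poolable form yet not pooled
  a <- ann_missing(FALSE, reported = TRUE, poolable = "yes", rnp = TRUE)
  expect_identical(classify_missing_outcome(a, FALSE)$other_subtype,
                   "REPORTED_NOT_POOLED")
})

test_that("the tree rejects contributing outcomes and inconsistent annotations", {
  expect_error(classify_missing_outcome(ann_present(), FALSE),
               "in_meta_analysis")
  # registered, unplanned, fully reported and poolable, yet flagged missing
  a <- ann_missing(TRUE, planned = "no", reported = TRUE, poolable = "yes")
  expect_error(classify_missing_outcome(a, TRUE), "inconsistent annotation")
})

test_that("exhaustive truth table: every admissible annotation reaches exactly the oracle's category", {
  grid <- admissible_annotations()
  expect_gt(nrow(grid), 30)
  for (adverse in c(FALSE, TRUE)) {
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      a <- outcome_annotation(FALSE, planned = g$planned,
                              planned_in_publication_methods = g$pim,
                              reported = g$reported, poolable = g$poolable,
                              zero_event = g$zero_event,
                              reported_not_pooled = g$rnp)
      want <- oracle_classify(g$registered, g$planned, g$pim, g$reported,
                              g$poolable, g$zero_event, g$rnp, adverse)
      cats <- if (adverse) "adverse_events" else "pain"
      if (want$category == "ERROR") {
        expect_error(classify_missing_outcome(a, g$registered, cats),
                     "inconsistent annotation")
      } else {
        got <- classify_missing_outcome(a, g$registered, cats)
        expect_identical(got$category, want$category)
        expect_identical(got$other_subtype, want$other_subtype)
      }
    }
  }
})

test_that("registered trials never yield INDISTINGUISHABLE", {
  grid <- admissible_annotations()
  grid <- grid[grid$registered, , drop = FALSE]
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    a <- outcome_annotation(FALSE, planned = g$planned,
                            planned_in_publication_methods = g$pim,
                            reported = g$reported, poolable = g$poolable,
                            zero_event = g$zero_event,
                            reported_not_pooled = g$rnp)
    got <- tryCatch(classify_missing_outcome(a, TRUE)$category,
                    error = function(e) "ERROR")
    expect_false(got == "INDISTINGUISHABLE")
  }
})

test_that("classify_trial maps exactly the missing cells", {
  tr <- trial_record("T1", 2012L, registration_found = TRUE, annotations = list(
    O1 = ann_present(TRUE), O2 = ann_missing(TRUE, planned = "no"),
    O3 = ann_missing(TRUE, planned = "yes"),
    O4 = ann_missing(TRUE, reported = TRUE), O5 = ann_present(TRUE)
  ))
  contributes <- c(O1 = TRUE, O2 = FALSE, O3 = FALSE, O4 = FALSE, O5 = TRUE)
  m <- classify_trial(tr, contributes)
  expect_setequal(names(m), c("O2", "O3", "O4"))
  expect_identical(m$O2$category, "INADEQUATE_PLANNING")
  expect_identical(m$O3$category, "SELECTIVE_REPORTING")
  expect_identical(m$O4$category, "INCOMPLETE_REPORTING")
  # fully included trial -> empty map
  expect_length(classify_trial(tr, c(O1 = TRUE, O2 = TRUE, O3 = TRUE,
                                     O4 = TRUE, O5 = TRUE)), 0L)
})

test_that("reason tables partition outcomes and cover trials", {
  # single trial, single missing outcome, selective reporting -> 100% there
  corp <- small_corpus(list(
    list(registered = TRUE,
         ann = list(O1 = ann_present(TRUE),
                    O2 = ann_missing(TRUE, planned = "yes")))
  ))
  tab <- tabulate_reasons(corp, "all_trials")
  expect_identical(tab$n_outcomes[tab$category == "SELECTIVE_REPORTING"], 1L)
  expect_identical(tab$pct_outcomes[tab$category == "SELECTIVE_REPORTING"], 100)
  expect_identical(sum(tab$n_outcomes), attr(tab, "n_missing_outcomes"))
  expect_true(all(tab$n_outcomes[tab$category != "SELECTIVE_REPORTING"] == 0L))

  # a multi-reason trial is counted in each of its trial-level rows
  corp2 <- small_corpus(list(
    list(registered = TRUE,
         ann = list(O1 = ann_missing(TRUE, planned = "no"),
                    O2 = ann_missing(TRUE, reported = TRUE)))
  ))
  tab2 <- tabulate_reasons(corp2, "registered_only")
  expect_identical(tab2$n_trials[tab2$category == "INADEQUATE_PLANNING"], 1L)
  expect_identical(tab2$n_trials[tab2$category == "INCOMPLETE_REPORTING"], 1L)
  expect_identical(sum(tab2$n_trials), 2L)  # coverage counts exceed the 1 trial
  expect_identical(attr(tab2, "n_trials_in_scope"), 1L)

  expect_error(tabulate_reasons(corp, "registered_only", min_year = 2050L),
               "no missing outcomes")
})

test_that("reason tables: the registered scope never contains INDISTINGUISHABLE, on generated corpora", {
  for (seed in c(5, 6)) {
    corp <- generate_corpus(small_config(), seed = seed)
    tab <- tryCatch(tabulate_reasons(corp, "registered_only"),
                    error = function(e) NULL)
    if (is.null(tab)) next
    expect_identical(tab$n_outcomes[tab$category == "INDISTINGUISHABLE"], 0L)
    # outcome-level counts are a partition of the missing outcomes in scope
    expect_identical(sum(tab$n_outcomes), attr(tab, "n_missing_outcomes"))
  }
})
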