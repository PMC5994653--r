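test_that("constructors reject values outside the domain model", {
  expect_error(sof_outcome("O1", categories = character()), "non-empty")
  expect_error(sof_outcome("O1", categories = "mortalty"), "admissible")
  expect_error(outcome_annotation(planned = "maybe"), "admissible")
  expect_error(expert_judgment("T1", "O1", "easy", "easy", "free", "major"),
               "admissible")
  expect_error(review("R1", comparisons = list(), intervention_type = "surgical"),
               "admissible")
})

test_that("the smallest valid corpus round-trips through JSON and CSV", {
  corp <- small_corpus(list(
    list(registered = FALSE, ann = list(O1 = ann_present()))
  ), n_out = 1L)
  expect_identical(nrow(validate_corpus(corp)), 0L)

  json <- withr::local_tempfile(fileext = ".json")
  write_corpus(corp, json, format = "json")
  back <- read_corpus(json, format = "json")
  expect_length(back$reviews, 1L)
  expect_length(back$reviews[[1]]$comparisons, 1L)
  expect_length(back$reviews[[1]]$comparisons[[1]]$sof_outcomes, 1L)
  expect_length(back$reviews[[1]]$trials, 1L)
  expect_true(corpus_identical(corp, back))

  dir <- withr::local_tempdir()
  files <- write_corpus(corp, dir, format = "csv_bundle")
  expect_setequal(basename(files),
                  c("reviews.csv", "comparisons.csv", "outcomes.csv",
                    "trials.csv", "annotations.csv", "judgments.csv"))
  back2 <- read_corpus(dir, format = "csv_bundle")
  expect_true(corpus_identical(corp, back2))
})

test_that("serialization is deterministic (byte-identical repeated writes)", {
  corp <- generate_corpus(small_config(), seed = 7)
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_corpus(corp, f1)
  write_corpus(corp, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("round-trip identity holds on generated corpora (both formats)", {
  for (seed in c(1, 2, 3)) {
    corp <- generate_corpus(small_config(), seed = seed)
    json <- withr::local_tempfile(fileext = ".json")
    write_corpus(corp, json)
    expect_true(corpus_identical(corp, read_corpus(json)))
    dir <- withr::local_tempdir()
    write_corpus(corp, dir, format = "csv_bundle")
    expect_true(corpus_identical(corp, read_corpus(dir, format = "csv_bundle")))
  }
})

test_that("reading an invalid corpus fails, naming the violated rule", {
  corp <- small_corpus(list(
    list(ann = list(O1 = outcome_annotation(FALSE, reported = FALSE,
                                            poolable = "yes")))
  ), n_out = 1L)
  f <- withr::local_tempfile(fileext = ".json")
  write_corpus(corp, f)
  expect_error(read_corpus(f), "unreported_not_poolable")
  expect_error(read_corpus(withr::local_tempfile(fileext = ".json")),
               "not found")
})

test_that("validate_corpus reports each seeded violation and none for valid corpora", {
  good <- small_corpus(list(
    list(registered = TRUE,
         ann = list(O1 = ann_present(TRUE), O2 = ann_missing(TRUE)))
  ))
  expect_identical(nrow(validate_corpus(good)), 0L)

  # annotation for an outcome absent from the main-comparison SoF list
  bad1 <- good
  bad1$reviews[[1]]$trials[[1]]$annotations$O3 <- ann_missing(TRUE)
  v1 <- validate_corpus(bad1)
  expect_true("annotations_cover_main_sof" %in% v1$rule)

  # registered trial with planned = unknown (tri-state rule)
  bad2 <- good
  bad2$reviews[[1]]$trials[[1]]$annotations$O2 <- ann_missing(FALSE)
  v2 <- validate_corpus(bad2)
  expect_true("planned_unknown_iff_unregistered" %in% v2$rule)

  # annotation disagreeing with meta-analysis membership
  bad3 <- good
  bad3$reviews[[1]]$trials[[1]]$annotations$O1 <-
    outcome_annotation(FALSE, planned = "yes", reported = TRUE,
                       poolable = "no")
  v3 <- validate_corpus(bad3)
  expect_true("annotation_matches_meta_analysis" %in% v3$rule)

  # every violation carries a record id, field, and rule
  expect_true(all(nzchar(v1$record_id)) && all(nzchar(v1$rule)))
})

test_that("validate_corpus catches structural violations", {
  good <- small_corpus(list(list(ann = list(O1 = ann_present()))), n_out = 1L)

  two_main <- good
  two_main$reviews[[1]]$comparisons[[2]] <-
    comparison("C2", sof_outcomes = list(sof_outcome("X1", "pain")),
               author_designated_main = TRUE)
  expect_true("single_main_flag" %in% validate_corpus(two_main)$rule)

  oversized <- good
  oversized$reviews[[1]]$comparisons[[1]]$sof_outcomes <-
    lapply(sprintf("O%d", 1:13), sof_outcome, categories = "pain")
  expect_true("sof_size_1_12" %in% validate_corpus(oversized)$rule)

  dangling <- good
  dangling$reviews[[1]]$comparisons[[1]]$meta_analyses[[1]]$contributing_trial_ids <-
    c("T01", "GHOST")
  expect_true("contributors_subset_trials" %in% validate_corpus(dangling)$rule)
})
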