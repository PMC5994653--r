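# Domain model for a corpus of systematic-review records: reviews hold
# comparisons (each with an ordered summary-of-findings outcome list and one
# meta-analysis per outcome) and trial records annotated, per important
# outcome, with the registration/planning/reporting evidence that drives the
# missing-outcome classification.

OUTCOME_CATEGORIES <- c(
  "mortality", "other_clinical_event", "therapeutic_decision", "function",
  "pain", "quality_of_life", "adverse_events", "physiological_variable",
  "biological_variable", "radiological_variable", "compliance", "process",
  "resource_use", "cost_effectiveness", "satisfaction_with_care"
)

REASON_CATEGORIES <- c(
  "INADEQUATE_PLANNING", "SELECTIVE_REPORTING", "INCOMPLETE_REPORTING",
  "INDISTINGUISHABLE", "OTHER"
)

OTHER_SUBTYPES <- c("none", "NO_EVENT", "NO_ADVERSE_EVENT", "REPORTED_NOT_POOLED")

FEASIBILITY_LEVELS <- c("easy", "moderately_easy", "difficult", "impossible")
COST_LEVELS <- c("no_cost", "minor", "moderate", "major")
IMPORTANCE_LEVELS <- c("major", "non_major")
PLANNED_LEVELS <- c("yes", "no", "unknown")
POOLABLE_LEVELS <- c("yes", "no", "not_applicable")
INTERVENTION_TYPES <- c("pharmacological", "non_pharmacological")

#' Admissible outcome categories
#'
#' The fifteen categories used to classify important (summary-of-findings)
#' outcomes: mortality, other clinical event, therapeutic decision, function,
#' pain, quality of life, adverse events, physiological / biological /
#' radiological variable, compliance, process, resource use,
#' cost-effectiveness, and satisfaction with care. An outcome may carry more
#' than one category.
#'
#' @return character vector of the 15 category labels
#' @export
outcome_categories <- function() OUTCOME_CATEGORIES

#' Missing-outcome reason categories
#'
#' @return character vector of the five reason categories
#' @export
reason_categories <- function() REASON_CATEGORIES

match_enum <- function(value, levels, field, record = NULL) {
  if (!is.character(value) || length(value) != 1L || is.na(value) ||
      !value %in% levels) {
    where <- if (is.null(record)) "" else sprintf(" in %s", record)
    stop(sprintf("invalid %s%s: %s (admissible: %s)",
                 field, where, paste(format(value), collapse = ", "),
                 paste(levels, collapse = ", ")),
         call. = FALSE)
  }
  value
}

#' Construct a per-(trial, outcome) evidence annotation
#'
#' Records what is known about one important outcome for one trial: whether
#' the trial contributes to the outcome's meta-analysis, whether the outcome
#' was planned according to a registry entry or protocol (`"unknown"` exactly
#' when no registration was found), whether it was listed in the
#' publication's methods section without registry evidence, whether any
#' result was reported, whether a reported result was poolable, and the two
#' special situations (outcome listed but no events; reported in poolable
#' form yet absent from the meta-analysis).
#'
#' @param in_meta_analysis does the trial contribute to this outcome's
#'   meta-analysis?
#' @param planned `"yes"`, `"no"`, or `"unknown"` (per registry/protocol)
#' @param planned_in_publication_methods outcome listed in the report's
#'   methods section without registry evidence
#' @param reported any result for the outcome appears in the trial reports
#' @param poolable `"yes"`, `"no"`, or `"not_applicable"` (the latter exactly
#'   when `reported` is `FALSE`)
#' @param zero_event outcome listed but no events occurred
#' @param reported_not_pooled reported in poolable form yet absent from the
#'   meta-analysis
#' @return an object of class `tw_annotation`
#' @export
outcome_annotation <- function(in_meta_analysis = FALSE,
                               planned = "unknown",
                               planned_in_publication_methods = FALSE,
                               reported = in_meta_analysis,
                               poolable = if (reported) "yes" else "not_applicable",
                               zero_event = FALSE,
                               reported_not_pooled = FALSE) {
  stopifnot(is_flag(in_meta_analysis), is_flag(planned_in_publication_methods),
            is_flag(reported), is_flag(zero_event), is_flag(reported_not_pooled))
  structure(
    list(
      in_meta_analysis = in_meta_analysis,
      planned = match_enum(planned, PLANNED_LEVELS, "planned"),
      planned_in_publication_methods = planned_in_publication_methods,
      reported = reported,
      poolable = match_enum(poolable, POOLABLE_LEVELS, "poolable"),
      zero_event = zero_event,
      reported_not_pooled = reported_not_pooled
    ),
    class = "tw_annotation"
  )
}

#' Construct a summary-of-findings outcome
#'
#' @param outcome_id opaque identifier, unique within its comparison
#' @param categories non-empty character vector of [outcome_categories()]
#' @param label free-text outcome label
#' @return an object of class `tw_outcome`
#' @export
sof_outcome <- function(outcome_id, categories, label = outcome_id) {
  stopifnot(is.character(outcome_id), length(outcome_id) == 1L)
  if (length(categories) == 0L) {
    stop(sprintf("outcome %s: categories must be non-empty", outcome_id),
         call. = FALSE)
  }
  for (cat in categories) match_enum(cat, OUTCOME_CATEGORIES, "outcome category",
                                     record = outcome_id)
  structure(
    list(outcome_id = outcome_id, label = label,
         categories = unique(as.character(categories))),
    class = "tw_outcome"
  )
}

#' Construct a meta-analysis record
#'
#' Links a summary-of-findings outcome to the set of trials contributing to
#' its pooled analysis; the set may be empty.
#'
#' @param outcome_id id of the outcome the meta-analysis addresses
#' @param contributing_trial_ids character vector of contributing trial ids
#' @return an object of class `tw_meta_analysis`
#' @export
meta_analysis <- function(outcome_id, contributing_trial_ids = character()) {
  structure(
    list(outcome_id = outcome_id,
         contributing_trial_ids = sort(unique(as.character(contributing_trial_ids)))),
    class = "tw_meta_analysis"
  )
}

#' Construct a comparison
#'
#' A comparison carries an ordered list of 1--12 summary-of-findings
#' outcomes, at most one meta-analysis per outcome, and the set of trials
#' available for the comparison (the union of all meta-analysis contributor
#' sets and any explicitly listed trials).
#'
#' @param comparison_id opaque identifier
#' @param sof_outcomes list of [sof_outcome()] objects (length 1--12)
#' @param meta_analyses list of [meta_analysis()] objects
#' @param trial_ids explicitly listed trial ids (in addition to contributors)
#' @param author_designated_main did the review authors flag this comparison
#'   as the main one?
#' @return an object of class `tw_comparison`
#' @export
comparison <- function(comparison_id, sof_outcomes, meta_analyses = list(),
                       trial_ids = character(),
                       author_designated_main = FALSE) {
  stopifnot(is.character(comparison_id), length(comparison_id) == 1L,
            is_flag(author_designated_main), is.list(sof_outcomes),
            is.list(meta_analyses))
  contributors <- unlist(lapply(meta_analyses, function(m) m$contributing_trial_ids))
  structure(
    list(
      comparison_id = comparison_id,
      author_designated_main = author_designated_main,
      sof_outcomes = sof_outcomes,
      meta_analyses = meta_analyses,
      trial_ids = sort(unique(c(as.character(trial_ids), contributors)))
    ),
    class = "tw_comparison"
  )
}

#' Construct a trial record
#'
#' @param trial_id opaque identifier, unique within the corpus
#' @param publication_year integer year (NA allowed, e.g. for records read
#'   from RevMan XML before manual annotation; NA never satisfies a
#'   minimum-year filter)
#' @param accessible is the trial report retrievable?
#' @param language_ok is the report in a readable language?
#' @param registration_found was a registration number or protocol retrieved?
#' @param annotations named list (by outcome id) of [outcome_annotation()]
#'   objects covering the summary-of-findings outcomes of the owning
#'   review's main comparison
#' @return an object of class `tw_trial`
#' @export
trial_record <- function(trial_id, publication_year = NA_integer_,
                         accessible = TRUE, language_ok = TRUE,
                         registration_found = FALSE, annotations = list()) {
  stopifnot(is.character(trial_id), length(trial_id) == 1L,
            is_flag(accessible), is_flag(language_ok),
            is_flag(registration_found))
  publication_year <- as.integer(publication_year)
  structure(
    list(trial_id = trial_id, publication_year = publication_year,
         accessible = accessible, language_ok = language_ok,
         registration_found = registration_found,
         annotations = annotations),
    class = "tw_trial"
  )
}

#' Construct a review
#'
#' @param review_id opaque identifier, unique within the corpus
#' @param comparisons non-empty list of [comparison()] objects; list order is
#'   meaningful (it breaks ties when selecting the main comparison)
#' @param trials list of [trial_record()] objects
#' @param review_group free-text topic label
#' @param intervention_type `"pharmacological"` or `"non_pharmacological"`
#' @param withdrawn was the review withdrawn?
#' @param includes_observational does the review include observational studies?
#' @param sof_mixes_interventions does the summary-of-findings table mix
#'   different interventions?
#' @return an object of class `tw_review`
#' @export
review <- function(review_id, comparisons, trials = list(),
                   review_group = "unspecified",
                   intervention_type = "pharmacological",
                   withdrawn = FALSE, includes_observational = FALSE,
                   sof_mixes_interventions = FALSE) {
  stopifnot(is.character(review_id), length(review_id) == 1L,
            is.list(comparisons), is.list(trials),
            is_flag(withdrawn), is_flag(includes_observational),
            is_flag(sof_mixes_interventions))
  structure(
    list(
      review_id = review_id,
      review_group = as.character(review_group),
      intervention_type = match_enum(intervention_type, INTERVENTION_TYPES,
                                     "intervention_type", record = review_id),
      withdrawn = withdrawn,
      includes_observational = includes_observational,
      sof_mixes_interventions = sof_mixes_interventions,
      comparisons = comparisons,
      trials = trials
    ),
    class = "tw_review"
  )
}

#' An empty expert-judgment table
#'
#' @return zero-row tibble with the judgment schema
#' @export
empty_judgments <- function() {
  tibble::tibble(
    trial_id = character(), outcome_id = character(),
    feasibility_trialist = character(), feasibility_patient = character(),
    cost = character(), importance = character()
  )
}

#' Construct one expert judgment row
#'
#' Expert judgments are inputs: the consensus of a panel on whether a missing
#' outcome classified as inadequately planned could have been measured. One
#' row per (trial, outcome) pair.
#'
#' @param trial_id,outcome_id references into the corpus
#' @param feasibility_trialist,feasibility_patient one of `"easy"`,
#'   `"moderately_easy"`, `"difficult"`, `"impossible"`
#' @param cost one of `"no_cost"` (<= 1\% of trial cost), `"minor"` (<= 5\%),
#'   `"moderate"` (5--15\%), `"major"` (>= 15\%)
#' @param importance `"major"` or `"non_major"`
#' @return one-row tibble with the judgment schema
#' @export
expert_judgment <- function(trial_id, outcome_id, feasibility_trialist,
                            feasibility_patient, cost, importance) {
  tibble::tibble(
    trial_id = trial_id, outcome_id = outcome_id,
    feasibility_trialist = match_enum(feasibility_trialist, FEASIBILITY_LEVELS,
                                      "feasibility_trialist"),
    feasibility_patient = match_enum(feasibility_patient, FEASIBILITY_LEVELS,
                                     "feasibility_patient"),
    cost = match_enum(cost, COST_LEVELS, "cost"),
    importance = match_enum(importance, IMPORTANCE_LEVELS, "importance")
  )
}

#' Construct a corpus
#'
#' The top-level container: a list of reviews plus a corpus-wide expert
#' judgment table.
#'
#' @param reviews list of [review()] objects
#' @param judgments tibble with the [expert_judgment()] schema
#' @param schema_version interchange schema version (currently `"1"`)
#' @return an object of class `tw_corpus`
#' @export
corpus <- function(reviews, judgments = empty_judgments(),
                   schema_version = "1") {
  stopifnot(is.list(reviews), is.data.frame(judgments))
  structure(
    list(schema_version = as.character(schema_version),
         reviews = reviews, judgments = tibble::as_tibble(judgments)),
    class = "tw_corpus"
  )
}

#' @export
print.tw_corpus <- function(x, ...) {
  n_rev <- length(x$reviews)
  n_tri <- sum(vapply(x$reviews, function(r) length(r$trials), integer(1)))
  cat(sprintf("<tw_corpus> %d review(s), %d trial(s), %d expert judgment(s)\n",
              n_rev, n_tri, nrow(x$judgments)))
  invisible(x)
}

#' @export
print.tw_review <- function(x, ...) {
  cat(sprintf("<tw_review> %s: %d comparison(s), %d trial(s)\n",
              x$review_id, length(x$comparisons), length(x$trials)))
  invisible(x)
}

# ---- validation --------------------------------------------------------

#' Validate a corpus against the model invariants
#'
#' Checks every structural invariant of the domain model and returns the
#' violations as data rather than raising: unknown enum values, comparison
#' sizes, meta-analysis linkage, the annotation consistency rules
#' (`registration_found = FALSE` iff `planned = "unknown"`; an unreported
#' outcome cannot be poolable, zero-event, or reported-not-pooled; a
#' contributing outcome must be reported and poolable), coverage of the main
#' comparison's outcomes by every trial's annotation map, agreement between
#' annotations and meta-analysis membership, id uniqueness, and referential
#' integrity of the judgment table.
#'
#' @param corpus a [corpus()] object
#' @return tibble with columns `record_id`, `field`, `rule`, `message`;
#'   zero rows iff the corpus is valid
#' @export
validate_corpus <- function(corpus) {
  violations <- list()
  add <- function(record_id, field, rule, message) {
    violations[[length(violations) + 1L]] <<- tibble::tibble(
      record_id = record_id, field = field, rule = rule, message = message
    )
  }

  if (!inherits(corpus, "tw_corpus")) {
    stop("validate_corpus() expects a tw_corpus object", call. = FALSE)
  }

  review_ids <- vapply(corpus$reviews, function(r) r$review_id, character(1))
  if (anyDuplicated(review_ids)) {
    dup <- unique(review_ids[duplicated(review_ids)])
    add(dup[1], "review_id", "unique_review_ids",
        sprintf("duplicated review id(s): %s", paste(dup, collapse = ", ")))
  }

  all_trial_ids <- character()

  for (rv in corpus$reviews) {
    rid <- rv$review_id
    if (length(rv$comparisons) == 0L) {
      add(rid, "comparisons", "nonempty_comparisons",
          sprintf("review %s has no comparisons", rid))
      next
    }
    n_main <- sum(vapply(rv$comparisons, function(cp) isTRUE(cp$author_designated_main),
                         logical(1)))
    if (n_main > 1L) {
      add(rid, "author_designated_main", "single_main_flag",
          sprintf("review %s flags %d comparisons as main", rid, n_main))
    }

    for (cp in rv$comparisons) {
      cid <- cp$comparison_id
      n_out <- length(cp$sof_outcomes)
      if (n_out < 1L || n_out > 12L) {
        add(cid, "sof_outcomes", "sof_size_1_12",
            sprintf("comparison %s has %d SoF outcomes (must be 1-12)", cid, n_out))
      }
      out_ids <- vapply(cp$sof_outcomes, function(o) o$outcome_id, character(1))
      if (anyDuplicated(out_ids)) {
        add(cid, "outcome_id", "unique_outcome_ids",
            sprintf("comparison %s has duplicated outcome ids", cid))
      }
      for (o in cp$sof_outcomes) {
        if (length(o$categories) == 0L ||
            !all(o$categories %in% OUTCOME_CATEGORIES)) {
          add(o$outcome_id, "categories", "admissible_categories",
              sprintf("outcome %s has empty or unknown categories", o$outcome_id))
        }
      }
      ma_out <- vapply(cp$meta_analyses, function(m) m$outcome_id, character(1))
      if (anyDuplicated(ma_out)) {
        add(cid, "meta_analyses", "one_ma_per_outcome",
            sprintf("comparison %s has more than one meta-analysis for an outcome", cid))
      }
      for (m in cp$meta_analyses) {
        if (!m$outcome_id %in% out_ids) {
          add(cid, "meta_analyses", "ma_outcome_in_sof",
              sprintf("comparison %s: meta-analysis outcome %s not in SoF list",
                      cid, m$outcome_id))
        }
        stray <- setdiff(m$contributing_trial_ids, cp$trial_ids)
        if (length(stray)) {
          add(cid, "contributing_trial_ids", "contributors_subset_trials",
              sprintf("comparison %s: contributors not in comparison trials: %s",
                      cid, paste(stray, collapse = ", ")))
        }
      }
    }

    main <- tryCatch(select_main_comparison(rv), error = function(e) NULL)
    main_cp <- if (!is.null(main)) {
      rv$comparisons[[which(vapply(rv$comparisons,
                                   function(cp) cp$comparison_id == main,
                                   logical(1)))[1]]]
    } else NULL
    main_out_ids <- if (!is.null(main_cp)) {
      vapply(main_cp$sof_outcomes, function(o) o$outcome_id, character(1))
    } else character()
    ma_index <- if (!is.null(main_cp)) {
      stats::setNames(main_cp$meta_analyses,
                      vapply(main_cp$meta_analyses, function(m) m$outcome_id,
                             character(1)))
    } else list()

    trial_ids <- vapply(rv$trials, function(t) t$trial_id, character(1))
    all_trial_ids <- c(all_trial_ids, trial_ids)

    for (tr in rv$trials) {
      tid <- tr$trial_id
      ann_ids <- names(tr$annotations)
      if (!is.null(main_cp) &&
          !setequal(ann_ids %||% character(), main_out_ids)) {
        add(tid, "annotations", "annotations_cover_main_sof",
            sprintf("trial %s annotations do not cover exactly the main-comparison outcomes of review %s",
                    tid, rid))
      }
      for (oid in ann_ids) {
        a <- tr$annotations[[oid]]
        rec <- sprintf("%s/%s", tid, oid)
        if (tr$registration_found != (a$planned != "unknown")) {
          add(rec, "planned", "planned_unknown_iff_unregistered",
              sprintf("%s: planned='%s' but registration_found=%s",
                      rec, a$planned, tr$registration_found))
        }
        if (!a$reported) {
          if (a$poolable != "not_applicable") {
            add(rec, "poolable", "unreported_not_poolable",
                sprintf("%s: reported=FALSE requires poolable='not_applicable'", rec))
          }
          if (a$zero_event) {
            add(rec, "zero_event", "unreported_no_zero_event",
                sprintf("%s: reported=FALSE forbids zero_event=TRUE", rec))
          }
          if (a$reported_not_pooled) {
            add(rec, "reported_not_pooled", "unreported_not_rnp",
                sprintf("%s: reported=FALSE forbids reported_not_pooled=TRUE", rec))
          }
        } else if (a$poolable == "not_applicable") {
          add(rec, "poolable", "reported_poolable_known",
              sprintf("%s: reported=TRUE requires poolable 'yes' or 'no'", rec))
        }
        if (a$reported_not_pooled && a$reported && a$poolable != "yes") {
          add(rec, "reported_not_pooled", "rnp_requires_poolable",
              sprintf("%s: reported_not_pooled=TRUE requires poolable='yes'", rec))
        }
        if (a$in_meta_analysis && !(a$reported && a$poolable == "yes")) {
          add(rec, "in_meta_analysis", "in_meta_requires_poolable_report",
              sprintf("%s: in_meta_analysis=TRUE requires reported=TRUE and poolable='yes'",
                      rec))
        }
        if (oid %in% main_out_ids) {
          m <- ma_index[[oid]]
          in_set <- !is.null(m) && tid %in% m$contributing_trial_ids
          if (a$in_meta_analysis != in_set) {
            add(rec, "in_meta_analysis", "annotation_matches_meta_analysis",
                sprintf("%s: annotation in_meta_analysis=%s but meta-analysis membership=%s",
                        rec, a$in_meta_analysis, in_set))
          }
        }
      }
    }
  }

  if (anyDuplicated(all_trial_ids)) {
    dup <- unique(all_trial_ids[duplicated(all_trial_ids)])
    add(dup[1], "trial_id", "unique_trial_ids",
        sprintf("duplicated trial id(s): %s", paste(dup, collapse = ", ")))
  }

  if (nrow(corpus$judgments)) {
    known <- unique(all_trial_ids)
    bad <- setdiff(unique(corpus$judgments$trial_id), known)
    if (length(bad)) {
      add(bad[1], "trial_id", "judgment_trial_exists",
          sprintf("judgments reference unknown trial id(s): %s",
                  paste(bad, collapse = ", ")))
    }
    key <- paste(corpus$judgments$trial_id, corpus$judgments$outcome_id)
    if (anyDuplicated(key)) {
      add(key[duplicated(key)][1], "trial_id/outcome_id", "one_judgment_per_pair",
          "more than one judgment for the same (trial, outcome) pair")
    }
  }

  if (length(violations) == 0L) {
    return(tibble::tibble(record_id = character(), field = character(),
                          rule = character(), message = character()))
  }
  dplyr::bind_rows(violations)
}
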