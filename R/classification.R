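# Step 2 of the audit: a deterministic decision tree assigning each missing
# (trial, outcome) pair to one of five reason categories, and Table-2-style
# tabulation at the outcome and trial level.

new_reason <- function(category, other_subtype = "none") {
  structure(list(category = category, other_subtype = other_subtype),
            class = "tw_reason")
}

#' @export
print.tw_reason <- function(x, ...) {
  sub <- if (x$other_subtype == "none") "" else sprintf(" / %s", x$other_subtype)
  cat(sprintf("<tw_reason> %s%s\n", x$category, sub))
  invisible(x)
}

#' Classify the reason one outcome is missing from a meta-analysis
#'
#' Deterministic decision tree over the evidence annotation, evaluated in a
#' fixed order. The two special situations are checked first because they
#' apply regardless of planning evidence: an outcome listed with zero events
#' (`OTHER/NO_EVENT`, or `OTHER/NO_ADVERSE_EVENT` when the outcome is an
#' adverse-events outcome), and an outcome reported in poolable form yet
#' absent from the meta-analysis (`OTHER/REPORTED_NOT_POOLED`). Then:
#' a registered trial whose outcome was neither planned nor reported is
#' `INADEQUATE_PLANNING`; a planned (per registry/protocol, or listed in the
#' publication methods when unregistered) but unreported outcome is
#' `SELECTIVE_REPORTING`; a reported but unpoolable outcome is
#' `INCOMPLETE_REPORTING`; and an unregistered, unreported outcome with no
#' planning evidence is `INDISTINGUISHABLE`. Any remaining combination
#' (e.g. registered, unplanned, yet fully reported and poolable without
#' being flagged reported-not-pooled) is an inconsistent annotation and
#' raises an error.
#'
#' @param annotation an [outcome_annotation()] with
#'   `in_meta_analysis = FALSE`
#' @param registration_found was a registration or protocol retrieved for
#'   the trial?
#' @param categories character vector of the outcome's categories (used only
#'   to distinguish the zero-event subtypes)
#' @return an object of class `tw_reason` with elements `category` and
#'   `other_subtype`
#' @export
classify_missing_outcome <- function(annotation, registration_found,
                                     categories = character()) {
  stopifnot(inherits(annotation, "tw_annotation"), is_flag(registration_found))
  a <- annotation
  if (a$in_meta_analysis) {
    stop("classify_missing_outcome() requires in_meta_analysis = FALSE",
         call. = FALSE)
  }
  if (a$zero_event) {
    sub <- if ("adverse_events" %in% categories) "NO_ADVERSE_EVENT" else "NO_EVENT"
    return(new_reason("OTHER", sub))
  }
  if (a$reported_not_pooled) {
    return(new_reason("OTHER", "REPORTED_NOT_POOLED"))
  }
  if (registration_found && a$planned == "no" && !a$reported) {
    return(new_reason("INADEQUATE_PLANNING"))
  }
  if ((registration_found && a$planned == "yes" && !a$reported) ||
      (!registration_found && a$planned_in_publication_methods && !a$reported)) {
    return(new_reason("SELECTIVE_REPORTING"))
  }
  if (a$reported && a$poolable == "no") {
    return(new_reason("INCOMPLETE_REPORTING"))
  }
  if (!registration_found && !a$reported && !a$planned_in_publication_methods) {
    return(new_reason("INDISTINGUISHABLE"))
  }
  stop(sprintf(
    paste0("inconsistent annotation: registration_found=%s, planned=%s, ",
           "planned_in_publication_methods=%s, reported=%s, poolable=%s ",
           "does not correspond to any missing-outcome reason"),
    registration_found, a$planned, a$planned_in_publication_methods,
    a$reported, a$poolable), call. = FALSE)
}

#' Classify every missing outcome of one trial
#'
#' @param trial a [trial_record()]
#' @param contributes named logical vector (by outcome id) giving the
#'   trial's contribution-matrix row
#' @param sof_outcomes optional list of [sof_outcome()] objects supplying
#'   outcome categories (for the zero-event subtypes)
#' @return named list (by outcome id) of `tw_reason` objects, one entry per
#'   `FALSE` cell of the row; contributing outcomes are absent from the map
#' @export
classify_trial <- function(trial, contributes, sof_outcomes = NULL) {
  stopifnot(inherits(trial, "tw_trial"), is.logical(contributes),
            !is.null(names(contributes)))
  cat_index <- list()
  for (o in sof_outcomes %||% list()) cat_index[[o$outcome_id]] <- o$categories
  out <- list()
  for (oid in names(contributes)[!contributes]) {
    a <- trial$annotations[[oid]]
    if (is.null(a)) {
      stop(sprintf("trial %s has no annotation for outcome %s",
                   trial$trial_id, oid), call. = FALSE)
    }
    out[[oid]] <- classify_missing_outcome(
      a, trial$registration_found,
      categories = cat_index[[oid]] %||% character()
    )
  }
  out
}

#' Classify all missing outcomes of the evaluable trials of a corpus
#'
#' Runs the extraction step (main-comparison contribution matrices and
#' evaluable-trial selection) and applies [classify_missing_outcome()] to
#' every missing (trial, outcome) pair of every evaluable trial.
#'
#' @param corpus a [corpus()] (already filtered for eligibility)
#' @inheritParams select_evaluable_trials
#' @return tibble with one row per missing (trial, outcome) pair:
#'   `review_id`, `trial_id`, `outcome_id`, `outcome_position`,
#'   `registration_found`, `category`, `other_subtype`
#' @export
classify_corpus <- function(corpus, min_year = 2010L,
                            require_accessible = TRUE,
                            require_language = TRUE) {
  evaluable <- select_evaluable_trials(corpus, min_year, require_accessible,
                                       require_language)
  rows <- list()
  for (rv in corpus$reviews) {
    cm <- build_contribution_matrix(rv)
    ids <- intersect(cm$trial_ids, evaluable)
    if (length(ids) == 0L) next
    cp <- get_comparison(rv, cm$comparison_id)
    trials <- stats::setNames(rv$trials,
                              vapply(rv$trials, function(t) t$trial_id,
                                     character(1)))
    for (tid in ids) {
      contributes <- cm$cells[tid, ]
      names(contributes) <- cm$outcome_ids
      reasons <- classify_trial(trials[[tid]], contributes,
                                sof_outcomes = cp$sof_outcomes)
      if (length(reasons) == 0L) next
      pos <- match(names(reasons), cm$outcome_ids)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        review_id = rv$review_id,
        trial_id = tid,
        outcome_id = names(reasons),
        outcome_position = pos,
        registration_found = trials[[tid]]$registration_found,
        category = vapply(reasons, function(r) r$category, character(1)),
        other_subtype = vapply(reasons, function(r) r$other_subtype, character(1))
      )
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(
      review_id = character(), trial_id = character(), outcome_id = character(),
      outcome_position = integer(), registration_found = logical(),
      category = character(), other_subtype = character()
    ))
  }
  dplyr::bind_rows(rows)
}

#' Tabulate missing-outcome reasons (Table-2 layout)
#'
#' Counts missing outcomes and affected trials per reason category, with
#' exact fractions and display percentages (rounded half-up to integers).
#' Outcome-level counts partition the missing outcomes in scope; trial-level
#' counts are coverage counts (a trial is counted in every category it has
#' at least one outcome in), so they can sum to more than the trial total.
#'
#' @param corpus a [corpus()] (already filtered for eligibility)
#' @param scope `"all_trials"` or `"registered_only"`
#' @inheritParams select_evaluable_trials
#' @return an object of class `tw_reason_table`: a tibble with one row per
#'   reason category (`category`, `n_outcomes`, `frac_outcomes`,
#'   `pct_outcomes`, `n_trials`, `frac_trials`, `pct_trials`), with the
#'   denominators in attributes `n_missing_outcomes` and `n_trials_in_scope`
#' @export
tabulate_reasons <- function(corpus, scope = c("all_trials", "registered_only"),
                             min_year = 2010L, require_accessible = TRUE,
                             require_language = TRUE) {
  scope <- match.arg(scope)
  cls <- classify_corpus(corpus, min_year, require_accessible, require_language)
  if (scope == "registered_only") {
    cls <- cls[cls$registration_found, , drop = FALSE]
  }
  if (nrow(cls) == 0L) {
    stop(sprintf("no missing outcomes in scope '%s'", scope), call. = FALSE)
  }
  denom_outcomes <- nrow(cls)
  denom_trials <- length(unique(cls$trial_id))
  tab <- lapply(REASON_CATEGORIES, function(cat) {
    sub <- cls[cls$category == cat, , drop = FALSE]
    n_out <- nrow(sub)
    n_tri <- length(unique(sub$trial_id))
    tibble::tibble(
      category = cat,
      n_outcomes = n_out,
      frac_outcomes = n_out / denom_outcomes,
      pct_outcomes = round_half_up(pct_exact(n_out, denom_outcomes)),
      n_trials = n_tri,
      frac_trials = n_tri / denom_trials,
      pct_trials = round_half_up(pct_exact(n_tri, denom_trials))
    )
  })
  out <- dplyr::bind_rows(tab)
  attr(out, "scope") <- scope
  attr(out, "n_missing_outcomes") <- denom_outcomes
  attr(out, "n_trials_in_scope") <- denom_trials
  class(out) <- c("tw_reason_table", class(out))
  out
}

#' @export
print.tw_reason_table <- function(x, ...) {
  cat(sprintf("Reasons for missing outcomes - scope: %s\n", attr(x, "scope")))
  cat(sprintf("  missing outcomes N = %d, trials N = %d\n",
              attr(x, "n_missing_outcomes"), attr(x, "n_trials_in_scope")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-22s %4d (%2.0f%%) outcomes in %4d (%2.0f%%) trials\n",
                x$category[i], x$n_outcomes[i], x$pct_outcomes[i],
                x$n_trials[i], x$pct_trials[i]))
  }
  invisible(x)
}
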