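# Step 3 of the audit: which missing outcomes represent avoidable waste, and
# at the trial level whether waste was partially or totally avoidable.
#
# Two scenarios: "reporting_only" counts selective and incomplete reporting
# as avoidable; "reporting_plus_planning" additionally admits inadequately
# planned outcomes that the expert panel judged easy to measure from both
# the trialist and patient perspective, at no or minor additional cost, and
# of major (critical) importance.

WASTE_SCENARIOS <- c("reporting_only", "reporting_plus_planning")

#' Is one missing outcome avoidable waste?
#'
#' @param reason a `tw_reason` from [classify_missing_outcome()]
#' @param judgment one-row data frame with the [expert_judgment()] columns,
#'   or `NULL`; required when `reason` is `INADEQUATE_PLANNING` and the
#'   scenario includes planning
#' @param scenario `"reporting_only"` or `"reporting_plus_planning"`
#' @return list with `avoidable` (logical) and `rationale` (short code:
#'   `"reporting"`, `"planning_feasible"`, `"planning_criteria_not_met"`,
#'   `"planning_not_in_scenario"`, or `"not_attributable"`)
#' @export
is_outcome_avoidable <- function(reason, judgment = NULL,
                                 scenario = WASTE_SCENARIOS) {
  scenario <- match.arg(scenario)
  stopifnot(inherits(reason, "tw_reason"))
  cat <- reason$category
  if (cat %in% c("SELECTIVE_REPORTING", "INCOMPLETE_REPORTING")) {
    return(list(avoidable = TRUE, rationale = "reporting"))
  }
  if (cat == "INADEQUATE_PLANNING") {
    if (scenario == "reporting_only") {
      return(list(avoidable = FALSE, rationale = "planning_not_in_scenario"))
    }
    if (is.null(judgment) || nrow(judgment) == 0L) {
      stop("expert judgment required for an inadequately planned outcome under reporting_plus_planning",
           call. = FALSE)
    }
    ok <- judgment$feasibility_trialist == "easy" &&
      judgment$feasibility_patient == "easy" &&
      judgment$cost %in% c("no_cost", "minor") &&
      judgment$importance == "major"
    return(list(avoidable = ok,
                rationale = if (ok) "planning_feasible" else "planning_criteria_not_met"))
  }
  # INDISTINGUISHABLE and OTHER are never avoidable
  list(avoidable = FALSE, rationale = "not_attributable")
}

#' Avoidable-waste level of one trial
#'
#' The assessable set is the trial's missing outcomes excluding the `OTHER`
#' category under the default policy (`other_policy = "exclude"`: zero-event
#' outcomes and data already available do not represent trialist-attributable
#' waste); with `other_policy = "block"` they stay in the assessable set as
#' never-avoidable, so their presence blocks a `"total"` verdict. Waste is
#' `"partial"` when at least one assessable missing outcome is avoidable and
#' `"total"` when the assessable set is non-empty and every assessable
#' outcome is avoidable (`INDISTINGUISHABLE` outcomes are assessable but
#' never avoidable, so they block `"total"` under either policy).
#'
#' @param reasons non-empty named list (by outcome id) of `tw_reason`
#' @param judgments data frame of [expert_judgment()] rows for this trial
#'   (matched by `outcome_id`), or `NULL`
#' @param scenario `"reporting_only"` or `"reporting_plus_planning"`
#' @param other_policy `"exclude"` or `"block"`
#' @return one of `"none"`, `"partial"`, `"total"`
#' @export
trial_waste_level <- function(reasons, judgments = NULL,
                              scenario = WASTE_SCENARIOS,
                              other_policy = c("exclude", "block")) {
  scenario <- match.arg(scenario)
  other_policy <- match.arg(other_policy)
  if (length(reasons) == 0L) {
    stop("trial_waste_level() requires a non-empty reason map", call. = FALSE)
  }
  cats <- vapply(reasons, function(r) r$category, character(1))
  assessable <- if (other_policy == "exclude") names(reasons)[cats != "OTHER"]
  else names(reasons)
  if (length(assessable) == 0L) return("none")
  avoidable <- vapply(assessable, function(oid) {
    j <- NULL
    if (!is.null(judgments) && nrow(judgments)) {
      j <- judgments[judgments$outcome_id == oid, , drop = FALSE]
      if (nrow(j) == 0L) j <- NULL
    }
    is_outcome_avoidable(reasons[[oid]], j, scenario)$avoidable
  }, logical(1))
  if (all(avoidable)) "total" else if (any(avoidable)) "partial" else "none"
}

#' Assess avoidable waste over a corpus
#'
#' Classifies every evaluable trial's missing outcomes, applies the
#' avoidability criterion under the given scenario, and summarizes the
#' partial/total avoidable-waste counts over the evaluable trials. The
#' partial count includes totally avoidable trials (total is a subset of
#' partial).
#'
#' @param corpus a [corpus()] (already filtered for eligibility); expert
#'   judgments are taken from `corpus$judgments`. Judgments attached to
#'   pairs not classified as inadequate planning are ignored with a warning.
#' @inheritParams trial_waste_level
#' @inheritParams select_evaluable_trials
#' @return an object of class `tw_waste_summary`: a list with counts
#'   (`n_evaluable`, `n_partial`, `n_total`), exact fractions, display
#'   percentages, and a `per_trial` tibble (`trial_id`, `level`,
#'   `n_missing`, `n_assessable`, `n_avoidable`)
#' @export
assess_waste <- function(corpus, scenario = WASTE_SCENARIOS,
                         other_policy = c("exclude", "block"),
                         min_year = 2010L, require_accessible = TRUE,
                         require_language = TRUE) {
  scenario <- match.arg(scenario)
  other_policy <- match.arg(other_policy)
  cls <- classify_corpus(corpus, min_year, require_accessible, require_language)
  if (nrow(cls) == 0L) stop("no evaluable trials with missing outcomes", call. = FALSE)

  jd <- corpus$judgments
  if (nrow(jd)) {
    key_cls <- paste(cls$trial_id, cls$outcome_id)
    key_ip <- key_cls[cls$category == "INADEQUATE_PLANNING"]
    stray <- !(paste(jd$trial_id, jd$outcome_id) %in% key_ip)
    # judgments on non-evaluable trials are simply out of scope here; warn
    # only about judgments contradicting a classified pair's category
    contradicted <- stray & (paste(jd$trial_id, jd$outcome_id) %in% key_cls)
    if (any(contradicted)) {
      warning(sprintf(
        "%d expert judgment(s) attached to pairs not classified as inadequate planning were ignored",
        sum(contradicted)), call. = FALSE)
    }
  }

  trial_ids <- unique(cls$trial_id)
  rows <- lapply(trial_ids, function(tid) {
    sub <- cls[cls$trial_id == tid, , drop = FALSE]
    reasons <- stats::setNames(
      lapply(seq_len(nrow(sub)),
             function(i) new_reason(sub$category[i], sub$other_subtype[i])),
      sub$outcome_id
    )
    j <- jd[jd$trial_id == tid, , drop = FALSE]
    cats <- sub$category
    assessable <- if (other_policy == "exclude") sum(cats != "OTHER") else length(cats)
    avoidable <- sum(vapply(sub$outcome_id[cats != "OTHER" | other_policy == "block"],
      function(oid) {
        ji <- j[j$outcome_id == oid, , drop = FALSE]
        if (nrow(ji) == 0L) ji <- NULL
        is_outcome_avoidable(reasons[[oid]], ji, scenario)$avoidable
      }, logical(1)))
    tibble::tibble(
      trial_id = tid,
      level = trial_waste_level(reasons, j, scenario, other_policy),
      n_missing = nrow(sub),
      n_assessable = assessable,
      n_avoidable = avoidable
    )
  })
  per_trial <- dplyr::bind_rows(rows)
  n_eval <- nrow(per_trial)
  n_total <- sum(per_trial$level == "total")
  n_partial <- sum(per_trial$level %in% c("partial", "total"))
  structure(
    list(
      scenario = scenario, other_policy = other_policy,
      n_evaluable = n_eval, n_partial = n_partial, n_total = n_total,
      frac_partial = n_partial / n_eval, frac_total = n_total / n_eval,
      pct_partial = round_half_up(pct_exact(n_partial, n_eval)),
      pct_total = round_half_up(pct_exact(n_total, n_eval)),
      per_trial = per_trial
    ),
    class = "tw_waste_summary"
  )
}

#' @export
print.tw_waste_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "<tw_waste_summary> scenario: %s (other-policy: %s)\n",
    "  evaluable trials: %d\n",
    "  waste partially avoidable: %d (%s%%)\n",
    "  waste totally avoidable:   %d (%s%%)\n"),
    x$scenario, x$other_policy, x$n_evaluable,
    x$n_partial, x$pct_partial, x$n_total, x$pct_total))
  invisible(x)
}
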