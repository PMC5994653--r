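# Descriptive statistics and report generation: proportions with confidence
# intervals, medians with quartiles, Table-1/Table-2-style summaries, and
# the long-format outcome-status matrix behind the heat-map figure.

#' Binomial proportion with confidence interval
#'
#' `"wilson"` computes the Wilson score interval (bounds always inside
#' \[0, 1\]); `"wald"` the normal approximation truncated to \[0, 1\].
#'
#' @param numerator,denominator counts, `0 <= numerator <= denominator`,
#'   `denominator >= 1`
#' @param method `"wilson"` (default) or `"wald"`
#' @param level confidence level (default 0.95)
#' @return an object of class `tw_proportion`: list with `numerator`,
#'   `denominator`, `point`, `ci_low`, `ci_high`, `level`, `method`
#' @examples
#' proportion_ci(596, 2711)
#' @export
proportion_ci <- function(numerator, denominator,
                          method = c("wilson", "wald"), level = 0.95) {
  method <- match.arg(method)
  if (!is_count(numerator) || !is_count(denominator) || denominator < 1) {
    stop("numerator and denominator must be counts with denominator >= 1",
         call. = FALSE)
  }
  if (numerator > denominator) {
    stop("numerator exceeds denominator", call. = FALSE)
  }
  n <- denominator
  p <- numerator / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (method == "wilson") {
    denom <- 1 + z^2 / n
    center <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- center - half
    hi <- center + half
  } else {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- p - half
    hi <- p + half
  }
  # guard against floating-point drift at the boundaries
  lo <- max(0, min(lo, p))
  hi <- min(1, max(hi, p))
  structure(
    list(numerator = numerator, denominator = denominator, point = p,
         ci_low = lo, ci_high = hi, level = level, method = method),
    class = "tw_proportion"
  )
}

#' @export
print.tw_proportion <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%d%% CI %.1f-%.1f, %s)\n",
              x$numerator, x$denominator, 100 * x$point, round(100 * x$level),
              100 * x$ci_low, 100 * x$ci_high, x$method))
  invisible(x)
}

#' Median with quartiles
#'
#' Quartiles use linear interpolation between order statistics at positions
#' `(n - 1) * {0.25, 0.5, 0.75}` (the `stats::quantile()` type-7 convention,
#' fixed and documented so summaries are reproducible).
#'
#' @param values non-empty numeric vector
#' @return named numeric vector `c(median, q1, q3)`
#' @examples
#' median_iqr(c(1, 2, 3, 4))
#' @export
median_iqr <- function(values) {
  if (length(values) == 0L || !is.numeric(values)) {
    stop("median_iqr() requires a non-empty numeric vector", call. = FALSE)
  }
  q <- stats::quantile(values, probs = c(0.5, 0.25, 0.75), type = 7,
                       names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Full descriptive summary of an audited corpus
#'
#' Runs the whole pipeline (exclusion statistics, reason classification per
#' scope, waste assessment per scenario) and collects review/outcome
#' characteristics. All aggregates are computed from the corpus alone; the
#' display percentages are rounded half-up, the exact fractions are kept
#' alongside.
#'
#' @param corpus a [corpus()] (already filtered for eligibility)
#' @param scopes reason-table scopes to tabulate
#' @param scenarios waste scenarios to assess
#' @param ci_method interval method for headline proportions
#' @inheritParams select_evaluable_trials
#' @inheritParams assess_waste
#' @return an object of class `tw_summary_report`: a list with elements
#'   `review_stats`, `outcome_category_table`, `exclusion`, `evaluable`,
#'   `reason_tables`, `waste`, `expert`
#' @export
summarize_corpus <- function(corpus,
                             scopes = c("all_trials", "registered_only"),
                             scenarios = WASTE_SCENARIOS,
                             ci_method = c("wilson", "wald"),
                             other_policy = c("exclude", "block"),
                             min_year = 2010L, require_accessible = TRUE,
                             require_language = TRUE) {
  ci_method <- match.arg(ci_method)
  other_policy <- match.arg(other_policy)

  n_reviews <- length(corpus$reviews)
  trials_per_review <- vapply(corpus$reviews, function(r) length(r$trials),
                              integer(1))
  comparisons_per_review <- vapply(corpus$reviews,
                                   function(r) length(r$comparisons), integer(1))
  main_cps <- lapply(corpus$reviews, function(rv) {
    get_comparison(rv, select_main_comparison(rv))
  })
  trials_main <- vapply(main_cps, function(cp) length(cp$trial_ids), integer(1))
  outcomes_per_sof <- vapply(main_cps, function(cp) length(cp$sof_outcomes),
                             integer(1))
  n_pharma <- sum(vapply(corpus$reviews,
                         function(r) r$intervention_type == "pharmacological",
                         logical(1)))

  review_stats <- list(
    n_reviews = n_reviews,
    trials_per_review = median_iqr(trials_per_review),
    trials_in_main_comparison = median_iqr(trials_main),
    comparisons_per_review = median_iqr(comparisons_per_review),
    outcomes_per_sof = median_iqr(outcomes_per_sof),
    n_pharmacological = n_pharma,
    pct_pharmacological = round_half_up(pct_exact(n_pharma, n_reviews))
  )

  # outcome-category frequencies over main-comparison SoF outcomes; process
  # and resource_use are merged for display only
  all_outcomes <- unlist(lapply(main_cps, function(cp) cp$sof_outcomes),
                         recursive = FALSE)
  n_outcomes_total <- length(all_outcomes)
  cat_counts <- stats::setNames(integer(length(OUTCOME_CATEGORIES)),
                                OUTCOME_CATEGORIES)
  for (o in all_outcomes) {
    cat_counts[o$categories] <- cat_counts[o$categories] + 1L
  }
  display_cat <- c(setdiff(OUTCOME_CATEGORIES, c("process", "resource_use")),
                   "process_resource_use")
  display_counts <- c(cat_counts[setdiff(OUTCOME_CATEGORIES,
                                         c("process", "resource_use"))],
                      process_resource_use = unname(cat_counts["process"] +
                                                      cat_counts["resource_use"]))
  outcome_category_table <- tibble::tibble(
    category = display_cat,
    n = as.integer(display_counts[display_cat]),
    pct = round_half_up(pct_exact(as.integer(display_counts[display_cat]),
                                  n_outcomes_total))
  )
  outcome_category_table <- outcome_category_table[order(-outcome_category_table$n,
                                                         outcome_category_table$category), ]

  excl <- exclusion_stats(corpus)
  excl_props <- list(
    included_all = proportion_ci(excl$n_included_all, excl$n_trials,
                                 method = ci_method),
    excluded_any = proportion_ci(excl$n_excluded_any, excl$n_trials,
                                 method = ci_method)
  )

  evaluable <- select_evaluable_trials(corpus, min_year, require_accessible,
                                       require_language)
  cls <- classify_corpus(corpus, min_year, require_accessible, require_language)
  n_eval <- length(evaluable)
  registered_eval <- unique(cls$trial_id[cls$registration_found])
  eval_stats <- list(
    n_evaluable = n_eval,
    n_missing_outcomes = nrow(cls),
    n_registered = length(registered_eval),
    pct_registered = if (n_eval > 0)
      round_half_up(pct_exact(length(registered_eval), n_eval)) else NA_real_,
    registered_ci = if (n_eval > 0)
      proportion_ci(length(registered_eval), n_eval, method = ci_method) else NULL
  )

  # a scope with no missing outcomes (e.g. no registered evaluable trial)
  # yields NULL rather than aborting the whole report
  reason_tables <- stats::setNames(lapply(scopes, function(sc) {
    tryCatch(
      tabulate_reasons(corpus, sc, min_year, require_accessible,
                       require_language),
      error = function(e) {
        if (grepl("no missing outcomes", conditionMessage(e))) NULL else stop(e)
      }
    )
  }), scopes)

  waste <- stats::setNames(lapply(scenarios, function(sn) {
    assess_waste(corpus, sn, other_policy, min_year, require_accessible,
                 require_language)
  }), scenarios)

  # expert-panel view over the judged (inadequately planned) outcomes
  jd <- corpus$judgments
  ip_keys <- paste(cls$trial_id, cls$outcome_id)[cls$category == "INADEQUATE_PLANNING"]
  judged <- jd[paste(jd$trial_id, jd$outcome_id) %in% ip_keys, , drop = FALSE]
  n_judged <- nrow(judged)
  n_major <- sum(judged$importance == "major")
  easy <- judged$feasibility_trialist == "easy" &
    judged$feasibility_patient == "easy" &
    judged$cost %in% c("no_cost", "minor")
  n_easy_major <- sum(easy & judged$importance == "major")
  expert <- list(
    n_judged = n_judged, n_major = n_major, n_easy_major = n_easy_major,
    pct_major = if (n_judged > 0)
      round_half_up(pct_exact(n_major, n_judged)) else NA_real_,
    pct_easy_among_major = if (n_major > 0)
      round_half_up(pct_exact(n_easy_major, n_major)) else NA_real_
  )

  structure(
    list(review_stats = review_stats,
         outcome_category_table = outcome_category_table,
         exclusion = excl, exclusion_props = excl_props,
         evaluable = eval_stats, reason_tables = reason_tables,
         waste = waste, expert = expert),
    class = "tw_summary_report"
  )
}

#' @export
print.tw_summary_report <- function(x, ...) {
  rs <- x$review_stats
  cat(sprintf("<tw_summary_report> %d review(s)\n", rs$n_reviews))
  cat(sprintf("  trials/review median %g (Q1-Q3 %g-%g); outcomes/SoF median %g (%g-%g)\n",
              rs$trials_per_review["median"], rs$trials_per_review["q1"],
              rs$trials_per_review["q3"], rs$outcomes_per_sof["median"],
              rs$outcomes_per_sof["q1"], rs$outcomes_per_sof["q3"]))
  print(x$exclusion)
  cat(sprintf("  evaluable trials: %d (%d registered, %s%%)\n",
              x$evaluable$n_evaluable, x$evaluable$n_registered,
              x$evaluable$pct_registered))
  for (tab in x$reason_tables) if (!is.null(tab)) print(tab)
  for (w in x$waste) print(w)
  if (x$expert$n_judged > 0) {
    cat(sprintf("  expert panel: %d judged, %d (%s%%) of critical importance, %d (%s%%) easily measurable at no/minor cost\n",
                x$expert$n_judged, x$expert$n_major, x$expert$pct_major,
                x$expert$n_easy_major, x$expert$pct_easy_among_major))
  }
  invisible(x)
}

#' Export the outcome-status matrix of the evaluable trials
#'
#' Long-format table behind the heat-map figure: one row per evaluable trial
#' and summary-of-findings position, with status `"present"` (the trial
#' contributes to that outcome's meta-analysis), `"absent_avoidable"`
#' (missing and avoidable under the scenario), or `"absent"`. Trials are
#' sorted by id; ordering is deterministic.
#'
#' @param corpus a [corpus()] (already filtered for eligibility)
#' @inheritParams assess_waste
#' @return tibble with columns `trial_id`, `outcome_position`, `outcome_id`,
#'   `status`
#' @export
export_waste_matrix <- function(corpus, scenario = WASTE_SCENARIOS,
                                other_policy = c("exclude", "block"),
                                min_year = 2010L, require_accessible = TRUE,
                                require_language = TRUE) {
  scenario <- match.arg(scenario)
  other_policy <- match.arg(other_policy)
  cls <- classify_corpus(corpus, min_year, require_accessible, require_language)
  evaluable <- sort(unique(cls$trial_id))
  jd <- corpus$judgments
  rows <- list()
  for (rv in corpus$reviews) {
    cm <- build_contribution_matrix(rv)
    ids <- intersect(cm$trial_ids, evaluable)
    if (length(ids) == 0L) next
    for (tid in ids) {
      sub <- cls[cls$trial_id == tid, , drop = FALSE]
      status <- unname(ifelse(cm$cells[tid, ], "present", "absent"))
      for (i in seq_len(nrow(sub))) {
        if (sub$category[i] == "OTHER" && other_policy == "exclude") next
        j <- jd[jd$trial_id == tid & jd$outcome_id == sub$outcome_id[i], ,
                drop = FALSE]
        if (nrow(j) == 0L) j <- NULL
        av <- is_outcome_avoidable(new_reason(sub$category[i], sub$other_subtype[i]),
                                   j, scenario)$avoidable
        if (av) status[sub$outcome_position[i]] <- "absent_avoidable"
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        trial_id = tid,
        outcome_position = seq_along(cm$outcome_ids),
        outcome_id = cm$outcome_ids,
        status = status
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out[order(out$trial_id, out$outcome_position), , drop = FALSE]
}
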