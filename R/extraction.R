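# Step 1 of the audit: which reviews are eligible, which comparison is the
# main one, and which trials contribute to which important-outcome
# meta-analyses.

#' Review eligibility criteria
#'
#' Defaults reproduce the audit's filters: drop withdrawn reviews, reviews
#' including observational studies, reviews whose trials were all published
#' before 2007, and reviews whose summary-of-findings table mixes different
#' interventions. Criteria are evaluated in that order and the first failing
#' one is logged.
#'
#' @param drop_withdrawn drop withdrawn reviews?
#' @param drop_observational drop reviews including observational studies?
#' @param min_any_trial_year reviews are kept only if at least one trial has
#'   `publication_year >=` this value (half-open lower bound; `NA` disables
#'   the criterion). Reviews with no dated trial fail the criterion.
#' @param drop_sof_mixing_interventions drop reviews whose SoF table mixes
#'   interventions?
#' @return an object of class `tw_eligibility`
#' @export
eligibility_criteria <- function(drop_withdrawn = TRUE,
                                 drop_observational = TRUE,
                                 min_any_trial_year = 2007L,
                                 drop_sof_mixing_interventions = TRUE) {
  stopifnot(is_flag(drop_withdrawn), is_flag(drop_observational),
            is_flag(drop_sof_mixing_interventions))
  structure(
    list(drop_withdrawn = drop_withdrawn,
         drop_observational = drop_observational,
         min_any_trial_year = if (is.na(min_any_trial_year)) NA_integer_ else
           as.integer(min_any_trial_year),
         drop_sof_mixing_interventions = drop_sof_mixing_interventions),
    class = "tw_eligibility"
  )
}

#' Disable every eligibility criterion
#' @return an identity-filter `tw_eligibility`
#' @export
eligibility_none <- function() {
  eligibility_criteria(FALSE, FALSE, NA, FALSE)
}

#' Filter a corpus to eligible reviews
#'
#' @param corpus a [corpus()]
#' @param criteria an [eligibility_criteria()] object
#' @return list with elements `corpus` (the filtered corpus) and `log`
#'   (tibble `review_id`, `eligible`, `reason`; `reason` is the first failing
#'   criterion or `NA` for kept reviews)
#' @export
filter_eligible_reviews <- function(corpus, criteria = eligibility_criteria()) {
  stopifnot(inherits(criteria, "tw_eligibility"))
  first_failure <- function(rv) {
    if (criteria$drop_withdrawn && rv$withdrawn) return("withdrawn")
    if (criteria$drop_observational && rv$includes_observational) {
      return("includes_observational")
    }
    if (!is.na(criteria$min_any_trial_year)) {
      years <- vapply(rv$trials, function(t) t$publication_year, integer(1))
      years <- years[!is.na(years)]
      if (length(years) == 0L || max(years) < criteria$min_any_trial_year) {
        return("all_trials_before_min_year")
      }
    }
    if (criteria$drop_sof_mixing_interventions && rv$sof_mixes_interventions) {
      return("sof_mixes_interventions")
    }
    NA_character_
  }
  reasons <- vapply(corpus$reviews, first_failure, character(1))
  keep <- is.na(reasons)
  log <- tibble::tibble(
    review_id = vapply(corpus$reviews, function(r) r$review_id, character(1)),
    eligible = keep,
    reason = reasons
  )
  kept <- corpus$reviews[keep]
  kept_trials <- unlist(lapply(kept, function(r) {
    vapply(r$trials, function(t) t$trial_id, character(1))
  })) %||% character()
  jd <- corpus$judgments
  jd <- jd[jd$trial_id %in% kept_trials, , drop = FALSE]
  list(corpus = corpus(kept, judgments = jd,
                       schema_version = corpus$schema_version),
       log = log)
}

#' Select the main comparison of a review
#'
#' Returns the author-designated main comparison when one is flagged.
#' Otherwise selects deterministically by the lexicographic rule (most
#' summary-of-findings outcomes, then most trials, then earliest list
#' position) -- outcomes first because the unit of analysis is the outcome.
#'
#' @param review a [review()]
#' @return the selected `comparison_id`
#' @export
select_main_comparison <- function(review) {
  cps <- review$comparisons
  if (length(cps) == 0L) {
    stop(sprintf("review %s has no comparisons", review$review_id), call. = FALSE)
  }
  flagged <- which(vapply(cps, function(cp) isTRUE(cp$author_designated_main),
                          logical(1)))
  if (length(flagged) >= 1L) return(cps[[flagged[1]]]$comparison_id)
  n_out <- vapply(cps, function(cp) length(cp$sof_outcomes), integer(1))
  n_tri <- vapply(cps, function(cp) length(cp$trial_ids), integer(1))
  best <- order(-n_out, -n_tri, seq_along(cps))[1]
  cps[[best]]$comparison_id
}

get_comparison <- function(review, comparison_id) {
  for (cp in review$comparisons) {
    if (cp$comparison_id == comparison_id) return(cp)
  }
  stop(sprintf("comparison %s not found in review %s", comparison_id,
               review$review_id), call. = FALSE)
}

#' Build the trial-by-outcome contribution matrix of a review
#'
#' Rows are the trials of the main comparison (the union of all meta-analysis
#' contributor sets and the comparison's explicitly listed trials), columns
#' its summary-of-findings outcomes; `cells[t, o]` is `TRUE` iff trial `t`
#' contributes to the meta-analysis of outcome `o`. An outcome with no
#' meta-analysis yields an all-`FALSE` column.
#'
#' @param review a [review()]
#' @return an object of class `tw_contribution_matrix` with elements
#'   `review_id`, `comparison_id`, `trial_ids`, `outcome_ids`, `cells`
#' @export
build_contribution_matrix <- function(review) {
  cid <- select_main_comparison(review)
  cp <- get_comparison(review, cid)
  trial_ids <- cp$trial_ids
  outcome_ids <- vapply(cp$sof_outcomes, function(o) o$outcome_id, character(1))
  cells <- matrix(FALSE, nrow = length(trial_ids), ncol = length(outcome_ids),
                  dimnames = list(trial_ids, outcome_ids))
  for (m in cp$meta_analyses) {
    if (m$outcome_id %in% outcome_ids) {
      cells[m$contributing_trial_ids, m$outcome_id] <- TRUE
    }
  }
  structure(
    list(review_id = review$review_id, comparison_id = cid,
         trial_ids = trial_ids, outcome_ids = outcome_ids, cells = cells),
    class = "tw_contribution_matrix"
  )
}

#' @export
print.tw_contribution_matrix <- function(x, ...) {
  cat(sprintf("<tw_contribution_matrix> %s/%s: %d trial(s) x %d outcome(s), %d contributing cell(s)\n",
              x$review_id, x$comparison_id, length(x$trial_ids),
              length(x$outcome_ids), sum(x$cells)))
  invisible(x)
}

# per-trial contribution rows pooled over reviews; backbone of
# exclusion_stats() and select_evaluable_trials()
contribution_rows <- function(corpus) {
  rows <- lapply(corpus$reviews, function(rv) {
    cm <- build_contribution_matrix(rv)
    if (length(cm$trial_ids) == 0L) return(NULL)
    years <- rep(NA_integer_, length(cm$trial_ids))
    acc <- rep(TRUE, length(cm$trial_ids))
    lang <- rep(TRUE, length(cm$trial_ids))
    reg <- rep(FALSE, length(cm$trial_ids))
    idx <- stats::setNames(seq_along(cm$trial_ids), cm$trial_ids)
    for (tr in rv$trials) {
      i <- idx[tr$trial_id]
      if (!is.na(i)) {
        years[i] <- tr$publication_year
        acc[i] <- tr$accessible
        lang[i] <- tr$language_ok
        reg[i] <- tr$registration_found
      }
    }
    tibble::tibble(
      review_id = cm$review_id,
      comparison_id = cm$comparison_id,
      trial_id = cm$trial_ids,
      publication_year = years,
      accessible = acc,
      language_ok = lang,
      registration_found = reg,
      n_outcomes = length(cm$outcome_ids),
      n_contributing = as.integer(rowSums(cm$cells)),
      fraction = rowSums(cm$cells) / length(cm$outcome_ids)
    )
  })
  dplyr::bind_rows(rows)
}

#' Pooled exclusion statistics
#'
#' Counts, over all trials of all main comparisons, how many contribute to
#' every important-outcome meta-analysis and how many are excluded from at
#' least one, along with the mean per-trial contribution fraction. The
#' pooled mean is unweighted over trials; a review-then-trial average is
#' also reported (`mean_contribution_fraction_by_review`) for comparison.
#'
#' @param corpus a [corpus()] (already filtered for eligibility)
#' @return an object of class `tw_exclusion_stats`
#' @export
exclusion_stats <- function(corpus) {
  rows <- contribution_rows(corpus)
  if (nrow(rows) == 0L) stop("no eligible reviews with trials", call. = FALSE)
  by_review <- tapply(rows$fraction, rows$review_id, mean)
  structure(
    list(
      n_trials = nrow(rows),
      n_included_all = sum(rows$fraction == 1),
      n_excluded_any = sum(rows$fraction < 1),
      mean_contribution_fraction = mean(rows$fraction),
      mean_contribution_fraction_by_review = mean(by_review),
      per_trial = rows
    ),
    class = "tw_exclusion_stats"
  )
}

#' @export
print.tw_exclusion_stats <- function(x, ...) {
  cat(sprintf(paste0(
    "<tw_exclusion_stats> %d trial(s)\n",
    "  included in all meta-analyses: %d (%s%%)\n",
    "  excluded from >= 1 meta-analysis: %d (%s%%)\n",
    "  mean contribution fraction (trial-level): %.3f\n"),
    x$n_trials,
    x$n_included_all, round_half_up(pct_exact(x$n_included_all, x$n_trials)),
    x$n_excluded_any, round_half_up(pct_exact(x$n_excluded_any, x$n_trials)),
    x$mean_contribution_fraction))
  invisible(x)
}

#' Select the trials evaluable for reason classification
#'
#' Candidates are trials excluded from at least one important-outcome
#' meta-analysis; of these, only recent, accessible, readable reports can be
#' evaluated for the reason the outcome is missing.
#'
#' @param corpus a [corpus()] (already filtered for eligibility)
#' @param min_year keep trials with `publication_year >= min_year`
#' @param require_accessible drop trials whose reports are not retrievable
#' @param require_language drop trials whose reports are not readable
#' @return character vector of trial ids
#' @export
select_evaluable_trials <- function(corpus, min_year = 2010L,
                                    require_accessible = TRUE,
                                    require_language = TRUE) {
  rows <- contribution_rows(corpus)
  if (nrow(rows) == 0L) return(character())
  keep <- rows$fraction < 1
  keep <- keep & !is.na(rows$publication_year) &
    rows$publication_year >= min_year
  if (require_accessible) keep <- keep & rows$accessible
  if (require_language) keep <- keep & rows$language_ok
  rows$trial_id[keep]
}
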