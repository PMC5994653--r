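# Shared fixtures and independent brute-force oracles. The oracles
# re-implement the audit rules directly from the annotation data, without
# touching the contribution-matrix / classification / waste code paths they
# are used to check.

ann_present <- function(registered = FALSE) {
  outcome_annotation(TRUE, planned = if (registered) "yes" else "unknown",
                     reported = TRUE, poolable = "yes")
}

ann_missing <- function(registered = FALSE, planned = NULL, pim = FALSE,
                        reported = FALSE, poolable = NULL, zero_event = FALSE,
                        rnp = FALSE) {
  planned <- planned %||% (if (registered) "no" else "unknown")
  poolable <- poolable %||% (if (reported) "no" else "not_applicable")
  outcome_annotation(FALSE, planned = planned,
                     planned_in_publication_methods = pim,
                     reported = reported, poolable = poolable,
                     zero_event = zero_event, reported_not_pooled = rnp)
}

# one review / one comparison / `n_out` outcomes; `patterns` is a list per
# trial: list(registered=, year=, ann=named list of annotations)
small_corpus <- function(patterns, n_out = 2L, judgments = empty_judgments(),
                         categories = NULL) {
  out_ids <- sprintf("O%d", seq_len(n_out))
  outs <- lapply(seq_len(n_out), function(k) {
    sof_outcome(out_ids[k],
                categories = (categories %||% rep("mortality", n_out))[k])
  })
  trials <- list()
  contributors <- stats::setNames(rep(list(character()), n_out), out_ids)
  for (i in seq_along(patterns)) {
    p <- patterns[[i]]
    tid <- sprintf("T%02d", i)
    ann <- p$ann
    stopifnot(setequal(names(ann), out_ids))
    for (oid in out_ids) {
      if (ann[[oid]]$in_meta_analysis) {
        contributors[[oid]] <- c(contributors[[oid]], tid)
      }
    }
    trials[[i]] <- trial_record(
      tid, publication_year = p$year %||% 2012L,
      accessible = p$accessible %||% TRUE,
      language_ok = p$language_ok %||% TRUE,
      registration_found = p$registered %||% FALSE,
      annotations = ann[out_ids]
    )
  }
  mas <- lapply(out_ids, function(oid) meta_analysis(oid, contributors[[oid]]))
  cp <- comparison("C1", sof_outcomes = outs, meta_analyses = mas,
                   trial_ids = vapply(trials, function(t) t$trial_id, character(1)),
                   author_designated_main = TRUE)
  corpus(list(review("R1", comparisons = list(cp), trials = trials)),
         judgments = judgments)
}

# generator config shrunk for fast property tests
small_config <- function(...) {
  generator_config(n_reviews = 8L,
                   trials_per_review = dist_spec(1:6, rep(1, 6)),
                   outcomes_per_sof = dist_spec(1:5, rep(1, 5)),
                   p_year_ge_2010 = 0.7, ...)
}

# ---- independent oracles ----------------------------------------------

# natural-order restatement of the five-category rules (plus the two special
# situations), written against the raw evidence fields
oracle_classify <- function(registered, planned, pim, reported, poolable,
                            zero_event, rnp, adverse = FALSE) {
  if (zero_event) {
    return(list(category = "OTHER",
                other_subtype = if (adverse) "NO_ADVERSE_EVENT" else "NO_EVENT"))
  }
  if (rnp) return(list(category = "OTHER", other_subtype = "REPORTED_NOT_POOLED"))
  if (reported && poolable == "no") {
    return(list(category = "INCOMPLETE_REPORTING", other_subtype = "none"))
  }
  if (!reported) {
    if (registered && planned == "no") {
      return(list(category = "INADEQUATE_PLANNING", other_subtype = "none"))
    }
    if (registered && planned == "yes") {
      return(list(category = "SELECTIVE_REPORTING", other_subtype = "none"))
    }
    if (!registered && pim) {
      return(list(category = "SELECTIVE_REPORTING", other_subtype = "none"))
    }
    if (!registered) {
      return(list(category = "INDISTINGUISHABLE", other_subtype = "none"))
    }
  }
  list(category = "ERROR", other_subtype = "none")
}

# every admissible combination of the evidence fields for a missing outcome
admissible_annotations <- function() {
  grid <- expand.grid(
    registered = c(TRUE, FALSE), planned = PLANNED_LEVELS <- c("yes", "no", "unknown"),
    pim = c(TRUE, FALSE), reported = c(TRUE, FALSE),
    poolable = c("yes", "no", "not_applicable"),
    zero_event = c(TRUE, FALSE), rnp = c(TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  ok <- (grid$registered == (grid$planned != "unknown")) &
    (grid$reported | (grid$poolable == "not_applicable" & !grid$zero_event & !grid$rnp)) &
    (!grid$reported | grid$poolable != "not_applicable") &
    (!grid$rnp | grid$poolable == "yes")
  grid[ok, , drop = FALSE]
}

# exclusion statistics recomputed pair by pair from the annotations, never
# touching build_contribution_matrix()
oracle_exclusion <- function(corp) {
  fracs <- c()
  for (rv in corp$reviews) {
    flagged <- which(vapply(rv$comparisons,
                            function(cp) isTRUE(cp$author_designated_main),
                            logical(1)))
    cp <- if (length(flagged)) rv$comparisons[[flagged[1]]] else {
      n_out <- vapply(rv$comparisons, function(cp) length(cp$sof_outcomes), integer(1))
      n_tri <- vapply(rv$comparisons, function(cp) length(cp$trial_ids), integer(1))
      rv$comparisons[[order(-n_out, -n_tri, seq_along(rv$comparisons))[1]]]
    }
    out_ids <- vapply(cp$sof_outcomes, function(o) o$outcome_id, character(1))
    for (tr in rv$trials) {
      if (!tr$trial_id %in% cp$trial_ids) next
      inm <- vapply(out_ids, function(oid) {
        isTRUE(tr$annotations[[oid]]$in_meta_analysis)
      }, logical(1))
      fracs <- c(fracs, mean(inm))
    }
  }
  list(n_trials = length(fracs),
       n_included_all = sum(fracs == 1),
       n_excluded_any = sum(fracs < 1),
       mean_contribution_fraction = mean(fracs))
}

oracle_avoidable <- function(category, judgment, scenario) {
  if (category %in% c("SELECTIVE_REPORTING", "INCOMPLETE_REPORTING")) return(TRUE)
  if (category == "INADEQUATE_PLANNING" && scenario == "reporting_plus_planning") {
    return(nrow(judgment) == 1L &&
             judgment$feasibility_trialist == "easy" &&
             judgment$feasibility_patient == "easy" &&
             judgment$cost %in% c("no_cost", "minor") &&
             judgment$importance == "major")
  }
  FALSE
}

# per-trial waste recount straight from the annotations
oracle_waste <- function(corp, scenario, min_year = 2010L) {
  n_partial <- 0L; n_total <- 0L; n_eval <- 0L
  for (rv in corp$reviews) {
    flagged <- which(vapply(rv$comparisons,
                            function(cp) isTRUE(cp$author_designated_main),
                            logical(1)))
    cp <- if (length(flagged)) rv$comparisons[[flagged[1]]] else {
      n_out <- vapply(rv$comparisons, function(cp) length(cp$sof_outcomes), integer(1))
      n_tri <- vapply(rv$comparisons, function(cp) length(cp$trial_ids), integer(1))
      rv$comparisons[[order(-n_out, -n_tri, seq_along(rv$comparisons))[1]]]
    }
    out_ids <- vapply(cp$sof_outcomes, function(o) o$outcome_id, character(1))
    adverse <- vapply(cp$sof_outcomes,
                      function(o) "adverse_events" %in% o$categories, logical(1))
    for (tr in rv$trials) {
      if (!tr$trial_id %in% cp$trial_ids) next
      inm <- vapply(out_ids, function(oid) {
        isTRUE(tr$annotations[[oid]]$in_meta_analysis)
      }, logical(1))
      if (all(inm)) next
      if (is.na(tr$publication_year) || tr$publication_year < min_year ||
          !tr$accessible || !tr$language_ok) next
      n_eval <- n_eval + 1L
      avo <- logical(0)
      for (k in which(!inm)) {
        a <- tr$annotations[[out_ids[k]]]
        cls <- oracle_classify(tr$registration_found, a$planned,
                               a$planned_in_publication_methods, a$reported,
                               a$poolable, a$zero_event, a$reported_not_pooled,
                               adverse[k])
        if (cls$category == "OTHER") next  # excluded from the assessable set
        j <- corp$judgments[corp$judgments$trial_id == tr$trial_id &
                              corp$judgments$outcome_id == out_ids[k], ,
                            drop = FALSE]
        avo <- c(avo, oracle_avoidable(cls$category, j, scenario))
      }
      if (length(avo) && all(avo)) n_total <- n_total + 1L
      if (any(avo)) n_partial <- n_partial + 1L
    }
  }
  list(n_evaluable = n_eval, n_partial = n_partial, n_total = n_total)
}
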