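# Synthetic review-corpus generator. The evidence chain per (trial, outcome)
# is a directed Bernoulli factorization -- planned -> reported -> poolable --
# with independent zero-event and reported-not-pooled overrides on reported
# outcomes; a trial contributes to an outcome's meta-analysis exactly when
# the outcome is reported, poolable, and neither override fires. Every
# conditional probability is exposed in the config, and the closed-form
# reason-share implications are available via expected_reason_shares() for
# parameter-recovery checks.

#' Discrete distribution specification
#'
#' @param values support (distinct values)
#' @param probs nonnegative weights, normalized internally
#' @return an object of class `tw_dist`
#' @export
dist_spec <- function(values, probs) {
  stopifnot(length(values) == length(probs), length(values) >= 1L,
            all(probs >= 0), sum(probs) > 0)
  structure(list(values = values, probs = probs / sum(probs)),
            class = "tw_dist")
}

draw <- function(dist, n) {
  dist$values[sample.int(length(dist$values), n, replace = TRUE,
                         prob = dist$probs)]
}

draw_cat <- function(weights, n) {
  names(weights)[sample.int(length(weights), n, replace = TRUE, prob = weights)]
}

# outcomes-per-SoF distribution on 1..12 whose population quartiles are
# (3, 5, 7): F(2)=.14 < .25 < F(3)=.28, F(4)=.42 < .5 < F(5)=.58,
# F(6)=.72 < .75 < F(7)=.84
OUTCOMES_PER_SOF_PROBS <- c(0.04, 0.10, 0.14, 0.14, 0.16, 0.14, 0.12,
                            0.06, 0.04, 0.03, 0.02, 0.01)

#' Generator configuration
#'
#' All probabilities driving the hierarchical sampling of a synthetic review
#' corpus. The defaults (also returned by [default_config_from_paper()]) are
#' calibrated to the published audit's marginals: 54\% of trials registered,
#' 60\% of reviews pharmacological, outcomes per summary-of-findings table
#' with median 5 and quartiles 3--7 on support 1--12, and an evidence chain
#' whose implied reason shares among registered missing outcomes are
#' approximately 61/7/21/10\% (inadequate planning / selective reporting /
#' incomplete reporting / other) with an overall missingness of about 45\%.
#' Expert defaults give about 78\% major-importance judgments and about
#' 82\% easy-easy-cheap among them.
#'
#' @param n_reviews number of reviews to generate
#' @param trials_per_review [dist_spec()] for trials per main comparison
#' @param outcomes_per_sof [dist_spec()] on 1..12 for SoF outcomes
#' @param p_pharmacological probability a review is pharmacological
#' @param outcome_category_weights 15 nonnegative weights (named by
#'   [outcome_categories()]) for the first category of an outcome
#' @param p_second_category probability an outcome carries a second category
#' @param p_year_ge_2010 probability a trial is published in 2010 or later
#' @param p_accessible,p_language_ok report accessibility probabilities
#' @param p_registered probability a registration/protocol is retrievable
#' @param p_planned_given_registered probability an outcome is planned per
#'   the registry/protocol of a registered trial
#' @param p_reported_given_planned,p_reported_given_unplanned reporting
#'   probabilities conditional on planning; unregistered trials use the
#'   marginal implied by the same chain
#' @param p_poolable_given_reported probability a reported outcome is
#'   poolable
#' @param p_zero_event probability a reported outcome had zero events
#' @param p_reported_not_pooled probability a reported poolable outcome was
#'   nevertheless left out of the meta-analysis
#' @param p_planned_in_methods_given_unregistered probability an unreported
#'   outcome of an unregistered trial was listed in the publication methods
#' @param expert list of categorical weight vectors `feasibility_trialist`,
#'   `feasibility_patient`, `cost`, `importance`
#' @return an object of class `tw_generator_config`
#' @export
generator_config <- function(
    n_reviews = 290L,
    trials_per_review = dist_spec(1:40, stats::dnbinom(0:39, size = 1.3, mu = 6)),
    outcomes_per_sof = dist_spec(1:12, OUTCOMES_PER_SOF_PROBS),
    p_pharmacological = 0.60,
    outcome_category_weights = c(
      mortality = 138, other_clinical_event = 198, therapeutic_decision = 33,
      `function` = 384, pain = 71, quality_of_life = 98, adverse_events = 174,
      physiological_variable = 56, biological_variable = 89,
      radiological_variable = 23, compliance = 45, process = 37,
      resource_use = 37, cost_effectiveness = 16, satisfaction_with_care = 24),
    p_second_category = 0.10,
    p_year_ge_2010 = 0.15,
    p_accessible = 0.97,
    p_language_ok = 0.97,
    p_registered = 0.54,
    p_planned_given_registered = 0.60,
    p_reported_given_planned = 0.945,
    p_reported_given_unplanned = 0.31,
    p_poolable_given_reported = 0.856,
    p_zero_event = 0.04,
    p_reported_not_pooled = 0.032,
    p_planned_in_methods_given_unregistered = 0.01,
    expert = list(
      feasibility_trialist = c(easy = 0.92, moderately_easy = 0.05,
                               difficult = 0.02, impossible = 0.01),
      feasibility_patient = c(easy = 0.95, moderately_easy = 0.03,
                              difficult = 0.015, impossible = 0.005),
      cost = c(no_cost = 0.90, minor = 0.044, moderate = 0.04, major = 0.016),
      importance = c(major = 0.78, non_major = 0.22))) {
  stopifnot(is_count(n_reviews), n_reviews >= 1,
            inherits(trials_per_review, "tw_dist"),
            inherits(outcomes_per_sof, "tw_dist"))
  if (!all(outcomes_per_sof$values %in% 1:12)) {
    stop("outcomes_per_sof must be supported on 1..12", call. = FALSE)
  }
  probs <- c(p_pharmacological = p_pharmacological,
             p_second_category = p_second_category,
             p_year_ge_2010 = p_year_ge_2010, p_accessible = p_accessible,
             p_language_ok = p_language_ok, p_registered = p_registered,
             p_planned_given_registered = p_planned_given_registered,
             p_reported_given_planned = p_reported_given_planned,
             p_reported_given_unplanned = p_reported_given_unplanned,
             p_poolable_given_reported = p_poolable_given_reported,
             p_zero_event = p_zero_event,
             p_reported_not_pooled = p_reported_not_pooled,
             p_planned_in_methods_given_unregistered = p_planned_in_methods_given_unregistered)
  for (nm in names(probs)) {
    if (!is_prob(probs[[nm]])) {
      stop(sprintf("invalid generator config: %s must be a probability", nm),
           call. = FALSE)
    }
  }
  if (!setequal(names(outcome_category_weights), OUTCOME_CATEGORIES) ||
      any(outcome_category_weights < 0) || sum(outcome_category_weights) <= 0) {
    stop("outcome_category_weights must be nonnegative weights named by the 15 categories",
         call. = FALSE)
  }
  need <- c("feasibility_trialist", "feasibility_patient", "cost", "importance")
  lvls <- list(FEASIBILITY_LEVELS, FEASIBILITY_LEVELS, COST_LEVELS,
               IMPORTANCE_LEVELS)
  for (i in seq_along(need)) {
    w <- expert[[need[i]]]
    if (is.null(w) || !setequal(names(w), lvls[[i]]) || any(w < 0) ||
        sum(w) <= 0) {
      stop(sprintf("invalid expert weights for %s", need[i]), call. = FALSE)
    }
    expert[[need[i]]] <- w / sum(w)
  }
  structure(
    c(list(n_reviews = as.integer(n_reviews),
           trials_per_review = trials_per_review,
           outcomes_per_sof = outcomes_per_sof),
      as.list(probs),
      list(outcome_category_weights = outcome_category_weights /
             sum(outcome_category_weights),
           expert = expert)),
    class = "tw_generator_config"
  )
}

#' Default generator configuration calibrated to the published marginals
#'
#' @return a [generator_config()] with its calibrated defaults
#' @export
default_config_from_paper <- function() generator_config()

#' Closed-form reason shares implied by a generator configuration
#'
#' For a registered trial, the evidence chain implies, conditional on an
#' outcome being missing from the meta-analysis, the category shares
#' (inadequate planning, selective reporting, incomplete reporting, other)
#' in closed form. Used as the analytic reference in parameter-recovery
#' checks of the simulator.
#'
#' @param config a [generator_config()]
#' @return list with `p_missing` (per registered (trial, outcome) pair) and
#'   `shares` (named numeric vector over the four registered-scope
#'   categories, summing to 1)
#' @export
expected_reason_shares <- function(config) {
  p_pl <- config$p_planned_given_registered
  r_p <- config$p_reported_given_planned
  r_u <- config$p_reported_given_unplanned
  q <- config$p_poolable_given_reported
  z <- config$p_zero_event
  w <- config$p_reported_not_pooled
  p_rep <- p_pl * r_p + (1 - p_pl) * r_u
  ip <- (1 - p_pl) * (1 - r_u)
  sr <- p_pl * (1 - r_p)
  ir <- p_rep * (1 - z) * (1 - q)
  oth <- p_rep * z + p_rep * (1 - z) * q * w
  m <- ip + sr + ir + oth
  list(p_missing = m,
       shares = c(inadequate_planning = ip, selective_reporting = sr,
                  incomplete_reporting = ir, other = oth) / m)
}

#' Expected expert-judgment shares implied by a generator configuration
#'
#' @param config a [generator_config()]
#' @return list with `p_major` (share of judged outcomes of major
#'   importance) and `p_easy_cheap` (share judged easy from both
#'   perspectives at no or minor cost; feasibility, cost, and importance
#'   are drawn independently)
#' @export
expected_expert_shares <- function(config) {
  e <- config$expert
  list(p_major = unname(e$importance["major"]),
       p_easy_cheap = unname(e$feasibility_trialist["easy"] *
                               e$feasibility_patient["easy"] *
                               (e$cost["no_cost"] + e$cost["minor"])))
}

#' Generate a synthetic review corpus
#'
#' Hierarchical sampling: reviews with 1--3 comparisons (the trial-bearing
#' main comparison always first, so the size rule selects it when the author
#' flag is not set), summary-of-findings outcomes with categories, trials
#' with publication year, accessibility and registration, the per-(trial,
#' outcome) evidence chain, derived meta-analysis membership, and expert
#' judgments for every inadequately planned (registered, unplanned,
#' unreported) pair. Fully reproducible: identical `(config, seed)` yield
#' identical corpora; each review uses a deterministically derived
#' sub-stream so earlier reviews are unaffected by later ones.
#'
#' @param config a [generator_config()]
#' @param seed integer seed
#' @return a valid [corpus()] object
#' @export
generate_corpus <- function(config, seed) {
  stopifnot(inherits(config, "tw_generator_config"), is.numeric(seed),
            length(seed) == 1L)
  set.seed(as.integer(seed))
  review_seeds <- sample.int(.Machine$integer.max - 1L, config$n_reviews)

  width_r <- max(3L, nchar(as.character(config$n_reviews)))
  groups <- c("airways", "menstrual disorders and subfertility", "anesthesia",
              "oral health", "schizophrenia", "hepato-biliary",
              "neuromuscular disease", "musculoskeletal",
              "infectious diseases", "other")
  cats <- config$outcome_category_weights

  reviews <- vector("list", config$n_reviews)
  judgment_rows <- list()

  for (r in seq_len(config$n_reviews)) {
    set.seed(review_seeds[r])
    rid <- sprintf(paste0("R%0", width_r, "d"), r)
    n_sof <- draw(config$outcomes_per_sof, 1L)
    n_cmp <- sample.int(3L, 1L)
    n_tri <- draw(config$trials_per_review, 1L)
    author_flag <- stats::runif(1) < 0.5

    out_ids <- sprintf("%s-O%d", rid, seq_len(n_sof))
    outs <- vector("list", n_sof)
    for (k in seq_len(n_sof)) {
      cc <- draw_cat(cats, 1L)
      if (stats::runif(1) < config$p_second_category) {
        cc <- unique(c(cc, draw_cat(cats, 1L)))
      }
      outs[[k]] <- sof_outcome(out_ids[k], categories = cc,
                               label = sprintf("outcome %d of %s", k, rid))
    }

    trial_ids <- sprintf("%s-T%02d", rid, seq_len(n_tri))
    year <- ifelse(stats::runif(n_tri) < config$p_year_ge_2010,
                   sample(2010:2013, n_tri, replace = TRUE),
                   sample(2000:2009, n_tri, replace = TRUE))
    acc <- stats::runif(n_tri) < config$p_accessible
    lang <- stats::runif(n_tri) < config$p_language_ok
    reg <- stats::runif(n_tri) < config$p_registered

    contributors <- stats::setNames(rep(list(character()), n_sof), out_ids)
    trials <- vector("list", n_tri)
    for (j in seq_len(n_tri)) {
      planned_known <- stats::runif(n_sof) < config$p_planned_given_registered
      reported <- ifelse(planned_known,
                         stats::runif(n_sof) < config$p_reported_given_planned,
                         stats::runif(n_sof) < config$p_reported_given_unplanned)
      poolable <- reported & (stats::runif(n_sof) < config$p_poolable_given_reported)
      zero_event <- reported & (stats::runif(n_sof) < config$p_zero_event)
      rnp <- reported & poolable & !zero_event &
        (stats::runif(n_sof) < config$p_reported_not_pooled)
      pim <- !reg[j] & !reported &
        (stats::runif(n_sof) < config$p_planned_in_methods_given_unregistered)
      in_meta <- reported & poolable & !zero_event & !rnp

      ann <- vector("list", n_sof)
      names(ann) <- out_ids
      for (k in seq_len(n_sof)) {
        ann[[k]] <- outcome_annotation(
          in_meta_analysis = in_meta[k],
          planned = if (reg[j]) (if (planned_known[k]) "yes" else "no") else "unknown",
          planned_in_publication_methods = pim[k],
          reported = reported[k],
          poolable = if (!reported[k]) "not_applicable" else
            (if (poolable[k]) "yes" else "no"),
          zero_event = zero_event[k],
          reported_not_pooled = rnp[k]
        )
        if (in_meta[k]) {
          contributors[[k]] <- c(contributors[[k]], trial_ids[j])
        }
        if (reg[j] && !planned_known[k] && !reported[k]) {
          judgment_rows[[length(judgment_rows) + 1L]] <- expert_judgment(
            trial_ids[j], out_ids[k],
            draw_cat(config$expert$feasibility_trialist, 1L),
            draw_cat(config$expert$feasibility_patient, 1L),
            draw_cat(config$expert$cost, 1L),
            draw_cat(config$expert$importance, 1L)
          )
        }
      }
      trials[[j]] <- trial_record(trial_ids[j], publication_year = year[j],
                                  accessible = acc[j], language_ok = lang[j],
                                  registration_found = reg[j],
                                  annotations = ann)
    }

    mas <- lapply(out_ids, function(oid) meta_analysis(oid, contributors[[oid]]))
    main <- comparison(sprintf("%s-C1", rid), sof_outcomes = outs,
                       meta_analyses = mas, trial_ids = trial_ids,
                       author_designated_main = author_flag)
    cmps <- list(main)
    if (n_cmp > 1L) {
      # secondary comparisons carry structure but no trials; never larger
      # than the main one, so the size rule cannot displace it
      for (s in 2:n_cmp) {
        n2 <- sample.int(n_sof, 1L)
        o2 <- lapply(seq_len(n2), function(k) {
          sof_outcome(sprintf("%s-C%d-O%d", rid, s, k),
                      categories = draw_cat(cats, 1L))
        })
        cmps[[s]] <- comparison(sprintf("%s-C%d", rid, s), sof_outcomes = o2)
      }
    }

    reviews[[r]] <- review(
      rid, comparisons = cmps, trials = trials,
      review_group = groups[sample.int(length(groups), 1L)],
      intervention_type = if (stats::runif(1) < config$p_pharmacological)
        "pharmacological" else "non_pharmacological"
    )
  }

  jd <- if (length(judgment_rows)) dplyr::bind_rows(judgment_rows) else empty_judgments()
  corpus(reviews, judgments = jd)
}
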