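# Deterministic fixture builder: materializes a full corpus from printed
# marginal counts (trial totals, per-category missing-outcome and
# affected-trial counts in two scopes, expert-judgment counts, and the four
# partial/total avoidable-waste counts), with no randomness. Running the
# audit pipeline on the result reproduces the specified marginals exactly.
#
# The joint (trial x reason) layout is not part of the input; it is derived
# algebraically. Trials are partitioned into groups whose sizes follow from
# the marginals -- registered: all-avoidable planning-only trials (A), mixed
# avoidable/non-avoidable planning-only (B), non-avoidable planning-only (C),
# reporting-only (D), planning + reporting (E), other-only (F); unregistered:
# incomplete-reporting-only, indistinguishable with/without co-occurring
# categories, and other-only -- and outcome counts are spread over each group
# deterministically (minimum one per covering trial, extras to the trial
# with the most remaining room). Inconsistent marginals surface as
# "specification error"s naming the violated constraint.

REASON_KEYS <- c("inadequate_planning", "selective_reporting",
                 "incomplete_reporting", "indistinguishable", "other")

#' Marginal counts for the fixture builder
#'
#' Returns the count specification consumed by [build_fixture_from_spec()].
#' The defaults are the published audit's headline counts: 2711 trials in
#' the main comparisons of 290 reviews, 596 contributing to every
#' meta-analysis, 310 recent trials excluded from at least one (19 of them
#' unevaluable), 291 evaluable trials with 971 missing outcomes, 156
#' registered trials with 461 missing outcomes, the per-category
#' missing-outcome and affected-trial counts in both scopes, the expert
#' counts (282 judged, 221 of critical importance, 182 of those easily
#' measurable at no or minor cost), and the partial/total avoidable-waste
#' counts under both scenarios (126/34 and 183/86).
#'
#' @param n_reviews number of reviews
#' @param sof_size outcomes per summary-of-findings table (uniform across
#'   the fixture)
#' @param n_trials total trials in main comparisons
#' @param n_included_all trials contributing to every meta-analysis
#' @param n_dropped_access,n_dropped_language recent excluded trials that
#'   cannot be evaluated (report not retrievable / not readable)
#' @param n_evaluable trials evaluable for reason classification
#' @param n_registered evaluable trials with a registration or protocol
#' @param reasons_registered,reasons_all named per-category missing-outcome
#'   counts (registered scope omits `indistinguishable`)
#' @param trials_registered,trials_all named per-category affected-trial
#'   counts (coverage counts)
#' @param expert_major judged outcomes of major (critical) importance
#' @param expert_easy_major of those, outcomes easily measurable from both
#'   perspectives at no or minor cost
#' @param partial_reporting,total_reporting,partial_planning,total_planning
#'   trial counts with partially/totally avoidable waste under the
#'   reporting-only and reporting-plus-planning scenarios
#' @param n_pharmacological reviews with a pharmacological intervention
#'   (`NULL`: 60\% of reviews)
#' @param mean_contribution_pct target pooled mean contribution percentage;
#'   extra missingness among non-evaluable excluded trials is set so the
#'   corpus-wide mean lands on this value after rounding (`NULL`: minimal
#'   missingness, one outcome per excluded trial)
#' @param recent_year,old_year publication years used for recent
#'   (`>= 2010`) and older trials
#' @return named list of class `tw_fixture_counts`
#' @export
fixture_counts <- function(n_reviews = 290L,
                           sof_size = 5L,
                           n_trials = 2711L,
                           n_included_all = 596L,
                           n_dropped_access = 10L,
                           n_dropped_language = 9L,
                           n_evaluable = 291L,
                           n_registered = 156L,
                           reasons_registered = c(inadequate_planning = 282L,
                                                  selective_reporting = 34L,
                                                  incomplete_reporting = 98L,
                                                  other = 47L),
                           reasons_all = c(inadequate_planning = 282L,
                                           selective_reporting = 36L,
                                           incomplete_reporting = 204L,
                                           indistinguishable = 363L,
                                           other = 86L),
                           trials_registered = c(inadequate_planning = 123L,
                                                 selective_reporting = 23L,
                                                 incomplete_reporting = 64L,
                                                 other = 41L),
                           trials_all = c(inadequate_planning = 123L,
                                          selective_reporting = 25L,
                                          incomplete_reporting = 117L,
                                          indistinguishable = 122L,
                                          other = 63L),
                           expert_major = 221L,
                           expert_easy_major = 182L,
                           partial_reporting = 126L,
                           total_reporting = 34L,
                           partial_planning = 183L,
                           total_planning = 86L,
                           n_pharmacological = NULL,
                           mean_contribution_pct = 55,
                           recent_year = 2012L,
                           old_year = 2009L) {
  fill <- function(x, keys) {
    out <- stats::setNames(integer(length(keys)), keys)
    out[names(x)] <- as.integer(x)
    out
  }
  structure(
    list(
      n_reviews = as.integer(n_reviews), sof_size = as.integer(sof_size),
      n_trials = as.integer(n_trials),
      n_included_all = as.integer(n_included_all),
      n_dropped_access = as.integer(n_dropped_access),
      n_dropped_language = as.integer(n_dropped_language),
      n_evaluable = as.integer(n_evaluable),
      n_registered = as.integer(n_registered),
      reasons_registered = fill(reasons_registered,
                                setdiff(REASON_KEYS, "indistinguishable")),
      reasons_all = fill(reasons_all, REASON_KEYS),
      trials_registered = fill(trials_registered,
                               setdiff(REASON_KEYS, "indistinguishable")),
      trials_all = fill(trials_all, REASON_KEYS),
      expert_major = as.integer(expert_major),
      expert_easy_major = as.integer(expert_easy_major),
      partial_reporting = as.integer(partial_reporting),
      total_reporting = as.integer(total_reporting),
      partial_planning = as.integer(partial_planning),
      total_planning = as.integer(total_planning),
      n_pharmacological = if (is.null(n_pharmacological)) NULL else
        as.integer(n_pharmacological),
      mean_contribution_pct = mean_contribution_pct,
      recent_year = as.integer(recent_year),
      old_year = as.integer(old_year)
    ),
    class = "tw_fixture_counts"
  )
}

spec_error <- function(fmt, ...) {
  stop(sprintf(paste0("specification error: ", fmt), ...), call. = FALSE)
}

check_fixture_counts <- function(ct) {
  if (ct$n_included_all > ct$n_trials) {
    spec_error("n_included_all (%d) exceeds n_trials (%d)",
               ct$n_included_all, ct$n_trials)
  }
  n_excluded <- ct$n_trials - ct$n_included_all
  n_recent <- ct$n_evaluable + ct$n_dropped_access + ct$n_dropped_language
  if (n_recent > n_excluded) {
    spec_error("recent excluded trials (%d) exceed excluded trials (%d)",
               n_recent, n_excluded)
  }
  if (ct$n_registered > ct$n_evaluable) {
    spec_error("n_registered (%d) exceeds n_evaluable (%d)",
               ct$n_registered, ct$n_evaluable)
  }
  if (ct$n_reviews > ct$n_trials && ct$n_trials > 0) {
    spec_error("more reviews (%d) than trials (%d)", ct$n_reviews, ct$n_trials)
  }
  rr <- ct$reasons_registered; ra <- ct$reasons_all
  tr <- ct$trials_registered; ta <- ct$trials_all
  if (ra["inadequate_planning"] != rr["inadequate_planning"]) {
    spec_error("inadequate planning requires registration: all-trials count (%d) must equal registered count (%d)",
               ra["inadequate_planning"], rr["inadequate_planning"])
  }
  for (k in names(rr)) {
    if (ra[k] < rr[k]) {
      spec_error("all-trials outcome count for %s (%d) below registered count (%d)",
                 k, ra[k], rr[k])
    }
    if (ta[k] < tr[k]) {
      spec_error("all-trials trial count for %s (%d) below registered count (%d)",
                 k, ta[k], tr[k])
    }
    if (tr[k] > ct$n_registered) {
      spec_error("registered trial count for %s (%d) exceeds registered trials (%d)",
                 k, tr[k], ct$n_registered)
    }
    if (tr[k] > rr[k]) {
      spec_error("more affected trials than outcomes for %s in registered scope (%d > %d)",
                 k, tr[k], rr[k])
    }
  }
  for (k in names(ta)) {
    if (ta[k] > ct$n_evaluable) {
      spec_error("trial count for %s (%d) exceeds evaluable trials (%d)",
                 k, ta[k], ct$n_evaluable)
    }
    if (ta[k] > ra[k]) {
      spec_error("more affected trials than outcomes for %s (%d > %d)", k,
                 ta[k], ra[k])
    }
  }
  if (sum(rr) > ct$n_registered * ct$sof_size) {
    spec_error("registered missing outcomes (%d) exceed capacity %d x %d",
               sum(rr), ct$n_registered, ct$sof_size)
  }
  if (sum(ra) - sum(rr) > (ct$n_evaluable - ct$n_registered) * ct$sof_size) {
    spec_error("unregistered missing outcomes exceed capacity")
  }
  if (ct$expert_major > rr["inadequate_planning"]) {
    spec_error("expert_major (%d) exceeds judged outcomes (%d)",
               ct$expert_major, rr["inadequate_planning"])
  }
  if (ct$expert_easy_major > ct$expert_major) {
    spec_error("expert_easy_major (%d) exceeds expert_major (%d)",
               ct$expert_easy_major, ct$expert_major)
  }
  if (ct$total_reporting > ct$partial_reporting ||
      ct$total_planning > ct$partial_planning) {
    spec_error("totally avoidable counts exceed partially avoidable counts")
  }
  if (ct$partial_reporting > ct$partial_planning ||
      ct$total_reporting > ct$total_planning) {
    spec_error("avoidable-waste counts must be non-decreasing from reporting to planning scenario")
  }
  if (ct$partial_planning > ct$n_evaluable) {
    spec_error("partially avoidable trials (%d) exceed evaluable trials (%d)",
               ct$partial_planning, ct$n_evaluable)
  }
  invisible(ct)
}

# blueprint for the evaluable trials: one row per trial, columns = how many
# missing outcomes of each kind the trial carries
evaluable_blueprint <- function(ct) {
  cols <- c("ip_av", "ip_nonav", "sr", "ir", "ind", "oth")
  rr <- ct$reasons_registered; ra <- ct$reasons_all
  tr <- ct$trials_registered; ta <- ct$trials_all
  S <- ct$sof_size

  empty <- function(n) {
    m <- matrix(0L, nrow = n, ncol = length(cols),
                dimnames = list(NULL, cols))
    m
  }
  if (ct$n_evaluable == 0L) {
    if (sum(ra) > 0L) spec_error("missing outcomes specified but no evaluable trials")
    return(list(rows = empty(0), registered = logical(0)))
  }

  # ---- unregistered side -------------------------------------------------
  U <- ct$n_evaluable - ct$n_registered
  u_sr <- ta["selective_reporting"] - tr["selective_reporting"]
  u_ir <- ta["incomplete_reporting"] - tr["incomplete_reporting"]
  u_ind <- ta["indistinguishable"]
  u_oth <- ta["other"] - tr["other"]
  o_sr_u <- ra["selective_reporting"] - rr["selective_reporting"]
  o_ir_u <- ra["incomplete_reporting"] - rr["incomplete_reporting"]
  o_ind_u <- ra["indistinguishable"]
  o_oth_u <- ra["other"] - rr["other"]
  if (u_ind > U) spec_error("indistinguishable trial count (%d) exceeds unregistered trials (%d)",
                            u_ind, U)
  non_ind <- U - u_ind
  ir_only_u <- min(non_ind, u_ir, ct$total_reporting)
  oth_only_u <- non_ind - ir_only_u
  if (oth_only_u > u_oth) {
    spec_error("unregistered trials without indistinguishable outcomes (%d) cannot all carry incomplete-reporting or other outcomes",
               non_ind)
  }
  n_indir <- u_ir - ir_only_u       # IND trials that also have IR
  sr_on_indir <- min(u_sr, n_indir) # SR rides on IND+IR trials first
  sr_overflow <- u_sr - sr_on_indir # then on IND-only trials
  u_partial <- u_ir + sr_overflow
  u_total <- ir_only_u

  # OTHER carriers among IND trials (pure-IND rows preferred)
  pure_avail <- u_ind - n_indir - sr_overflow
  if (pure_avail < 0) spec_error("unregistered category coverage exceeds indistinguishable trials")
  oth_need <- u_oth - oth_only_u
  oth_on_pure <- min(oth_need, pure_avail)
  oth_on_indir <- oth_need - oth_on_pure
  if (oth_on_indir > n_indir) {
    spec_error("unregistered other-category coverage (%d) cannot be placed", u_oth)
  }
  n_pure <- pure_avail - oth_on_pure

  u_rows <- empty(U)
  u_kind <- character(U)
  i <- 0L
  take <- function(n, kind) {
    idx <- i + seq_len(n)
    i <<- i + n
    u_kind[idx] <<- kind
    idx
  }
  idx_ironly  <- take(ir_only_u, "ironly")
  idx_indir   <- take(n_indir, "indir")
  idx_indsr   <- take(sr_overflow, "indsr")
  idx_indoth  <- take(oth_on_pure, "indoth")
  idx_indpure <- take(n_pure, "indpure")
  idx_othonly <- take(oth_only_u, "othonly")
  u_rows[idx_ironly, "ir"] <- 1L
  u_rows[idx_indir, "ir"] <- 1L
  u_rows[idx_indir, "ind"] <- 1L
  if (sr_on_indir > 0) u_rows[idx_indir[seq_len(sr_on_indir)], "sr"] <- 1L
  if (oth_on_indir > 0) u_rows[rev(idx_indir)[seq_len(oth_on_indir)], "oth"] <- 1L
  u_rows[idx_indsr, c("sr", "ind")] <- 1L
  u_rows[idx_indoth, c("oth", "ind")] <- 1L
  u_rows[idx_indpure, "ind"] <- 1L
  u_rows[idx_othonly, "oth"] <- 1L

  add_extras <- function(rows, col, total, member) {
    extra <- total - sum(rows[, col])
    if (extra < 0) spec_error("outcome count for %s below trial coverage", col)
    if (extra > 0) {
      room <- ct$sof_size - rowSums(rows)
      room[!member] <- 0L
      rows[, col] <- rows[, col] + distribute_greedy(extra, room, what = col)
    }
    rows
  }
  u_rows <- add_extras(u_rows, "ind", o_ind_u, u_rows[, "ind"] > 0)
  u_rows <- add_extras(u_rows, "ir", o_ir_u, u_rows[, "ir"] > 0)
  u_rows <- add_extras(u_rows, "sr", o_sr_u, u_rows[, "sr"] > 0)
  u_rows <- add_extras(u_rows, "oth", o_oth_u, u_rows[, "oth"] > 0)

  # ---- registered side ---------------------------------------------------
  R <- ct$n_registered
  p_reg <- ct$partial_reporting - u_partial
  if (p_reg < 0) spec_error("reporting-scenario partial count (%d) below unregistered contribution (%d)",
                            ct$partial_reporting, u_partial)
  nD <- ct$total_reporting - u_total
  if (nD < 0) spec_error("reporting-scenario total count (%d) below unregistered contribution (%d)",
                         ct$total_reporting, u_total)
  nE <- p_reg - nD
  if (nE < 0) spec_error("registered reporting-only trials exceed registered partial trials")
  nA <- ct$total_planning - ct$total_reporting
  nB <- (ct$partial_planning - ct$partial_reporting) - nA
  if (nB < 0) spec_error("planning-scenario total increment exceeds partial increment")
  nC <- tr["inadequate_planning"] - nA - nB - nE
  if (nC < 0) spec_error("inadequate-planning trial coverage (%d) too small for the waste counts",
                         tr["inadequate_planning"])
  nF <- R - (nA + nB + nC + nD + nE)
  if (nF < 0) spec_error("registered trial groups exceed registered trials (%d)", R)
  if (nF > tr["other"]) {
    spec_error("registered trials covered by no category: %d trials need an 'other' outcome but coverage is %d",
               nF, tr["other"])
  }

  tSR <- tr["selective_reporting"]; tIR <- tr["incomplete_reporting"]
  if (nD + nE > 0) {
    if (tSR + tIR < nD + nE) {
      spec_error("selective/incomplete trial coverage (%d) cannot fill %d reporting trials",
                 tSR + tIR, nD + nE)
    }
    if (max(tSR, tIR) > nD + nE) {
      spec_error("selective/incomplete trial coverage exceeds reporting trials")
    }
  } else if (tSR + tIR > 0) {
    spec_error("selective/incomplete coverage specified but no reporting trials")
  }
  n_both <- max(0L, tSR + tIR - (nD + nE))
  n_sronly <- tSR - n_both
  n_ironly <- tIR - n_both
  # membership pool in fixed order; D takes the head, E the tail
  pool <- c(rep("sr", n_sronly), rep("ir", n_ironly), rep("both", n_both))

  r_rows <- empty(R)
  r_kind <- character(R)
  j <- 0L
  rtake <- function(n, kind) {
    idx <- j + seq_len(n)
    j <<- j + n
    r_kind[idx] <<- kind
    idx
  }
  idx_A <- rtake(nA, "A"); idx_B <- rtake(nB, "B"); idx_C <- rtake(nC, "C")
  idx_D <- rtake(nD, "D"); idx_E <- rtake(nE, "E"); idx_F <- rtake(nF, "F")

  r_rows[idx_A, "ip_av"] <- 1L
  r_rows[idx_B, "ip_av"] <- 1L
  r_rows[idx_B, "ip_nonav"] <- 1L
  r_rows[idx_C, "ip_nonav"] <- 1L
  r_rows[idx_E, "ip_nonav"] <- 1L
  de_pool <- pool[seq_len(nD + nE)]
  de_idx <- c(idx_D, idx_E)
  r_rows[de_idx[de_pool %in% c("sr", "both")], "sr"] <- 1L
  r_rows[de_idx[de_pool %in% c("ir", "both")], "ir"] <- 1L
  r_rows[idx_F, "oth"] <- 1L

  # avoidable inadequately planned outcomes live on A (all) and B (one each)
  av_total <- ct$expert_easy_major
  av_A <- av_total - nB
  if (av_A < nA) spec_error("avoidable planned-outcome count (%d) too small for %d all-avoidable trials",
                            av_total, nA)
  if (nA == 0L && av_A > 0L) {
    spec_error("avoidable planned-outcome count (%d) but no all-avoidable trials", av_total)
  }
  if (nA > 0L) {
    r_rows[idx_A, "ip_av"] <- distribute_counts(av_A, nA, min_each = 1L,
                                                cap = S, what = "avoidable planned outcomes")
  }
  nonav_total <- rr["inadequate_planning"] - av_total
  if (nonav_total < 0) spec_error("expert_easy_major exceeds inadequately planned outcomes")
  nonav_rest <- nonav_total - nB - nE
  if (nonav_rest < 0) spec_error("non-avoidable planned outcomes (%d) cannot cover the mixed trials",
                                 nonav_total)
  if (nC > 0L) {
    r_rows[idx_C, "ip_nonav"] <- distribute_counts(nonav_rest, nC, min_each = 1L,
                                                   cap = S, what = "non-avoidable planned outcomes")
  } else if (nonav_rest > 0L) {
    if (nE == 0L) spec_error("non-avoidable planned outcomes (%d) have no trials to land on", nonav_rest)
    room <- S - rowSums(r_rows)
    room[-idx_E] <- 0L
    r_rows[, "ip_nonav"] <- r_rows[, "ip_nonav"] +
      distribute_greedy(nonav_rest, room, what = "non-avoidable planned outcomes")
  }

  radd <- function(rows, col, total, member) {
    extra <- total - sum(rows[, col])
    if (extra < 0) spec_error("registered outcome count for %s below trial coverage", col)
    if (extra > 0) {
      room <- S - rowSums(rows)
      room[!member] <- 0L
      rows[, col] <- rows[, col] + distribute_greedy(extra, room, what = col)
    }
    rows
  }
  r_rows <- radd(r_rows, "sr", rr["selective_reporting"], r_rows[, "sr"] > 0)
  r_rows <- radd(r_rows, "ir", rr["incomplete_reporting"], r_rows[, "ir"] > 0)

  # OTHER carriers: all F trials plus enough A..E trials with room
  extra_carriers <- tr["other"] - nF
  carrier <- r_rows[, "oth"] > 0
  if (extra_carriers > 0L) {
    room <- S - rowSums(r_rows)
    cand <- which(!carrier & room >= 1L)
    if (length(cand) < extra_carriers) {
      spec_error("cannot place %d additional other-category trials", extra_carriers)
    }
    sel <- cand[seq_len(extra_carriers)]
    r_rows[sel, "oth"] <- 1L
    carrier[sel] <- TRUE
  }
  r_rows <- radd(r_rows, "oth", rr["other"], carrier)

  rows <- rbind(r_rows, u_rows)
  registered <- c(rep(TRUE, R), rep(FALSE, U))
  tot <- rowSums(rows)
  if (any(tot < 1L)) spec_error("an evaluable trial ended up with no missing outcome")
  if (any(tot > S)) spec_error("a trial's missing outcomes exceed the SoF size")
  list(rows = rows, registered = registered)
}

#' Build a deterministic corpus from marginal counts
#'
#' Materializes a complete, valid corpus -- reviews, comparisons,
#' summary-of-findings outcomes, trials, annotations, meta-analyses and
#' expert judgments, with systematic ids (`R001`, `R001-C1`, `R001-O1`,
#' `T0001`, ...) -- whose audit statistics reproduce the supplied marginal
#' counts exactly. Contains no randomness: the same counts always yield the
#' same corpus. Internally inconsistent counts raise a
#' `"specification error"` naming the violated constraint.
#'
#' @param counts a [fixture_counts()] specification
#' @return a [corpus()] object
#' @examples
#' ct <- fixture_counts(
#'   n_reviews = 2, sof_size = 2, n_trials = 2, n_included_all = 2,
#'   n_dropped_access = 0, n_dropped_language = 0, n_evaluable = 0,
#'   n_registered = 0, reasons_registered = integer(), reasons_all = integer(),
#'   trials_registered = integer(), trials_all = integer(),
#'   expert_major = 0, expert_easy_major = 0,
#'   partial_reporting = 0, total_reporting = 0,
#'   partial_planning = 0, total_planning = 0,
#'   mean_contribution_pct = NULL
#' )
#' corp <- build_fixture_from_spec(ct)
#' exclusion_stats(corp)$n_excluded_any
#' @export
build_fixture_from_spec <- function(counts = fixture_counts()) {
  ct <- check_fixture_counts(counts)
  S <- ct$sof_size
  bp <- evaluable_blueprint(ct)

  n_excluded <- ct$n_trials - ct$n_included_all
  n_nonev <- n_excluded - ct$n_evaluable
  n_old <- n_nonev - ct$n_dropped_access - ct$n_dropped_language
  missing_eval <- sum(bp$rows)

  if (is.null(ct$mean_contribution_pct)) {
    m_rest <- n_nonev  # minimal: one missing outcome per excluded trial
  } else {
    m_total <- round(S * ct$n_trials * (1 - ct$mean_contribution_pct / 100))
    m_rest <- m_total - missing_eval
  }
  missing_nonev <- distribute_counts(m_rest, n_nonev, min_each = 1L, cap = S,
                                     what = "missing outcomes of non-evaluable trials")

  # ---- master trial table ------------------------------------------------
  # order: evaluable (registered then unregistered), dropped, old excluded,
  # fully included
  n_eval <- ct$n_evaluable
  kind <- c(rep("evaluable", n_eval),
            rep("dropped_access", ct$n_dropped_access),
            rep("dropped_language", ct$n_dropped_language),
            rep("old", n_old),
            rep("included", ct$n_included_all))
  year <- ifelse(kind == "old", ct$old_year, ct$recent_year)
  accessible <- kind != "dropped_access"
  language_ok <- kind != "dropped_language"
  registered <- c(bp$registered, rep(FALSE, ct$n_trials - n_eval))
  n_missing <- c(as.integer(rowSums(bp$rows)),
                 missing_nonev[seq_len(ct$n_dropped_access + ct$n_dropped_language + n_old)] %||% integer(),
                 rep(0L, ct$n_included_all))
  if (length(n_missing) != ct$n_trials) {
    spec_error("trial bookkeeping mismatch (%d rows for %d trials)",
               length(n_missing), ct$n_trials)
  }

  width_t <- max(4L, nchar(as.character(ct$n_trials)))
  trial_ids <- sprintf(paste0("T%0", width_t, "d"), seq_len(ct$n_trials))
  width_r <- max(3L, nchar(as.character(ct$n_reviews)))
  review_ids <- sprintf(paste0("R%0", width_r, "d"), seq_len(ct$n_reviews))

  review_sizes <- distribute_counts(ct$n_trials, ct$n_reviews, min_each = 1L,
                                    what = "trials per review")
  review_of_trial <- rep(seq_len(ct$n_reviews), times = review_sizes)

  n_pharma <- ct$n_pharmacological %||% as.integer(round_half_up(0.6 * ct$n_reviews))
  if (n_pharma > ct$n_reviews) spec_error("n_pharmacological exceeds n_reviews")
  groups <- c("airways", "menstrual disorders and subfertility", "anesthesia",
              "oral health", "schizophrenia", "hepato-biliary",
              "neuromuscular disease", "musculoskeletal",
              "infectious diseases", "other")

  # expert-judgment counters: among the non-avoidable planned outcomes, the
  # first (expert_major - expert_easy_major) are judged of major importance
  # but not easily measurable; the rest are easily measurable but non-major
  nonav_major_left <- ct$expert_major - ct$expert_easy_major
  if (nonav_major_left > sum(bp$rows[, "ip_nonav"])) {
    spec_error("expert importance counts inconsistent with non-avoidable planned outcomes")
  }

  reason_order <- c("ip_av", "ip_nonav", "sr", "ir", "ind", "oth")
  judgment_rows <- list()
  cat_cycle <- 0L

  reviews <- vector("list", ct$n_reviews)
  t_cursor <- 0L
  for (r in seq_len(ct$n_reviews)) {
    rid <- review_ids[r]
    t_idx <- t_cursor + seq_len(review_sizes[r])
    t_cursor <- t_cursor + review_sizes[r]

    out_ids <- sprintf("%s-O%d", rid, seq_len(S))
    outs <- vector("list", S)
    for (k in seq_len(S)) {
      cat_cycle <- cat_cycle + 1L
      outs[[k]] <- sof_outcome(
        out_ids[k],
        categories = OUTCOME_CATEGORIES[(cat_cycle - 1L) %% length(OUTCOME_CATEGORIES) + 1L],
        label = sprintf("outcome %d of %s", k, rid)
      )
    }

    contributors <- stats::setNames(vector("list", S), out_ids)
    for (k in seq_len(S)) contributors[[k]] <- character()

    trials <- vector("list", length(t_idx))
    for (q in seq_along(t_idx)) {
      ti <- t_idx[q]
      tid <- trial_ids[ti]
      m <- n_missing[ti]
      reasons <- character(0)
      if (kind[ti] == "evaluable") {
        row <- bp$rows[ti, ]
        reasons <- rep(reason_order, times = row[reason_order])
      } else if (m > 0L) {
        reasons <- rep("ind", m)
      }
      ann <- vector("list", S)
      names(ann) <- out_ids
      is_reg <- registered[ti]
      for (k in seq_len(S)) {
        if (k <= length(reasons)) {
          ann[[k]] <- switch(
            reasons[k],
            ip_av = ,
            ip_nonav = outcome_annotation(FALSE, planned = "no",
                                          reported = FALSE),
            sr = if (is_reg) {
              outcome_annotation(FALSE, planned = "yes", reported = FALSE)
            } else {
              outcome_annotation(FALSE, planned = "unknown",
                                 planned_in_publication_methods = TRUE,
                                 reported = FALSE)
            },
            ir = outcome_annotation(FALSE,
                                    planned = if (is_reg) "yes" else "unknown",
                                    reported = TRUE, poolable = "no"),
            ind = outcome_annotation(FALSE, planned = "unknown",
                                     reported = FALSE),
            oth = outcome_annotation(FALSE,
                                     planned = if (is_reg) "yes" else "unknown",
                                     reported = TRUE, poolable = "no",
                                     zero_event = TRUE)
          )
          if (reasons[k] %in% c("ip_av", "ip_nonav")) {
            if (reasons[k] == "ip_av") {
              jr <- expert_judgment(tid, out_ids[k], "easy", "easy", "no_cost",
                                    "major")
            } else if (nonav_major_left > 0L) {
              nonav_major_left <- nonav_major_left - 1L
              jr <- expert_judgment(tid, out_ids[k], "difficult", "easy",
                                    "no_cost", "major")
            } else {
              jr <- expert_judgment(tid, out_ids[k], "easy", "easy", "no_cost",
                                    "non_major")
            }
            judgment_rows[[length(judgment_rows) + 1L]] <- jr
          }
        } else {
          ann[[k]] <- outcome_annotation(TRUE,
                                         planned = if (is_reg) "yes" else "unknown",
                                         reported = TRUE, poolable = "yes")
          contributors[[k]] <- c(contributors[[k]], tid)
        }
      }
      trials[[q]] <- trial_record(tid, publication_year = year[ti],
                                  accessible = accessible[ti],
                                  language_ok = language_ok[ti],
                                  registration_found = registered[ti],
                                  annotations = ann)
    }

    mas <- lapply(out_ids, function(oid) meta_analysis(oid, contributors[[oid]]))
    cp <- comparison(sprintf("%s-C1", rid), sof_outcomes = outs,
                     meta_analyses = mas, trial_ids = trial_ids[t_idx],
                     author_designated_main = TRUE)
    reviews[[r]] <- review(
      rid, comparisons = list(cp), trials = trials,
      review_group = groups[(r - 1L) %% length(groups) + 1L],
      intervention_type = if (r <= n_pharma) "pharmacological" else "non_pharmacological"
    )
  }

  jd <- if (length(judgment_rows)) dplyr::bind_rows(judgment_rows) else empty_judgments()
  corpus(reviews, judgments = jd)
}
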