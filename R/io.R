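# Canonical interchange: nested JSON (authoritative) and an equivalent flat
# CSV bundle. Serialization is deterministic -- reviews, trials, annotation
# keys and judgment rows are emitted in sorted order with a fixed key order --
# so repeated writes of the same corpus are byte-identical.

annotation_to_list <- function(a) {
  list(
    in_meta_analysis = a$in_meta_analysis,
    planned = a$planned,
    planned_in_publication_methods = a$planned_in_publication_methods,
    reported = a$reported,
    poolable = a$poolable,
    zero_event = a$zero_event,
    reported_not_pooled = a$reported_not_pooled
  )
}

corpus_to_list <- function(corpus) {
  reviews <- corpus$reviews
  rids <- vapply(reviews, function(r) r$review_id, character(1))
  reviews <- reviews[order(rids)]
  jd <- corpus$judgments
  jd <- jd[order(jd$trial_id, jd$outcome_id), , drop = FALSE]
  list(
    schema_version = corpus$schema_version,
    reviews = lapply(reviews, function(rv) {
      trials <- rv$trials
      tids <- vapply(trials, function(t) t$trial_id, character(1))
      trials <- trials[order(tids)]
      list(
        review_id = rv$review_id,
        review_group = rv$review_group,
        intervention_type = rv$intervention_type,
        withdrawn = rv$withdrawn,
        includes_observational = rv$includes_observational,
        sof_mixes_interventions = rv$sof_mixes_interventions,
        comparisons = lapply(rv$comparisons, function(cp) {
          list(
            comparison_id = cp$comparison_id,
            author_designated_main = cp$author_designated_main,
            sof_outcomes = lapply(cp$sof_outcomes, function(o) {
              list(outcome_id = o$outcome_id, label = o$label,
                   categories = I(as.list(o$categories)))
            }),
            meta_analyses = lapply(cp$meta_analyses, function(m) {
              list(outcome_id = m$outcome_id,
                   contributing_trial_ids = I(as.list(m$contributing_trial_ids)))
            }),
            trial_ids = I(as.list(cp$trial_ids))
          )
        }),
        trials = lapply(trials, function(tr) {
          ann <- tr$annotations[order(names(tr$annotations))]
          list(
            trial_id = tr$trial_id,
            publication_year = if (is.na(tr$publication_year)) NULL else tr$publication_year,
            accessible = tr$accessible,
            language_ok = tr$language_ok,
            registration_found = tr$registration_found,
            annotations = lapply(ann, annotation_to_list)
          )
        })
      )
    }),
    judgments = lapply(seq_len(nrow(jd)), function(i) as.list(jd[i, ]))
  )
}

corpus_from_list <- function(x) {
  if (is.null(x$schema_version) || !identical(as.character(x$schema_version), "1")) {
    stop(sprintf("unsupported corpus schema_version: %s",
                 x$schema_version %||% "<missing>"), call. = FALSE)
  }
  reviews <- lapply(x$reviews, function(rv) {
    review(
      review_id = rv$review_id,
      review_group = rv$review_group %||% "unspecified",
      intervention_type = rv$intervention_type %||% "pharmacological",
      withdrawn = isTRUE(rv$withdrawn),
      includes_observational = isTRUE(rv$includes_observational),
      sof_mixes_interventions = isTRUE(rv$sof_mixes_interventions),
      comparisons = lapply(rv$comparisons, function(cp) {
        comparison(
          comparison_id = cp$comparison_id,
          author_designated_main = isTRUE(cp$author_designated_main),
          sof_outcomes = lapply(cp$sof_outcomes, function(o) {
            sof_outcome(o$outcome_id, categories = unlist(o$categories),
                        label = o$label %||% o$outcome_id)
          }),
          meta_analyses = lapply(cp$meta_analyses, function(m) {
            meta_analysis(m$outcome_id,
                          contributing_trial_ids = unlist(m$contributing_trial_ids) %||% character())
          }),
          trial_ids = unlist(cp$trial_ids) %||% character()
        )
      }),
      trials = lapply(rv$trials, function(tr) {
        ann <- lapply(tr$annotations, function(a) {
          outcome_annotation(
            in_meta_analysis = isTRUE(a$in_meta_analysis),
            planned = a$planned %||% "unknown",
            planned_in_publication_methods = isTRUE(a$planned_in_publication_methods),
            reported = isTRUE(a$reported),
            poolable = a$poolable %||% "not_applicable",
            zero_event = isTRUE(a$zero_event),
            reported_not_pooled = isTRUE(a$reported_not_pooled)
          )
        })
        trial_record(
          trial_id = tr$trial_id,
          publication_year = tr$publication_year %||% NA_integer_,
          accessible = isTRUE(tr$accessible %||% TRUE),
          language_ok = isTRUE(tr$language_ok %||% TRUE),
          registration_found = isTRUE(tr$registration_found),
          annotations = ann
        )
      })
    )
  })
  jd <- if (length(x$judgments)) {
    dplyr::bind_rows(lapply(x$judgments, function(j) {
      expert_judgment(j$trial_id, j$outcome_id, j$feasibility_trialist,
                      j$feasibility_patient, j$cost, j$importance)
    }))
  } else {
    empty_judgments()
  }
  corpus(reviews, judgments = jd, schema_version = "1")
}

corpus_json_string <- function(corpus) {
  jsonlite::toJSON(corpus_to_list(corpus), auto_unbox = TRUE, pretty = 2,
                   digits = NA, null = "null")
}

#' Test two corpora for structural identity
#'
#' Compares the canonical serialized forms, so object-internal list ordering
#' (trial order, annotation key order) is ignored.
#'
#' @param a,b corpora
#' @return logical scalar
#' @export
corpus_identical <- function(a, b) {
  identical(as.character(corpus_json_string(a)), as.character(corpus_json_string(b)))
}

stop_on_violations <- function(violations, where) {
  if (nrow(violations) > 0L) {
    v <- violations[1, ]
    stop(sprintf("invalid corpus in %s: %d violation(s); first: [%s] %s",
                 where, nrow(violations), v$rule, v$message), call. = FALSE)
  }
}

#' Write a corpus to disk
#'
#' `"json"` writes a single nested file (the authoritative format);
#' `"csv_bundle"` writes six flat UTF-8 CSV files (`reviews.csv`,
#' `comparisons.csv`, `outcomes.csv`, `trials.csv`, `annotations.csv`,
#' `judgments.csv`) into the directory `path`. Both serializations are
#' deterministic: writing the same corpus twice produces byte-identical
#' files.
#'
#' @param corpus a validated [corpus()]
#' @param path file path (json) or directory (csv_bundle)
#' @param format `"json"` or `"csv_bundle"`
#' @return invisibly, the character vector of files written
#' @export
write_corpus <- function(corpus, path, format = c("json", "csv_bundle")) {
  format <- match.arg(format)
  if (format == "json") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(as.character(corpus_json_string(corpus)), con, sep = "\n",
               useBytes = TRUE)
    return(invisible(path))
  }
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  tabs <- corpus_to_tables(corpus)
  files <- character()
  for (nm in names(tabs)) {
    f <- file.path(path, paste0(nm, ".csv"))
    readr::write_csv(tabs[[nm]], f, eol = "\n", progress = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read a corpus from disk
#'
#' Reads either the canonical JSON file or a CSV bundle directory, rebuilds
#' the fully linked object graph, and runs [validate_corpus()]; any
#' violation is raised as an error naming the offending record and rule.
#'
#' @param path file path (json) or directory (csv_bundle)
#' @param format `"json"` or `"csv_bundle"`
#' @return a [corpus()] object
#' @export
read_corpus <- function(path, format = c("json", "csv_bundle")) {
  format <- match.arg(format)
  if (format == "json") {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
    x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    out <- corpus_from_list(x)
  } else {
    if (!dir.exists(path)) stop(sprintf("directory not found: %s", path), call. = FALSE)
    out <- corpus_from_tables(read_bundle_tables(path))
  }
  stop_on_violations(validate_corpus(out), path)
  out
}

# ---- flat (CSV bundle) view -------------------------------------------

corpus_to_tables <- function(corpus) {
  reviews <- corpus$reviews
  rids <- vapply(reviews, function(r) r$review_id, character(1))
  reviews <- reviews[order(rids)]

  rev_rows <- list(); cmp_rows <- list(); out_rows <- list()
  tri_rows <- list(); ann_rows <- list()

  for (rv in reviews) {
    rev_rows[[length(rev_rows) + 1L]] <- tibble::tibble(
      review_id = rv$review_id, review_group = rv$review_group,
      intervention_type = rv$intervention_type, withdrawn = rv$withdrawn,
      includes_observational = rv$includes_observational,
      sof_mixes_interventions = rv$sof_mixes_interventions
    )
    for (k in seq_along(rv$comparisons)) {
      cp <- rv$comparisons[[k]]
      cmp_rows[[length(cmp_rows) + 1L]] <- tibble::tibble(
        review_id = rv$review_id, comparison_id = cp$comparison_id,
        position = k, author_designated_main = cp$author_designated_main,
        trial_ids = paste(cp$trial_ids, collapse = "|")
      )
      ma_index <- stats::setNames(
        cp$meta_analyses,
        vapply(cp$meta_analyses, function(m) m$outcome_id, character(1))
      )
      for (j in seq_along(cp$sof_outcomes)) {
        o <- cp$sof_outcomes[[j]]
        m <- ma_index[[o$outcome_id]]
        out_rows[[length(out_rows) + 1L]] <- tibble::tibble(
          review_id = rv$review_id, comparison_id = cp$comparison_id,
          outcome_id = o$outcome_id, position = j, label = o$label,
          category = o$categories,
          has_meta_analysis = !is.null(m),
          contributing_trial_ids = if (is.null(m)) "" else
            paste(m$contributing_trial_ids, collapse = "|")
        )
      }
    }
    trials <- rv$trials[order(vapply(rv$trials, function(t) t$trial_id, character(1)))]
    for (tr in trials) {
      tri_rows[[length(tri_rows) + 1L]] <- tibble::tibble(
        review_id = rv$review_id, trial_id = tr$trial_id,
        publication_year = tr$publication_year, accessible = tr$accessible,
        language_ok = tr$language_ok, registration_found = tr$registration_found
      )
      for (oid in sort(names(tr$annotations))) {
        a <- tr$annotations[[oid]]
        ann_rows[[length(ann_rows) + 1L]] <- tibble::tibble(
          review_id = rv$review_id, trial_id = tr$trial_id, outcome_id = oid,
          in_meta_analysis = a$in_meta_analysis, planned = a$planned,
          planned_in_publication_methods = a$planned_in_publication_methods,
          reported = a$reported, poolable = a$poolable,
          zero_event = a$zero_event, reported_not_pooled = a$reported_not_pooled
        )
      }
    }
  }
  jd <- corpus$judgments
  jd <- jd[order(jd$trial_id, jd$outcome_id), , drop = FALSE]
  list(
    reviews = dplyr::bind_rows(rev_rows),
    comparisons = dplyr::bind_rows(cmp_rows),
    outcomes = dplyr::bind_rows(out_rows),
    trials = dplyr::bind_rows(tri_rows),
    annotations = dplyr::bind_rows(ann_rows),
    judgments = jd
  )
}

read_bundle_tables <- function(dir) {
  need <- c("reviews", "comparisons", "outcomes", "trials", "annotations",
            "judgments")
  tabs <- list()
  for (nm in need) {
    f <- file.path(dir, paste0(nm, ".csv"))
    if (!file.exists(f)) stop(sprintf("missing bundle file: %s", f), call. = FALSE)
    tabs[[nm]] <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
  }
  tabs
}

split_ids <- function(s) {
  if (is.na(s) || !nzchar(s)) character() else strsplit(s, "|", fixed = TRUE)[[1]]
}

corpus_from_tables <- function(tabs) {
  rt <- tabs$reviews
  reviews <- lapply(seq_len(nrow(rt)), function(i) {
    rid <- rt$review_id[i]
    cmp_t <- tabs$comparisons[tabs$comparisons$review_id == rid, , drop = FALSE]
    cmp_t <- cmp_t[order(cmp_t$position), , drop = FALSE]
    comparisons <- lapply(seq_len(nrow(cmp_t)), function(k) {
      cid <- cmp_t$comparison_id[k]
      ot <- tabs$outcomes[tabs$outcomes$comparison_id == cid &
                            tabs$outcomes$review_id == rid, , drop = FALSE]
      ot <- ot[order(ot$position), , drop = FALSE]
      outs <- list(); mas <- list()
      for (oid in unique(ot$outcome_id)) {
        rows <- ot[ot$outcome_id == oid, , drop = FALSE]
        outs[[length(outs) + 1L]] <- sof_outcome(
          oid, categories = rows$category, label = rows$label[1]
        )
        if (isTRUE(rows$has_meta_analysis[1])) {
          mas[[length(mas) + 1L]] <- meta_analysis(
            oid, contributing_trial_ids = split_ids(rows$contributing_trial_ids[1])
          )
        }
      }
      comparison(cid, sof_outcomes = outs, meta_analyses = mas,
                 trial_ids = split_ids(cmp_t$trial_ids[k]),
                 author_designated_main = isTRUE(cmp_t$author_designated_main[k]))
    })
    tt <- tabs$trials[tabs$trials$review_id == rid, , drop = FALSE]
    trials <- lapply(seq_len(nrow(tt)), function(j) {
      tid <- tt$trial_id[j]
      at <- tabs$annotations[tabs$annotations$trial_id == tid, , drop = FALSE]
      ann <- stats::setNames(lapply(seq_len(nrow(at)), function(q) {
        outcome_annotation(
          in_meta_analysis = isTRUE(at$in_meta_analysis[q]),
          planned = at$planned[q],
          planned_in_publication_methods = isTRUE(at$planned_in_publication_methods[q]),
          reported = isTRUE(at$reported[q]),
          poolable = at$poolable[q],
          zero_event = isTRUE(at$zero_event[q]),
          reported_not_pooled = isTRUE(at$reported_not_pooled[q])
        )
      }), at$outcome_id)
      trial_record(tid, publication_year = tt$publication_year[j],
                   accessible = isTRUE(tt$accessible[j]),
                   language_ok = isTRUE(tt$language_ok[j]),
                   registration_found = isTRUE(tt$registration_found[j]),
                   annotations = ann)
    })
    review(rid, comparisons = comparisons, trials = trials,
           review_group = rt$review_group[i],
           intervention_type = rt$intervention_type[i],
           withdrawn = isTRUE(rt$withdrawn[i]),
           includes_observational = isTRUE(rt$includes_observational[i]),
           sof_mixes_interventions = isTRUE(rt$sof_mixes_interventions[i]))
  })
  jd <- tibble::as_tibble(tabs$judgments)
  if (nrow(jd) == 0L) jd <- empty_judgments()
  corpus(reviews, judgments = jd)
}
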