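# Read-only reader for a subset of RevMan 5 review XML: the ANALYSES_AND_DATA
# section (COMPARISON / DICH_OUTCOME / CONT_OUTCOME with their
# DICH_DATA / CONT_DATA study linkage) and the included-studies list.
# Which analysis outcomes constitute the summary-of-findings set is not
# reliably machine-readable in RevMan XML, so it is supplied as a sidecar.

#' Read a review from a RevMan 5 XML subset
#'
#' Parses the analyses section of a RevMan 5 review file and builds a
#' [review()]: one [comparison()] per `COMPARISON` element, one
#' [sof_outcome()] + [meta_analysis()] per sidecar-listed outcome, and one
#' [trial_record()] per linked or included study. Trial-level evidence
#' fields are initialized for later manual annotation: `in_meta_analysis`
#' is set from the study linkage, everything else defaults to
#' unknown/unreported (`registration_found = FALSE`, `planned = "unknown"`;
#' a contributing outcome is marked reported and poolable, as the model
#' requires). Publication years are taken from the `YEAR` attribute of
#' `STUDY` elements when present, `NA` otherwise.
#'
#' @param path path to a RevMan 5 review XML file (or an `xml2` document)
#' @param sof_sidecar which analysis outcomes constitute the
#'   summary-of-findings set: either a character vector of outcome ids
#'   (categories default to `"other_clinical_event"`) or a data frame with
#'   columns `outcome_id` and `category` (one row per outcome-category
#'   pair). Ids must exist in the analyses section.
#' @param review_id identifier for the resulting review (default: the
#'   document's `ID` attribute, or `"REVMAN"`)
#' @return a [review()] object whose comparisons carry only the
#'   sidecar-listed outcomes; comparisons with none are dropped
#' @export
read_revman_subset <- function(path, sof_sidecar, review_id = NULL) {
  doc <- if (inherits(path, "xml_document")) path else {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
    xml2::read_xml(path)
  }
  if (xml2::xml_name(doc) != "COCHRANE_REVIEW") {
    stop(sprintf("not a RevMan 5 review document (root element <%s>)",
                 xml2::xml_name(doc)), call. = FALSE)
  }
  if (is.data.frame(sof_sidecar)) {
    if (!all(c("outcome_id", "category") %in% names(sof_sidecar))) {
      stop("sidecar data frame needs columns outcome_id and category",
           call. = FALSE)
    }
    sof_ids <- unique(sof_sidecar$outcome_id)
    sof_cats <- lapply(stats::setNames(sof_ids, sof_ids), function(oid) {
      sof_sidecar$category[sof_sidecar$outcome_id == oid]
    })
  } else {
    sof_ids <- unique(as.character(sof_sidecar))
    sof_cats <- lapply(stats::setNames(sof_ids, sof_ids),
                       function(oid) "other_clinical_event")
  }
  if (length(sof_ids) == 0L) {
    stop("sidecar lists no summary-of-findings outcomes", call. = FALSE)
  }

  review_id <- review_id %||% xml2::xml_attr(doc, "ID") %||% "REVMAN"
  if (is.na(review_id)) review_id <- "REVMAN"

  # study years from the included-studies list (optional in the subset)
  study_year <- list()
  for (st in xml2::xml_find_all(doc, ".//STUDIES_AND_REFERENCES//STUDY")) {
    sid <- xml2::xml_attr(st, "ID")
    yr <- xml2::xml_attr(st, "YEAR")
    if (!is.na(sid)) {
      study_year[[sid]] <- if (is.na(yr)) NA_integer_ else
        suppressWarnings(as.integer(yr))
    }
  }

  seen_ids <- character()
  comparisons <- list()
  trial_in_meta <- list()  # trial_id -> character vector of outcome ids
  all_trials <- character()

  for (cmp in xml2::xml_find_all(doc, ".//ANALYSES_AND_DATA/COMPARISON")) {
    cid <- xml2::xml_attr(cmp, "ID")
    if (is.na(cid)) cid <- sprintf("%s-CMP%d", review_id, length(comparisons) + 1L)
    outs <- list()
    mas <- list()
    cmp_trials <- character()
    for (node in xml2::xml_find_all(cmp, "./DICH_OUTCOME | ./CONT_OUTCOME")) {
      oid <- xml2::xml_attr(node, "ID")
      seen_ids <- c(seen_ids, oid)
      studies <- xml2::xml_attr(
        xml2::xml_find_all(node, "./DICH_DATA | ./CONT_DATA"), "STUDY_ID")
      studies <- unique(studies[!is.na(studies)])
      cmp_trials <- c(cmp_trials, studies)
      if (!oid %in% sof_ids) next
      name <- xml2::xml_text(xml2::xml_find_first(node, "./NAME"))
      outs[[length(outs) + 1L]] <- sof_outcome(
        oid, categories = sof_cats[[oid]],
        label = if (is.na(name) || !nzchar(name)) oid else name
      )
      mas[[length(mas) + 1L]] <- meta_analysis(oid, studies)
      for (sid in studies) {
        trial_in_meta[[sid]] <- c(trial_in_meta[[sid]], oid)
      }
    }
    all_trials <- c(all_trials, cmp_trials)
    if (length(outs) == 0L) next
    comparisons[[length(comparisons) + 1L]] <- comparison(
      cid, sof_outcomes = outs, meta_analyses = mas, trial_ids = cmp_trials
    )
  }

  missing_sidecar <- setdiff(sof_ids, unique(seen_ids))
  if (length(missing_sidecar)) {
    stop(sprintf("sidecar outcome id(s) not found in the analyses section: %s",
                 paste(missing_sidecar, collapse = ", ")), call. = FALSE)
  }
  if (length(comparisons) == 0L) {
    stop("no comparison carries a sidecar-listed outcome", call. = FALSE)
  }

  # trials annotated for the main comparison's outcomes
  rv0 <- review(review_id, comparisons = comparisons)
  main_cp <- get_comparison(rv0, select_main_comparison(rv0))
  main_out <- vapply(main_cp$sof_outcomes, function(o) o$outcome_id, character(1))
  trial_ids <- sort(unique(c(all_trials, names(study_year))))
  trials <- lapply(trial_ids, function(tid) {
    ann <- stats::setNames(lapply(main_out, function(oid) {
      if (tid %in% main_cp$trial_ids &&
          oid %in% (trial_in_meta[[tid]] %||% character())) {
        outcome_annotation(TRUE, planned = "unknown", reported = TRUE,
                           poolable = "yes")
      } else {
        outcome_annotation(FALSE, planned = "unknown", reported = FALSE)
      }
    }), main_out)
    trial_record(tid, publication_year = study_year[[tid]] %||% NA_integer_,
                 annotations = ann)
  })

  review(review_id, comparisons = comparisons, trials = trials)
}
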