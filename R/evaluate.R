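# Rule evaluation: structured predicates over a patient record.
#
# Only regular (non-SOS) medications are visible to drug predicates; a
# missing qualifier means "benefit of the doubt" (the predicate is FALSE,
# so rules conditioned on a qualifier do not fire and rules negating one
# do).

matches_prefix <- function(codes, class_def) {
  if (!length(codes)) return(logical(0))
  hit <- function(prefixes) {
    if (!length(prefixes)) return(rep(FALSE, length(codes)))
    Reduce(`|`, lapply(prefixes, function(p) startsWith(codes, p)))
  }
  hit(class_def$include) & !hit(class_def$exclude)
}

# Rows of the patient's regular medication list matching a declared class.
class_rows <- function(patient, catalog, class_name) {
  meds <- regular_medications(patient)
  cl <- catalog$drug_classes[[class_name]]
  if (is.null(cl))
    stop("unknown drug class '", class_name, "'", call. = FALSE)
  meds[matches_prefix(meds$drug_code, cl), , drop = FALSE]
}

eval_condition <- function(node, patient, catalog) {
  key <- names(node)
  body <- node[[1]]
  switch(key,
    all = all(vapply(body, eval_condition, logical(1), patient = patient,
                     catalog = catalog)),
    any = any(vapply(body, eval_condition, logical(1), patient = patient,
                     catalog = catalog)),
    not = !eval_condition(body, patient, catalog),
    has_drug_class = {
      rows <- class_rows(patient, catalog, body$class)
      if (!is.null(body$min_duration_days))
        rows <- rows[rows$duration_days >= body$min_duration_days, ,
                     drop = FALSE]
      nrow(rows) > 0L
    },
    lacks_drug_class = nrow(class_rows(patient, catalog, body$class)) == 0L,
    drug_class_count_ge =
      nrow(class_rows(patient, catalog, body$class)) >= body$min_count,
    duplicate_drug_class = {
      meds <- regular_medications(patient)
      # duplicate class: two distinct entries within the same ATC chemical
      # subgroup (first five characters)
      cls <- substr(meds$drug_code, 1L, 5L)
      any(duplicated(cls))
    },
    co_prescribed =
      nrow(class_rows(patient, catalog, body$class_a)) > 0L &&
      nrow(class_rows(patient, catalog, body$class_b)) > 0L,
    has_condition = body %in% patient$diagnoses,
    qualifier = body %in% patient$qualifiers,
    flag = isTRUE(patient[[body]]),
    age_gt = patient$age_years > body,
    stop("unknown condition primitive '", key, "'", call. = FALSE)
  )
}

#' Screen one patient against a criteria catalog
#'
#' Evaluates every rule in the catalog against the patient and returns the
#' sets of fired STOPP (PIM) and START (PPO) criterion ids. A criterion
#' contributes at most once per patient, but a single drug may fire several
#' criteria (a benzodiazepine taken for 28 days or more fires both the
#' duration rule and the falls-risk rule).
#'
#' @param patient A [patient_record()].
#' @param catalog A `criteria_catalog`, see [load_catalog()].
#' @return A list of class `screening_result` with `patient_id`,
#'   `stopp_ids`, `start_ids`, `n_pims`, `n_ppos`.
#' @export
#' @examples
#' p <- patient_record("p1", 80, "female",
#'   medications = medication("N05BA06", duration_days = 60))
#' evaluate_patient(p, default_catalog())
evaluate_patient <- function(patient, catalog) {
  stopifnot(inherits(patient, "patient_record"),
            inherits(catalog, "criteria_catalog"))
  fired <- vapply(catalog$rules, function(r) {
    isTRUE(eval_condition(r$condition, patient, catalog))
  }, logical(1))
  ids <- vapply(catalog$rules, function(r) r$id, character(1))
  tools <- vapply(catalog$rules, function(r) r$tool, character(1))
  stopp_ids <- ids[fired & tools == "STOPP"]
  start_ids <- ids[fired & tools == "START"]
  structure(
    list(patient_id = patient$id,
         stopp_ids = stopp_ids,
         start_ids = start_ids,
         n_pims = length(stopp_ids),
         n_ppos = length(start_ids)),
    class = "screening_result"
  )
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result %s: %d PIMs [%s], %d PPOs [%s]>\n",
              x$patient_id, x$n_pims, paste(x$stopp_ids, collapse = ","),
              x$n_ppos, paste(x$start_ids, collapse = ",")))
  invisible(x)
}

#' Screen a whole cohort
#'
#' @param cohort List of [patient_record()]s.
#' @param catalog A `criteria_catalog`.
#' @return List of `screening_result`s, one per patient, in cohort order.
#' @export
screen_cohort <- function(cohort, catalog = default_catalog()) {
  lapply(cohort, evaluate_patient, catalog = catalog)
}

#' Write screening results as delimited text
#'
#' One row per patient with the fired criterion ids semicolon-joined.
#'
#' @param results List of `screening_result`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_screening <- function(results, path) {
  tab <- data.frame(
    patient_id = vapply(results, function(r) r$patient_id, character(1)),
    n_pims = vapply(results, function(r) r$n_pims, integer(1)),
    n_ppos = vapply(results, function(r) r$n_ppos, integer(1)),
    stopp_ids = vapply(results, function(r)
      paste(r$stopp_ids, collapse = ";"), character(1)),
    start_ids = vapply(results, function(r)
      paste(r$start_ids, collapse = ";"), character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
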