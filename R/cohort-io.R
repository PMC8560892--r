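#' Cohort file input/output
#'
#' Cohorts are exchanged as UTF-8 comma-separated text, one row per patient.
#' Multi-valued fields are semicolon-joined inside a cell: `diagnoses` and
#' `qualifiers` as plain label lists, `medications` as
#' `code:duration_days:daily_doses:flags` where `flags` is a compact string
#' containing `S` for an as-needed (SOS) entry and `C` for a fixed-dose
#' combination (empty means regular, single-product). Boolean covariates are
#' `0`/`1`. Writing then reading a cohort reproduces every field.
#'
#' @param path File path.
#' @param cohort A list of [patient_record()] objects.
#' @return `read_cohort()` returns a list of `patient_record`s;
#'   `write_cohort()` returns `path` invisibly.
#' @name cohort_io
NULL

cohort_columns <- function() {
  c("id", "age_years", "gender", "provenience", "discharge",
    "length_of_stay_days", "diagnoses", "qualifiers", "medications",
    patient_flag_fields())
}

format_medications <- function(meds) {
  if (!nrow(meds)) return("")
  flags <- paste0(ifelse(meds$is_regular, "", "S"),
                  ifelse(meds$is_fixed_combination, "C", ""))
  paste(sprintf("%s:%d:%d:%s", meds$drug_code, meds$duration_days,
                meds$daily_doses, flags), collapse = ";")
}

parse_medications <- function(cell, row) {
  if (is.na(cell) || !nzchar(cell)) return(empty_medications())
  parts <- strsplit(strsplit(cell, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(parts, function(p) length(p) < 3L || !nzchar(p[1]), logical(1))
  if (any(bad))
    stop(sprintf("row %d: malformed medication sub-field '%s'", row, cell),
         call. = FALSE)
  do.call(rbind, lapply(parts, function(p) {
    flags <- if (length(p) >= 4L) p[4] else ""
    dur <- suppressWarnings(as.integer(p[2]))
    dose <- suppressWarnings(as.integer(p[3]))
    if (is.na(dur) || is.na(dose))
      stop(sprintf("row %d: malformed medication sub-field '%s'",
                   row, paste(p, collapse = ":")), call. = FALSE)
    medication(p[1], is_regular = !grepl("S", flags, fixed = TRUE),
               duration_days = dur, daily_doses = dose,
               is_fixed_combination = grepl("C", flags, fixed = TRUE))
  }))
}

split_labels <- function(cell) {
  if (is.na(cell) || !nzchar(cell)) return(character())
  strsplit(cell, ";", fixed = TRUE)[[1]]
}

#' @rdname cohort_io
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.list(cohort))
  rows <- lapply(cohort, function(p) {
    stopifnot(inherits(p, "patient_record"))
    base <- data.frame(
      id = p$id, age_years = p$age_years, gender = p$gender,
      provenience = p$provenience, discharge = p$discharge,
      length_of_stay_days = p$length_of_stay_days,
      diagnoses = paste(p$diagnoses, collapse = ";"),
      qualifiers = paste(p$qualifiers, collapse = ";"),
      medications = format_medications(p$medications),
      stringsAsFactors = FALSE
    )
    for (f in patient_flag_fields()) base[[f]] <- as.integer(p[[f]])
    base
  })
  tab <- if (length(rows)) do.call(rbind, rows) else {
    empty <- as.data.frame(setNames(rep(list(character(0)),
                                        length(cohort_columns())),
                                    cohort_columns()))
    empty
  }
  utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         fileEncoding = "UTF-8")
  missing_cols <- setdiff(cohort_columns(), names(tab))
  if (length(missing_cols))
    stop("cohort file is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!nrow(tab)) return(list())
  lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    age <- suppressWarnings(as.integer(r$age_years))
    if (is.na(age))
      stop(sprintf("row %d: age_years '%s' is not an integer", i, r$age_years),
           call. = FALSE)
    if (age < 65L)
      stop(sprintf(paste0("row %d: age %d violates the inclusion criterion ",
                          "(patients aged >= 65 years)"), i, age),
           call. = FALSE)
    flags <- lapply(patient_flag_fields(), function(f) {
      v <- suppressWarnings(as.integer(r[[f]]))
      if (is.na(v) || !v %in% c(0L, 1L))
        stop(sprintf("row %d: flag %s must be 0 or 1", i, f), call. = FALSE)
      v == 1L
    })
    names(flags) <- patient_flag_fields()
    tryCatch(
      do.call(patient_record, c(
        list(id = r$id, age_years = age, gender = r$gender,
             provenience = r$provenience, discharge = r$discharge,
             length_of_stay_days = as.integer(r$length_of_stay_days),
             diagnoses = split_labels(r$diagnoses),
             qualifiers = split_labels(r$qualifiers),
             medications = parse_medications(r$medications, i)),
        flags
      )),
      error = function(e) {
        stop(sprintf("row %d: %s", i, conditionMessage(e)), call. = FALSE)
      }
    )
  })
}
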