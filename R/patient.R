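#' Construct a medication entry
#'
#' One row of a patient's therapeutic list. A fixed-dose combination is a
#' single entry (it counts as one medication); as-needed (SOS) entries are
#' kept on the record but excluded from all counts and screening rules.
#'
#' @param drug_code ATC-style class code, e.g. `"N05BA"` or `"N05BA06"`.
#' @param is_regular `TRUE` for regular intake, `FALSE` for as-needed (SOS).
#' @param duration_days Non-negative integer, days on the drug.
#' @param daily_doses Positive integer, administrations per day.
#' @param is_fixed_combination `TRUE` when the entry is a fixed-dose
#'   combination product.
#' @return A one-row `data.frame` with the five medication fields.
#' @export
#' @examples
#' medication("N05BA06", duration_days = 60)
medication <- function(drug_code, is_regular = TRUE, duration_days = 0L,
                       daily_doses = 1L, is_fixed_combination = FALSE) {
  stopifnot(is.character(drug_code), length(drug_code) == 1L,
            nzchar(drug_code))
  duration_days <- as.integer(duration_days)
  daily_doses <- as.integer(daily_doses)
  if (is.na(duration_days) || duration_days < 0L)
    stop("duration_days must be a non-negative integer", call. = FALSE)
  if (is.na(daily_doses) || daily_doses < 1L)
    stop("daily_doses must be a positive integer", call. = FALSE)
  data.frame(
    drug_code = drug_code,
    is_regular = isTRUE(is_regular),
    duration_days = duration_days,
    daily_doses = daily_doses,
    is_fixed_combination = isTRUE(is_fixed_combination),
    stringsAsFactors = FALSE
  )
}

empty_medications <- function() {
  data.frame(
    drug_code = character(), is_regular = logical(),
    duration_days = integer(), daily_doses = integer(),
    is_fixed_combination = logical(), stringsAsFactors = FALSE
  )
}

#' Construct a patient record
#'
#' One admitted patient: demographics, coded diagnoses, the therapeutic
#' list, and the geriatric-syndrome flags used as covariates. Patients are
#' aged 65 or over (the study setting's inclusion criterion); younger ages
#' are rejected unless `validate_age = FALSE` (useful for isolated Charlson
#' arithmetic on arbitrary ages).
#'
#' @param id Opaque patient identifier.
#' @param age_years Integer age, `>= 65` unless `validate_age = FALSE`.
#' @param gender `"male"` or `"female"`.
#' @param provenience Admission origin, one of
#'   `r paste(provenience_levels(), collapse = ", ")`.
#' @param discharge Discharge destination, one of
#'   `r paste(discharge_levels(), collapse = ", ")`.
#' @param length_of_stay_days Positive integer.
#' @param diagnoses Character vector of labels from
#'   [condition_vocabulary()]; duplicates are collapsed.
#' @param qualifiers Character vector of labels from
#'   [qualifier_vocabulary()].
#' @param medications A `data.frame` as built by [medication()] (rows may be
#'   `rbind`ed together).
#' @param enteral_nutrition,housebound_or_falls,fall_risk_medium_high,dependency_adl,malnutrition,obesity,pressure_ulcers,recent_fracture
#'   Logical geriatric-syndrome flags; absent information defaults to
#'   `FALSE` (a rule that needs a finding does not fire without it).
#' @param validate_age Enforce the `>= 65` inclusion criterion.
#' @return An object of class `patient_record`.
#' @export
#' @examples
#' p <- patient_record("p1", 82, "female",
#'   diagnoses = c("congestive_heart_failure", "diabetes_mellitus"),
#'   medications = medication("N05BA06", duration_days = 60))
#' compute_cci(p)
patient_record <- function(id, age_years, gender = c("female", "male"),
                           provenience = "hospital",
                           discharge = "residence",
                           length_of_stay_days = 90L,
                           diagnoses = character(),
                           qualifiers = character(),
                           medications = empty_medications(),
                           enteral_nutrition = FALSE,
                           housebound_or_falls = FALSE,
                           fall_risk_medium_high = FALSE,
                           dependency_adl = FALSE,
                           malnutrition = FALSE,
                           obesity = FALSE,
                           pressure_ulcers = FALSE,
                           recent_fracture = FALSE,
                           validate_age = TRUE) {
  gender <- match.arg(gender)
  provenience <- match.arg(provenience, provenience_levels())
  discharge <- match.arg(discharge, discharge_levels())
  age_years <- as.integer(age_years)
  length_of_stay_days <- as.integer(length_of_stay_days)
  if (is.na(age_years)) stop("age_years must be an integer", call. = FALSE)
  if (validate_age && age_years < 65L)
    stop("age_years must be >= 65: patients below the study's inclusion ",
         "criterion (aged >= 65 years) are not admissible", call. = FALSE)
  if (is.na(length_of_stay_days) || length_of_stay_days < 1L)
    stop("length_of_stay_days must be a positive integer", call. = FALSE)

  diagnoses <- unique(as.character(diagnoses))
  unknown <- setdiff(diagnoses, condition_vocabulary())
  if (length(unknown))
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  qualifiers <- unique(as.character(qualifiers))
  unknown_q <- setdiff(qualifiers, qualifier_vocabulary())
  if (length(unknown_q))
    stop("unknown qualifier label(s): ", paste(unknown_q, collapse = ", "),
         call. = FALSE)
  stopifnot(is.data.frame(medications),
            all(c("drug_code", "is_regular", "duration_days", "daily_doses",
                  "is_fixed_combination") %in% names(medications)))

  structure(
    list(
      id = as.character(id),
      age_years = age_years,
      gender = gender,
      provenience = provenience,
      discharge = discharge,
      length_of_stay_days = length_of_stay_days,
      diagnoses = diagnoses,
      qualifiers = qualifiers,
      medications = medications,
      enteral_nutrition = isTRUE(enteral_nutrition),
      housebound_or_falls = isTRUE(housebound_or_falls),
      fall_risk_medium_high = isTRUE(fall_risk_medium_high),
      dependency_adl = isTRUE(dependency_adl),
      malnutrition = isTRUE(malnutrition),
      obesity = isTRUE(obesity),
      pressure_ulcers = isTRUE(pressure_ulcers),
      recent_fracture = isTRUE(recent_fracture)
    ),
    class = "patient_record"
  )
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s: %s, %d y, %d dx, %d meds>\n",
              x$id, x$gender, x$age_years, length(x$diagnoses),
              nrow(x$medications)))
  invisible(x)
}

# Regular (non-SOS) medications; combinations are single rows already.
regular_medications <- function(patient) {
  patient$medications[patient$medications$is_regular, , drop = FALSE]
}

#' Age-adjusted Charlson Comorbidity Index
#'
#' Sums the 1987 Charlson condition weights over the patient's coded
#' diagnoses and adds one age point per completed decade from 50-59 upward,
#' capped at four (so ages 80+ contribute 4 points). Hierarchical pairs are
#' scored once at the higher weight: diabetes with renal complication
#' supersedes uncomplicated diabetes, and a metastatic tumor supersedes a
#' non-metastatic one.
#'
#' @param patient A [patient_record()].
#' @return Integer score.
#' @export
#' @examples
#' p <- patient_record("x", 82, "female",
#'   diagnoses = c("congestive_heart_failure", "diabetes_mellitus"))
#' compute_cci(p)  # 4 age points + 1 + 1 = 6
compute_cci <- function(patient) {
  stopifnot(inherits(patient, "patient_record"))
  dx <- patient$diagnoses
  unknown <- setdiff(dx, condition_vocabulary())
  if (length(unknown))
    stop("unknown condition label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  # hierarchy: keep only the more severe member of each pair
  if ("proteinuric_diabetic_renal_disease" %in% dx)
    dx <- setdiff(dx, "diabetes_mellitus")
  if ("metastatic_solid_tumor" %in% dx)
    dx <- setdiff(dx, "non_metastatic_solid_tumor")
  w <- charlson_weights()
  condition_points <- sum(w[intersect(dx, names(w))])
  age_points <- min(max(patient$age_years %/% 10L - 4L, 0L), 4L)
  as.integer(condition_points + age_points)
}

#' Derive the geriatric profile of a patient
#'
#' Computes the counted covariates used throughout the analysis: the number
#' of regular medications (as-needed entries excluded, fixed combinations
#' counted once), total daily doses, the polypharmacy flag (>= 5 drugs per
#' day), the comorbid-disease count restricted to
#' [comorbidity_conditions()], the multimorbidity flag (>= 2), and the
#' age-adjusted Charlson index with its >= 4 and >= 6 dichotomisations.
#'
#' @param patient A [patient_record()].
#' @return A list of class `geriatric_profile`.
#' @export
derive_profile <- function(patient) {
  stopifnot(inherits(patient, "patient_record"))
  meds <- regular_medications(patient)
  n_medications <- nrow(meds)
  n_daily_doses <- if (n_medications) sum(meds$daily_doses) else 0L
  n_comorbid <- length(intersect(patient$diagnoses, comorbidity_conditions()))
  cci <- compute_cci(patient)
  structure(
    list(
      n_medications = as.integer(n_medications),
      n_daily_doses = as.integer(n_daily_doses),
      polypharmacy = n_medications >= 5L,
      n_comorbid = as.integer(n_comorbid),
      multimorbid = n_comorbid >= 2L,
      cci = cci,
      cci_ge4 = cci >= 4L,
      cci_ge6 = cci >= 6L
    ),
    class = "geriatric_profile"
  )
}
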