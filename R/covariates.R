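#' Covariate matrix of a cohort
#'
#' Flattens a cohort into the analysis covariates: demographics
#' (`age`, `female`, `hospital` provenience, `length_of_stay`), counted
#' profile variables (`n_medications`, `n_daily_doses`, `n_comorbid`,
#' `multimorbid`, `cci`, `cci_ge4`, `cci_ge6`, `polypharmacy`), the
#' geriatric-syndrome flags, and one indicator per comorbidity in
#' [comorbidity_conditions()]. Binary variables are 0/1 numeric.
#'
#' @param cohort List of [patient_record()]s.
#' @return A data frame with one row per patient, first column `id`.
#' @export
cohort_covariates <- function(cohort) {
  profiles <- lapply(cohort, derive_profile)
  out <- data.frame(
    id = vapply(cohort, function(p) p$id, character(1)),
    age = vapply(cohort, function(p) as.numeric(p$age_years), numeric(1)),
    female = vapply(cohort, function(p)
      as.numeric(p$gender == "female"), numeric(1)),
    hospital = vapply(cohort, function(p)
      as.numeric(p$provenience == "hospital"), numeric(1)),
    length_of_stay = vapply(cohort, function(p)
      as.numeric(p$length_of_stay_days), numeric(1)),
    n_medications = vapply(profiles, function(g)
      as.numeric(g$n_medications), numeric(1)),
    n_daily_doses = vapply(profiles, function(g)
      as.numeric(g$n_daily_doses), numeric(1)),
    n_comorbid = vapply(profiles, function(g)
      as.numeric(g$n_comorbid), numeric(1)),
    multimorbid = vapply(profiles, function(g)
      as.numeric(g$multimorbid), numeric(1)),
    cci = vapply(profiles, function(g) as.numeric(g$cci), numeric(1)),
    cci_ge4 = vapply(profiles, function(g)
      as.numeric(g$cci_ge4), numeric(1)),
    cci_ge6 = vapply(profiles, function(g)
      as.numeric(g$cci_ge6), numeric(1)),
    polypharmacy = vapply(profiles, function(g)
      as.numeric(g$polypharmacy), numeric(1)),
    stringsAsFactors = FALSE
  )
  for (f in patient_flag_fields())
    out[[f]] <- vapply(cohort, function(p) as.numeric(p[[f]]), numeric(1))
  for (cond in comorbidity_conditions())
    out[[cond]] <- vapply(cohort, function(p)
      as.numeric(cond %in% p$diagnoses), numeric(1))
  out
}
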