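#' Controlled condition vocabulary
#'
#' Diagnoses are coded against a closed vocabulary rather than raw ICD-9-CM
#' codes: screening rules and the Charlson index both key off these labels,
#' so free-text or unknown labels are rejected at the door.
#'
#' @return Character vector of valid condition labels.
#' @export
condition_vocabulary <- function() {
  c(
    # chronic conditions tallied as comorbidities
    "hypertension",
    "cerebrovascular_disease",
    "depression",
    "diabetes_mellitus",
    "constipation",
    "dementia",
    "urinary_incontinence",
    "rheumatic_disease",
    "congestive_heart_failure",
    "atrial_fibrillation",
    "benign_prostatic_hypertrophy",
    "renal_disease",
    "copd_asthma",
    "non_metastatic_solid_tumor",
    "hemiplegia",
    "parkinsons_disease",
    "metastatic_solid_tumor",
    "coronary_artery_disease",
    "osteoporosis",
    "glaucoma_narrow_angle",
    # additional findings individual screening rules key on
    "osteopenia",
    "peptic_ulcer",
    "delirium",
    "respiratory_failure",
    "prostatism_urinary_retention",
    "cardiac_conduction_abnormality",
    "bradycardia",
    "psychosis",
    "major_depressive_symptoms",
    "proteinuric_diabetic_renal_disease",
    "myocardial_infarction",
    "peripheral_vascular_disease"
  )
}

#' Comorbidities counted in the multimorbidity tally
#'
#' The per-patient comorbid-disease count (and the derived `multimorbid`
#' flag, two or more) is restricted to the chronic conditions a medication
#' review in this setting reports, not every vocabulary label.
#'
#' @return Character vector, a subset of [condition_vocabulary()].
#' @export
comorbidity_conditions <- function() {
  c(
    "hypertension", "cerebrovascular_disease", "depression",
    "diabetes_mellitus", "constipation", "dementia", "urinary_incontinence",
    "rheumatic_disease", "congestive_heart_failure", "atrial_fibrillation",
    "benign_prostatic_hypertrophy", "renal_disease", "copd_asthma",
    "non_metastatic_solid_tumor", "hemiplegia", "parkinsons_disease",
    "metastatic_solid_tumor", "coronary_artery_disease", "osteoporosis",
    "glaucoma_narrow_angle"
  )
}

#' Qualifier flags consumed by judgement-dependent screening rules
#'
#' Some explicit criteria hinge on clinical judgement that cannot be derived
#' from a drug or diagnosis list (e.g. whether behavioural symptoms of
#' dementia are severe, or whether prostatectomy is considered necessary).
#' These are recorded as explicit per-patient flags; an absent flag gives the
#' prescription the benefit of the doubt and the rule does not fire.
#'
#' @return Character vector of valid qualifier labels.
#' @export
qualifier_vocabulary <- function() {
  c(
    "behavioural_symptoms_severe",   # BPSD severe enough to justify a neuroleptic
    "prostatectomy_necessary",       # prostatectomy considered necessary
    "end_of_life",                   # end-of-life status
    "no_clinical_indication",        # >=1 drug on the list without an indication
    "tca_first_line",                # a TCA was started as first-line antidepressant
    "serum_potassium_not_monitored"  # no serum K+ monitoring on record
  )
}

# Charlson weights over the controlled vocabulary (1987 weighting).
# Conditions absent from the map score 0.
charlson_weights <- function() {
  c(
    myocardial_infarction              = 1L,
    congestive_heart_failure           = 1L,
    peripheral_vascular_disease        = 1L,
    cerebrovascular_disease            = 1L,
    dementia                           = 1L,
    copd_asthma                        = 1L,
    rheumatic_disease                  = 1L,
    peptic_ulcer                       = 1L,
    diabetes_mellitus                  = 1L,
    hemiplegia                         = 2L,
    renal_disease                      = 2L,
    proteinuric_diabetic_renal_disease = 2L,
    non_metastatic_solid_tumor         = 2L,
    metastatic_solid_tumor             = 6L
  )
}

# Patient-level binary fields usable as covariates and by rule predicates.
patient_flag_fields <- function() {
  c("enteral_nutrition", "housebound_or_falls", "fall_risk_medium_high",
    "dependency_adl", "malnutrition", "obesity", "pressure_ulcers",
    "recent_fracture")
}

provenience_levels <- function() {
  c("hospital", "residence", "nursing_home", "primary_care", "other")
}

discharge_levels <- function() {
  c("residence", "death", "rncci", "social", "nursing_home", "other",
    "emergency")
}
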