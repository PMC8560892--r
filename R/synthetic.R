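#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the marginal structure of a geriatric post-acute/
#' long-term care population: 64.0% female, 50.9% hospital provenience,
#' age truncated-normal (mean 81.6, SD 7.4, minimum 65), a medication
#' count whose truncated negative-binomial parameters reproduce a median
#' of 9 drugs per day with quartiles (6; 11), and the comorbidity
#' prevalences of such a cohort (hypertension 68.3%, cerebrovascular
#' disease 34.8%, depression 34.2%, ...). Covariates are sampled
#' independently except where a rule needs a clinically coherent joint
#' draw (drug assignment probabilities are conditional on diagnoses).
#'
#' @param n Cohort size.
#' @param seed Integer root seed; all randomness in [generate_cohort()]
#'   flows from it through deterministic per-patient substreams.
#' @param overrides Named list merged over the defaults (top-level names
#'   only).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 161, seed = 1, overrides = list()) {
  config <- list(
    n = as.integer(n),
    seed = as.integer(seed),
    female = 0.640,
    provenience = c(hospital = 0.509, residence = 0.435,
                    nursing_home = 0.031, primary_care = 0.0125,
                    other = 0.0125),
    discharge = c(residence = 0.379, death = 0.174, rncci = 0.174,
                  social = 0.124, nursing_home = 0.106, other = 0.037,
                  emergency = 0.006),
    age = list(mean = 81.6, sd = 7.4, min = 65, max = 105),
    length_of_stay = list(meanlog = log(93), sdlog = 0.8, max = 1500),
    med_count = list(mu = 9.0, size = 12, max = 25),
    # comorbidity prevalences (bph and prostatism apply to males only)
    comorbidity = c(
      hypertension = 0.683, cerebrovascular_disease = 0.348,
      depression = 0.342, diabetes_mellitus = 0.335, constipation = 0.335,
      dementia = 0.292, urinary_incontinence = 0.280,
      rheumatic_disease = 0.236, congestive_heart_failure = 0.224,
      atrial_fibrillation = 0.180, benign_prostatic_hypertrophy = 0.483,
      renal_disease = 0.143, copd_asthma = 0.124,
      non_metastatic_solid_tumor = 0.124, hemiplegia = 0.093,
      parkinsons_disease = 0.037, metastatic_solid_tumor = 0.031,
      coronary_artery_disease = 0.060, osteoporosis = 0.019,
      glaucoma_narrow_angle = 0.019
    ),
    # findings individual rules key on, not tallied as comorbidities
    extra_conditions = c(
      osteopenia = 0.25, peptic_ulcer = 0.12, delirium = 0.10,
      respiratory_failure = 0.08, prostatism_urinary_retention = 0.12,
      cardiac_conduction_abnormality = 0.06, bradycardia = 0.04,
      psychosis = 0.05, myocardial_infarction = 0.08,
      peripheral_vascular_disease = 0.10
    ),
    major_depressive_given_depression = 0.40,
    major_depressive_base = 0.02,
    diabetic_renal_given_diabetes = 0.10,
    flags = c(
      dependency_adl = 0.888, fall_risk_medium_high = 0.814,
      recent_fracture = 0.286, enteral_nutrition = 0.130,
      malnutrition = 0.043, obesity = 0.137, pressure_ulcers = 0.168,
      housebound_or_falls = 0.60
    ),
    qualifiers = c(
      no_clinical_indication = 0.09, end_of_life = 0.05,
      serum_potassium_not_monitored = 0.70
    ),
    tca_first_line_given_tca = 0.45,
    severe_bpsd_given_dementia = 0.30,
    prostatectomy_given_bph = 0.10,
    duplicate_class_prob = 0.095,
    # drug assignment probabilities; `base` applies without the listed
    # indication, `given` with it
    drugs = list(
      benzodiazepine = list(base = 0.56, long_share = 0.93),
      neuroleptic = list(base = 0.25),
      tca = list(base = 0.08, given = 0.35),
      non_tca_antidepressant = list(base = 0.08, given = 0.55),
      antimuscarinic_urological = list(given = 0.25),
      first_gen_antihistamine = list(base = 0.05),
      achei = list(given = 0.20),
      ppi = list(base = 0.55, long_share = 0.80),
      opioid = list(base = 0.18, long_given = 0.45, short_given = 0.60),
      laxative = list(base = 0.25, given_opioid = 0.40),
      loop_diuretic = list(base = 0.15, given = 0.50),
      aldosterone_antagonist = list(base = 0.03, given = 0.25),
      ticlopidine = list(base = 0.03),
      z_drug = list(base = 0.055),
      antiplatelet = list(base = 0.15, given = 0.60),
      statin = list(base = 0.20, given = 0.70),
      ace_inhibitor = list(base = 0.30, given = 0.45),
      beta_blocker = list(base = 0.12, given = 0.50),
      anticoagulant = list(base = 0.03, given = 0.75),
      bronchodilator = list(given = 0.50),
      vitamin_d = list(base = 0.25),
      calcium_vitamin_d = list(base = 0.15),
      alpha1_blocker = list(given = 0.35),
      five_alpha_reductase = list(given = 0.25),
      antidiabetic = list(given = 0.70)
    ),
    daily_dose_probs = c(`1` = 0.85, `2` = 0.13, `3` = 0.02),
    sos_max = 2
  )
  for (nm in names(overrides)) config[[nm]] <- overrides[[nm]]
  validate_config(config)
  structure(config, class = "cohort_config")
}

validate_config <- function(config) {
  if (config$n < 0) stop("n must be >= 0", call. = FALSE)
  probs <- c(config$female, config$comorbidity, config$extra_conditions,
             config$flags, config$qualifiers, config$provenience,
             config$discharge)
  if (any(probs < 0 | probs > 1))
    stop("all marginal probabilities must lie in [0, 1]", call. = FALSE)
  mc <- config$med_count
  if (mc$max < 1 || mc$mu <= 0 || mc$size <= 0)
    stop("infeasible medication-count model", call. = FALSE)
  if (mc$max < 5 && stats::pnbinom(mc$max, size = mc$size, mu = mc$mu) < 0.5)
    stop("infeasible config: medication-count cap is incompatible with ",
         "its distribution", call. = FALSE)
  invisible(TRUE)
}

# neutral chronic-care filler codes matching no declared rule class
filler_codes <- function() {
  c("N02BE01", "A02AD01", "B03BB01", "A11DA01", "M04AA01", "H03AA01",
    "C01DA14", "S01XA20", "A11HA03", "A12CC04", "R05CB06", "C04AD03",
    "N06BX03", "A05BA03", "C01EB09", "M01AE01", "B03AB05", "D02AC00",
    "R01AX10", "A07EC02")
}

rbern <- function(p) stats::runif(1) < p

#' Generate a synthetic cohort
#'
#' Draws `config$n` patient records reproducibly from `config$seed`. Each
#' patient gets its own deterministic random substream, so results do not
#' depend on generation order. Diagnoses are drawn from the configured
#' marginals and medications are then drawn conditionally on the diagnoses
#' (depressed patients tend to receive antidepressants, heart-failure
#' patients ACE inhibitors, and so on), so that every shipped screening
#' rule can fire at realistic rates.
#'
#' @param config A [cohort_config()].
#' @return A list of [patient_record()]s of length `config$n`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 25, seed = 42))
#' length(cohort)
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  if (n == 0L) return(list())
  set.seed(config$seed)
  substreams <- sample.int(.Machine$integer.max - 1L, n)
  lapply(seq_len(n), function(i) {
    set.seed(substreams[i])
    generate_patient(sprintf("synth-%05d", i), config)
  })
}

generate_patient <- function(id, config) {
  gender <- if (rbern(config$female)) "female" else "male"
  provenience <- sample(names(config$provenience), 1,
                        prob = config$provenience)
  discharge <- sample(names(config$discharge), 1, prob = config$discharge)
  age <- config$age$min - 1
  while (age < config$age$min || age > config$age$max)
    age <- round(stats::rnorm(1, config$age$mean, config$age$sd))
  los <- min(max(1, round(stats::rlnorm(1, config$length_of_stay$meanlog,
                                        config$length_of_stay$sdlog))),
             config$length_of_stay$max)

  # --- diagnoses -----------------------------------------------------
  dx <- character()
  for (cond in names(config$comorbidity)) {
    p <- config$comorbidity[[cond]]
    if (cond %in% c("benign_prostatic_hypertrophy") && gender != "male")
      next
    if (rbern(p)) dx <- c(dx, cond)
  }
  for (cond in names(config$extra_conditions)) {
    p <- config$extra_conditions[[cond]]
    if (cond == "prostatism_urinary_retention" && gender != "male") next
    if (rbern(p)) dx <- c(dx, cond)
  }
  p_mdd <- if ("depression" %in% dx) config$major_depressive_given_depression
           else config$major_depressive_base
  if (rbern(p_mdd)) dx <- c(dx, "major_depressive_symptoms")
  if ("diabetes_mellitus" %in% dx &&
      rbern(config$diabetic_renal_given_diabetes))
    dx <- c(dx, "proteinuric_diabetic_renal_disease")

  # --- flags and qualifiers ------------------------------------------
  flags <- lapply(config$flags[patient_flag_fields()], rbern)
  names(flags) <- patient_flag_fields()
  quals <- names(config$qualifiers)[vapply(config$qualifiers, rbern,
                                           logical(1))]
  if ("dementia" %in% dx && rbern(config$severe_bpsd_given_dementia))
    quals <- c(quals, "behavioural_symptoms_severe")
  if ("benign_prostatic_hypertrophy" %in% dx &&
      rbern(config$prostatectomy_given_bph))
    quals <- c(quals, "prostatectomy_necessary")

  # --- medications ---------------------------------------------------
  d <- config$drugs
  has <- function(...) any(c(...) %in% dx)
  codes <- character()
  durations <- integer()
  long_duration <- function() sample(30:360, 1)
  short_duration <- function() sample(3:27, 1)
  add <- function(code, dur = long_duration()) {
    codes <<- c(codes, code); durations <<- c(durations, as.integer(dur))
  }

  tca_given <- has("dementia", "glaucoma_narrow_angle",
                   "cardiac_conduction_abnormality",
                   "prostatism_urinary_retention")
  vascular <- has("coronary_artery_disease", "cerebrovascular_disease",
                  "peripheral_vascular_disease", "myocardial_infarction")
  cardiac <- has("congestive_heart_failure", "coronary_artery_disease")

  if (rbern(d$benzodiazepine$base))
    add("N05BA06", if (rbern(d$benzodiazepine$long_share)) long_duration()
                   else short_duration())
  if (rbern(d$neuroleptic$base)) add("N05AH04")
  if (rbern(if (tca_given) d$tca$given else d$tca$base)) {
    add("N06AA09")
    if (rbern(config$tca_first_line_given_tca))
      quals <- c(quals, "tca_first_line")
  }
  if (rbern(if (has("depression")) d$non_tca_antidepressant$given
            else d$non_tca_antidepressant$base)) add("N06AB03")
  if (has("urinary_incontinence") &&
      rbern(d$antimuscarinic_urological$given)) add("G04BD04")
  if (rbern(d$first_gen_antihistamine$base)) add("R06AA02")
  if (has("dementia") && rbern(d$achei$given)) add("N06DA02")
  if (rbern(d$ppi$base))
    add("A02BC01", if (rbern(d$ppi$long_share)) sample(57:360, 1)
                   else sample(14:56, 1))
  opioid <- rbern(d$opioid$base)
  if (opioid) {
    long <- rbern(d$opioid$long_given)
    short <- rbern(d$opioid$short_given)
    if (long) add("N02AB03")
    if (short || !long) add("N02AX02")
  }
  if (rbern(if (opioid) d$laxative$given_opioid else d$laxative$base))
    add("A06AB02")
  chf <- has("congestive_heart_failure")
  if (rbern(if (chf) d$loop_diuretic$given else d$loop_diuretic$base))
    add("C03CA01")
  if (rbern(if (chf) d$aldosterone_antagonist$given
            else d$aldosterone_antagonist$base)) add("C03DA01")
  if (rbern(d$ticlopidine$base)) add("B01AC05")
  if (rbern(d$z_drug$base)) add("N05CF01")
  if (rbern(if (vascular) d$antiplatelet$given else d$antiplatelet$base))
    add("B01AC06")
  if (rbern(if (vascular) d$statin$given else d$statin$base))
    add("C10AA01")
  if (rbern(if (cardiac) d$ace_inhibitor$given else d$ace_inhibitor$base))
    add("C09AA02")
  if (rbern(if (chf) d$beta_blocker$given else d$beta_blocker$base))
    add("C07AB07")
  if (rbern(if (has("atrial_fibrillation")) d$anticoagulant$given
            else d$anticoagulant$base)) add("B01AA03")
  if (has("copd_asthma") && rbern(d$bronchodilator$given)) add("R03AC02")
  if (rbern(d$vitamin_d$base)) add("A11CC05")
  if (rbern(d$calcium_vitamin_d$base)) add("A12AX00")
  if (has("benign_prostatic_hypertrophy", "prostatism_urinary_retention")) {
    if (rbern(d$alpha1_blocker$given)) add("G04CA01")
    if (rbern(d$five_alpha_reductase$given)) add("G04CB01")
  }
  if (has("diabetes_mellitus") && rbern(d$antidiabetic$given))
    add("A10BA02")

  # occasional duplicate within an ATC chemical subgroup
  if (length(codes) && rbern(config$duplicate_class_prob)) {
    base_code <- sample(codes, 1)
    add(paste0(substr(base_code, 1, 5), "99"))
  }

  # pad with neutral fillers toward the target medication count
  target <- min(stats::rnbinom(1, size = config$med_count$size,
                               mu = config$med_count$mu),
                config$med_count$max)
  pool <- setdiff(filler_codes(), codes)
  if (length(codes) < target && length(pool)) {
    extra <- sample(pool, min(target - length(codes), length(pool)))
    for (code in extra) add(code)
  }

  dose_opts <- as.integer(names(config$daily_dose_probs))
  meds <- if (length(codes)) {
    do.call(rbind, lapply(seq_along(codes), function(j) {
      medication(codes[j], is_regular = TRUE, duration_days = durations[j],
                 daily_doses = sample(dose_opts, 1,
                                      prob = config$daily_dose_probs))
    }))
  } else empty_medications()
  n_sos <- sample(0:config$sos_max, 1)
  if (n_sos > 0) {
    sos_pool <- c("N02BB02", "A03FA01", "R05DA04")
    for (code in sample(sos_pool, n_sos))
      meds <- rbind(meds, medication(code, is_regular = FALSE,
                                     duration_days = short_duration()))
  }

  do.call(patient_record, c(
    list(id = id, age_years = age, gender = gender,
         provenience = provenience, discharge = discharge,
         length_of_stay_days = los, diagnoses = dx,
         qualifiers = unique(quals), medications = meds),
    flags
  ))
}

#' Plant a binary outcome on a cohort from a logistic model
#'
#' Draws `y ~ Bernoulli(plogis(b0 + sum(b_i * x_i)))` over the cohort's
#' covariates; used for parameter-recovery and coverage experiments
#' against the model fitters.
#'
#' @param cohort List of [patient_record()]s.
#' @param coefficients Named numeric vector; names are columns of
#'   [cohort_covariates()] plus `"(Intercept)"`.
#' @param seed Integer seed.
#' @return Integer 0/1 outcome vector, one per patient.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n = 50, seed = 7))
#' y <- plant_outcome(cohort, c("(Intercept)" = -1, female = log(4.04)),
#'                    seed = 7)
plant_outcome <- function(cohort, coefficients, seed) {
  covs <- cohort_covariates(cohort)
  nms <- setdiff(names(coefficients), "(Intercept)")
  unknown <- setdiff(nms, names(covs))
  if (length(unknown))
    stop("unknown covariate name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  eta <- rep(coefficients[["(Intercept)"]] %||% 0, length(cohort))
  for (nm in nms) eta <- eta + coefficients[[nm]] * covs[[nm]]
  set.seed(seed)
  as.integer(stats::runif(length(eta)) < stats::plogis(eta))
}
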