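# Independent brute-force screening oracle.
#
# Each criterion is re-read from its text and coded directly against the
# patient record, sharing no predicate machinery, drug-class tables or
# catalog parsing with the package engine. Used to cross-check
# evaluate_patient() on small cohorts.

oracle_evaluate <- function(p) {
  reg <- p$medications[p$medications$is_regular, , drop = FALSE]
  codes <- reg$drug_code
  dur <- reg$duration_days
  starts <- function(code, prefix) substr(code, 1, nchar(prefix)) == prefix
  n_match <- function(prefixes) {
    if (!length(codes)) return(0L)
    sum(sapply(codes, function(cd) any(sapply(prefixes, starts, code = cd))))
  }
  on_any <- function(...) n_match(c(...)) > 0L
  on_any_dur <- function(prefixes, min_days) {
    if (!length(codes)) return(FALSE)
    any(sapply(seq_along(codes), function(i)
      any(sapply(prefixes, starts, code = codes[i])) && dur[i] >= min_days))
  }
  dx <- function(lbl) lbl %in% p$diagnoses
  q <- function(lbl) lbl %in% p$qualifiers

  benzo <- c("N05BA", "N05CD")
  # neuroleptic = any N05A drug that is not lithium (N05AN)
  neuroleptic_on <- length(codes) > 0 &&
    any(sapply(codes, function(cd) starts(cd, "N05A") && !starts(cd, "N05AN")))
  achol <- c("N06AA", "N04A", "R06AA", "R06AB", "R06AD", "G04BD", "A03BA")
  vascular <- dx("coronary_artery_disease") ||
    dx("cerebrovascular_disease") || dx("peripheral_vascular_disease")

  stopp <- c(
    "STOPP-A1" = q("no_clinical_indication"),
    "STOPP-A3" = any(duplicated(substr(codes, 1, 5))),
    "STOPP-B9" = on_any("C03C") && dx("hypertension") &&
      dx("urinary_incontinence"),
    "STOPP-B12" = on_any("C03DA") &&
      on_any("C03DB", "A12BA", "C09A", "C09C") &&
      q("serum_potassium_not_monitored"),
    "STOPP-C7" = on_any("B01AC05"),
    "STOPP-D1" = on_any("N06AA") &&
      (dx("dementia") || dx("glaucoma_narrow_angle") ||
         dx("cardiac_conduction_abnormality") ||
         dx("prostatism_urinary_retention")),
    "STOPP-D2" = on_any("N06AA") && q("tca_first_line"),
    "STOPP-D5" = on_any_dur(benzo, 28),
    "STOPP-D7" = on_any(achol) && (dx("delirium") || dx("dementia")),
    "STOPP-D9" = neuroleptic_on && dx("dementia") &&
      !q("behavioural_symptoms_severe"),
    "STOPP-D11" = on_any("N06DA") &&
      (dx("bradycardia") || dx("cardiac_conduction_abnormality") ||
         on_any("C07", "C01AA05", "C08DA01", "C08DB01")),
    "STOPP-D14" = on_any("R06AA", "R06AB", "R06AD"),
    "STOPP-F2" = on_any_dur("A02BC", 57) && dx("peptic_ulcer"),
    "STOPP-F3" = on_any("N02A", "N04A", "A03BA", "C08DA01", "B03AA") &&
      dx("constipation"),
    "STOPP-G5" = on_any(benzo) && dx("respiratory_failure"),
    "STOPP-K1" = on_any(benzo),
    "STOPP-K2" = neuroleptic_on,
    "STOPP-K4" = on_any("N05CF"),
    "STOPP-L2" = on_any("N02A") && !on_any("A06A"),
    "STOPP-L3" = on_any("N02AB03", "N02AE01") &&
      !on_any("N02AA01", "N02AX02"),
    "STOPP-N1" = n_match(achol) >= 2L
  )
  start <- c(
    "START-A1" = dx("atrial_fibrillation") &&
      !on_any("B01AA", "B01AE", "B01AF"),
    "START-A3" = vascular && !on_any("B01AC"),
    "START-A5" = vascular && !on_any("C10AA") && !q("end_of_life") &&
      p$age_years <= 85,
    "START-A6" = (dx("congestive_heart_failure") ||
                    dx("coronary_artery_disease")) && !on_any("C09A"),
    "START-A8" = dx("congestive_heart_failure") &&
      !on_any("C07AB02", "C07AB07", "C07AB12", "C07AG02"),
    "START-B1" = dx("copd_asthma") && !on_any("R03AC", "R03AL", "R03BB"),
    "START-C2" = dx("major_depressive_symptoms") &&
      !on_any("N06AB", "N06AX"),
    "START-E3" = (dx("osteoporosis") || isTRUE(p$recent_fracture)) &&
      !(on_any("A12AX") || (on_any("A11CC") && on_any("A12AA"))),
    "START-E5" = (isTRUE(p$housebound_or_falls) || dx("osteopenia")) &&
      !on_any("A11CC", "A12AX"),
    "START-F1" = dx("proteinuric_diabetic_renal_disease") &&
      !on_any("C09A") && !on_any("C09C"),
    "START-G1" = (dx("benign_prostatic_hypertrophy") ||
                    dx("prostatism_urinary_retention")) &&
      !on_any("G04CA") && !q("prostatectomy_necessary"),
    "START-G2" = (dx("benign_prostatic_hypertrophy") ||
                    dx("prostatism_urinary_retention")) &&
      !on_any("G04CB") && !q("prostatectomy_necessary"),
    "START-H2" = on_any("N02A") && !on_any("A06A")
  )
  list(stopp_ids = names(stopp)[stopp], start_ids = names(start)[start])
}
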