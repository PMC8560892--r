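test_that("age-adjusted Charlson score matches hand-computed cases", {
  # no scored conditions, below the first age band
  p <- patient_record("a", 45, "male", validate_age = FALSE)
  expect_identical(compute_cci(p), 0L)

  # 4 age points (82) + CHF (1) + uncomplicated diabetes (1)
  p <- toy_patient(age = 82, diagnoses = c("congestive_heart_failure",
                                           "diabetes_mellitus"))
  expect_identical(compute_cci(p), 6L)

  # metastatic solid tumor alone carries weight 6
  p <- patient_record("c", 45, "male",
                      diagnoses = "metastatic_solid_tumor",
                      validate_age = FALSE)
  expect_identical(compute_cci(p), 6L)

  # age points: one per decade from 50-59, capped at 4
  for (case in list(c(52, 1), c(65, 2), c(79, 3), c(80, 4), c(99, 4))) {
    p <- patient_record("d", case[1], "male", validate_age = FALSE)
    expect_identical(compute_cci(p), as.integer(case[2]))
  }
})

test_that("Charlson hierarchies score the severer member once", {
  base <- toy_patient(age = 70, diagnoses = "diabetes_mellitus")
  both <- toy_patient(age = 70,
                      diagnoses = c("diabetes_mellitus",
                                    "proteinuric_diabetic_renal_disease"))
  expect_identical(compute_cci(both) - compute_cci(toy_patient(age = 70)), 2L)
  expect_identical(compute_cci(base) - compute_cci(toy_patient(age = 70)), 1L)

  tum <- toy_patient(age = 70,
                     diagnoses = c("non_metastatic_solid_tumor",
                                   "metastatic_solid_tumor"))
  expect_identical(compute_cci(tum) - compute_cci(toy_patient(age = 70)), 6L)
})

test_that("Charlson score is monotone in added conditions", {
  scored <- names(stoppstart:::charlson_weights())
  set.seed(41)
  for (rep in 1:25) {
    dx <- sample(condition_vocabulary(), sample(0:6, 1))
    p <- toy_patient(age = sample(65:95, 1), diagnoses = dx)
    extra <- sample(setdiff(scored, dx), 1)
    p2 <- toy_patient(age = p$age_years, diagnoses = c(dx, extra))
    expect_gte(compute_cci(p2), compute_cci(p))
  }
})

test_that("unknown condition labels are rejected by name", {
  expect_error(toy_patient(diagnoses = "gout"), "gout")
  expect_error(toy_patient(qualifiers = "frailty"), "frailty")
})

test_that("profile derivation applies the counting rules", {
  # 6 entries: one as-needed (excluded), one fixed combination (counts once)
  meds <- med_rows(
    medication("C09AA02", daily_doses = 1),
    medication("C10AA01", daily_doses = 1),
    medication("A02BC01", daily_doses = 2),
    medication("C07AB07", daily_doses = 1, is_fixed_combination = TRUE),
    medication("A06AB02", daily_doses = 1),
    medication("N02BE01", is_regular = FALSE, daily_doses = 3)
  )
  g <- derive_profile(toy_patient(meds = meds))
  expect_identical(g$n_medications, 5L)
  expect_true(g$polypharmacy)   # threshold inclusive at 5
  expect_identical(g$n_daily_doses, 6L)

  g4 <- derive_profile(toy_patient(meds = meds[1:4, ]))
  expect_identical(g4$n_medications, 4L)
  expect_false(g4$polypharmacy)  # boundary below threshold
})

test_that("comorbidity count is restricted to the comorbidity list", {
  p <- toy_patient(diagnoses = c("hypertension", "dementia", "delirium",
                                 "osteopenia"))
  g <- derive_profile(p)
  expect_identical(g$n_comorbid, 2L)
  expect_true(g$multimorbid)
  expect_false(derive_profile(toy_patient(diagnoses = "dementia"))$multimorbid)
})

test_that("cci >= 6 implies cci >= 4 across a synthetic cohort", {
  cohort <- generate_cohort(cohort_config(n = 150, seed = 5))
  profs <- lapply(cohort, derive_profile)
  ge4 <- sum(vapply(profs, `[[`, logical(1), "cci_ge4"))
  ge6 <- sum(vapply(profs, `[[`, logical(1), "cci_ge6"))
  expect_lte(ge6, ge4)
  expect_true(all(vapply(profs, function(g) !g$cci_ge6 || g$cci_ge4,
                         logical(1))))
})

test_that("cohort round-trips losslessly through the delimited format", {
  cohort <- generate_cohort(cohort_config(n = 40, seed = 9))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  expect_length(back, 40)
  for (i in seq_along(cohort)) {
    a <- cohort[[i]]; b <- back[[i]]
    rownames(a$medications) <- rownames(b$medications) <- NULL
    expect_equal(b, a)
  }
})

test_that("cohort reader validates rows with their row numbers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(paste(stoppstart:::cohort_columns(), collapse = ","), path)
  expect_identical(read_cohort(path), list())

  ok <- toy_patient(meds = medication("N05BA06", duration_days = 40))
  write_cohort(list(ok), path)
  txt <- readLines(path)
  writeLines(sub(",80,", ",60,", txt, fixed = TRUE), path)
  expect_error(read_cohort(path), "row 1.*65")

  writeLines(sub(",80,", ",8x,", txt, fixed = TRUE), path)
  expect_error(read_cohort(path), "row 1")

  writeLines(sub("N05BA06:40", "N05BA06:xx", txt, fixed = TRUE), path)
  expect_error(read_cohort(path), "row 1.*malformed")

  # missing mandatory column
  writeLines(c("id,age_years", "p,80"), path)
  expect_error(read_cohort(path), "missing mandatory column")
})
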