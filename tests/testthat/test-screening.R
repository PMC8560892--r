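catalog <- default_catalog()

test_that("a patient with nothing on record fires nothing", {
  r <- evaluate_patient(toy_patient(), catalog)
  expect_identical(r$stopp_ids, character(0))
  expect_identical(r$start_ids, character(0))
  expect_identical(r$n_pims, 0L)
  expect_identical(r$n_ppos, 0L)
})

test_that("a long-course benzodiazepine fires both the duration and falls rules", {
  p <- toy_patient(meds = medication("N05BA06", duration_days = 60))
  r <- evaluate_patient(p, catalog)
  expect_setequal(r$stopp_ids, c("STOPP-D5", "STOPP-K1"))

  # below four weeks only the falls-risk rule remains
  p_short <- toy_patient(meds = medication("N05BA06", duration_days = 27))
  expect_setequal(evaluate_patient(p_short, catalog)$stopp_ids, "STOPP-K1")

  # as-needed benzodiazepine is invisible to the rules
  p_sos <- toy_patient(meds = medication("N05BA06", duration_days = 60,
                                         is_regular = FALSE))
  expect_identical(evaluate_patient(p_sos, catalog)$n_pims, 0L)
})

test_that("statin/antiplatelet omissions respect the age-85 disqualifier", {
  p80 <- toy_patient(age = 80, diagnoses = "coronary_artery_disease")
  r80 <- evaluate_patient(p80, catalog)
  expect_true(all(c("START-A3", "START-A5") %in% r80$start_ids))

  p86 <- toy_patient(age = 86, diagnoses = "coronary_artery_disease")
  r86 <- evaluate_patient(p86, catalog)
  expect_true("START-A3" %in% r86$start_ids)
  expect_false("START-A5" %in% r86$start_ids)

  # end-of-life status disqualifies the statin omission too
  p_eol <- toy_patient(age = 80, diagnoses = "coronary_artery_disease",
                       qualifiers = "end_of_life")
  expect_false("START-A5" %in% evaluate_patient(p_eol, catalog)$start_ids)
})

test_that("judgement qualifiers give the benefit of the doubt", {
  base <- list(age = 80, diagnoses = "dementia",
               meds = medication("N05AH04", duration_days = 30))
  fires <- evaluate_patient(do.call(toy_patient, base), catalog)
  expect_true("STOPP-D9" %in% fires$stopp_ids)
  severe <- evaluate_patient(
    do.call(toy_patient, c(base, list(qualifiers = "behavioural_symptoms_severe"))),
    catalog)
  expect_false("STOPP-D9" %in% severe$stopp_ids)
})

test_that("screening is deterministic", {
  cohort <- generate_cohort(cohort_config(n = 30, seed = 12))
  r1 <- screen_cohort(cohort, catalog)
  r2 <- screen_cohort(cohort, catalog)
  expect_identical(r1, r2)
})

test_that("adding an indicated therapy never adds an omission for it", {
  p <- toy_patient(diagnoses = c("congestive_heart_failure",
                                 "atrial_fibrillation", "copd_asthma"))
  before <- evaluate_patient(p, catalog)$start_ids
  therapies <- c("C09AA02" = "START-A6", "C07AB07" = "START-A8",
                 "B01AA03" = "START-A1", "R03AC02" = "START-B1")
  for (code in names(therapies)) {
    p2 <- toy_patient(diagnoses = p$diagnoses,
                      meds = medication(code, duration_days = 30))
    after <- evaluate_patient(p2, catalog)$start_ids
    expect_false(therapies[[code]] %in% after)
    expect_true(therapies[[code]] %in% before)
  }
})

test_that("adding non-negated medications never removes a fired STOPP rule", {
  # the only STOPP rules with absence clauses are the opioid/laxative pair;
  # additions outside those classes must preserve every fired criterion
  set.seed(77)
  cohort <- generate_cohort(cohort_config(n = 25, seed = 21))
  neutral <- c("N05BA12", "N05AH03", "A02BC02", "C03CA04", "R06AA04")
  for (p in cohort) {
    before <- evaluate_patient(p, catalog)$stopp_ids
    add <- medication(sample(neutral, 1), duration_days = 90)
    p2 <- p
    p2$medications <- rbind(p2$medications, add)
    after <- evaluate_patient(p2, catalog)$stopp_ids
    expect_true(all(setdiff(before, c("STOPP-L2", "STOPP-L3")) %in% after))
  }
})

test_that("engine agrees with the independent brute-force oracle", {
  for (seed in c(31, 32)) {
    cohort <- generate_cohort(cohort_config(n = 50, seed = seed))
    for (p in cohort) {
      engine <- evaluate_patient(p, catalog)
      oracle <- oracle_evaluate(p)
      expect_setequal(engine$stopp_ids, oracle$stopp_ids)
      expect_setequal(engine$start_ids, oracle$start_ids)
    }
  }
})

test_that("summary distribution, prevalence and section bounds are coherent", {
  cohort <- generate_cohort(cohort_config(n = 200, seed = 8))
  results <- screen_cohort(cohort, catalog)
  s <- summarize_screening(results, catalog)
  for (tool in c("pim", "ppo")) {
    st <- s[[tool]]
    expect_identical(sum(st$distribution), 200L)
    expect_identical(st$prevalence_n,
                     200L - st$distribution[["0"]])
    # section count bounded by max and sum of member criteria
    for (sec in st$section_freq$section) {
      members <- st$criterion_freq[st$criterion_freq$section == sec, ]
      sec_n <- st$section_freq$n[st$section_freq$section == sec]
      expect_gte(sec_n, max(members$n))
      expect_lte(sec_n, sum(members$n))
    }
  }
  expect_error(summarize_screening(c(results, results[1]), catalog),
               "duplicate patient_id")
})

test_that("screening results write as delimited text", {
  cohort <- generate_cohort(cohort_config(n = 10, seed = 3))
  results <- screen_cohort(cohort, catalog)
  path <- withr::local_tempfile(fileext = ".csv")
  write_screening(results, path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_identical(nrow(tab), 10L)
  expect_identical(tab$n_pims,
                   vapply(results, `[[`, integer(1), "n_pims"))
})
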