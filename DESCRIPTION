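Package: stoppstart
Title: STOPP/START Medication Review for Post-Acute and Long-Term Care Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule engine for a subset of the STOPP/START v2 explicit
    screening criteria used to detect potentially inappropriate medications
    (PIMs) and potential prescribing omissions (PPOs) in patients aged 65 and
    over, together with the statistical toolkit used in medication-review
    studies of post-acute and long-term care cohorts: age-adjusted Charlson
    comorbidity scoring, cohort prevalence summaries, unadjusted 2x2 odds
    ratios with Woolf confidence intervals and Wald tests, and forward-selection
    logistic regression with Hosmer-Lemeshow calibration, ROC/AUC discrimination
    and joint sensitivity/specificity cutoffs. A synthetic cohort generator
    reproduces the marginal structure of a geriatric long-term care population
    so the whole pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
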