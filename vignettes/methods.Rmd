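---
title: "Screening methodology and statistical design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening methodology and statistical design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoppstart)
```

## The screening problem

Older patients in post-acute and long-term care accumulate long medication
lists and multiple chronic conditions. Explicit criteria-based review —
the STOPP list for potentially inappropriate medications (PIMs) and the
START list for potential prescribing omissions (PPOs) — turns that review
into a reproducible rule evaluation: each criterion is a predicate over a
patient's drugs, diagnoses and clinical flags. `stoppstart` implements a
machine-evaluable subset of the v2 criteria (21 STOPP, 13 START) as a
declarative catalog plus an evaluator, and the statistical toolkit used to
analyse screening results in a cross-sectional cohort.

## Patient records and derived covariates

A `patient_record` holds demographics, a coded diagnosis list, the
therapeutic list, and binary geriatric-syndrome flags. Three counting
conventions matter and are enforced centrally:

* only **regular** medications count — as-needed (SOS) entries are stored
  but invisible to all counts and rules;
* a **fixed-dose combination** is one entry and counts as one medication;
* **polypharmacy** is an intake of five or more regular drugs per day
  (threshold inclusive).

Diagnoses use a closed vocabulary rather than ICD codes: the analysis
needs a stable label per condition, not a full terminology, and coded
records in this setting mix ICD-coded and free-text diagnoses. Unknown
labels are rejected naming the offender.

The Charlson Comorbidity Index is computed in its **age-adjusted** form:
1987 condition weights plus one point per completed decade from 50–59,
capped at four. The age-adjusted variant is the one consistent with a
population whose median index is 6 at a median age of 82 — condition
weights alone rarely reach that in a long-term-care population — and the
dichotomisations CCI ≥ 4 and CCI ≥ 6 used as covariates presuppose it.
Hierarchical pairs (diabetes vs. diabetes with renal complication,
metastatic vs. non-metastatic tumor) score once at the higher weight.

Quartiles in all summaries use weighted-average interpolation between
order statistics (R's `type = 6`), the convention of the mainstream
clinical statistics packages whose table layouts these reports mirror.

## The rule catalog

Rules live in a YAML catalog (`inst/extdata/stopp_start_catalog.yaml`),
not in code. Drug classes are ATC prefix sets with optional exclusions
(neuroleptics are `N05A` minus lithium `N05AN`); conditions are
`all`/`any`/`not` combinators over primitives (`has_drug_class` with an
optional minimum duration, `lacks_drug_class`, `drug_class_count_ge`,
`duplicate_drug_class`, `co_prescribed`, `has_condition`, `qualifier`,
`flag`, `age_gt`). Design choices a maintainer should know:

* **One PIM = one fired STOPP criterion**, not one drug: a benzodiazepine
  taken ≥28 days fires both the duration rule D5 and the falls-risk rule
  K1, and both count. Published per-criterion frequencies (D5 and K1 each
  above 50%) are only consistent with criterion-level counting.
* **Duration thresholds** are stored in days; "≥ 4 weeks" compares
  against 28, "> 8 weeks" against 57.
* **Judgement qualifiers.** Criteria that hinge on clinical judgement
  (severe behavioural symptoms of dementia, prostatectomy considered
  necessary, end-of-life status, a drug having no indication, serum
  potassium unmonitored, a TCA started first-line) consume explicit
  per-patient qualifier flags. An absent flag gives the prescription the
  benefit of the doubt: a rule that needs a finding does not fire without
  it. Screening is therefore conservative under incomplete records.
* **START omissions** fire only when the indication is an explicit
  diagnosis or flag, the indicated class is absent from the regular list,
  and no disqualifier is recorded (e.g. the statin omission A5 is
  suppressed above age 85 or at end of life).
* **Anticholinergic burden** (STOPP section N) has no burden scale in the
  criteria text; it is operationalised as ≥ 2 concurrent drugs from a
  declared anticholinergic prefix list.
* **Duplicate drug class** (A3) means two distinct regular entries within
  the same ATC chemical subgroup (first five characters).
* Sections with no machine-evaluable representative in this setting
  (STOPP E and J, START D and I — renal-dose, endocrine, gastrointestinal
  and vaccine criteria) are deliberately absent and are the natural
  extension points; long-acting vs. short-acting opioids (L3) is a
  distinction ATC does not draw, so the catalog enumerates representative
  substance codes.

One STOPP rule pair (L2, and its START mirror H2) contains an absence
clause ("opioids **without** laxative"), so the engine's monotonicity —
adding a drug never removes a fired STOPP criterion — holds for all rules
except those two, and the tests state it that way.

## The synthetic cohort

No patient-level data ship with the package; the generator produces
cohorts with the marginal structure of the study population the analysis
targets: 64.0% female; hospital provenience 50.9%; age truncated-normal
(mean 81.6, SD 7.4, minimum 65); length of stay log-normal around a
median of 93 days; dependency in ADL 88.8%, fall risk 81.4%, recent
fractures 28.6%; the comorbidity prevalences of such a cohort
(hypertension 68.3% down to glaucoma 1.9%, with prostatic conditions
restricted to males). The regular-medication count is a negative binomial
(mean 9.0, size 12) truncated to [0, 25]; these constants were tuned once
so the quartiles are exactly 9 (6; 11), and they also imply a
polypharmacy rate near 90%.

Covariates are sampled independently except where a rule needs a
clinically coherent joint draw: drug assignment is conditional on
diagnoses (antidepressants given depression, ACE inhibitors given heart
failure, alpha-blockers given prostatic disease, ...), with probabilities
chosen once so that every shipped criterion fires at rates of the order
observed in practice. Conditions for which the study population gives no
prevalence (osteopenia, delirium, respiratory failure, conduction
abnormalities, ...) use values a geriatric clinician would call
realistic; they are config fields, documented in `cohort_config()`.

What the generator does **not** emulate: the real joint correlation
structure between comorbidities (no published joint distribution exists;
independence is the documented default), longitudinal medication
histories, and dose strengths. Passing tests on synthetic cohorts
therefore validate the *machinery* — rule evaluation, counting,
estimation — not the epidemiology of any real population.

Randomness: one root seed; per-patient substreams are drawn from it up
front, so a patient's record does not depend on how many patients precede
it. `plant_outcome()` draws binary outcomes from a logistic model over
the cohort covariates for parameter-recovery experiments.

## Statistics

**Unadjusted associations.** For binary covariates, the cross-product
odds ratio $ad/bc$, the Woolf interval
$\exp(\ln\mathrm{OR} \pm z_{0.975}\sqrt{1/a+1/b+1/c+1/d})$, and the
two-sided Wald test $z = \ln\mathrm{OR}/\mathrm{SE}$. A zero cell leaves
the estimate undefined and the row renders as a dash, exactly as the
clinical literature prints it; the Haldane–Anscombe +0.5 correction is
available but off by default, because silently correcting changes the
estimand. Continuous covariates (age, medication count, CCI, ...) get a
per-unit odds ratio from a single-covariate logistic fit. No
multiple-testing adjustment is applied at the univariate stage — these
are screens feeding a multivariate model, not confirmatory tests.
Reported values round half away from zero: two decimals for odds ratios
and intervals, three for p-values, percentages to one decimal.

**Logistic regression.** Maximum likelihood by iteratively reweighted
least squares with step-halving (the likelihood never decreases across
iterations, and a test asserts it). Convergence: largest score component
below 1e−8 or relative log-likelihood change below 1e−10, at most 25
iterations. Rank-deficient designs error naming the collinear columns;
quasi-separation (diverging coefficients with pinned fitted
probabilities) flags the fit and warns rather than returning silently.
Grouped (frequency-weighted) data are supported so a 2×2 table can be fit
directly; a property test requires $\exp(\hat\beta)$ to agree with the
cross-product odds ratio to at least six significant digits.

**Forward selection** starts from the intercept-only model and admits, at
each step, the candidate with the smallest Wald p below `p_enter = 0.05`
(the default of the mainstream clinical statistics packages for this
procedure); the final report keeps covariates with p < 0.1, the reporting
convention of the predictor tables this mirrors. The candidate pool can
be either the univariate-significant covariates or all covariates with
defined associations — published descriptions of this procedure are
ambiguous between the two, so both modes exist and neither is asserted as
canonical.

**Calibration and discrimination.** Hosmer–Lemeshow over deciles of risk
(df = groups − 2; tied fitted probabilities stay in one group; a group
with zero expected events merges into its neighbour, with a message — at
least three groups always remain). The AUC is the rank-based Mann–Whitney
statistic with half credit for ties, with a Hanley–McNeil interval. The
"simultaneously maximised" sensitivity/specificity cutoff is interpreted
as maximising the **minimum** of the two (ties broken toward the larger
sum, then the smaller threshold), since the phrase has no standard
definition; the Youden criterion is available behind a flag.

## Numerical and degenerate-input choices

* Empty cohorts summarise to all-zero tables without division by zero.
* A constant outcome, a single-class ROC input, or an all-tied score
  vector raise explicit errors or flagged degenerate results, never `NA`
  propagation.
* Reports carry a provenance header (seed, catalog, package version) and
  deliberately no timestamp, so identical configurations re-run to
  byte-identical outputs.

## Problem sizes used by the test suite

Simulation-backed tests run at sizes chosen to make their Monte-Carlo
error small relative to the asserted bands: marginal convergence at
n = 10,000 (binomial SE ≈ 0.5%), Wald type-I error at n = 2,000 with
1,000 replicates (asserted band 3.5–6.5%), coefficient recovery and CI
coverage at n = 5,000 with 200 replicates, Hosmer–Lemeshow uniformity at
n = 500 with 1,000 replicates (Kolmogorov–Smirnov at the 1% level), and
brute-force cross-checks of the rule engine on 50-patient cohorts and of
the AUC on fixtures up to 200 points.

## Known limitations

* The catalog covers the criteria subset observable from structured
  records in this setting, not all 81 + 34 v2 criteria; free-text
  inference, dose-strength arithmetic and renal-function-based dosing are
  out of scope.
* ATC prefix sets approximate drug classes; national formularies differ
  (e.g. which Z-drugs or benzodiazepines are marketed).
* Adjusted odds ratios from any particular published cohort are not
  reproducible without its raw data; the multivariate procedure is
  validated by recovery, coverage and calibration properties instead.
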