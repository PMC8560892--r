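# stoppstart

Medication review for older patients in post-acute and long-term care,
built around the STOPP/START v2 explicit screening criteria.

In patients aged 65 and over, a **potentially inappropriate medication
(PIM)** is a prescribed drug whose risk outweighs its benefit or that lacks
an indication; a **potential prescribing omission (PPO)** is an indicated
drug missing from the regimen. The STOPP criteria (Screening Tool of Older
People's Prescriptions) detect PIMs; the paired START criteria (Screening
Tool to Alert to Right Treatment) detect PPOs. `stoppstart` implements, as
a tested pipeline:

- a **rule engine** for a machine-evaluable subset of the STOPP/START v2
  criteria (21 STOPP, 13 START), declared in an editable YAML catalog of
  ATC drug-class prefix sets and structured predicates over a patient
  record (diagnoses, therapeutic list, geriatric-syndrome flags, clinical
  qualifiers);
- **cohort summaries**: per-patient PIM/PPO count distributions,
  prevalence of at least one, per-criterion and per-section frequencies;
- **univariate association screens**: for a 2×2 table with cells *a*
  (exposed, outcome), *b* (unexposed, outcome), *c* (exposed, no outcome),
  *d* (unexposed, no outcome), the unadjusted odds ratio *OR = ad/bc*,
  the Woolf confidence interval
  exp(ln OR ± z·√(1/a + 1/b + 1/c + 1/d)), and the two-sided Wald test
  z = ln OR / SE;
- **multivariate modelling**: logit-link logistic regression by IRLS,
  forward selection on the Wald test, adjusted odds ratios exp(β),
  Hosmer–Lemeshow calibration over deciles of risk, rank-based
  (Mann–Whitney) ROC AUC, and the cutoff that simultaneously maximises
  sensitivity and specificity (max of the minimum);
- a **synthetic cohort generator** reproducing the marginal structure of a
  geriatric long-term-care population (64.0% female, age ~N(81.6, 7.4²)
  truncated at 65, median 9 regular medications with quartiles 6–11,
  hypertension 68.3%, cerebrovascular disease 34.8%, ...), with drug
  assignment conditional on diagnoses so every shipped rule fires, plus
  planted logistic outcomes for parameter-recovery experiments;
- derived covariates: the **age-adjusted Charlson Comorbidity Index**
  (1987 weights plus one point per decade from 50–59, capped at 4),
  polypharmacy (≥5 regular drugs/day), multimorbidity (≥2 comorbid
  diseases).

## Worked example

```r
library(stoppstart)

p <- patient_record("p1", age_years = 80, gender = "female",
  diagnoses = c("coronary_artery_disease", "dementia"),
  medications = medication("N05BA06", duration_days = 60))  # a benzodiazepine
evaluate_patient(p, default_catalog())
#> <screening_result p1: 2 PIMs [STOPP-D5,STOPP-K1], 3 PPOs [START-A3,START-A5,START-A6]>
```

The benzodiazepine at 60 days fires both the ≥4-week duration rule (D5)
and the falls-risk rule (K1) — one drug may fire several criteria. The
documented coronary disease with no antiplatelet, statin or ACE inhibitor
on the list raises the corresponding omission rules (A3, A5, A6); at age
86 the statin omission A5 would be disqualified.

A published 2×2 row (female vs male exposure, ≥1 PIM outcome: 94/43/9/15)
reproduces at printed precision:

```r
t <- contingency_2x2(94, 43, 9, 15)
round_half_up(odds_ratio(t), 2)        #> 3.64
round_half_up(woolf_ci(t), 2)          #> low 1.48, high 8.98
round_half_up(wald_p(t), 3)            #> 0.005
```

And the whole pipeline on a synthetic cohort:

```r
out <- run_pipeline(tempfile("run"), n = 2000, seed = 1)
out$summary$pim$prevalence_pct         #> 84.2
out$summary$ppo$prevalence_pct         #> 83.3
```

which writes `cohort.csv`, `screening.csv`, `summary.txt`,
`associations.tsv` and `model_{pim,ppo}.txt` (byte-identical on re-run
with the same seed).

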