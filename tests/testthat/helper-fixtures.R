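# small builders used across test files

toy_patient <- function(id = "t1", age = 80, gender = "female",
                        diagnoses = character(), qualifiers = character(),
                        meds = empty_meds(), ...) {
  patient_record(id, age, gender, diagnoses = diagnoses,
                 qualifiers = qualifiers, medications = meds, ...)
}

empty_meds <- function() {
  medication("ZZZZ")[0, ]
}

med_rows <- function(...) {
  do.call(rbind, list(...))
}

# counts of the published per-patient PIM/PPO distribution (N = 161);
# the 7-or-more bucket is materialised at exactly 7
table4_pim_counts <- function() {
  rep(c(0, 1, 2, 3, 4, 5, 6, 7), times = c(24, 23, 32, 33, 16, 16, 10, 7))
}

table4_ppo_counts <- function() {
  rep(c(0, 1, 2, 3, 4, 5, 6, 0), times = c(30, 36, 47, 28, 13, 6, 1, 0))
}
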