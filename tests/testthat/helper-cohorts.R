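# Shared scaled-down cohort configurations. The generator model is identical
# to the default world; only patient/spectrum counts are reduced so the
# slower suites stay inside their runtime budgets.

small_counts <- function(n_patients = 4L, n_normal = 8L, n_abnormal = 8L) {
  data.frame(n_normal = rep(n_normal, n_patients),
             n_abnormal = rep(n_abnormal, n_patients))
}

small_config <- function(n_patients = 4L, n_normal = 8L, n_abnormal = 8L,
                         seed = 7L, ...) {
  cohort_config(n_patients = n_patients,
                per_patient_counts = small_counts(n_patients, n_normal,
                                                  n_abnormal),
                qc_fail_fraction = 0, seed = seed, ...)
}

# catalogue with all tissue effects removed (null world)
null_catalogue <- function() {
  cat <- default_line_catalogue()
  cat$abnormal_multiplier <- 1
  cat
}

# full small-cohort pipeline: panel -> matrix
small_matrix <- function(cohort) {
  panel <- suppressWarnings(select_panel(cohort))
  build_matrix(cohort, panel)
}
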