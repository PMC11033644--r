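# Shared fixtures, built in code. The small cohort is generated once per
# test run and reused by structural tests.
small_config <- function(n = 300, seed = 42, ...) {
  cohort_config(n_patients = n, seed = seed, ...)
}

.fixture_env <- new.env(parent = emptyenv())

small_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(small_config())
  }
  .fixture_env$cohort
}

note_tbl <- function(text, note_id = "n1", patient_id = "p1") {
  tibble::tibble(note_id = note_id, patient_id = patient_id, text = text)
}

# patient-level data with outcome taken from the latent truth, for model
# tests that do not need note text
patients_with_truth <- function(config) {
  pats <- generate_patients(config)
  dplyr::mutate(pats,
                pain_class = dplyr::if_else(.data$truth_pain, "class1", "class0"))
}
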