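test_that("SMI flag covers F20-F29 and F30-F33 and nothing else", {
  expect_true(derive_smi_flag("F20.0"))
  expect_false(derive_smi_flag("F41.1"))
  # boundary enumeration across F20..F39
  codes <- sprintf("F%d.1", 20:39)
  expected <- c(rep(TRUE, 10), rep(TRUE, 4), rep(FALSE, 6))
  expect_equal(derive_smi_flag(codes), expected)
  expect_true(derive_smi_flag("F33.2"))
  expect_false(derive_smi_flag("F34.1"))
  expect_false(derive_smi_flag(NA))
  expect_false(derive_smi_flag(""))
  expect_false(derive_smi_flag("F19.9"))
  expect_warning(res <- derive_smi_flag("not-a-code"), "malformed")
  expect_false(res)
  expect_true(derive_smi_flag("f25"))  # case and dotless forms tolerated
})

test_that("deprivation flag dichotomizes deciles at 5 and keeps missing", {
  expect_equal(derive_deprived_flag(c(1, 5, 6, 10, NA)),
               c(TRUE, TRUE, FALSE, FALSE, NA))
  expect_error(derive_deprived_flag(11), "1..10")
})

test_that("eligibility applies age, window and document-length rules", {
  cfg <- small_config(n = 10)
  pat <- function(age) tibble::tibble(patient_id = "p1", age_years = age)
  note <- function(nchr, date) {
    tibble::tibble(note_id = "n1", patient_id = "p1",
                   date = as.Date(date), text = strrep("x", nchr))
  }
  in_win <- "2018-01-01"
  expect_false(eligibility(pat(17), note(100, in_win), cfg)$eligible)
  expect_equal(eligibility(pat(17), note(100, in_win), cfg)$exclusion_reason,
               "age")
  expect_false(eligibility(pat(30), note(29, in_win), cfg)$eligible)
  expect_true(eligibility(pat(30), note(30, in_win), cfg)$eligible)
  expect_true(eligibility(pat(18), note(30, in_win), cfg)$eligible)
  # window endpoints are inclusive on both ends
  expect_true(eligibility(pat(30), note(30, cfg$window_start), cfg)$eligible)
  expect_true(eligibility(pat(30), note(30, cfg$window_end), cfg)$eligible)
  expect_false(eligibility(pat(30), note(30, cfg$window_start - 1), cfg)$eligible)
  expect_false(eligibility(pat(30), note(30, cfg$window_end + 1), cfg)$eligible)
  # inactive referral excludes
  p <- pat(30)
  p$active_referral <- FALSE
  expect_equal(eligibility(p, note(100, in_win), cfg)$exclusion_reason,
               "not_active")
})

test_that("build_cohort matches generator eligibility truth and is stable", {
  co <- small_cohort()
  cfg <- co$config
  cohort <- build_cohort(co$patients, co$notes, cfg)
  # the generator only produces eligible patients
  expect_equal(cohort$n, nrow(co$patients))
  expect_equal(cohort$patients$patient_id, sort(co$patients$patient_id))
  # degrading a patient's notes excludes exactly that patient
  notes2 <- co$notes
  victim <- co$patients$patient_id[1]
  notes2$text[notes2$patient_id == victim] <- "short"
  cohort2 <- build_cohort(co$patients, notes2, cfg)
  expect_equal(cohort2$n, cohort$n - 1)
  expect_equal(cohort2$exclusions$patient_id, victim)
  expect_equal(cohort2$exclusions$exclusion_reason, "no_qualifying_document")
  # empty input is an empty cohort, not an error
  empty <- build_cohort(co$patients[0, ], co$notes[0, ], cfg)
  expect_equal(empty$n, 0)
})

test_that("shrinking the window or raising min_doc_chars never grows the cohort", {
  co <- small_cohort()
  base <- build_cohort(co$patients, co$notes, co$config)$n
  cfg_narrow <- small_config()
  cfg_narrow$window_start <- cfg_narrow$window_start + 200
  cfg_narrow$window_end <- cfg_narrow$window_end - 200
  expect_lte(build_cohort(co$patients, co$notes, cfg_narrow)$n, base)
  cfg_long <- small_config(min_doc_chars = 200)
  expect_lte(build_cohort(co$patients, co$notes, cfg_long)$n, base)
})

test_that("every patient is in the cohort or has exactly one exclusion reason", {
  co <- small_cohort()
  pats <- co$patients
  pats$age_years[1:5] <- 17L
  notes <- dplyr::filter(co$notes, !.data$patient_id %in% pats$patient_id[6:10])
  flags <- eligibility(pats, notes, co$config)
  expect_equal(sum(flags$eligible) + sum(!is.na(flags$exclusion_reason)),
               nrow(pats))
  expect_true(all(is.na(flags$exclusion_reason[flags$eligible])))
  expect_true(all(flags$exclusion_reason[!flags$eligible] %in%
                    c("age", "not_active", "no_qualifying_document")))
})
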