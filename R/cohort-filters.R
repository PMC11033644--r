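#' Derive the severe-mental-illness flag from an ICD-10 code
#'
#' SMI is operationalized as a primary diagnosis in F20–F29 (schizophrenia
#' spectrum) or F30–F33 (bipolar and severe depressive disorders), decided
#' on the code's three-character prefix. Missing or malformed codes count
#' as non-SMI (malformed codes raise a warning).
#'
#' @param icd10_primary Character vector of ICD-10 codes (may contain `NA`
#'   or empty strings).
#' @return Logical vector, same length.
#' @export
#' @examples
#' derive_smi_flag(c("F20.0", "F33.2", "F34.1", "F41.1", NA))
derive_smi_flag <- function(icd10_primary) {
  x <- toupper(trimws(as.character(icd10_primary)))
  present <- !is.na(x) & nzchar(x)
  shaped <- present & stringr::str_detect(x, "^[A-Z][0-9]{2}")
  if (any(present & !shaped)) {
    warn(sprintf("%d malformed ICD-10 codes treated as non-SMI",
                 sum(present & !shaped)))
  }
  prefix <- ifelse(shaped, stringr::str_sub(x, 1, 3), NA_character_)
  smi_codes <- c(paste0("F2", 0:9), paste0("F3", 0:3))
  !is.na(prefix) & prefix %in% smi_codes
}

#' Derive the deprivation flag from an IMD decile
#'
#' Lower IMD decile = more deprived; the standard dichotomy is decile <= 5.
#' Missing deciles stay missing (`NA`).
#'
#' @param imd_decile Integer vector of deciles in 1..10 (or `NA`).
#' @return Logical vector (`TRUE` = more deprived), `NA` where unknown.
#' @export
derive_deprived_flag <- function(imd_decile) {
  d <- suppressWarnings(as.integer(imd_decile))
  if (any(!is.na(d) & (d < 1 | d > 10))) {
    abort("imd_decile values must lie in 1..10 or be missing",
          class = "painrecord_config_error")
  }
  ifelse(is.na(d), NA, d <= 5)
}

#' Patient eligibility for the analysis cohort
#'
#' A patient is eligible iff aged at least `min_age` years at the index
#' date, under active referral, and holding at least one note whose date
#' falls inside `[window_start, window_end]` (both ends inclusive) with raw
#' text length (including whitespace) of at least `min_doc_chars`.
#'
#' @param patients Tibble with `patient_id`, `age_years`; an optional
#'   logical `active_referral` column defaults to `TRUE`.
#' @param notes Tibble with `patient_id`, `date`, `text`.
#' @param config A [cohort_config()] (only the window/eligibility fields
#'   are used).
#' @return `eligibility()` returns `patients` plus logical `eligible` and a
#'   character `exclusion_reason` (`NA` when eligible, otherwise exactly
#'   one of `"age"`, `"not_active"`, `"no_qualifying_document"`).
#' @export
eligibility <- function(patients, notes, config) {
  active <- if ("active_referral" %in% names(patients)) {
    dplyr::coalesce(as.logical(patients$active_referral), TRUE)
  } else rep(TRUE, nrow(patients))
  qual <- notes |>
    mutate(date = as.Date(.data$date)) |>
    filter(.data$date >= config$window_start,
           .data$date <= config$window_end,
           nchar(.data$text) >= config$min_doc_chars) |>
    distinct(.data$patient_id) |>
    mutate(has_doc = TRUE)
  out <- patients |>
    left_join(qual, by = "patient_id") |>
    mutate(has_doc = dplyr::coalesce(.data$has_doc, FALSE),
           age_ok = .data$age_years >= config$min_age,
           active_ok = active,
           eligible = .data$age_ok & .data$active_ok & .data$has_doc,
           exclusion_reason = case_when(
             eligible ~ NA_character_,
             !age_ok ~ "age",
             !active_ok ~ "not_active",
             TRUE ~ "no_qualifying_document"
           )) |>
    select(-"has_doc", -"age_ok", -"active_ok")
  out
}

#' Build the analysis cohort
#'
#' Applies [eligibility()] and returns the eligible patients (sorted by
#' `patient_id`) together with their in-window notes.
#'
#' @inheritParams eligibility
#' @return A list of class `pain_cohort`: `patients` (eligible, with
#'   derived `smi` and `deprived` flags), `notes` (in-window notes of
#'   eligible patients), `exclusions` (excluded patients with reasons) and
#'   `n` (cohort size).
#' @export
build_cohort <- function(patients, notes, config) {
  flagged <- eligibility(patients, notes, config)
  kept <- flagged |>
    filter(.data$eligible) |>
    select(-"eligible", -"exclusion_reason") |>
    mutate(smi = derive_smi_flag(.data$icd10_primary),
           deprived = derive_deprived_flag(.data$imd_decile)) |>
    arrange(.data$patient_id)
  in_window <- notes |>
    mutate(date = as.Date(.data$date)) |>
    filter(.data$patient_id %in% kept$patient_id,
           .data$date >= config$window_start,
           .data$date <= config$window_end) |>
    arrange(.data$patient_id, .data$date, .data$note_id)
  structure(
    list(patients = kept,
         notes = in_window,
         exclusions = filter(flagged, !.data$eligible) |>
           select("patient_id", "exclusion_reason"),
         n = nrow(kept)),
    class = "pain_cohort"
  )
}

#' @export
print.pain_cohort <- function(x, ...) {
  cat("<pain_cohort>", x$n, "eligible patients,", nrow(x$notes),
      "in-window notes,", nrow(x$exclusions), "excluded\n")
  invisible(x)
}
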