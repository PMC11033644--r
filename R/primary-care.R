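#' Load pain code lists for primary-care records
#'
#' Code lists identify coded pain in structured primary-care records via
#' medication (analgesic prescriptions), diagnosis, and treatment
#' (pain-clinic referral/attendance) codes. The bundled defaults are small
#' synthetic fixture lists in a Read-code-like style
#' (`synthetic_codes_*.csv`), intended for tests and examples; substitute
#' production code lists for real analyses.
#'
#' @param paths Character vector of CSV paths, each with columns `code`,
#'   `kind` (`medication`/`diagnosis`/`treatment`) and optional
#'   `description`.
#' @return Tibble of class `pain_code_lists` with columns `code`, `kind`,
#'   `description`, `source`; codes are deduplicated within each kind.
#' @export
load_code_lists <- function(paths = default_code_list_paths()) {
  lists <- purrr::map(paths, function(p) {
    raw <- readr::read_csv(p, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
    if (nrow(raw) == 0 || !all(c("code", "kind") %in% names(raw))) {
      abort(paste0("empty or malformed code list: ", p),
            class = "painrecord_config_error")
    }
    if (!"description" %in% names(raw)) raw$description <- NA_character_
    raw$source <- basename(p)
    raw[, c("code", "kind", "description", "source")]
  })
  out <- bind_rows(lists) |>
    mutate(kind = tolower(.data$kind)) |>
    distinct(.data$code, .data$kind, .keep_all = TRUE)
  bad <- setdiff(unique(out$kind), c("medication", "diagnosis", "treatment"))
  if (length(bad)) {
    abort(paste0("unknown code-list kind: ", paste(bad, collapse = ", ")),
          class = "painrecord_config_error")
  }
  class(out) <- c("pain_code_lists", class(out))
  out
}

default_code_list_paths <- function() {
  vapply(c("synthetic_codes_medication.csv", "synthetic_codes_diagnosis.csv",
           "synthetic_codes_treatment.csv"),
         painrecord_file, character(1), USE.NAMES = FALSE)
}

#' Flag patients with coded pain in primary-care events
#'
#' @param events Tibble of coded events: `patient_id`, `code`, `date`.
#' @param code_lists A [load_code_lists()] tibble.
#' @param window_start,window_end Dates; events are counted when their date
#'   lies in `[window_start, window_end]` (both ends inclusive).
#' @return One row per patient appearing in `events`: `patient_id`,
#'   `coded_pain` (logical) and logical breakdown columns `medication`,
#'   `diagnosis`, `treatment` recording which kinds matched.
#' @export
flag_coded_pain <- function(events, code_lists, window_start, window_end) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  stopifnot(window_start <= window_end)
  ev <- events |>
    mutate(date = as.Date(.data$date)) |>
    filter(.data$date >= window_start, .data$date <= window_end) |>
    inner_join(select(code_lists, "code", "kind"),
               by = "code", relationship = "many-to-many")
  flags <- ev |>
    distinct(.data$patient_id, .data$kind) |>
    mutate(hit = TRUE) |>
    tidyr::pivot_wider(names_from = "kind", values_from = "hit",
                       values_fill = FALSE)
  out <- tibble(patient_id = unique(events$patient_id)) |>
    left_join(flags, by = "patient_id")
  for (k in c("medication", "diagnosis", "treatment")) {
    if (!k %in% names(out)) out[[k]] <- FALSE
    out[[k]] <- dplyr::coalesce(out[[k]], FALSE)
  }
  out |>
    mutate(coded_pain = .data$medication | .data$diagnosis | .data$treatment) |>
    select("patient_id", "coded_pain", "medication", "diagnosis", "treatment") |>
    arrange(.data$patient_id)
}

#' Partition the cohort by where pain is recorded
#'
#' Computes the four-way overlap between pain recorded in secondary-care
#' free text (class 1) and coded pain in linked primary-care records:
#' pain in both, primary-care only, secondary-care only, neither — plus the
#' linkage row. Percent denominators follow the reporting convention for
#' linked-cohort overlap: both-pain and primary-only are percentages of the
#' linked subset; linkage and secondary-only are percentages of the full
#' cohort. Each row names its denominator.
#'
#' @param cohort_flags Tibble with one row per cohort patient and logical
#'   (or coercible) columns `pain_class` (`"class1"`/`"class0"` or logical),
#'   `in_primary_care`, `coded_pain` (`NA` treated as `FALSE`).
#' @return Tibble of class `overlap_partition`: `cell`, `count`,
#'   `denominator_name`, `denominator`, `percent`.
#' @export
overlap_partition <- function(cohort_flags) {
  stopifnot(all(c("pain_class", "in_primary_care", "coded_pain") %in%
                  names(cohort_flags)))
  cls1 <- if (is.logical(cohort_flags$pain_class)) cohort_flags$pain_class
          else cohort_flags$pain_class == "class1"
  linked <- dplyr::coalesce(as.logical(cohort_flags$in_primary_care), FALSE)
  coded <- dplyr::coalesce(as.logical(cohort_flags$coded_pain), FALSE) & linked
  n <- nrow(cohort_flags)
  n_linked <- sum(linked)
  cells <- tibble(
    cell = c("cohort_total", "linked_primary_care", "pain_both",
             "pain_primary_only", "pain_secondary_only", "pain_neither"),
    count = c(n, n_linked,
              sum(coded & cls1),
              sum(coded & !cls1),
              sum(cls1 & !coded),
              sum(!cls1 & !coded)),
    denominator_name = c("cohort", "cohort", "linked", "linked",
                         "cohort", "cohort"),
    denominator = c(n, n, n_linked, n_linked, n, n)
  )
  cells$percent <- ifelse(cells$denominator > 0,
                          100 * cells$count / cells$denominator, 0)
  class(cells) <- c("overlap_partition", class(cells))
  cells
}
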