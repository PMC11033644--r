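#' Run the full recorded-pain pipeline on patient and note streams
#'
#' Chains every stage: eligibility filtering, sentence segmentation and
#' keyword detection, relevance classification, patient-level class
#' roll-up, anatomy aggregation (over relevant mentions only), primary-care
#' coded-pain flagging with the overlap partition, the two-class
#' descriptive summary, and the unadjusted plus incrementally adjusted
#' model suite. A structured count log records the size of every
#' intermediate product.
#'
#' @param patients,notes,coded_events Input tibbles (see
#'   [generate_cohort()] / [read_cohort()] for the expected columns).
#' @param config A [cohort_config()]; supplies the window and eligibility
#'   thresholds.
#' @param lexicon,rules,region_map,code_lists Stage resources; bundled
#'   defaults used when omitted.
#' @param fit_models Set `FALSE` to skip the regression suite (useful on
#'   tiny cohorts where covariate levels may not vary).
#' @return List of class `pain_pipeline`: `cohort`, `mentions` (classified),
#'   `patient_classes`, `anatomy`, `region_freq`, `overlap`, `description`,
#'   `models` (or `NULL`), `log` (tibble of stage counts).
#' @export
run_pipeline <- function(patients, notes, coded_events = NULL,
                         config = cohort_config(),
                         lexicon = load_lexicon(),
                         rules = default_ruleset(),
                         region_map = default_region_map(),
                         code_lists = load_code_lists(),
                         fit_models = TRUE) {
  log <- list()
  note_it <- function(stage, n) log[[length(log) + 1]] <<- tibble(stage = stage, n = n)
  note_it("patients_in", nrow(patients))
  note_it("notes_in", nrow(notes))

  cohort <- build_cohort(patients, notes, config)
  note_it("cohort_patients", cohort$n)
  note_it("cohort_notes", nrow(cohort$notes))

  mentions <- detect_mentions(cohort$notes, lexicon)
  note_it("keyword_hits", nrow(mentions))

  classified <- classify_mentions(mentions, rules)
  note_it("relevant_mentions", sum(classified$label == "relevant"))

  patient_classes <- rollup_patients(classified, cohort$patients)
  note_it("class1_patients", sum(patient_classes$pain_class == "class1"))

  relevant <- filter(classified, .data$label == "relevant")
  anatomy <- extract_anatomy(relevant, region_map)
  note_it("anatomy_mentions", nrow(anatomy))
  anatomy <- left_join(anatomy,
                       select(patient_classes, "patient_id",
                              smi_group = "smi"),
                       by = "patient_id") |>
    mutate(smi_group = if_else(.data$smi_group, "smi", "non_smi"))
  region_freq <- region_frequency(anatomy)

  overlap <- NULL
  if (!is.null(coded_events)) {
    coded_flags <- flag_coded_pain(coded_events, code_lists,
                                   config$window_start, config$window_end)
    flags <- patient_classes |>
      left_join(coded_flags, by = "patient_id") |>
      mutate(coded_pain = dplyr::coalesce(.data$coded_pain, FALSE),
             in_primary_care = if ("in_primary_care" %in% names(patient_classes))
               dplyr::coalesce(.data$in_primary_care, FALSE)
             else .data$patient_id %in% coded_events$patient_id)
    overlap <- overlap_partition(flags)
    note_it("coded_pain_patients", sum(flags$coded_pain & flags$in_primary_care))
  }

  description <- describe_cohort(patient_classes)
  models <- if (fit_models) run_models(patient_classes) else NULL

  structure(list(cohort = cohort, mentions = classified,
                 patient_classes = patient_classes, anatomy = anatomy,
                 region_freq = region_freq, overlap = overlap,
                 description = description, models = models,
                 log = bind_rows(log)),
            class = "pain_pipeline")
}

#' @export
print.pain_pipeline <- function(x, ...) {
  cat("<pain_pipeline>\n")
  print(x$log, n = Inf)
  invisible(x)
}
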