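# Fixed sub-stream offsets from the single config seed, one per generator
# block, so adding a block never perturbs the others. The seed is scrambled
# through a fixed LCG step per block: sequentially seeded Mersenne-Twister
# streams carry detectable cross-stream correlation, which biases
# covariate/outcome independence in the generated cohorts.
seed_offsets <- c(patients = 1L, pain = 2L, notes = 3L, coded = 4L)

block_seed <- function(seed, block) {
  (as.double(seed) * 69069 + seed_offsets[[block]] * 104729) %% 2147483647
}

rtruncnorm_int <- function(n, mean, sd, lower, upper) {
  p_lo <- pnorm(lower, mean, sd)
  p_hi <- pnorm(upper, mean, sd)
  x <- qnorm(runif(n, p_lo, p_hi), mean, sd)
  pmin(pmax(as.integer(round(x)), as.integer(lower)), as.integer(upper))
}

smi_icd10_codes <- function() {
  c("F20.0", "F20.5", "F22.0", "F23.1", "F25.0", "F29", "F31.2", "F31.8",
    "F32.2", "F33.1", "F33.2")
}

non_smi_icd10_codes <- function() {
  c("F40.1", "F41.1", "F42.0", "F43.1", "F43.2", "F50.0", "F60.3",
    "F84.5", "F90.0", "F10.2")
}

#' Generate the patient table with latent recorded-pain status
#'
#' Draws demographics from the configured marginals (age from a truncated
#' normal, mean 44, SD 17.5, on [18, 100]) and the latent recorded-pain
#' indicator from the logistic model implied by the configured log-odds
#' effects. This is the covariate/label layer of [generate_cohort()]; it is
#' fast enough for repeated-replicate effect-recovery studies because no
#' note text is built.
#'
#' @param config A [cohort_config()].
#' @return Tibble: `patient_id`, `age_years`, `gender`, `ethnicity`,
#'   `imd_decile`, `icd10_primary`, `active_referral`, `in_primary_care`,
#'   and the latent `truth_pain` label.
#' @export
generate_patients <- function(config) {
  validate_cohort_config(config)
  n <- config$n_patients
  m <- config$marginals
  set.seed(block_seed(config$seed, "patients"))
  age <- rtruncnorm_int(n, 44, 17.5, config$min_age, 100)
  gender <- sample(names(m$gender), n, replace = TRUE, prob = m$gender)
  ethnicity <- sample(names(m$ethnicity), n, replace = TRUE, prob = m$ethnicity)
  imd_raw <- sample(names(m$imd_decile), n, replace = TRUE, prob = m$imd_decile)
  imd <- suppressWarnings(as.integer(imd_raw))  # "not_known" -> NA
  smi <- sample(names(m$smi), n, replace = TRUE, prob = m$smi) == "smi"
  icd <- ifelse(smi,
                sample(smi_icd10_codes(), n, replace = TRUE),
                sample(non_smi_icd10_codes(), n, replace = TRUE))
  ef <- config$effects
  lp <- ef$intercept +
    ef$age_per_10y * (age - 44) / 10 +
    dplyr::coalesce(unname(ef$gender[gender]), 0) +
    dplyr::coalesce(unname(ef$ethnicity[ethnicity]), 0) +
    ifelse(!is.na(imd) & imd <= 5, ef$imd_deprived, 0) +
    ifelse(smi, ef$smi, 0)
  set.seed(block_seed(config$seed, "pain"))
  pain <- rbinom(n, 1, plogis(lp)) == 1
  tibble(
    patient_id = sprintf("p%06d", seq_len(n)),
    age_years = age,
    gender = gender,
    ethnicity = ethnicity,
    imd_decile = imd,
    icd10_primary = icd,
    active_referral = TRUE,
    in_primary_care = NA,  # filled by the coded-events block
    truth_pain = pain
  )
}

relevant_plain_templates <- function() {
  c("Complains of %s.", "Reports %s today.",
    "Has been experiencing %s for several days.", "Still troubled by %s.")
}

relevant_anatomy_templates <- function() {
  c("Complains of %s pain.", "Reports worsening %s pain.",
    "Ongoing %s pain noted.")
}

relevant_plain_terms <- function() {
  # deliberately free of body-part gazetteer terms, so planted anatomy
  # mentions are the only source of region counts
  c("pain", "headache", "myalgia", "sciatica", "toothache", "earache",
    "migraine", "soreness")
}

not_relevant_templates <- function() {
  list(
    negated = c("Denied pain this morning.", "No complaint of pain.",
                "Denies any headache.", "Not complaining of any discomfort."),
    form = c("Experiencing other physical symptoms? For example, chest pain.",
             "Screening item: any of the following, for example, joint pain?"),
    misspelling = c("Pained and decorated the walls.",
                    "Pained and plastered the ceiling last week."),
    hypothetical = c("Fear that eating will cause throat pain.",
                     "Reduce risk of pressure sores.",
                     "Monitor in case of headache."),
    metaphorical = c("Life is too painful to carry on living.",
                     "Pain will end when she repents.",
                     "Defensive of painful feelings.",
                     "Described the painful consequences of using alcohol.")
  )
}

filler_sentences <- function() {
  c("Attended the clinic today.", "Medication reviewed with the team.",
    "Sleeping and eating well.", "Engaging with the care plan.")
}

anatomy_parts_by_region <- function() {
  map <- default_region_map()
  parts <- map$term[!map$term %in% c("feet", "calves", "teeth")]
  split(parts, map$region[!map$term %in% c("feet", "calves", "teeth")])
}

# lexicon term a keyword matcher will report for a planted "<part> pain"
expected_hit_term <- function(phrase, lexicon_terms) {
  cand <- lexicon_terms[vapply(lexicon_terms, function(t)
    stringr::str_detect(phrase, paste0("\\b", t, "$")), logical(1))]
  if (!length(cand)) return("pain")
  cand[which.max(nchar(cand))]
}

nr_expected_terms <- function() {
  # one keyword hit per not-relevant template, in template order
  list(
    negated = c("pain", "pain", "headache", "discomfort"),
    form = c("chest pain", "joint pain"),
    misspelling = c("pained", "pained"),
    hypothetical = c("pain", "sore", "headache"),
    metaphorical = c("painful", "pain", "painful", "painful")
  )
}

#' Generate dated clinical notes realizing the latent pain labels
#'
#' Truth precedes text: every pain-positive patient receives at least one
#' planted relevant mention (built from lexicon terms, optionally carrying
#' a body-part term drawn from the configured region distribution), and
#' pain-negative patients receive none. Not-relevant mentions of each
#' category are planted per note with the configured probabilities in both
#' groups, using the bundled template sentences. Note dates are uniform
#' over the window; each patient holds `1 + Poisson(mean - 1)` notes.
#'
#' @param config A [cohort_config()].
#' @param patients Output of [generate_patients()].
#' @return List with `notes` (tibble `note_id`, `patient_id`, `date`,
#'   `text`) and `mentions` — the planted-mention truth ledger (`note_id`,
#'   `patient_id`, `category`, `relevant`, `term` = the lexicon term a
#'   keyword scan should report, `anatomy_term`, `region`, `sentence`).
#' @export
generate_notes <- function(config, patients) {
  set.seed(block_seed(config$seed, "notes"))
  n <- nrow(patients)
  mp <- config$mention_profile
  lex_terms <- load_lexicon()$term
  parts <- anatomy_parts_by_region()
  nr_templates <- not_relevant_templates()
  nr_terms <- nr_expected_terms()
  window_days <- as.integer(config$window_end - config$window_start)

  n_notes <- 1L + rpois(n, max(config$notes_per_patient - 1, 0))
  note_pat <- rep(seq_len(n), n_notes)
  total_notes <- length(note_pat)
  note_id <- sprintf("n%07d", seq_len(total_notes))
  note_date <- config$window_start + sample.int(window_days + 1L, total_notes,
                                                replace = TRUE) - 1L
  # planted relevant mentions per note (pain-positive patients only)
  k_rel <- ifelse(patients$truth_pain[note_pat],
                  rpois(total_notes, mp$mean_relevant), 0L)
  # guarantee >= 1 relevant mention per pain-positive patient
  tot_rel <- tapply(k_rel, note_pat, sum)
  need <- which(patients$truth_pain & tot_rel[as.character(seq_len(n))] == 0)
  if (length(need)) {
    first_note <- match(need, note_pat)
    k_rel[first_note] <- 1L
  }
  # planted not-relevant mentions: per note, per category
  cats <- names(nr_templates)
  k_nr <- vapply(cats, function(cat)
    rbinom(total_notes, 1, mp$p_not_relevant[[cat]]), integer(total_notes))
  if (is.null(dim(k_nr))) k_nr <- matrix(k_nr, nrow = total_notes)

  # planted relevant mentions, realized in one vectorized pass
  rel_note <- rep.int(seq_len(total_notes), k_rel)
  n_rel <- length(rel_note)
  rel <- NULL
  if (n_rel > 0) {
    has_anat <- runif(n_rel) < mp$p_anatomy
    region <- rep(NA_character_, n_rel)
    part <- rep(NA_character_, n_rel)
    term <- character(n_rel)
    sentence <- character(n_rel)
    n_a <- sum(has_anat)
    if (n_a > 0) {
      region[has_anat] <- sample(names(mp$region_probs), n_a, replace = TRUE,
                                 prob = mp$region_probs)
      for (r in unique(region[has_anat])) {
        sel <- which(has_anat & region == r)
        part[sel] <- sample(parts[[r]], length(sel), replace = TRUE)
      }
      # which lexicon term a keyword scan will report for "<part> pain"
      part_term <- vapply(unique(part[has_anat]), function(p)
        expected_hit_term(paste(p, "pain"), lex_terms), character(1))
      term[has_anat] <- part_term[part[has_anat]]
      sentence[has_anat] <- sprintf(
        sample(relevant_anatomy_templates(), n_a, replace = TRUE),
        part[has_anat])
    }
    if (n_rel - n_a > 0) {
      term[!has_anat] <- sample(relevant_plain_terms(), n_rel - n_a,
                                replace = TRUE)
      sentence[!has_anat] <- sprintf(
        sample(relevant_plain_templates(), n_rel - n_a, replace = TRUE),
        term[!has_anat])
    }
    rel <- tibble(note_idx = rel_note, category = "affirmed", relevant = TRUE,
                  term = term, anatomy_term = part, region = region,
                  sentence = sentence)
  }
  # planted not-relevant mentions per category
  nr <- purrr::map(seq_along(cats), function(ci) {
    rows <- which(k_nr[, ci] > 0)
    if (!length(rows)) return(NULL)
    ti <- sample.int(length(nr_templates[[ci]]), length(rows), replace = TRUE)
    tibble(note_idx = rows, category = cats[ci], relevant = FALSE,
           term = nr_terms[[ci]][ti], anatomy_term = NA_character_,
           region = NA_character_, sentence = nr_templates[[ci]][ti])
  }) |> bind_rows()
  mentions <- bind_rows(rel, nr)
  if (nrow(mentions) == 0) {
    mentions <- tibble(note_idx = integer(), category = character(),
                       relevant = logical(), term = character(),
                       anatomy_term = character(), region = character(),
                       sentence = character())
  }
  mentions <- arrange(mentions, .data$note_idx, dplyr::desc(.data$relevant))
  fillers <- filler_sentences()
  body <- vapply(split(mentions$sentence, factor(mentions$note_idx,
                                                 levels = seq_len(total_notes))),
                 paste, character(1), collapse = " ")
  i <- seq_len(total_notes)
  texts <- stringr::str_squish(paste(fillers[1 + (i %% 2)], body,
                                     fillers[3 + (i %% 2)]))
  notes <- tibble(note_id = note_id,
                  patient_id = patients$patient_id[note_pat],
                  date = note_date, text = texts)
  mentions <- mentions |>
    mutate(note_id = note_id[.data$note_idx],
           patient_id = patients$patient_id[note_pat[.data$note_idx]]) |>
    select("note_id", "patient_id", "category", "relevant", "term",
           "anatomy_term", "region", "sentence")
  list(notes = notes, mentions = mentions)
}

non_pain_codes <- function() {
  c("9N11.", "42Q5.", "246..", "65E..", "8B316", "1371.")
}

#' Generate linked primary-care coded events
#'
#' A configurable fraction of patients has primary-care records; among
#' them, the probability of carrying a coded pain record depends on the
#' latent recorded-pain status. Pain codes are drawn from the bundled
#' synthetic code lists; linked patients without coded pain may carry
#' unrelated administrative codes.
#'
#' @param config A [cohort_config()].
#' @param patients Output of [generate_patients()].
#' @return List with `events` (tibble `patient_id`, `code`, `code_type`,
#'   `date`) and `linkage` (tibble `patient_id`, `linked`, `coded_pain`).
#' @export
generate_coded_events <- function(config, patients) {
  set.seed(block_seed(config$seed, "coded"))
  n <- nrow(patients)
  lk <- config$linkage
  linked <- rbinom(n, 1, lk$p_linked) == 1
  p_coded <- ifelse(patients$truth_pain, lk$p_coded_given_pain,
                    lk$p_coded_given_no_pain)
  coded <- linked & (rbinom(n, 1, p_coded) == 1)
  lists <- load_code_lists()
  window_days <- as.integer(config$window_end - config$window_start)
  mk_events <- function(idx, k_mean, pool_codes, pool_kinds) {
    k <- 1L + rpois(length(idx), k_mean)
    pat <- rep(patients$patient_id[idx], k)
    pick <- sample.int(length(pool_codes), length(pat), replace = TRUE)
    tibble(patient_id = pat,
           code = pool_codes[pick],
           code_type = pool_kinds[pick],
           date = config$window_start +
             sample.int(window_days + 1L, length(pat), replace = TRUE) - 1L)
  }
  ev_pain <- if (any(coded)) {
    mk_events(which(coded), 1, lists$code, lists$kind)
  } else NULL
  other_idx <- which(linked & !coded)
  ev_other <- if (length(other_idx)) {
    mk_events(other_idx, 0.5, non_pain_codes(),
              rep("administrative", length(non_pain_codes())))
  } else NULL
  events <- bind_rows(ev_pain, ev_other)
  if (is.null(events) || nrow(events) == 0) {
    events <- tibble(patient_id = character(), code = character(),
                     code_type = character(), date = as.Date(character()))
  }
  events <- arrange(events, .data$patient_id, .data$date, .data$code)
  list(events = events,
       linkage = tibble(patient_id = patients$patient_id,
                        linked = linked, coded_pain = coded))
}

#' Generate a full synthetic linked-EHR cohort
#'
#' Runs the three generator blocks — patients with latent recorded-pain
#' status, dated notes realizing that status through planted mentions, and
#' linked primary-care coded events — under a single seed. Identical
#' config and seed give byte-identical output.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort`: `patients` (no latent label),
#'   `notes`, `coded_events`, `truth` (list with `patients` — latent labels
#'   and linkage — and `mentions`, the planted-mention ledger) and `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 20, seed = 42))
#' cohort$patients
generate_cohort <- function(config) {
  validate_cohort_config(config)
  pats <- generate_patients(config)
  txt <- generate_notes(config, pats)
  cd <- generate_coded_events(config, pats)
  patients <- pats |>
    mutate(in_primary_care = cd$linkage$linked) |>
    select(-"truth_pain")
  truth <- list(
    patients = pats |>
      select("patient_id", pain = "truth_pain") |>
      left_join(cd$linkage, by = "patient_id"),
    mentions = txt$mentions
  )
  structure(list(patients = patients, notes = txt$notes,
                 coded_events = cd$events, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$patients), "patients,", nrow(x$notes),
      "notes,", nrow(x$coded_events), "coded events\n")
  invisible(x)
}

#' Write a synthetic cohort to disk / read it back
#'
#' Emits `patients.csv`, `notes.jsonl` (one JSON object per note),
#' `coded_events.csv` and `truth.json` into `directory`.
#'
#' @param cohort A `synthetic_cohort`.
#' @param directory Output directory (created if absent).
#' @return `write_cohort()` returns the manifest tibble (`file`,
#'   `n_records`); `read_cohort()` returns a `synthetic_cohort` equal to
#'   the one written (minus the config).
#' @export
write_cohort <- function(cohort, directory) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(paste0("cannot create directory: ", directory))
  }
  p <- function(f) file.path(directory, f)
  readr::write_csv(cohort$patients, p("patients.csv"), na = "")
  con <- file(p("notes.jsonl"), open = "wt")
  on.exit(close(con), add = TRUE)
  if (nrow(cohort$notes) > 0) {
    lines <- vapply(seq_len(nrow(cohort$notes)), function(i) {
      jsonlite::toJSON(list(note_id = cohort$notes$note_id[i],
                            patient_id = cohort$notes$patient_id[i],
                            date = format(cohort$notes$date[i]),
                            text = cohort$notes$text[i]),
                       auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, con)
  }
  readr::write_csv(cohort$coded_events, p("coded_events.csv"), na = "")
  jsonlite::write_json(
    list(patients = cohort$truth$patients, mentions = cohort$truth$mentions),
    p("truth.json"), dataframe = "rows", na = "null", auto_unbox = TRUE,
    digits = NA)
  tibble(file = c("patients.csv", "notes.jsonl", "coded_events.csv",
                  "truth.json"),
         n_records = c(nrow(cohort$patients), nrow(cohort$notes),
                       nrow(cohort$coded_events),
                       nrow(cohort$truth$patients)))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(directory) {
  p <- function(f) file.path(directory, f)
  for (f in c("patients.csv", "notes.jsonl", "coded_events.csv", "truth.json")) {
    if (!file.exists(p(f))) abort(paste0("missing cohort file: ", p(f)))
  }
  patients <- readr::read_csv(
    p("patients.csv"), show_col_types = FALSE,
    col_types = readr::cols(patient_id = "c", age_years = "i", gender = "c",
                            ethnicity = "c", imd_decile = "i",
                            icd10_primary = "c", active_referral = "l",
                            in_primary_care = "l"))
  lines <- readLines(p("notes.jsonl"))
  notes <- if (length(lines)) {
    bind_rows(lapply(lines, function(l) {
      o <- jsonlite::fromJSON(l)
      tibble(note_id = o$note_id, patient_id = o$patient_id,
             date = as.Date(o$date), text = o$text)
    }))
  } else {
    tibble(note_id = character(), patient_id = character(),
           date = as.Date(character()), text = character())
  }
  coded <- readr::read_csv(
    p("coded_events.csv"), show_col_types = FALSE,
    col_types = readr::cols(patient_id = "c", code = "c", code_type = "c",
                            date = "D"))
  tr <- jsonlite::fromJSON(p("truth.json"))
  truth <- list(patients = as_tibble(tr$patients),
                mentions = as_tibble(tr$mentions))
  structure(list(patients = patients, notes = notes, coded_events = coded,
                 truth = truth, config = NULL),
            class = "synthetic_cohort")
}
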