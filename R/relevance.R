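#' Load a relevance rule set
#'
#' The rule set drives [classify_mention()]: ordered cue/pattern families
#' with token scope windows. Families apply in fixed precedence —
#' form > misspelling > negation > hypothetical > metaphorical — and a hit
#' that triggers none of them is affirmed (relevant). The bundled default
#' operationalizes the standard not-relevant taxonomy for pain mentions in
#' clinical text: negated mentions ("denied pain"), form/questionnaire
#' boilerplate ("...? for example, chest pain"), misspelling artefacts
#' ("pained and decorated the walls"), hypothetical mentions ("fear that
#' eating will cause throat pain") and metaphorical uses ("life is too
#' painful to carry on living").
#'
#' @param path YAML file; defaults to the bundled rule set.
#' @return A list of class `pain_ruleset` with elements `negation`
#'   (`cues`, `scope`), `hypothetical` (`cues`, `scope`), `form_patterns`,
#'   `misspelling_patterns`, `metaphorical_patterns`.
#' @export
load_ruleset <- function(path = painrecord_file("relevance_rules.yaml")) {
  raw <- yaml::read_yaml(path)
  rules <- list(
    negation = list(cues = tolower(unlist(raw$negation$cues)),
                    scope = as.integer(raw$negation$scope %||% 5L)),
    hypothetical = list(cues = tolower(unlist(raw$hypothetical$cues)),
                        scope = as.integer(raw$hypothetical$scope %||% 10L)),
    form_patterns = unlist(raw$form_patterns),
    misspelling_patterns = unlist(raw$misspelling_patterns),
    metaphorical_patterns = unlist(raw$metaphorical_patterns)
  )
  if (rules$negation$scope < 0 || rules$hypothetical$scope < 0) {
    abort("rule scope windows must be >= 0", class = "painrecord_config_error")
  }
  structure(rules, class = "pain_ruleset")
}

#' @rdname load_ruleset
#' @export
default_ruleset <- function() load_ruleset()

not_relevant_categories <- function() {
  c("negated", "form", "misspelling", "hypothetical", "metaphorical")
}

# token windows before each hit; "but" resets the scope
cue_windows <- function(pre_text, scope) {
  toks_all <- stringr::str_split(tolower(pre_text), "[^a-z0-9']+")
  win <- character(length(pre_text))
  initial <- character(length(pre_text))
  for (i in seq_along(toks_all)) {
    toks <- toks_all[[i]]
    toks <- toks[nzchar(toks)]
    but_pos <- which(toks == "but")
    no_but <- length(but_pos) == 0
    if (!no_but) toks <- toks[seq_along(toks) > max(but_pos)]
    win[i] <- paste(tail(toks, scope), collapse = " ")
    initial[i] <- if (no_but && length(toks)) toks[1] else ""
  }
  list(window = win, initial = initial)
}

# first cue (in list order) found in each window; sentence-initial single-token
# cues govern the hit even beyond the window unless a "but" intervenes
match_cues <- function(pre_text, cues, scope) {
  w <- cue_windows(pre_text, scope)
  out <- rep(NA_character_, length(pre_text))
  for (cue in cues) {
    hit <- is.na(out) & stringr::str_detect(w$window, paste0("\\b", cue, "\\b"))
    out[hit] <- cue
  }
  init <- is.na(out) & w$initial %in% cues
  out[init] <- w$initial[init]
  out
}

# first pattern (in list order) matching each string
match_patterns <- function(text, patterns) {
  out <- rep(NA_character_, length(text))
  for (p in patterns) {
    hit <- is.na(out) &
      stringr::str_detect(text, stringr::regex(p, ignore_case = TRUE))
    out[hit] <- p
  }
  out
}

#' Classify a single keyword hit as relevant or not-relevant
#'
#' @param sentence_text Sentence containing the hit.
#' @param start,end 1-based inclusive offsets of the hit in the sentence.
#' @param rules A `pain_ruleset` (default bundled).
#' @return A one-row tibble: `label` (`relevant`/`not_relevant`), `category`
#'   (`affirmed` for relevant; `negated`, `form`, `misspelling`,
#'   `hypothetical` or `metaphorical` otherwise) and `trigger` (the cue or
#'   pattern that fired, `"default"` for affirmed hits).
#' @export
#' @examples
#' classify_mention("denied pain this morning", 8, 11)
#' classify_mention("complains of pain", 14, 17)
classify_mention <- function(sentence_text, start, end,
                             rules = default_ruleset()) {
  classify_hits(sentence_text, start, rules)
}

classify_hits <- function(sentence_text, start, rules) {
  low <- tolower(sentence_text)
  pre <- stringr::str_sub(low, 1, start - 1)
  n <- length(low)
  category <- rep(NA_character_, n)
  trigger <- rep(NA_character_, n)
  set_cat <- function(idx, cat, trig) {
    category[idx] <<- cat
    trigger[idx] <<- trig[idx]
  }
  t_form <- match_patterns(low, rules$form_patterns)
  set_cat(which(!is.na(t_form)), "form", t_form)
  t_miss <- match_patterns(low, rules$misspelling_patterns)
  set_cat(which(is.na(category) & !is.na(t_miss)), "misspelling", t_miss)
  t_neg <- match_cues(pre, rules$negation$cues, rules$negation$scope)
  set_cat(which(is.na(category) & !is.na(t_neg)), "negated", t_neg)
  t_hyp <- match_cues(pre, rules$hypothetical$cues, rules$hypothetical$scope)
  set_cat(which(is.na(category) & !is.na(t_hyp)), "hypothetical", t_hyp)
  t_met <- match_patterns(low, rules$metaphorical_patterns)
  set_cat(which(is.na(category) & !is.na(t_met)), "metaphorical", t_met)
  trigger[is.na(category)] <- "default"
  category[is.na(category)] <- "affirmed"
  tibble(label = if_else(category == "affirmed", "relevant", "not_relevant"),
         category = category, trigger = trigger)
}

#' Classify every keyword hit in a mention stream
#'
#' @param mentions Tibble of keyword hits from [detect_mentions()] /
#'   [match_keywords()] (needs `sentence_text`, `start`, `end`).
#' @param rules A `pain_ruleset`.
#' @return The input tibble with `label`, `category`, `trigger` columns
#'   appended; every hit receives exactly one label.
#' @export
classify_mentions <- function(mentions, rules = default_ruleset()) {
  if (nrow(mentions) == 0) {
    return(bind_cols(mentions, tibble(label = character(),
                                      category = character(),
                                      trigger = character())))
  }
  labs <- classify_hits(mentions$sentence_text, mentions$start, rules)
  bind_cols(mentions, labs)
}

#' Summarise classified mentions by label and category
#'
#' @param classified Output of [classify_mentions()].
#' @return Tibble with `label`, `category`, `n`.
#' @export
mention_counts <- function(classified) {
  classified |>
    count(.data$label, .data$category, name = "n") |>
    arrange(dplyr::desc(.data$label), .data$category)
}

#' Roll classified mentions up to patient-level recorded-pain classes
#'
#' A patient is class 1 (recorded pain) iff at least one of their keyword
#' hits was labelled relevant; patients with no hits, or only not-relevant
#' hits, are class 0.
#'
#' @param classified Output of [classify_mentions()] (needs `patient_id`,
#'   `label`).
#' @param patients Cohort patient tibble (needs `patient_id`). Mentions for
#'   patients outside this cohort are dropped with a warning.
#' @return `patients` with appended columns `n_mentions` (keyword hits),
#'   `n_relevant`, `keyword_any` (logical) and `pain_class`
#'   (`"class0"`/`"class1"`).
#' @export
rollup_patients <- function(classified, patients) {
  stopifnot("patient_id" %in% names(patients))
  orphan <- setdiff(unique(classified$patient_id), patients$patient_id)
  if (length(orphan)) {
    warn(sprintf("dropping %d mentions for %d patients outside the cohort",
                 sum(classified$patient_id %in% orphan), length(orphan)))
    classified <- filter(classified, !.data$patient_id %in% orphan)
  }
  per_pat <- classified |>
    group_by(.data$patient_id) |>
    summarise(n_mentions = dplyr::n(),
              n_relevant = sum(.data$label == "relevant"),
              .groups = "drop")
  patients |>
    left_join(per_pat, by = "patient_id") |>
    mutate(n_mentions = dplyr::coalesce(.data$n_mentions, 0L),
           n_relevant = dplyr::coalesce(.data$n_relevant, 0L),
           keyword_any = .data$n_mentions > 0,
           pain_class = if_else(.data$n_relevant > 0, "class1", "class0"))
}
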