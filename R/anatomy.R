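#' The closed set of body regions
#'
#' Seven aggregate regions used to summarise body-part mentions:
#' lower limbs; upper body excluding back; upper limbs; stomach/abdomen;
#' head and neck; non-specific site; back.
#'
#' @return Character vector of the seven region identifiers.
#' @export
body_regions <- function() {
  c("lower_limbs", "upper_body_excl_back", "upper_limbs", "stomach_abdomen",
    "head_neck", "non_specific", "back")
}

#' Load a body-part to region gazetteer
#'
#' @param path CSV with columns `term`, `region` and optional `concept_id`
#'   (e.g. a SNOMED CT identifier, kept as inert metadata). Defaults to the
#'   bundled map covering common body-part surface forms ("knee", "lower
#'   back", "side of chest", ...) aggregated into the seven regions of
#'   [body_regions()].
#' @return Tibble of class `body_region_map` with columns `term`, `region`,
#'   `concept_id`.
#' @export
load_region_map <- function(path = painrecord_file("body_regions.csv")) {
  map <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c")) |>
    mutate(term = stringr::str_squish(tolower(.data$term)),
           region = tolower(.data$region)) |>
    distinct(.data$term, .keep_all = TRUE)
  if (!"concept_id" %in% names(map)) map$concept_id <- NA_character_
  bad <- setdiff(unique(map$region), body_regions())
  if (length(bad)) {
    abort(paste0("unknown body regions in map: ", paste(bad, collapse = ", ")),
          class = "painrecord_config_error")
  }
  class(map) <- c("body_region_map", class(map))
  map
}

#' @rdname load_region_map
#' @export
default_region_map <- function() load_region_map()

#' Extract body-part mentions from relevant pain sentences
#'
#' One case-insensitive, word-boundary gazetteer pass per sentence, with
#' regular-plural tolerance and longest-match-first overlap resolution
#' ("lower back" beats "back"). Intended to run on sentences that carry a
#' relevant pain mention; enforcement of that restriction is the caller's.
#'
#' @param sentences Tibble with `sentence_id` and a sentence text column
#'   (`sentence_text` or `text`); other columns are carried through.
#' @param region_map A [load_region_map()] tibble.
#' @return Tibble: carried columns plus `term`, `region`, `start`, `end`.
#' @export
#' @examples
#' s <- tibble::tibble(sentence_id = "s1", sentence_text = "worsening knee pain")
#' extract_anatomy(s)
extract_anatomy <- function(sentences, region_map = default_region_map()) {
  txt_col <- if ("sentence_text" %in% names(sentences)) "sentence_text" else "text"
  stopifnot(txt_col %in% names(sentences), "sentence_id" %in% names(sentences))
  lex <- tibble(term = region_map$term, verb = FALSE)
  class(lex) <- c("pain_lexicon", class(lex))
  sent <- sentences |>
    distinct(.data$sentence_id, .keep_all = TRUE) |>
    rename(text = dplyr::all_of(txt_col)) |>
    select(-dplyr::any_of(c("start", "end", "term")))
  hits <- match_keywords(sent, lex)
  left_join(hits, select(region_map, "term", "region"), by = "term")
}

#' Region frequency table for anatomy mentions
#'
#' Percentages are computed over mapped anatomy mentions within each group
#' (the only convention under which they sum to 100).
#'
#' @param anatomy Output of [extract_anatomy()]; may carry a grouping
#'   column (e.g. an `smi` flag joined from the cohort) and a `patient_id`.
#' @param by Optional name of a grouping column; `NULL` gives one overall
#'   group `"all"`.
#' @return Tibble with `group`, `region`, `count`, `percent` (all seven
#'   regions always present, zero-filled). Attributes `n_patients_with_anatomy`
#'   and `mean_regions_per_patient` are attached when `patient_id` is
#'   available. An empty input yields the zero table.
#' @export
region_frequency <- function(anatomy, by = NULL) {
  grp <- if (is.null(by)) rep("all", nrow(anatomy)) else as.character(anatomy[[by]])
  groups <- if (is.null(by)) "all" else unique(grp)
  base <- tidyr::expand_grid(group = groups, region = body_regions())
  counts <- tibble(group = grp, region = anatomy$region) |>
    count(.data$group, .data$region, name = "count")
  out <- base |>
    left_join(counts, by = c("group", "region")) |>
    mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    group_by(.data$group) |>
    mutate(percent = if (sum(.data$count) > 0)
      100 * .data$count / sum(.data$count) else 0) |>
    ungroup()
  if ("patient_id" %in% names(anatomy) && nrow(anatomy) > 0) {
    per_pat <- anatomy |>
      group_by(.data$patient_id) |>
      summarise(k = dplyr::n_distinct(.data$region), .groups = "drop")
    attr(out, "n_patients_with_anatomy") <- nrow(per_pat)
    attr(out, "mean_regions_per_patient") <- mean(per_pat$k)
  }
  out
}
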