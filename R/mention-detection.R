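#' Load a pain-term lexicon
#'
#' Reads a CSV lexicon, one term per row in the first column. An optional
#' `verb` column flags terms that take verbal inflection ("-ed"/"-ing") in
#' addition to the plural "s" every term tolerates. Terms are lowercased,
#' trimmed, deduplicated and sorted.
#'
#' @param path CSV path. Defaults to the bundled lexicon, a compact default
#'   built around the common surface forms of pain language in clinical
#'   notes ("pain", "back pain", "headache", "aching muscles", "myalgia",
#'   ...); replace it with a larger domain lexicon for production use.
#' @return A tibble of class `pain_lexicon` with columns `term`, `verb`.
#' @export
#' @examples
#' lex <- load_lexicon()
#' head(lex$term)
load_lexicon <- function(path = painrecord_file("pain_lexicon.csv")) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    abort(paste0("lexicon contains no terms: ", path),
          class = "painrecord_config_error")
  }
  # tolerate headerless single-column files: read_csv treats row 1 as header
  first_col <- names(raw)[1]
  terms <- c(if (!tolower(first_col) %in% c("term", "terms")) first_col,
             raw[[1]])
  verb <- if ("verb" %in% names(raw)) {
    v <- tolower(raw$verb) %in% c("true", "t", "1", "yes")
    c(if (!tolower(first_col) %in% c("term", "terms")) FALSE, v)
  } else {
    rep(FALSE, length(terms))
  }
  lex <- tibble(term = stringr::str_squish(tolower(terms)), verb = verb) |>
    filter(nzchar(.data$term)) |>
    distinct(.data$term, .keep_all = TRUE) |>
    arrange(.data$term)
  if (nrow(lex) == 0) {
    abort(paste0("lexicon contains no terms: ", path),
          class = "painrecord_config_error")
  }
  class(lex) <- c("pain_lexicon", class(lex))
  lex
}

painrecord_file <- function(...) {
  system.file("extdata", ..., package = "painrecord", mustWork = TRUE)
}

#' Split note text into sentences
#'
#' Deterministic rule-based splitter: a sentence ends at terminal
#' punctuation (`.`, `!`, `?`, possibly repeated) followed by whitespace or
#' end of text, or at a newline. Offsets are 1-based inclusive character
#' positions into the note text, so
#' `stringr::str_sub(text, start, end)` reproduces each sentence exactly.
#'
#' @param notes A tibble with columns `note_id` and `text` (a `patient_id`
#'   column, if present, is carried through).
#' @return A tibble with one row per sentence: `sentence_id`, `note_id`,
#'   (`patient_id`,) `start`, `end`, `text`. Empty or all-whitespace notes
#'   yield no rows.
#' @export
#' @examples
#' notes <- tibble::tibble(note_id = "n1", text = "Complains of pain. Slept well.")
#' split_sentences(notes)
split_sentences <- function(notes) {
  stopifnot(all(c("note_id", "text") %in% names(notes)))
  carry <- intersect("patient_id", names(notes))
  txts <- as.character(notes$text)
  txts[is.na(txts)] <- ""
  bounds <- stringr::str_locate_all(txts, "[.!?]+(?=\\s|$)|\\n")
  idx_l <- vector("list", length(txts))
  start_l <- vector("list", length(txts))
  end_l <- vector("list", length(txts))
  for (i in seq_along(txts)) {
    nc <- nchar(txts[i])
    if (nc == 0) next
    cut_ends <- unique(c(bounds[[i]][, "end"], nc))
    idx_l[[i]] <- rep.int(i, length(cut_ends))
    start_l[[i]] <- c(1L, head(cut_ends, -1) + 1L)
    end_l[[i]] <- cut_ends
  }
  idx <- unlist(idx_l)
  res <- if (length(idx)) {
    st <- as.integer(unlist(start_l))
    en <- as.integer(unlist(end_l))
    raw <- stringr::str_sub(txts[idx], st, en)
    st <- st + stringr::str_length(stringr::str_extract(raw, "^\\s*"))
    en <- en - stringr::str_length(stringr::str_extract(raw, "\\s*$"))
    ok <- st <= en
    tibble(note_id = notes$note_id[idx[ok]],
           start = st[ok], end = en[ok],
           text = stringr::str_sub(txts[idx[ok]], st[ok], en[ok]))
  } else {
    tibble(note_id = character(), start = integer(), end = integer(),
           text = character())
  }
  if (nrow(res) == 0) {
    return(tibble(sentence_id = character(), note_id = character(),
                  start = integer(), end = integer(), text = character()))
  }
  res <- res |>
    group_by(.data$note_id) |>
    mutate(sentence_id = paste0(.data$note_id, "_s", row_number())) |>
    ungroup() |>
    select("sentence_id", "note_id", "start", "end", "text")
  if (length(carry)) {
    res <- left_join(res, notes[, c("note_id", carry)], by = "note_id") |>
      select("sentence_id", "note_id", dplyr::all_of(carry), "start", "end", "text")
  }
  res
}

term_pattern <- function(term, verb) {
  words <- strsplit(term, " ", fixed = TRUE)[[1]]
  last <- words[length(words)]
  esc <- function(w) stringr::str_replace_all(w, "([.\\\\+*?\\[^\\]$(){}=!<>|:\\-#])", "\\\\\\1")
  infl <- if (verb) {
    stem <- sub("e$", "", esc(last))
    paste0(stem, "(?:e|es|ed|ing)")
  } else {
    paste0(esc(last), "s?")
  }
  body <- paste(c(vapply(head(words, -1), esc, character(1)), infl), collapse = "\\s+")
  paste0("\\b", body, "\\b")
}

#' Match pain-lexicon keywords in sentences
#'
#' Case-insensitive, word-boundary matching with longest-match-first
#' overlap resolution: a shorter term wholly or partly inside an accepted
#' longer match is suppressed ("back pain" beats "pain"). Every term
#' tolerates a plural "s"; terms flagged as verbs in the lexicon also match
#' "-ed"/"-ing" forms.
#'
#' @param sentences A tibble from [split_sentences()] (needs `sentence_id`,
#'   `text`; other columns carried through).
#' @param lexicon A [load_lexicon()] tibble.
#' @return A tibble of keyword hits: the sentence columns plus `term`,
#'   `start`, `end` (1-based inclusive offsets within the sentence).
#'   Hits are ordered by sentence and start offset.
#' @export
#' @examples
#' s <- split_sentences(tibble::tibble(note_id = "n1", text = "Worsening back pain."))
#' match_keywords(s, load_lexicon())
match_keywords <- function(sentences, lexicon) {
  stopifnot(all(c("sentence_id", "text") %in% names(sentences)))
  meta <- sentences |>
    rename(sentence_text = "text") |>
    select(-dplyr::any_of(c("start", "end")))
  empty <- bind_cols(meta[0, , drop = FALSE],
                     tibble(term = character(), start = integer(),
                            end = integer()))
  if (nrow(sentences) == 0) return(empty)
  txts <- tolower(sentences$text)
  pats <- purrr::map2_chr(lexicon$term, lexicon$verb, term_pattern)
  # one vectorized scan over all sentences per lexicon term
  cand <- purrr::imap(pats, function(p, j) {
    locs <- stringr::str_locate_all(txts, p)
    nhit <- vapply(locs, nrow, integer(1))
    if (sum(nhit) == 0) return(NULL)
    m <- do.call(rbind, locs[nhit > 0])
    tibble(row = rep(which(nhit > 0), nhit[nhit > 0]),
           term = lexicon$term[j],
           start = as.integer(m[, "start"]),
           end = as.integer(m[, "end"]))
  }) |> bind_rows()
  if (is.null(cand) || nrow(cand) == 0) return(empty)
  cand <- cand |>
    mutate(len = .data$end - .data$start) |>
    arrange(.data$row, dplyr::desc(.data$len), .data$start)
  # longest-match-first suppression of overlapping shorter hits, per sentence
  keep <- logical(nrow(cand))
  grp_start <- which(!duplicated(cand$row))
  grp_end <- c(grp_start[-1] - 1L, nrow(cand))
  for (g in seq_along(grp_start)) {
    idx <- grp_start[g]:grp_end[g]
    t_s <- integer(0); t_e <- integer(0)
    for (k in idx) {
      if (!any(cand$start[k] <= t_e & cand$end[k] >= t_s)) {
        keep[k] <- TRUE
        t_s <- c(t_s, cand$start[k]); t_e <- c(t_e, cand$end[k])
      }
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- bind_cols(meta[cand$row, , drop = FALSE],
                   select(cand, "term", "start", "end"))
  arrange(out, .data$sentence_id, .data$start)
}

#' Detect pain-keyword mentions across a set of notes
#'
#' Convenience wrapper: segments each note into sentences and scans every
#' sentence for lexicon hits. This is the keyword prefilter of the
#' pipeline; its hits are then labelled by [classify_mentions()].
#'
#' @param notes Tibble with `note_id`, `patient_id`, `text`.
#' @param lexicon A [load_lexicon()] tibble (default: bundled lexicon).
#' @return Tibble of keyword hits (see [match_keywords()]).
#' @export
detect_mentions <- function(notes, lexicon = load_lexicon()) {
  match_keywords(split_sentences(notes), lexicon)
}
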