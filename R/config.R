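#' Configuration for the synthetic linked-EHR cohort generator
#'
#' Builds and validates the full parameter set that drives
#' [generate_cohort()]: cohort size and eligibility window, covariate
#' marginals, log-odds effects of each covariate on the latent
#' recorded-pain status, the mention-planting profile for note text, and
#' the primary-care linkage block.
#'
#' Defaults emulate a large urban secondary mental-healthcare cohort:
#' roughly balanced gender with a rare "not known" category, six ethnicity
#' categories including "not stated/known", about 72% of patients in the
#' more-deprived half of national IMD deciles (decile <= 5, lower decile =
#' more deprived), about 3% missing IMD, and a one-third SMI share. Effect
#' defaults are the log odds ratios typically reported for recorded pain in
#' such cohorts (female 1.42, Asian 1.30, black 1.49, deprived 1.64, SMI
#' 0.43, age 1.17 per 10 years); the intercept is calibrated so overall
#' recorded-pain prevalence is close to 52%.
#'
#' @param n_patients Number of patients to simulate (>= 1).
#' @param index_date,window_start,window_end Calendar dates (coerced with
#'   [as.Date()]); must satisfy `window_start < index_date < window_end`.
#' @param min_doc_chars Minimum note length (characters) for eligibility.
#' @param min_age Minimum age in years at the index date.
#' @param marginals Named list of per-covariate category probability tables
#'   (`gender`, `ethnicity`, `imd_decile` including a `not_known` entry,
#'   `smi`); each must sum to 1.
#' @param effects Named list of log-odds increments on recorded pain:
#'   `intercept`, `age_per_10y`, `gender` (female, not_known), `ethnicity`
#'   (asian, black, other, mixed, not_stated), `imd_deprived`, `smi`.
#'   Age enters as (age - 44)/10 so the intercept refers to a 44-year-old
#'   male white non-deprived non-SMI patient.
#' @param mention_profile Named list controlling planted text:
#'   `mean_relevant` (mean relevant mentions per pain-positive note),
#'   `p_not_relevant` (per-note probability of planting one mention of each
#'   not-relevant category), `p_anatomy` (probability a relevant mention
#'   names a body part), `region_probs` (distribution over the seven body
#'   regions, sums to 1).
#' @param notes_per_patient Mean notes per patient; every patient gets at
#'   least one note (1 + Poisson(mean - 1)).
#' @param linkage Named list: `p_linked` (probability a patient has
#'   primary-care records), `p_coded_given_pain` and `p_coded_given_no_pain`
#'   (probability of a coded pain record among linked patients, conditional
#'   on latent recorded-pain status).
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A validated list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 100, seed = 1)
#' cfg$effects$gender[["female"]]
cohort_config <- function(n_patients = 2000,
                          index_date = "2018-07-01",
                          window_start = "2017-07-01",
                          window_end = "2019-07-01",
                          min_doc_chars = 30,
                          min_age = 18,
                          marginals = default_marginals(),
                          effects = default_effects(),
                          mention_profile = default_mention_profile(),
                          notes_per_patient = 5,
                          linkage = default_linkage(),
                          seed = 1L) {
  cfg <- structure(
    list(
      n_patients = as.integer(n_patients),
      index_date = as.Date(index_date),
      window_start = as.Date(window_start),
      window_end = as.Date(window_end),
      min_doc_chars = as.integer(min_doc_chars),
      min_age = as.integer(min_age),
      marginals = marginals,
      effects = effects,
      mention_profile = mention_profile,
      notes_per_patient = notes_per_patient,
      linkage = linkage,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @export
default_marginals <- function() {
  imd <- c(rep(0.72250 / 5, 5), rep(0.24571 / 5, 5))
  names(imd) <- as.character(1:10)
  imd <- c(imd, not_known = 1 - sum(imd))
  list(
    gender = c(male = 0.49506, female = 0.50380, not_known = 0.00114),
    ethnicity = c(white = 0.48285, black = 0.21558, not_stated = 0.17302,
                  asian = 0.05535, other = 0.04399, mixed = 0.02921),
    imd_decile = imd,
    smi = c(smi = 0.32935, non_smi = 0.67065)
  )
}

#' @rdname cohort_config
#' @export
default_effects <- function() {
  list(
    intercept = -0.07,
    age_per_10y = log(1.17),
    gender = c(female = log(1.42), not_known = log(0.69)),
    ethnicity = c(asian = log(1.30), black = log(1.49), other = log(1.12),
                  mixed = log(1.03), not_stated = log(0.31)),
    imd_deprived = log(1.64),
    smi = log(0.43)
  )
}

#' @rdname cohort_config
#' @export
default_mention_profile <- function() {
  list(
    mean_relevant = 3,
    p_not_relevant = c(negated = 0.15, form = 0.05, misspelling = 0.02,
                       hypothetical = 0.05, metaphorical = 0.05),
    p_anatomy = 0.5,
    region_probs = c(lower_limbs = 0.20, upper_body_excl_back = 0.19,
                     upper_limbs = 0.17, stomach_abdomen = 0.16,
                     head_neck = 0.15, non_specific = 0.08, back = 0.05)
  )
}

#' @rdname cohort_config
#' @export
default_linkage <- function() {
  list(p_linked = 0.177, p_coded_given_pain = 0.60, p_coded_given_no_pain = 0.30)
}

config_error <- function(field, msg) {
  abort(paste0("invalid cohort_config: field `", field, "` ", msg),
        class = "painrecord_config_error")
}

check_prob_table <- function(x, field) {
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    config_error(field, "must be a named numeric probability table")
  }
  if (any(x < 0)) config_error(field, "has negative probabilities")
  if (abs(sum(x) - 1) > 1e-9) {
    config_error(field, sprintf("must sum to 1 (got %.12f)", sum(x)))
  }
  invisible(x)
}

validate_cohort_config <- function(cfg) {
  if (is.na(cfg$n_patients) || cfg$n_patients < 1L) {
    config_error("n_patients", "must be >= 1")
  }
  for (f in c("index_date", "window_start", "window_end")) {
    if (is.na(cfg[[f]])) config_error(f, "is not a valid date")
  }
  if (!(cfg$window_start < cfg$index_date && cfg$index_date < cfg$window_end)) {
    config_error("index_date", "must satisfy window_start < index_date < window_end")
  }
  if (is.na(cfg$min_doc_chars) || cfg$min_doc_chars < 0L) {
    config_error("min_doc_chars", "must be >= 0")
  }
  if (is.na(cfg$min_age) || cfg$min_age < 0L) config_error("min_age", "must be >= 0")
  check_prob_table(cfg$marginals$gender, "marginals$gender")
  check_prob_table(cfg$marginals$ethnicity, "marginals$ethnicity")
  check_prob_table(cfg$marginals$imd_decile, "marginals$imd_decile")
  check_prob_table(cfg$marginals$smi, "marginals$smi")
  mp <- cfg$mention_profile
  if (!is.numeric(mp$mean_relevant) || mp$mean_relevant < 0) {
    config_error("mention_profile$mean_relevant", "must be >= 0")
  }
  if (any(mp$p_not_relevant < 0 | mp$p_not_relevant > 1)) {
    config_error("mention_profile$p_not_relevant", "entries must lie in [0, 1]")
  }
  if (mp$p_anatomy < 0 || mp$p_anatomy > 1) {
    config_error("mention_profile$p_anatomy", "must lie in [0, 1]")
  }
  check_prob_table(mp$region_probs, "mention_profile$region_probs")
  if (!setequal(names(mp$region_probs), body_regions())) {
    config_error("mention_profile$region_probs",
                 "must cover exactly the seven body regions")
  }
  if (!is.numeric(cfg$notes_per_patient) || cfg$notes_per_patient < 1) {
    config_error("notes_per_patient", "must be >= 1")
  }
  lk <- cfg$linkage
  for (f in c("p_linked", "p_coded_given_pain", "p_coded_given_no_pain")) {
    if (is.null(lk[[f]]) || lk[[f]] < 0 || lk[[f]] > 1) {
      config_error(paste0("linkage$", f), "must lie in [0, 1]")
    }
  }
  if (is.na(cfg$seed)) config_error("seed", "must be an integer")
  invisible(cfg)
}

#' Read or write a generator configuration as YAML
#'
#' @param path Path to a YAML file.
#' @return `read_cohort_config()` returns a `cohort_config`;
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  for (blk in c("marginals", "effects", "mention_profile", "linkage")) {
    if (!is.null(args[[blk]])) {
      args[[blk]] <- lapply(args[[blk]], function(x) {
        if (is.list(x)) unlist(x) else x
      })
    }
  }
  do.call(cohort_config, args)
}

#' @rdname read_cohort_config
#' @param config A `cohort_config` object.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  out <- unclass(config)
  out$index_date <- format(out$index_date)
  out$window_start <- format(out$window_start)
  out$window_end <- format(out$window_end)
  for (blk in c("marginals", "effects", "mention_profile", "linkage")) {
    out[[blk]] <- lapply(out[[blk]], function(x) {
      if (!is.null(names(x)) && length(x) > 1) as.list(x) else unname(x)
    })
  }
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat("  n_patients:", x$n_patients, " seed:", x$seed, "\n")
  cat("  window:", format(x$window_start), "..", format(x$window_end),
      " index:", format(x$index_date), "\n")
  cat("  eligibility: age >=", x$min_age, ", note >=", x$min_doc_chars, "chars\n")
  invisible(x)
}
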