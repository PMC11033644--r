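#' Unadjusted odds ratio from a 2x2 contingency table
#'
#' Cross-product estimate with a Wald confidence interval on the log scale:
#' OR = (a d)/(b c), SE(log OR) = sqrt(1/a + 1/b + 1/c + 1/d), two-sided p
#' from the Wald z statistic. All four cells must be positive: a zero cell
#' is an error (no silent continuity correction is applied) and the caller
#' should decide on a continuity handling explicitly.
#'
#' @param a Exposed with outcome.
#' @param b Unexposed with outcome.
#' @param c Exposed without outcome.
#' @param d Unexposed without outcome.
#' @param term,reference Optional labels carried into the result.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `term`, `reference`, `estimate`, `ci_low`,
#'   `ci_high`, `p_value`, `a`, `b`, `c`, `d`.
#' @export
#' @examples
#' unadjusted_or(a = 7756, b = 6434, c = 5953, d = 7037,
#'               term = "female", reference = "male")
unadjusted_or <- function(a, b, c, d, term = "exposed", reference = "unexposed",
                          conf_level = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    abort("contingency cells must be non-negative numbers",
          class = "painrecord_stat_error")
  }
  if (any(cells == 0)) {
    abort(paste0("zero cell in 2x2 table (",
                 paste(names(cells)[cells == 0], collapse = ", "),
                 "): odds ratio undefined; apply an explicit continuity ",
                 "correction before calling unadjusted_or()"),
          class = "painrecord_stat_error")
  }
  log_or <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  wald <- log_or / se
  tibble(term = term, reference = reference,
         estimate = exp(log_or),
         ci_low = exp(log_or - z * se),
         ci_high = exp(log_or + z * se),
         p_value = 2 * pnorm(-abs(wald)),
         a = a, b = b, c = c, d = d)
}

#' Build a 2x2 table for a binary exposure contrast
#'
#' Counts `a` = exposed with outcome, `b` = reference with outcome,
#' `c` = exposed without outcome, `d` = reference without outcome. Rows
#' whose exposure value is neither level (e.g. "not known" categories) are
#' excluded from the table.
#'
#' @param data Tibble with one row per patient.
#' @param exposure Name of the exposure column.
#' @param outcome Name of a logical (or `"class1"`-coded) outcome column.
#' @param exposed_level,reference_level Values of `exposure` defining the
#'   contrast.
#' @return One-row tibble with `a`, `b`, `c`, `d`.
#' @export
contingency_2x2 <- function(data, exposure, outcome = "pain_class",
                            exposed_level, reference_level) {
  y <- data[[outcome]]
  if (!is.logical(y)) y <- y == "class1"
  x <- as.character(data[[exposure]])
  tibble(
    a = sum(x == exposed_level & y, na.rm = TRUE),
    b = sum(x == reference_level & y, na.rm = TRUE),
    c = sum(x == exposed_level & !y, na.rm = TRUE),
    d = sum(x == reference_level & !y, na.rm = TRUE)
  )
}

#' Unadjusted OR for a named contrast in patient-level data
#'
#' Convenience composition of [contingency_2x2()] and [unadjusted_or()].
#'
#' @inheritParams contingency_2x2
#' @inheritParams unadjusted_or
#' @export
cohort_or <- function(data, exposure, exposed_level, reference_level,
                      outcome = "pain_class", conf_level = 0.95) {
  tab <- contingency_2x2(data, exposure, outcome, exposed_level, reference_level)
  unadjusted_or(tab$a, tab$b, tab$c, tab$d,
                term = paste0(exposure, ":", exposed_level),
                reference = reference_level, conf_level = conf_level)
}
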