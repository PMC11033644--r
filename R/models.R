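#' Prepare patient-level data for association analysis
#'
#' Derives the analysis covariates used throughout the modelling stage:
#' `age_10` (age in decades, so coefficients are per 10 years), `gender`
#' and `ethnicity` factors with male / white references, `imd_group`
#' (deprivation dichotomized at national decile <= 5, reference `gt5`, with
#' `not_known` retained as an estimable level rather than dropped), and
#' `smi_group` (reference `non_smi`). The binary outcome `pain` is 1 for
#' recorded pain (class 1).
#'
#' @param data Tibble with `age_years`, `gender`, `ethnicity`, `imd_decile`,
#'   `pain_class` and either `smi` (logical) or `icd10_primary`.
#' @return The input with analysis columns appended. Factor levels are
#'   restricted to observed categories, reference first.
#' @export
prepare_analysis_data <- function(data) {
  if (!"smi" %in% names(data)) {
    data$smi <- derive_smi_flag(data$icd10_primary)
  }
  lvl <- function(x, preferred) {
    obs <- unique(as.character(x))
    c(intersect(preferred, obs), setdiff(obs, preferred))
  }
  data |>
    mutate(
      age_10 = .data$age_years / 10,
      gender = factor(as.character(.data$gender),
                      levels = lvl(.data$gender,
                                   c("male", "female", "not_known"))),
      ethnicity = factor(as.character(.data$ethnicity),
                         levels = lvl(.data$ethnicity,
                                      c("white", "asian", "black", "other",
                                        "mixed", "not_stated"))),
      imd_group = factor(
        case_when(is.na(.data$imd_decile) ~ "not_known",
                  .data$imd_decile <= 5 ~ "le5",
                  TRUE ~ "gt5"),
        levels = lvl(case_when(is.na(.data$imd_decile) ~ "not_known",
                               .data$imd_decile <= 5 ~ "le5",
                               TRUE ~ "gt5"),
                     c("gt5", "le5", "not_known"))),
      smi_group = factor(if_else(.data$smi, "smi", "non_smi"),
                         levels = lvl(if_else(.data$smi, "smi", "non_smi"),
                                      c("non_smi", "smi"))),
      pain = as.integer(if (is.logical(.data$pain_class)) .data$pain_class
                        else .data$pain_class == "class1")
    )
}

covariate_columns <- function() {
  c(age_per_10y = "age_10", gender = "gender", ethnicity = "ethnicity",
    imd = "imd_group", smi = "smi_group")
}

#' Fit a logistic regression of recorded pain on selected covariates
#'
#' Maximum-likelihood logistic fit with dummy-coded categorical covariates
#' against their stated references (male, white, IMD decile > 5, non-SMI)
#' and age entered linearly per 10 years. Effects are reported as odds
#' ratios with Wald confidence intervals via [tidy()].
#'
#' @param data Output of [prepare_analysis_data()] (or raw data with the
#'   columns it needs, prepared automatically).
#' @param covariates Subset of `c("age_per_10y", "gender", "ethnicity",
#'   "imd", "smi")`, in model order.
#' @param conf_level Confidence level for the Wald intervals.
#' @return An object of class `pain_model` wrapping the [stats::glm()] fit.
#' @export
#' @examples
#' \donttest{
#' cfg <- cohort_config(n_patients = 500, seed = 7)
#' pats <- generate_patients(cfg)
#' d <- dplyr::mutate(pats, pain_class = dplyr::if_else(truth_pain, "class1", "class0"))
#' fit <- fit_pain_model(d, c("age_per_10y", "gender"))
#' tidy(fit)
#' }
fit_pain_model <- function(data, covariates = names(covariate_columns()),
                           conf_level = 0.95) {
  covariates <- match.arg(covariates, names(covariate_columns()),
                          several.ok = TRUE)
  if (!"pain" %in% names(data)) data <- prepare_analysis_data(data)
  cols <- covariate_columns()[covariates]
  for (cv in names(cols)) {
    x <- data[[cols[[cv]]]]
    if (is.factor(x)) {
      obs <- table(droplevels(x))
      if (length(obs) < 2) {
        abort(paste0("covariate `", cv, "` has a single observed level (",
                     names(obs), "); cannot estimate a contrast"),
              class = "painrecord_stat_error")
      }
      empty <- setdiff(levels(x), names(table(x))[table(x) > 0])
      if (length(empty)) {
        abort(paste0("covariate `", cv, "` has empty level(s): ",
                     paste(empty, collapse = ", ")),
              class = "painrecord_stat_error")
      }
    }
  }
  fml <- stats::as.formula(paste("pain ~", paste(cols, collapse = " + ")))
  fit <- glm(fml, data = data, family = binomial())
  if (!fit$converged) {
    abort(paste0("logistic fit did not converge (deviance ",
                 format(fit$deviance), ", ", fit$iter, " iterations)"),
          class = "painrecord_stat_error")
  }
  se <- sqrt(diag(vcov(fit)))
  if (any(!is.finite(se)) || any(se > 50)) {
    abort(paste0("possible separation: unstable standard errors for ",
                 paste(names(se)[!is.finite(se) | se > 50], collapse = ", ")),
          class = "painrecord_stat_error")
  }
  structure(list(fit = fit, covariates = covariates, n = nrow(fit$model),
                 conf_level = conf_level),
            class = "pain_model")
}

#' @export
print.pain_model <- function(x, ...) {
  cat("<pain_model> logistic regression of recorded pain on:",
      paste(x$covariates, collapse = ", "), "\n  n =", x$n, "\n")
  invisible(x)
}

#' Tidy a fitted pain model into an odds-ratio table
#'
#' @param x A `pain_model`.
#' @param exponentiate Report odds ratios (default) rather than log odds.
#' @param ... Unused.
#' @return Tibble with `term`, `reference`, `or` (or `log_or`), `ci_low`,
#'   `ci_high`, `p_value`. The intercept is omitted.
#' @export
tidy.pain_model <- function(x, exponentiate = TRUE, ...) {
  fit <- x$fit
  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - x$conf_level) / 2)
  keep <- names(est) != "(Intercept)"
  lab <- model_term_labels(x)
  res <- tibble(
    term = lab$term[match(names(est)[keep], lab$coef)],
    reference = lab$reference[match(names(est)[keep], lab$coef)],
    estimate = unname(est[keep]),
    ci_low = unname(est[keep] - z * se[keep]),
    ci_high = unname(est[keep] + z * se[keep]),
    p_value = unname(2 * pnorm(-abs(est[keep] / se[keep])))
  )
  if (exponentiate) {
    res <- mutate(res, across(c("estimate", "ci_low", "ci_high"), exp)) |>
      rename(or = "estimate")
  } else {
    res <- rename(res, log_or = "estimate")
  }
  res
}

model_term_labels <- function(x) {
  cols <- covariate_columns()[x$covariates]
  out <- list(coef = character(), term = character(), reference = character())
  dat <- x$fit$model
  for (cv in names(cols)) {
    col <- cols[[cv]]
    v <- dat[[col]]
    if (is.factor(v)) {
      ref <- levels(v)[1]
      for (l in levels(v)[-1]) {
        out$coef <- c(out$coef, paste0(col, l))
        out$term <- c(out$term, paste0(cv, ":", l))
        out$reference <- c(out$reference, ref)
      }
    } else {
      out$coef <- c(out$coef, col)
      out$term <- c(out$term, cv)
      out$reference <- c(out$reference, "per unit")
    }
  }
  tibble(coef = out$coef, term = out$term, reference = out$reference)
}

#' @rdname tidy.pain_model
#' @export
glance.pain_model <- function(x, ...) {
  fit <- x$fit
  tibble(n = x$n, converged = fit$converged,
         deviance = fit$deviance, null_deviance = fit$null.deviance,
         aic = fit$aic, df_residual = fit$df.residual)
}

#' Run the unadjusted and incrementally adjusted model suite
#'
#' Fits one single-covariate logistic model per covariate ("unadjusted")
#' and four mutually adjusted models: model 1 = demographics (age, gender,
#' ethnicity); model 2 = model 1 + deprivation; model 3 = model 2 +
#' diagnosis (SMI); model 4 = ethnicity + deprivation alone. Significance
#' is flagged at p < 0.001 with no multiple-testing correction.
#'
#' @inheritParams fit_pain_model
#' @return Tibble of class `pain_model_table`: `model`, `term`,
#'   `reference`, `or`, `ci_low`, `ci_high`, `p_value`, `sig`.
#' @export
run_models <- function(data, conf_level = 0.95) {
  data <- prepare_analysis_data(data)
  specs <- list(
    model1 = c("age_per_10y", "gender", "ethnicity"),
    model2 = c("age_per_10y", "gender", "ethnicity", "imd"),
    model3 = c("age_per_10y", "gender", "ethnicity", "imd", "smi"),
    model4 = c("ethnicity", "imd")
  )
  unadj <- purrr::map(names(covariate_columns()), function(cv) {
    tidy(fit_pain_model(data, cv, conf_level = conf_level)) |>
      mutate(model = "unadjusted")
  }) |> bind_rows()
  adj <- purrr::imap(specs, function(cvs, nm) {
    tidy(fit_pain_model(data, cvs, conf_level = conf_level)) |>
      mutate(model = nm)
  }) |> bind_rows()
  out <- bind_rows(unadj, adj) |>
    mutate(sig = .data$p_value < 0.001) |>
    select("model", "term", "reference", "or", "ci_low", "ci_high",
           "p_value", "sig")
  class(out) <- c("pain_model_table", class(out))
  out
}

#' Descriptive two-class cohort summary
#'
#' Counts and within-class column percentages for each categorical
#' covariate, split by recorded-pain class, plus an age summary (mean,
#' quartiles, SD) per class — the standard two-class baseline table.
#'
#' @inheritParams fit_pain_model
#' @return A list of class `cohort_description` with tibbles `categorical`
#'   (`variable`, `level`, `total_n`, `class0_n`, `class0_pct`, `class1_n`,
#'   `class1_pct`) and `age` (`group`, `n`, `mean_age`, `q25`, `median`,
#'   `q75`, `sd`).
#' @export
describe_cohort <- function(data) {
  data <- prepare_analysis_data(data)
  vars <- c(gender = "gender", ethnicity = "ethnicity", imd = "imd_group",
            diagnosis = "smi_group")
  cat_tbl <- purrr::imap(vars, function(col, nm) {
    data |>
      count(level = as.character(.data[[col]]), cls = .data$pain) |>
      tidyr::pivot_wider(names_from = "cls", values_from = "n",
                         values_fill = 0L, names_prefix = "class") |>
      mutate(variable = nm)
  }) |> bind_rows()
  for (k in c("class0", "class1")) {
    if (!k %in% names(cat_tbl)) cat_tbl[[k]] <- 0L
  }
  n0 <- sum(data$pain == 0)
  n1 <- sum(data$pain == 1)
  cat_tbl <- cat_tbl |>
    mutate(total_n = .data$class0 + .data$class1,
           class0_pct = if (n0 > 0) 100 * .data$class0 / n0 else 0,
           class1_pct = if (n1 > 0) 100 * .data$class1 / n1 else 0) |>
    select("variable", "level", "total_n",
           class0_n = "class0", "class0_pct",
           class1_n = "class1", "class1_pct")
  age_tbl <- data |>
    mutate(group = if_else(.data$pain == 1, "class1", "class0")) |>
    bind_rows(mutate(data, group = "overall")) |>
    group_by(.data$group) |>
    summarise(n = dplyr::n(),
              mean_age = mean(.data$age_years),
              q25 = unname(quantile(.data$age_years, 0.25)),
              median = unname(quantile(.data$age_years, 0.5)),
              q75 = unname(quantile(.data$age_years, 0.75)),
              sd = sd(.data$age_years), .groups = "drop")
  structure(list(categorical = cat_tbl, age = age_tbl),
            class = "cohort_description")
}

#' @export
print.cohort_description <- function(x, ...) {
  cat("<cohort_description>\n")
  print(x$age)
  print(x$categorical, n = Inf)
  invisible(x)
}
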