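test_that("cross-product odds ratio and Wald interval behave algebraically", {
  r <- unadjusted_or(10, 10, 10, 10)
  expect_equal(r$estimate, 1)
  # CI symmetric about 1 on the log scale
  expect_equal(log(r$ci_low), -log(r$ci_high))
  # inverse identity
  r1 <- unadjusted_or(7, 11, 13, 17)
  r2 <- unadjusted_or(11, 7, 17, 13)
  expect_equal(r1$estimate * r2$estimate, 1, tolerance = 1e-12)
  # invariance under uniform scaling of all cells (2x replication)
  s1 <- unadjusted_or(7, 11, 13, 17)
  s2 <- unadjusted_or(14, 22, 26, 34)
  expect_equal(s1$estimate, s2$estimate, tolerance = 1e-12)
  expect_lt(s2$ci_high - s2$ci_low, s1$ci_high - s1$ci_low)
  # zero cells error rather than silently correcting
  expect_error(unadjusted_or(0, 10, 10, 10), "zero cell")
  expect_error(unadjusted_or(5, 10, 0, 10), "continuity")
})

test_that("odds ratios from two-class contingency counts match reported values", {
  # female vs male contrast in a 27k-patient two-class cohort
  fem <- unadjusted_or(a = 7756, b = 6434, c = 5953, d = 7037)
  expect_equal(fem$estimate, 1.42, tolerance = 0.01)
  expect_lt(fem$ci_low, 1.42)
  expect_gt(fem$ci_high, 1.42)
  asian <- unadjusted_or(a = 914, b = 7125, c = 592, d = 6014)
  expect_equal(asian$estimate, 1.30, tolerance = 0.01)
})

test_that("contingency tables are built from patient-level data", {
  d <- tibble::tibble(
    gender = c("female", "female", "male", "male", "not_known"),
    pain_class = c("class1", "class0", "class1", "class0", "class1"))
  tab <- contingency_2x2(d, "gender", "pain_class", "female", "male")
  expect_equal(unlist(tab), c(a = 1, b = 1, c = 1, d = 1))
  # rows in neither level (not_known) are excluded from the 2x2
  expect_equal(sum(unlist(tab)), 4)
})

test_that("single-binary-covariate logistic fit equals the 2x2 cross-product", {
  cfg <- cohort_config(n_patients = 4000, seed = 21)
  d <- patients_with_truth(cfg)
  d <- d[d$gender != "not_known", ]
  fit <- fit_pain_model(d, "gender")
  t_or <- tidy(fit)
  direct <- cohort_or(d, "gender", "female", "male")
  expect_equal(t_or$or[t_or$term == "gender:female"], direct$estimate,
               tolerance = 1e-6)
  expect_equal(t_or$ci_low[t_or$term == "gender:female"], direct$ci_low,
               tolerance = 1e-4)
})

test_that("adjusted models recover configured effects at scale", {
  cfg <- cohort_config(n_patients = 20000, seed = 14)
  d <- patients_with_truth(cfg)
  fit <- fit_pain_model(d)
  res <- tidy(fit)
  truth <- c("gender:female" = 1.42, "ethnicity:asian" = 1.30,
             "ethnicity:black" = 1.49, "imd:le5" = 1.64, "smi:smi" = 0.43,
             "age_per_10y" = 1.17)
  for (term in names(truth)) {
    row <- res[res$term == term, ]
    expect_lt(row$ci_low, truth[[term]] * 1.08, label = term)
    expect_gt(row$ci_high, truth[[term]] * 0.92, label = term)
  }
  g <- glance(fit)
  expect_true(g$converged)
  expect_equal(g$n, 20000)
})

test_that("'not known' categories are estimable levels, never dropped", {
  cfg <- cohort_config(n_patients = 20000, seed = 8)
  d <- patients_with_truth(cfg)
  res <- tidy(fit_pain_model(d, c("gender", "ethnicity", "imd")))
  expect_true("gender:not_known" %in% res$term)
  expect_true("ethnicity:not_stated" %in% res$term)
  expect_true("imd:not_known" %in% res$term)
  expect_true(all(is.finite(res$or)))
})

test_that("degenerate single-level covariates raise a named error", {
  d <- tibble::tibble(
    age_years = rep(40, 50), gender = "female",
    ethnicity = rep(c("white", "black"), 25),
    imd_decile = rep(c(2L, 8L), 25), smi = FALSE,
    pain_class = rep(c("class0", "class1"), 25))
  expect_error(fit_pain_model(d, "gender"), "gender")
})

test_that("the model suite reports the expected row structure", {
  cfg <- cohort_config(n_patients = 20000, seed = 14)
  d <- patients_with_truth(cfg)
  tab <- run_models(d)
  expect_setequal(unique(tab$model),
                  c("unadjusted", "model1", "model2", "model3", "model4"))
  # model 1 = demographics only; model 4 = ethnicity + deprivation alone
  m1 <- tab$term[tab$model == "model1"]
  expect_true(any(grepl("^age_per_10y", m1)))
  expect_false(any(grepl("^imd", m1)))
  expect_false(any(grepl("^smi", m1)))
  m4 <- tab$term[tab$model == "model4"]
  expect_false(any(grepl("^age|^gender", m4)))
  expect_true(any(grepl("^imd:le5$", m4)))
  expect_true(all(c("or", "ci_low", "ci_high", "p_value", "sig") %in%
                    names(tab)))
  expect_equal(tab$sig, tab$p_value < 0.001)
})

test_that("null-effect cohorts keep confidence intervals around 1", {
  ef <- default_effects()
  ef$intercept <- 0; ef$age_per_10y <- 0
  ef$gender[] <- 0; ef$ethnicity[] <- 0; ef$imd_deprived <- 0; ef$smi <- 0
  m <- default_marginals()
  m$gender <- c(male = 0.5, female = 0.5)  # no sparse level at this n
  terms_cover <- c("gender:female", "ethnicity:black", "imd:le5", "smi:smi")
  # 40 replicates keep the Monte Carlo error of the coverage estimate well
  # below the 5 percentage points of headroom over the nominal 95% level
  n_runs <- 40
  covered <- matrix(FALSE, n_runs, length(terms_cover),
                    dimnames = list(NULL, terms_cover))
  for (i in seq_len(n_runs)) {
    cfg <- cohort_config(n_patients = 3000, seed = 100 + i, effects = ef,
                         marginals = m)
    d <- patients_with_truth(cfg)
    res <- tidy(fit_pain_model(d, c("gender", "ethnicity", "imd", "smi")))
    for (tm in terms_cover) {
      row <- res[res$term == tm, ]
      covered[i, tm] <- row$ci_low <= 1 && 1 <= row$ci_high
    }
  }
  expect_true(all(colMeans(covered) >= 0.9))
})

test_that("cohort description matches a hand tally", {
  d <- tibble::tibble(
    age_years = c(30, 40, 50, 60),
    gender = c("female", "female", "male", "male"),
    ethnicity = c("white", "black", "white", "black"),
    imd_decile = c(2L, 8L, NA, 3L),
    smi = c(TRUE, FALSE, FALSE, TRUE),
    pain_class = c("class1", "class1", "class0", "class1"))
  desc <- describe_cohort(d)
  cat_tbl <- desc$categorical
  fem <- cat_tbl[cat_tbl$variable == "gender" & cat_tbl$level == "female", ]
  expect_equal(fem$total_n, 2)
  expect_equal(fem$class1_n, 2)
  expect_equal(fem$class1_pct, 100 * 2 / 3)
  expect_equal(fem$class0_n, 0)
  imd_nk <- cat_tbl[cat_tbl$variable == "imd" & cat_tbl$level == "not_known", ]
  expect_equal(imd_nk$class0_n, 1)
  expect_equal(imd_nk$class0_pct, 100)
  age <- desc$age
  expect_equal(age$mean_age[age$group == "class1"], mean(c(30, 40, 60)))
  expect_equal(age$mean_age[age$group == "overall"], 45)
  # column percentages sum to 100 per variable per class
  sums <- cat_tbl |>
    dplyr::group_by(variable) |>
    dplyr::summarise(p0 = sum(class0_pct), p1 = sum(class1_pct))
  expect_true(all(abs(sums$p0 - 100) < 1e-9))
  expect_true(all(abs(sums$p1 - 100) < 1e-9))
})
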