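test_that("absolute prediction error follows its definition and is scale invariant", {
  expect_equal(absolute_prediction_error(200, 200), 0)
  expect_equal(absolute_prediction_error(230, 200), 15)
  expect_equal(absolute_prediction_error(170, 200), 15)
  expect_error(absolute_prediction_error(200, 0), "positive")
  set.seed(15)
  pred <- runif(10, 100, 300); obs <- runif(10, 100, 300)
  for (c_scale in c(0.5, 3, 100)) {
    expect_equal(absolute_prediction_error(c_scale * pred, c_scale * obs),
                 absolute_prediction_error(pred, obs))
  }
})

test_that("MAPE summary reports median, mean, SD and the strict deviation fraction", {
  s <- mape_summary(c(5, 10, 20))
  expect_equal(s$median, 10)
  expect_equal(s$fraction_above, 1 / 3)
  z <- mape_summary(rep(0, 4))
  expect_equal(unlist(z[c("median", "mean", "sd", "fraction_above")]),
               c(median = 0, mean = 0, sd = 0, fraction_above = 0))
  expect_equal(mape_summary(c(15, 15))$fraction_above, 0)
  expect_error(mape_summary(numeric(0)), "non-empty")
})

test_that("published three-point equations evaluate to hand-computed values", {
  eqs <- external_equations()
  # 39.179 + 52.632 + 34.455 + 79.26
  expect_equal(apply_external_equation(eqs$almeida_c0c1c4,
                                       c(C0 = 6, C1 = 15, C4 = 10)), 205.526)
  # 46.062 + 54.774 + 38.752 + 64.50
  expect_equal(apply_external_equation(eqs$almeida_c0c2c4,
                                       c(C0 = 6, C2 = 14, C4 = 10)), 204.088)
  expect_equal(apply_external_equation(eqs$almeida_c0c2c4,
                                       c(C0 = 0, C2 = 0, C4 = 0)), 46.062)
  expect_error(lss_equation("bad", Inf, c(C0 = 1)), "finite")
})

test_that("Bland-Altman agreement satisfies its closed-form identities", {
  a <- c(200, 220, 250, 180)
  ident <- bland_altman(a, a)
  expect_equal(unlist(ident[c("mean_diff", "sd_diff", "loa_lower", "loa_upper")]),
               c(mean_diff = 0, sd_diff = 0, loa_lower = 0, loa_upper = 0))

  shifted <- bland_altman(a, a + 10)
  expect_equal(shifted$mean_diff, -10)
  expect_equal(shifted$sd_diff, 0)

  two <- bland_altman(c(1, 3), c(2, 2))  # d = (-1, 1)
  expect_equal(two$mean_diff, 0)
  expect_equal(two$sd_diff, sqrt(2))
  expect_equal(two$loa_lower, -1.96 * sqrt(2))
  expect_equal(two$loa_upper, 1.96 * sqrt(2))

  set.seed(19)
  x <- rnorm(15, 200, 40); y <- rnorm(15, 210, 40)
  expect_equal(bland_altman(x, y)$mean_diff, mean(x) - mean(y))
  expect_error(bland_altman(1:3, 1:4), "equal length")
  expect_error(bland_altman(1, 2), "at least 2")
})

test_that("in-sample fitted equations have zero mean signed difference", {
  co <- simulate_cohort(simulation_config(n_patients = 51, seed = 23))
  ex <- summarize_exposure(co)
  fit <- build_lss_models(ex, co$concentrations)
  m12 <- fit$models[["12"]]
  pred <- predict_auc(m12, fit$data)
  ba <- bland_altman(pred, fit$data$auc_0_24)
  expect_lt(abs(ba$mean_diff), 1e-8)
})

test_that("subgroup consistency detects a shifted group and validates input", {
  expect_error(subgroup_consistency(1:10, 1:10, rep("a", 10)), "2 subgroups")
  expect_error(subgroup_consistency(1:4, 1:4, c("a", "a", "a", "b")),
               "at least 2 members")

  set.seed(41)
  reject <- 0
  for (r in 1:50) {
    n <- 200
    pred <- runif(n, 120, 350)
    grp <- sample(c("innovator", "bioequivalent"), n, replace = TRUE)
    obs <- 5 + 0.98 * pred + rnorm(n, 0, 25)
    obs[grp == "bioequivalent"] <- obs[grp == "bioequivalent"] + 50
    reject <- reject + (subgroup_consistency(pred, obs, grp)$p < 0.05)
  }
  expect_gt(reject / 50, 0.9)

  # degrees of freedom: k groups add k - 1 numerator df
  set.seed(42)
  res <- subgroup_consistency(runif(30, 100, 300), rnorm(30, 200, 30),
                              rep(c("a", "b", "c"), 10))
  expect_equal(res$df1, 2)
  expect_equal(res$df2, 30 - 4)
})

test_that("cross-validation is deterministic and honest about optimism", {
  co <- simulate_cohort(noisefree_config(n_patients = 30, seed = 4))
  ex <- summarize_exposure(co)
  fit <- build_lss_models(ex, co$concentrations)
  strata <- classify_expressor(co$metadata$genotype)

  cv1 <- crossvalidate_lss(fit$data, c("C0", "C1", "C4"), folds = 5,
                           seed = 7, strata = strata)
  cv2 <- crossvalidate_lss(fit$data, c("C0", "C1", "C4"), folds = 5,
                           seed = 7, strata = strata)
  expect_identical(cv1$fold, cv2$fold)
  expect_identical(cv1$apes, cv2$apes)

  # a response exactly linear in the predictors cross-validates to ~0 error
  lin <- fit$data
  lin$auc_0_24 <- 30 + 11 * lin$C0 + 2 * lin$C1 + 8 * lin$C4
  cv_lin <- crossvalidate_lss(lin, c("C0", "C1", "C4"), folds = 5, seed = 1)
  expect_lt(cv_lin$summary$median, 1e-8)

  # out-of-sample MAPE >= in-sample MAPE on average over seeds
  noisy_cfg <- simulation_config(n_patients = 40)
  diffs <- vapply(1:20, function(s) {
    con <- simulate_cohort(noisy_cfg, seed = 300 + s)
    exn <- summarize_exposure(con)
    fitn <- build_lss_models(exn, con$concentrations)
    cv <- crossvalidate_lss(fitn$data, c("C0", "C1", "C4"), folds = 5,
                            seed = s)
    cv$summary$median - fitn$models[["12"]]$mape
  }, numeric(1))
  expect_gt(mean(diffs), 0)
  expect_error(crossvalidate_lss(fit$data, "C0", folds = 100), "more folds")
})

test_that("three-point models beat the trough-only model in nearly all cohorts", {
  better <- 0
  n_seeds <- 40
  for (s in 1:n_seeds) {
    co <- simulate_cohort(simulation_config(), seed = 500 + s)
    ex <- summarize_exposure(co)
    wide <- concentrations_wide(co$concentrations)
    d <- merge(ex[, c("patient_id", "auc_0_24")], wide, by = "patient_id")
    m_c0 <- fit_ols(d[, "C0", drop = FALSE], d$auc_0_24)
    m_3p <- fit_ols(d[, c("C0", "C1", "C4")], d$auc_0_24)
    better <- better + (m_3p$mape < m_c0$mape)
  }
  expect_gte(better / n_seeds, 0.95)
})

test_that("validate_equations summarises fitted and fixed equations together", {
  co <- simulate_cohort(simulation_config(n_patients = 51, seed = 77))
  ex <- summarize_exposure(co)
  fit <- build_lss_models(ex, co$concentrations)
  eqs <- c(list(fitted_c0c1c4 = fit$models[["12"]]),
           external_equations()[c("almeida_c0c1c4", "almeida_c0c2c4")])
  val <- validate_equations(eqs, fit$data)
  expect_equal(nrow(val$table), 3)
  expect_true(all(val$table$fraction_above_threshold >= 0 &
                  val$table$fraction_above_threshold <= 1))
  expect_true(all(val$table$ba_loa_upper >= val$table$ba_mean_diff))
  expect_true(all(val$table$ba_mean_diff >= val$table$ba_loa_lower))
  # the in-sample fitted equation is unbiased; its |mean difference| is
  # smaller than the external equations can guarantee
  expect_lt(abs(val$table$ba_mean_diff[1]), 1e-8)
})
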