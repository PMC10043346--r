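test_that("genotype sampling follows Hardy-Weinberg proportions", {
  set.seed(11)
  expect_true(all(sample_genotype(1, 50) == "*3/*3"))
  expect_true(all(sample_genotype(0, 50) == "*1/*1"))
  expect_error(sample_genotype(1.2), "\\[0, 1\\]")
  expect_error(sample_genotype(-0.1), "\\[0, 1\\]")

  q3 <- 0.8125
  draws <- sample_genotype(q3, 10000)
  frac33 <- mean(draws == "*3/*3")
  se <- sqrt(q3^2 * (1 - q3^2) / 10000)
  expect_lt(abs(frac33 - q3^2), 3 * se)

  obs <- c(sum(draws == "*1/*1"), sum(draws == "*1/*3"), sum(draws == "*3/*3"))
  expected <- 10000 * c((1 - q3)^2, 2 * q3 * (1 - q3), q3^2)
  chi2 <- sum((obs - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 2))
})

test_that("individual PK parameters respect medians and the expressor multiplier", {
  cfg <- quiet_config()
  set.seed(1)
  p <- sample_pk_parameters("*3/*3", cfg)
  expect_equal(p$cl_f, cfg$medians$cl_f)
  expect_equal(p$vc_f, cfg$medians$vc_f)
  expect_equal(p$weight, cfg$medians$weight)

  p_ex <- sample_pk_parameters("*1/*3", cfg)
  expect_equal(p_ex$cl_f, 1.6 * cfg$medians$cl_f)

  # Monte-Carlo: the realised expressor/non-expressor clearance ratio
  # recovers the generating multiplier.
  cfg_v <- simulation_config(occasion_cv = 0)
  set.seed(22)
  cl_ex <- replicate(400, sample_pk_parameters("*1/*1", cfg_v)$cl_f)
  cl_ne <- replicate(400, sample_pk_parameters("*3/*3", cfg_v)$cl_f)
  expect_lt(abs(mean(cl_ex) / mean(cl_ne) - 1.6), 0.15)
})

test_that("pk_parameters validates inputs and resolves rate-constant collisions", {
  expect_error(pk_parameters(-1, 100, 250, 500, 1.2, 40), "strictly positive")
  p <- pk_parameters(22, 100, 250, 500, 1.2, 40)
  # force a collision: set ka equal to the alpha of the same disposition
  pc <- pk_parameters(22, 100, 250, 500, p$alpha, 40)
  expect_true(attr(pc, "ka_perturbed"))
  expect_gt(min(abs(pc$ka - pc$alpha), abs(pc$ka - pc$beta)), 0)
  expect_false(is.na(concentration_ss(pc, 5, 2)))
})

test_that("steady-state concentration is linear in dose and periodic", {
  p <- pk_parameters(22, 100, 250, 500, 1.2, 40)
  t <- c(0, 1, 2, 4, 12, 24)
  expect_equal(concentration_ss(p, 0, t), rep(0, 6))
  expect_equal(concentration_ss(p, 10, t), 2 * concentration_ss(p, 5, t))
  expect_equal(concentration_ss(p, 5, 0), concentration_ss(p, 5, 24))
  expect_error(concentration_ss(p, 5, 25), "within")
})

test_that("q_f -> 0 limit matches an independent one-compartment closed form", {
  p <- pk_parameters(22, 1e-6, 250, 500, 1.2, 40)
  t <- c(0, 1, 2, 4, 12, 24)
  got <- concentration_ss(p, 5, t, 24)
  want <- oracle_one_compartment_ss(22, 250, p$ka, 5, t, 24)
  expect_lt(max(abs(got - want) / want), 1e-3)
})

test_that("steady-state mass balance: integral over one interval equals 1000*dose/CL", {
  set.seed(5)
  for (i in 1:5) {
    p <- pk_parameters(cl_f = runif(1, 10, 40), q_f = runif(1, 20, 150),
                       vc_f = runif(1, 100, 400), vp_f = runif(1, 200, 800),
                       ka = runif(1, 0.5, 2), weight = 40)
    dose <- runif(1, 2, 10)
    num <- integrate(function(x) concentration_ss(p, dose, x), 0, 24,
                     rel.tol = 1e-10, subdivisions = 500L)$value
    expect_lt(abs(num - steady_state_auc(p, dose)) / steady_state_auc(p, dose),
              1e-6)
  }
})

test_that("dose titration hits the trough window and is monotone in clearance", {
  cfg <- quiet_config()
  p <- pk_parameters(22, 100, 250, 500, 1.2, 40)
  titr <- titrate_dose(p, cfg)
  expect_false(titr$flagged)
  expect_gte(titr$trough, 5)
  expect_lte(titr$trough, 7)

  # a starting dose already inside the window is kept unchanged
  cfg_fp <- quiet_config(initial_dose_per_kg = 0.125)
  titr_fp <- titrate_dose(p, cfg_fp)
  expect_equal(titr_fp$dose, 0.125 * 40)

  p2 <- pk_parameters(44, 100, 250, 500, 1.2, 40)
  expect_gte(titrate_dose(p2, cfg)$dose, titr$dose)

  # linearity of C in dose: hitting the same trough window means the dose
  # ratio equals the inverse ratio of trough-per-unit-dose (on a fine grid)
  cfg_fine <- quiet_config(dose_increment = 0.1)
  p_ex <- pk_parameters(22 * 1.6, 100, 250, 500, 1.2, 40)
  t_ne <- titrate_dose(p, cfg_fine)
  t_ex <- titrate_dose(p_ex, cfg_fine)
  c1_ne <- concentration_ss(p, 1, 24)
  c1_ex <- concentration_ss(p_ex, 1, 24)
  expect_equal(t_ex$dose / t_ne$dose,
               (t_ex$trough / c1_ex) / (t_ne$trough / c1_ne))
  # expressors need more drug than non-expressors for the same target,
  # within the clinically described 1.5-2.0x dose-requirement range
  expect_gte(t_ex$dose / t_ne$dose, 1.5)
  expect_lte(t_ex$dose / t_ne$dose, 2.0)

  # infeasible window: flagged, trough closest to midpoint
  cfg_hi <- quiet_config(target_c0 = c(90, 95), dose_range = c(0.5, 5))
  titr_hi <- titrate_dose(p, cfg_hi)
  expect_true(titr_hi$flagged)
  expect_equal(titr_hi$dose, 5)
})

test_that("assay noise model reproduces its error magnitudes and LLOQ rule", {
  cfg0 <- quiet_config()
  expect_equal(add_assay_noise(c(0.6, 10), cfg0)$conc, c(0.6, 10))

  res0 <- add_assay_noise(0, cfg0)
  expect_true(res0$below_lloq)
  expect_equal(res0$conc, cfg0$lloq / 2)

  cfg <- quiet_config(assay_cv = 0.1)
  set.seed(77)
  meas <- add_assay_noise(rep(10, 10000), cfg)$conc
  expect_lt(abs(sd(meas) - 1.0), 0.05)
  expect_error(add_assay_noise(-1, cfg), "non-negative")
})

test_that("cohort simulation is reproducible bit-for-bit given the seed", {
  cfg <- simulation_config(n_patients = 12, seed = 31)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$metadata, c2$metadata)
  expect_identical(c1$concentrations, c2$concentrations)
  expect_identical(c1$ground_truth, c2$ground_truth)

  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(c1, d1); write_cohort(c2, d2)
  for (f in c("cohort_metadata.csv", "concentrations.csv", "ground_truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # patient substreams: patient i is unchanged when the cohort grows
  c3 <- simulate_cohort(simulation_config(n_patients = 20, seed = 31))
  expect_identical(c3$metadata[1:12, ], c1$metadata)
})

test_that("simulated genotype tallies match Hardy-Weinberg expectations", {
  counts <- c(0, 0, 0)
  n_seeds <- 20
  for (s in 1:n_seeds) {
    co <- simulate_cohort(simulation_config(n_patients = 51, seed = 100 + s))
    counts <- counts + unname(genotype_counts(co$metadata$genotype))
  }
  N <- 51 * n_seeds
  q3 <- 0.8125
  expected <- N * c((1 - q3)^2, 2 * q3 * (1 - q3), q3^2)
  for (i in 1:3) {
    se <- sqrt(expected[i] * (1 - expected[i] / N))
    expect_lt(abs(counts[i] - expected[i]), 1.96 * se + 1)
  }
})

test_that("noise-free profiles integrate to within 15% of the analytic AUC", {
  co <- simulate_cohort(noisefree_config(n_patients = 25, seed = 9))
  ex <- summarize_exposure(co)
  d <- merge(ex, co$ground_truth, by = "patient_id")
  rel <- abs(d$auc_0_24 - d$true_auc_ng_h_ml) / d$true_auc_ng_h_ml
  expect_lt(max(rel), 0.15)
})
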