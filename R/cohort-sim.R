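# Synthetic steady-state tacrolimus cohort generator.
#
# Emulates a pediatric kidney-transplant cohort under extended-release
# tacrolimus at steady state: CYP3A5 genotype sampled under Hardy-Weinberg
# proportions, genotype-dependent apparent clearance, trough-targeted dose
# titration (therapeutic drug monitoring), a two-compartment oral
# steady-state concentration model sampled at the nominal profile times
# {0, 1, 2, 4, 12, 24} h, and proportional + additive assay noise.

GENOTYPES <- c("*1/*1", "*1/*3", "*3/*3")
PROFILE_TIMES <- c(0, 1, 2, 4, 12, 24)
PROFILE_LABELS <- c("C0", "C1", "C2", "C4", "C12", "C24")

#' Two-compartment oral pharmacokinetic parameters
#'
#' Apparent (oral) parameters of a two-compartment disposition model with
#' first-order absorption. Derived hybrid rate constants \eqn{\alpha} and
#' \eqn{\beta} satisfy \eqn{\alpha + \beta = k_{10} + k_{12} + k_{21}} and
#' \eqn{\alpha\beta = k_{10} k_{21}} with micro-constants
#' \eqn{k_{10} = CL/F / V_c}, \eqn{k_{12} = Q/F / V_c},
#' \eqn{k_{21} = Q/F / V_p}. If the absorption constant `ka` collides with
#' \eqn{\alpha} or \eqn{\beta} (the superposition coefficients would be
#' singular) it is perturbed by a fixed tiny factor and the perturbation is
#' recorded in the `ka_perturbed` attribute.
#'
#' @param cl_f apparent clearance CL/F, L/h.
#' @param q_f apparent inter-compartmental clearance Q/F, L/h.
#' @param vc_f apparent central volume Vc/F, L.
#' @param vp_f apparent peripheral volume Vp/F, L.
#' @param ka first-order absorption rate constant, 1/h.
#' @param weight body weight, kg.
#' @return object of class `pk_parameters`.
#' @export
pk_parameters <- function(cl_f, q_f, vc_f, vp_f, ka, weight) {
  vals <- c(cl_f = cl_f, q_f = q_f, vc_f = vc_f, vp_f = vp_f,
            ka = ka, weight = weight)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all pharmacokinetic parameters must be strictly positive and finite")
  }
  perturbed <- FALSE
  repeat {
    hc <- hybrid_constants(cl_f, q_f, vc_f, vp_f)
    if (min(abs(ka - hc$alpha), abs(ka - hc$beta)) / ka > 1e-9) break
    ka <- ka * (1 + 1e-6)
    perturbed <- TRUE
  }
  structure(
    list(cl_f = cl_f, q_f = q_f, vc_f = vc_f, vp_f = vp_f, ka = ka,
         weight = weight, alpha = hc$alpha, beta = hc$beta),
    ka_perturbed = perturbed, class = "pk_parameters"
  )
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("Two-compartment oral PK parameters (apparent)\n")
  cat(sprintf("  CL/F %.3g L/h, Q/F %.3g L/h, Vc/F %.3g L, Vp/F %.3g L\n",
              x$cl_f, x$q_f, x$vc_f, x$vp_f))
  cat(sprintf("  ka %.3g 1/h (alpha %.4g, beta %.4g), weight %.3g kg\n",
              x$ka, x$alpha, x$beta, x$weight))
  invisible(x)
}

# Hybrid rate constants; beta computed as product/alpha for numerical
# stability when the compartments are nearly uncoupled (q_f -> 0).
hybrid_constants <- function(cl_f, q_f, vc_f, vp_f) {
  k10 <- cl_f / vc_f
  k12 <- q_f / vc_f
  k21 <- q_f / vp_f
  s <- k10 + k12 + k21
  p <- k10 * k21
  alpha <- (s + sqrt(s^2 - 4 * p)) / 2
  list(alpha = alpha, beta = p / alpha, k10 = k10, k12 = k12, k21 = k21)
}

#' Simulation configuration for a synthetic tacrolimus cohort
#'
#' Defaults emulate a pediatric extended-release tacrolimus maintenance
#' cohort: 51 patients, *3 allele frequency 0.8125, CYP3A5 expressors with
#' 1.6-fold higher apparent clearance, troughs titrated into 5--7 ng/mL,
#' and population median parameters chosen so the noise-free profile has
#' AUC0-24 near 220 ng*h/mL, C0 near 6 ng/mL, Cmax near 16.5 ng/mL and
#' Tmax at 1--2 h.
#'
#' @param n_patients cohort size.
#' @param q3 CYP3A5 *3 allele frequency, in `[0, 1]`.
#' @param cl_expressor_multiplier fold-increase of `cl_f` in expressors
#'   (*1/*1 or *1/*3 carriers); must be >= 1.
#' @param medians named list of population median `pk_parameters` fields.
#' @param iiv_cv named log-normal between-subject coefficient of variation
#'   per parameter (0 disables variability).
#' @param occasion_cv between-occasion log-normal CV of `cl_f`: the dose is
#'   titrated against the trough of an earlier monitoring visit, and the
#'   patient's clearance drifts by `exp(N(0, sigma))` between that visit
#'   and the profiling day. This reproduces the dispersion of observed
#'   troughs around the target window (and the partial, imperfect
#'   correlation of C0 with AUC0-24) that routine TDM cohorts show;
#'   0 disables it.
#' @param assay_cv proportional assay error fraction.
#' @param assay_sd additive assay error SD, ng/mL.
#' @param lloq lower limit of quantification, ng/mL; measurements below it
#'   are imputed as `lloq / 2` and flagged.
#' @param tau dosing interval, h.
#' @param target_c0 trough target range `(low, high)`, ng/mL.
#' @param dose_increment dose grid step, mg.
#' @param dose_range allowed daily dose range `(min, max)`, mg.
#' @param initial_dose_per_kg weight-based starting daily dose, mg/kg.
#' @param brand_probs named sampling probabilities for the brand label.
#' @param seed integer RNG seed; required by [simulate_cohort()].
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 51,
                              q3 = 0.8125,
                              cl_expressor_multiplier = 1.6,
                              medians = list(cl_f = 22, q_f = 100, vc_f = 250,
                                             vp_f = 500, ka = 1.2, weight = 40),
                              iiv_cv = c(cl_f = 0.3, q_f = 0.3, vc_f = 0.3,
                                         vp_f = 0.3, ka = 0.3, weight = 0.3),
                              occasion_cv = 0.25,
                              assay_cv = 0.10,
                              assay_sd = 0.3,
                              lloq = 0.5,
                              tau = 24,
                              target_c0 = c(5, 7),
                              dose_increment = 0.5,
                              dose_range = c(0.5, 30),
                              initial_dose_per_kg = 0.1,
                              brand_probs = c(innovator = 0.745,
                                              bioequivalent = 0.196,
                                              mixed = 0.059),
                              seed = NULL) {
  if (q3 < 0 || q3 > 1) stop("q3 must lie in [0, 1]")
  if (cl_expressor_multiplier < 1) stop("cl_expressor_multiplier must be >= 1")
  if (tau <= 0) stop("tau must be positive")
  if (length(target_c0) != 2 || target_c0[1] >= target_c0[2]) {
    stop("target_c0 must be (low, high) with low < high")
  }
  if (dose_increment <= 0) stop("dose_increment must be positive")
  if (length(dose_range) != 2 || dose_range[1] <= 0 ||
      dose_range[1] >= dose_range[2]) {
    stop("dose_range must be positive with min < max")
  }
  needed <- c("cl_f", "q_f", "vc_f", "vp_f", "ka", "weight")
  if (!all(needed %in% names(medians)) ||
      any(unlist(medians[needed]) <= 0)) {
    stop("medians must name strictly positive ", paste(needed, collapse = ", "))
  }
  if (any(iiv_cv < 0) || occasion_cv < 0 || assay_cv < 0 || assay_sd < 0 ||
      lloq < 0) {
    stop("variability parameters must be non-negative")
  }
  structure(
    list(n_patients = n_patients, q3 = q3,
         cl_expressor_multiplier = cl_expressor_multiplier,
         medians = medians, iiv_cv = iiv_cv, occasion_cv = occasion_cv,
         assay_cv = assay_cv, assay_sd = assay_sd, lloq = lloq, tau = tau,
         target_c0 = target_c0, dose_increment = dose_increment,
         dose_range = dose_range, initial_dose_per_kg = initial_dose_per_kg,
         brand_probs = brand_probs, seed = seed),
    class = "simulation_config"
  )
}

#' Sample CYP3A5 genotypes under Hardy-Weinberg proportions
#'
#' Genotypes `*1/*1`, `*1/*3`, `*3/*3` are drawn with probabilities
#' \eqn{(1-q)^2}, \eqn{2q(1-q)}, \eqn{q^2} where `q3` is the *3 allele
#' frequency.
#'
#' @param q3 *3 allele frequency in `[0, 1]`.
#' @param n number of draws.
#' @return character vector of genotype labels.
#' @export
sample_genotype <- function(q3, n = 1) {
  if (!is.finite(q3) || q3 < 0 || q3 > 1) stop("q3 must lie in [0, 1]")
  probs <- c((1 - q3)^2, 2 * q3 * (1 - q3), q3^2)
  GENOTYPES[sample.int(3, n, replace = TRUE, prob = probs)]
}

#' Sample individual pharmacokinetic parameters
#'
#' Each parameter is its population median multiplied by a log-normal
#' deviate \eqn{\exp(N(0, \sigma))} with \eqn{\sigma = \sqrt{\log(1+CV^2)}},
#' so the configured value is the population median. CYP3A5 expressors
#' (`*1/*1`, `*1/*3`) get `cl_f` multiplied by `cl_expressor_multiplier`.
#'
#' @param genotype CYP3A5 genotype label.
#' @param config a [simulation_config()].
#' @return a [pk_parameters()] object.
#' @export
sample_pk_parameters <- function(genotype, config) {
  med <- config$medians
  cv <- config$iiv_cv
  draw <- function(name) {
    sigma <- sqrt(log(1 + cv[[name]]^2))
    med[[name]] * exp(stats::rnorm(1, 0, sigma))
  }
  vals <- lapply(c(cl_f = "cl_f", q_f = "q_f", vc_f = "vc_f",
                   vp_f = "vp_f", ka = "ka", weight = "weight"), draw)
  if (classify_expressor(genotype) == "expressor") {
    vals$cl_f <- vals$cl_f * config$cl_expressor_multiplier
  }
  pk_parameters(vals$cl_f, vals$q_f, vals$vc_f, vals$vp_f, vals$ka, vals$weight)
}

#' Steady-state concentration of a two-compartment oral model
#'
#' Multiple-dose steady-state superposition of the three exponential phases
#' (hybrid constants \eqn{\alpha}, \eqn{\beta} and absorption `ka`):
#' \deqn{C(t) = \frac{1000\, D\, k_a}{V_c} \sum_i
#'   \frac{A_i e^{-\lambda_i t}}{1 - e^{-\lambda_i \tau}}}
#' with the standard coefficients
#' \eqn{A_1 = (k_{21}-\alpha)/((k_a-\alpha)(\beta-\alpha))},
#' \eqn{A_2 = (k_{21}-\beta)/((k_a-\beta)(\alpha-\beta))},
#' \eqn{A_3 = (k_{21}-k_a)/((\alpha-k_a)(\beta-k_a))}. The factor 1000
#' converts mg/L to ng/mL. By periodicity \eqn{C(0) = C(\tau)}.
#'
#' @param params a [pk_parameters()] object.
#' @param dose dose per interval, mg.
#' @param t time(s) since last dose, h, each in `[0, tau]`.
#' @param tau dosing interval, h.
#' @return concentration(s), ng/mL.
#' @export
concentration_ss <- function(params, dose, t, tau = 24) {
  stopifnot(inherits(params, "pk_parameters"))
  if (dose < 0) stop("dose must be non-negative")
  if (any(t < 0 | t > tau)) stop("t must lie within [0, tau]")
  hc <- hybrid_constants(params$cl_f, params$q_f, params$vc_f, params$vp_f)
  a <- hc$alpha; b <- hc$beta; k21 <- hc$k21; ka <- params$ka
  A <- c((k21 - a) / ((ka - a) * (b - a)),
         (k21 - b) / ((ka - b) * (a - b)),
         (k21 - ka) / ((a - ka) * (b - ka)))
  lam <- c(a, b, ka)
  acc <- 0
  for (i in 1:3) {
    acc <- acc + A[i] * exp(-lam[i] * t) / (-expm1(-lam[i] * tau))
  }
  1000 * dose * ka / params$vc_f * acc
}

#' Analytic steady-state AUC over one dosing interval
#'
#' At steady state the area under one interval equals `1000 * dose / cl_f`
#' (ng*h/mL for dose in mg and CL/F in L/h) independent of the model shape.
#'
#' @inheritParams concentration_ss
#' @return AUC over `[0, tau]`, ng*h/mL.
#' @export
steady_state_auc <- function(params, dose) {
  1000 * dose / params$cl_f
}

#' Titrate the daily dose to a trough target
#'
#' Mimics therapeutic drug monitoring: on a grid of `dose_increment`
#' multiples, returns the dose closest to the weight-based starting dose
#' whose noise-free predicted trough \eqn{C(\tau)} lies inside
#' `target_c0` (ties resolved to the lower dose). If no grid dose reaches
#' the window, the dose whose trough is closest to the window midpoint is
#' returned and flagged.
#'
#' @param params a [pk_parameters()] object.
#' @param config a [simulation_config()].
#' @return list with `dose` (mg), `trough` (ng/mL) and logical `flagged`.
#' @export
titrate_dose <- function(params, config) {
  grid <- seq(config$dose_range[1], config$dose_range[2],
              by = config$dose_increment)
  trough_per_mg <- concentration_ss(params, 1, config$tau, config$tau)
  troughs <- trough_per_mg * grid
  initial <- config$initial_dose_per_kg * params$weight
  initial <- min(max(round_half_up(initial / config$dose_increment) *
                       config$dose_increment,
                     config$dose_range[1]), config$dose_range[2])
  in_window <- troughs >= config$target_c0[1] & troughs <= config$target_c0[2]
  if (any(in_window)) {
    cand <- grid[in_window]
    dist <- abs(cand - initial)
    dose <- min(cand[dist == min(dist)])
    flagged <- FALSE
  } else {
    mid <- mean(config$target_c0)
    dist <- abs(troughs - mid)
    dose <- min(grid[dist == min(dist)])
    flagged <- TRUE
  }
  list(dose = dose, trough = trough_per_mg * dose, flagged = flagged)
}

#' Apply immunoassay measurement noise
#'
#' `measured = conc * (1 + ep) + ea` with `ep ~ N(0, assay_cv)` and
#' `ea ~ N(0, assay_sd)`. Values falling below the lower limit of
#' quantification are imputed as `lloq / 2` and flagged.
#'
#' @param conc non-negative true concentration(s), ng/mL.
#' @param config a [simulation_config()].
#' @return list with numeric `conc` and logical `below_lloq`.
#' @export
add_assay_noise <- function(conc, config) {
  if (any(conc < 0)) stop("conc must be non-negative")
  n <- length(conc)
  measured <- conc * (1 + stats::rnorm(n, 0, config$assay_cv)) +
    stats::rnorm(n, 0, config$assay_sd)
  below <- measured < config$lloq
  measured[below] <- config$lloq / 2
  list(conc = measured, below_lloq = below)
}

#' Simulate a steady-state tacrolimus cohort
#'
#' For each patient: sample genotype and individual PK parameters, titrate
#' the daily dose to the trough window at a monitoring visit, drift the
#' clearance by the between-occasion deviate (`occasion_cv`), evaluate the
#' profile-day steady-state curve at the nominal times 0, 1, 2, 4, 12, 24 h
#' and apply assay noise. Ground-truth AUC refers to the profile day. Each
#' patient uses an RNG substream derived from the cohort seed by counter,
#' so patient `i` is reproducible independently of `n_patients`.
#'
#' @param config a [simulation_config()]; `config$seed` (or `seed`) must be
#'   a finite integer.
#' @param seed overrides `config$seed`.
#' @return object of class `tac_cohort`: list with data.frames `metadata`
#'   (patient_id, weight_kg, genotype, daily_dose_mg, tac_d_mg_per_kg,
#'   brand, titration_flagged), `concentrations` (long: patient_id, label,
#'   time_h, conc_ng_ml, below_lloq) and `ground_truth` (patient_id,
#'   true_auc_ng_h_ml, cl_f), plus the `config`.
#' @export
simulate_cohort <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(seed) || !is.finite(seed)) stop("a finite integer seed is required")
  seed <- as.integer(seed)
  n <- config$n_patients
  meta <- vector("list", n)
  conc <- vector("list", n)
  truth <- vector("list", n)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (i in seq_len(n)) {
    set.seed(patient_seed(seed, i))
    id <- sprintf("P%03d", i)
    genotype <- sample_genotype(config$q3)
    params <- sample_pk_parameters(genotype, config)
    brand <- names(config$brand_probs)[
      sample.int(length(config$brand_probs), 1, prob = config$brand_probs)]
    titr <- titrate_dose(params, config)
    if (config$occasion_cv > 0) {
      sigma_occ <- sqrt(log(1 + config$occasion_cv^2))
      drift <- exp(stats::rnorm(1, 0, sigma_occ))
      params <- pk_parameters(params$cl_f * drift, params$q_f, params$vc_f,
                              params$vp_f, params$ka, params$weight)
    }
    true_c <- concentration_ss(params, titr$dose, PROFILE_TIMES, config$tau)
    meas <- add_assay_noise(true_c, config)
    meta[[i]] <- data.frame(
      patient_id = id, weight_kg = params$weight, genotype = genotype,
      daily_dose_mg = titr$dose,
      tac_d_mg_per_kg = titr$dose / params$weight,
      brand = brand, titration_flagged = titr$flagged,
      stringsAsFactors = FALSE)
    conc[[i]] <- data.frame(
      patient_id = id, label = PROFILE_LABELS, time_h = PROFILE_TIMES,
      conc_ng_ml = meas$conc, below_lloq = meas$below_lloq,
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      patient_id = id,
      true_auc_ng_h_ml = steady_state_auc(params, titr$dose),
      cl_f = params$cl_f, stringsAsFactors = FALSE)
  }
  structure(
    list(metadata = do.call(rbind, meta),
         concentrations = do.call(rbind, conc),
         ground_truth = do.call(rbind, truth),
         config = config, seed = seed),
    class = "tac_cohort"
  )
}

#' @export
print.tac_cohort <- function(x, ...) {
  cat(sprintf("Synthetic tacrolimus cohort: %d patients (seed %d)\n",
              nrow(x$metadata), x$seed))
  print(table(x$metadata$genotype))
  invisible(x)
}

#' Write cohort tables to a directory
#'
#' Writes `cohort_metadata.csv`, `concentrations.csv` and
#' `ground_truth.csv` (UTF-8, comma separated, full precision, seed
#' recorded in a header comment line).
#'
#' @param cohort a `tac_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "tac_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_csv_precise(cohort$metadata, file.path(dir, "cohort_metadata.csv"),
                    seed = cohort$seed)
  write_csv_precise(cohort$concentrations, file.path(dir, "concentrations.csv"),
                    seed = cohort$seed)
  write_csv_precise(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                    seed = cohort$seed)
  invisible(dir)
}
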