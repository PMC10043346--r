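# End-to-end pipeline: configuration, validated file I/O, stage runner
# with manifest, and a human-readable report.

#' Pipeline configuration
#'
#' Bundles the simulation settings and the analysis thresholds for
#' [run_pipeline()].
#'
#' @param simulation a [simulation_config()] (ignored when `input_dir` is
#'   given).
#' @param input_dir optional directory of an existing cohort (read instead
#'   of simulating).
#' @param candidates candidate time-point labels for the LSS fit.
#' @param retention_threshold adjusted-r2 retention threshold.
#' @param ape_threshold clinical APE acceptability bound, percent.
#' @param c0_range,auc_range therapeutic windows.
#' @param out_dir output directory.
#' @param seed integer seed driving all randomness (overrides the
#'   simulation config's seed).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            input_dir = NULL,
                            candidates = c("C0", "C1", "C2", "C4"),
                            retention_threshold = 0.799,
                            ape_threshold = 15,
                            c0_range = c(5, 7),
                            auc_range = c(170, 250),
                            out_dir = tempfile("taclss_run_"),
                            seed = 20230314) {
  if (retention_threshold <= 0 || retention_threshold >= 1) {
    stop("retention_threshold must lie in (0, 1)")
  }
  if (ape_threshold <= 0) stop("ape_threshold must be positive")
  structure(
    list(simulation = simulation, input_dir = input_dir,
         candidates = candidates,
         retention_threshold = retention_threshold,
         ape_threshold = ape_threshold,
         c0_range = c0_range, auc_range = auc_range,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "pipeline_config")
}

#' Read and validate a cohort directory
#'
#' Loads `cohort_metadata.csv` and `concentrations.csv` (plus
#' `ground_truth.csv` when present), checks the schema, cross-references
#' patients, rejects duplicate `(patient, label)` rows, and flags patients
#' whose profile misses any of the six nominal time-points; those are
#' excluded from AUC analyses with a logged reason.
#'
#' @param dir cohort directory.
#' @return a `tac_cohort` (complete profiles only) with attribute
#'   `exclusions`: data.frame of excluded patients and reasons.
#' @export
read_cohort <- function(dir) {
  meta_path <- file.path(dir, "cohort_metadata.csv")
  conc_path <- file.path(dir, "concentrations.csv")
  if (!file.exists(meta_path) || !file.exists(conc_path)) {
    stop("cohort directory must contain cohort_metadata.csv and concentrations.csv")
  }
  meta <- read_csv_precise(meta_path)
  conc <- read_csv_precise(conc_path)
  need_meta <- c("patient_id", "weight_kg", "genotype", "daily_dose_mg",
                 "tac_d_mg_per_kg")
  need_conc <- c("patient_id", "label", "time_h", "conc_ng_ml")
  miss <- setdiff(need_meta, names(meta))
  if (length(miss)) stop("cohort_metadata.csv lacks column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(need_conc, names(conc))
  if (length(miss)) stop("concentrations.csv lacks column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("weight_kg", "daily_dose_mg", "tac_d_mg_per_kg")) {
    if (!is.numeric(meta[[col]])) {
      stop("non-numeric values in cohort_metadata.csv column ", col)
    }
  }
  for (col in c("time_h", "conc_ng_ml")) {
    if (!is.numeric(conc[[col]])) {
      stop("non-numeric values in concentrations.csv column ", col)
    }
  }
  dup <- duplicated(conc[, c("patient_id", "label")])
  if (any(dup)) {
    stop("duplicate (patient, label) concentration row(s): ",
         paste(sprintf("row %d (%s, %s)", which(dup), conc$patient_id[dup],
                       conc$label[dup]), collapse = "; "))
  }
  orphan <- setdiff(conc$patient_id, meta$patient_id)
  if (length(orphan)) {
    stop("concentration rows reference unknown patient(s): ",
         paste(orphan, collapse = ", "))
  }
  have <- tapply(conc$label, conc$patient_id,
                 function(l) sum(PROFILE_LABELS %in% l))
  incomplete <- names(have)[have < length(PROFILE_LABELS)]
  no_profile <- setdiff(meta$patient_id, conc$patient_id)
  exclusions <- data.frame(
    patient_id = c(incomplete, no_profile),
    reason = c(rep("incomplete profile", length(incomplete)),
               rep("no concentration rows", length(no_profile))),
    stringsAsFactors = FALSE)
  if (nrow(exclusions) > 0) {
    message(nrow(exclusions), " patient(s) excluded from AUC analyses: ",
            paste(exclusions$patient_id, collapse = ", "))
  }
  keep <- !(meta$patient_id %in% exclusions$patient_id)
  truth_path <- file.path(dir, "ground_truth.csv")
  truth <- if (file.exists(truth_path)) read_csv_precise(truth_path) else NULL
  structure(
    list(metadata = meta[keep, , drop = FALSE],
         concentrations = conc[conc$patient_id %in% meta$patient_id[keep], ,
                               drop = FALSE],
         ground_truth = truth, config = NULL, seed = NA_integer_),
    exclusions = exclusions, class = "tac_cohort")
}

#' Run the full LSS pipeline
#'
#' Stages: simulate (or load) the cohort, exposure summary, CYP3A5
#' pharmacogenetic report, all-subsets LSS fit, and clinical validation of
#' the retained fitted equations plus the two published three-point
#' pediatric equations. All tables are written to `config$out_dir` and a
#' run manifest (config snapshot, row counts per stage, MD5 checksums) is
#' written as `manifest.json`. Deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @return the manifest, invisibly; the full stage results are attached as
#'   attribute `results`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "simulate"
  manifest <- list(package = "taclss",
                   version = as.character(utils::packageVersion("taclss")),
                   seed = config$seed,
                   config = config_snapshot(config),
                   stages = list(), checksums = list())
  res <- list()
  tryCatch({
    if (is.null(config$input_dir)) {
      cohort <- simulate_cohort(config$simulation, seed = config$seed)
      write_cohort(cohort, config$out_dir)
    } else {
      cohort <- read_cohort(config$input_dir)
    }
    manifest$stages$simulate <- list(n_patients = nrow(cohort$metadata))
    res$cohort <- cohort

    stage <- "exposure"
    exposure <- summarize_exposure(cohort, config$c0_range, config$auc_range)
    write_csv_precise(exposure, file.path(config$out_dir, "exposure_summary.csv"),
                      seed = config$seed)
    manifest$stages$exposure <- list(n_rows = nrow(exposure))
    res$exposure <- exposure

    stage <- "pgx"
    pgx <- pgx_report(cohort$metadata, exposure)
    write_csv_precise(pgx_report_table(pgx),
                      file.path(config$out_dir, "pgx_report.csv"),
                      seed = config$seed)
    manifest$stages$pgx <- list(n_genotyped = sum(pgx$counts))
    res$pgx <- pgx

    stage <- "lss_fit"
    fit <- build_lss_models(exposure, cohort$concentrations,
                            config$candidates, config$retention_threshold)
    comparison <- fit$comparison
    comparison$equation <- vapply(fit$models, format_equation, character(1))
    write_csv_precise(comparison, file.path(config$out_dir, "lss_models.csv"),
                      seed = config$seed)
    manifest$stages$lss_fit <- list(n_models = nrow(comparison),
                                    n_retained = sum(comparison$retained))
    res$lss <- fit

    stage <- "lss_validate"
    eqs <- fit$models[fit$comparison$retained]
    names(eqs) <- paste0("fitted_",
                         gsub("\\+", "", fit$comparison$predictors[fit$comparison$retained]))
    eqs <- c(eqs, external_equations()[c("almeida_c0c1c4", "almeida_c0c2c4")])
    validation <- validate_equations(eqs, fit$data, config$ape_threshold)
    write_csv_precise(validation$table,
                      file.path(config$out_dir, "validation_report.csv"),
                      seed = config$seed)
    for (nm in setdiff(names(validation), "table")) {
      write_csv_precise(validation[[nm]]$bland_altman$pairs,
                        file.path(config$out_dir,
                                  sprintf("bland_altman_%s.csv", nm)),
                        seed = config$seed)
    }
    manifest$stages$lss_validate <- list(n_equations = nrow(validation$table))
    res$validation <- validation
  }, error = function(e) {
    manifest$stages$failed_stage <<- stage
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  files <- sort(list.files(config$out_dir, pattern = "\\.csv$"))
  sums <- tools::md5sum(file.path(config$out_dir, files))
  manifest$checksums <- as.list(stats::setNames(unname(sums), files))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out <- structure(manifest, class = "run_manifest", results = res)
  invisible(out)
}

config_snapshot <- function(config) {
  sim <- config$simulation
  list(n_patients = sim$n_patients, q3 = sim$q3,
       cl_expressor_multiplier = sim$cl_expressor_multiplier,
       medians = sim$medians, iiv_cv = as.list(sim$iiv_cv),
       assay_cv = sim$assay_cv, assay_sd = sim$assay_sd, lloq = sim$lloq,
       tau = sim$tau, target_c0 = sim$target_c0,
       dose_increment = sim$dose_increment, dose_range = sim$dose_range,
       initial_dose_per_kg = sim$initial_dose_per_kg,
       input_dir = config$input_dir, candidates = config$candidates,
       retention_threshold = config$retention_threshold,
       ape_threshold = config$ape_threshold,
       c0_range = config$c0_range, auc_range = config$auc_range)
}

#' Render a markdown report for a completed run
#'
#' Produces the cohort summary, genotype/allele section (percentages at
#' one decimal, rounded half away from zero), the model table with
#' equations in the conventional `AUC = a + C0*b0 + ...` style, and the
#' validation section.
#'
#' @param manifest a `run_manifest` from [run_pipeline()].
#' @param path optional file to write the report to.
#' @return character vector of report lines, invisibly if `path` is given.
#' @export
render_report <- function(manifest, path = NULL) {
  res <- attr(manifest, "results")
  if (is.null(res)) stop("manifest carries no attached results")
  exposure <- res$exposure
  pgx <- res$pgx
  comp <- res$lss$comparison
  lines <- c(
    "# Tacrolimus limited-sampling-strategy report",
    "",
    sprintf("Seed: %d; patients analysed: %d", manifest$seed, nrow(exposure)),
    "",
    "## Cohort exposure summary",
    sprintf("- Trapezoidal AUC0-24: %.1f +/- %.1f ng*h/mL (min %.1f, max %.1f)",
            mean(exposure$auc_0_24), stats::sd(exposure$auc_0_24),
            min(exposure$auc_0_24), max(exposure$auc_0_24)),
    sprintf("- C0: %.1f +/- %.1f ng/mL; Cmax: %.1f +/- %.1f ng/mL",
            mean(exposure$c0), stats::sd(exposure$c0),
            mean(exposure$cmax), stats::sd(exposure$cmax)),
    sprintf("- TAC-D: %.3f +/- %.3f mg/kg",
            mean(exposure$tac_d_mg_per_kg), stats::sd(exposure$tac_d_mg_per_kg)),
    sprintf("- C0 out of range: %d/%d; AUC0-24 out of range: %d/%d",
            sum(exposure$c0_flag != "within"), nrow(exposure),
            sum(exposure$auc_flag != "within"), nrow(exposure)),
    "",
    "## CYP3A5 pharmacogenetics",
    sprintf("- Genotypes: *1/*1 %d (%.1f%%), *1/*3 %d (%.1f%%), *3/*3 %d (%.1f%%)",
            pgx$counts[1], pgx$percent[1], pgx$counts[2], pgx$percent[2],
            pgx$counts[3], pgx$percent[3]),
    sprintf("- *3 allele frequency: %.1f%%", pgx$allele$freq3_pct),
    sprintf("- Hardy-Weinberg goodness of fit: chi2 = %.2f, p = %.2f",
            pgx$hwe$chi2, pgx$hwe$p),
    sprintf("- TAC-D (mg/kg): expressors %.3f vs non-expressors %.3f (ANOVA p = %.2g; Mann-Whitney p = %.2g)",
            pgx$group_means$tac_d["expressor"],
            pgx$group_means$tac_d["non_expressor"],
            pgx$tests$tac_d$anova$p, pgx$tests$tac_d$mann_whitney$p),
    sprintf("- AUC0-24/TAC-D: expressors %.1f vs non-expressors %.1f (ANOVA p = %.2g; Mann-Whitney p = %.2g)",
            pgx$group_means$auc_per_dose["expressor"],
            pgx$group_means$auc_per_dose["non_expressor"],
            pgx$tests$auc_per_dose$anova$p,
            pgx$tests$auc_per_dose$mann_whitney$p),
    "",
    "## Candidate LSS models (all subsets)",
    "",
    "| Model | Predictors | adj r2 | retained |",
    "|---|---|---|---|",
    sprintf("| %d | %s | %.4f | %s |", comp$model, comp$predictors,
            comp$adj_r2, ifelse(comp$retained, "yes", "no")),
    "",
    "## Retained equations")
  for (i in which(comp$retained)) {
    m <- res$lss$models[[i]]
    lines <- c(lines, sprintf(
      "- Model %d: %s (adj r2 %.4f, MAPE %.1f%%, AICw %.3f, BICw %.3f)",
      comp$model[i], format_equation(m), comp$adj_r2[i], comp$mape[i],
      comp$aic_weight[i], comp$bic_weight[i]))
  }
  vt <- res$validation$table
  lines <- c(lines, "", "## Clinical validation",
             "",
             "| Equation | MAPE median | mean +/- SD | frac > threshold | BA mean diff [LoA] |",
             "|---|---|---|---|---|",
             sprintf("| %s | %.1f%% | %.1f%% +/- %.1f%% | %.1f%% | %.1f [%.1f, %.1f] |",
                     vt$equation, vt$mape_median, vt$mape_mean, vt$mape_sd,
                     round_half_up(100 * vt$fraction_above_threshold, 1),
                     vt$ba_mean_diff, vt$ba_loa_lower, vt$ba_loa_upper))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("taclss run manifest (seed %d)\n", x$seed))
  for (nm in names(x$stages)) {
    cat(sprintf("  %s: %s\n", nm,
                paste(names(x$stages[[nm]]), unlist(x$stages[[nm]]),
                      sep = "=", collapse = ", ")))
  }
  cat(sprintf("  %d output file(s) checksummed\n", length(x$checksums)))
  invisible(x)
}
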