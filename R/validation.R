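# Clinical validation of LSS equations against trapezoidal AUC0-24:
# absolute prediction error, the 15% clinical-acceptability fraction,
# Bland-Altman agreement, subgroup-consistency (ANCOVA-style) tests and
# cross-validation.

#' Absolute prediction error (APE)
#'
#' `APE(%) = 100 |predicted - observed| / observed`.
#'
#' @param predicted LSS-predicted AUC0-24 value(s).
#' @param observed trapezoidal AUC0-24 value(s); must be positive.
#' @return APE percentage(s).
#' @export
absolute_prediction_error <- function(predicted, observed) {
  if (any(observed <= 0)) stop("observed reference values must be positive")
  100 * abs(predicted - observed) / observed
}

#' Summary of absolute prediction errors
#'
#' Median (the MAPE proper), mean, sample SD, and the fraction of values
#' strictly above the clinical-acceptability threshold.
#'
#' @param apes numeric vector of APE percentages.
#' @param threshold acceptability bound, percent (default 15).
#' @return list with `median`, `mean`, `sd`, `fraction_above`, `n`.
#' @export
mape_summary <- function(apes, threshold = 15) {
  if (length(apes) == 0) stop("APE list must be non-empty")
  list(median = stats::median(apes),
       mean = mean(apes),
       sd = if (length(apes) > 1) stats::sd(apes) else 0,
       fraction_above = mean(apes > threshold),
       n = length(apes))
}

#' A fixed limited-sampling equation
#'
#' @param name equation identifier.
#' @param intercept intercept, ng*h/mL.
#' @param coefficients named numeric vector of per-time-point coefficients
#'   (names among C0, C1, C2, C4).
#' @return object of classes `lss_equation` (usable by [predict_auc()]).
#' @export
lss_equation <- function(name, intercept, coefficients) {
  if (any(!is.finite(c(intercept, coefficients)))) {
    stop("equation constants must be finite")
  }
  structure(list(name = name, intercept = intercept,
                 coefficients = coefficients,
                 predictors = names(coefficients)),
            class = c("lss_equation", "lss_model"))
}

#' Built-in published limited-sampling equations
#'
#' Fixed three-point pediatric equations from Almeida-Paulo and
#' colleagues (2014), developed in Spanish pediatric liver/kidney
#' transplant recipients:
#' `almeida_c0c1c4`: AUC = 39.179 + 8.772 C0 + 2.297 C1 + 7.926 C4 and
#' `almeida_c0c2c4`: AUC = 46.062 + 9.129 C0 + 2.768 C2 + 6.450 C4;
#' plus the retained equations developed in an extended-release pediatric
#' kidney cohort (`lss_c0c4`, `lss_c0c1c4`, `lss_c0c2c4`, `lss_c0c1c2c4`).
#'
#' @return named list of [lss_equation()] objects.
#' @export
external_equations <- function() {
  list(
    almeida_c0c1c4 = lss_equation("almeida_c0c1c4", 39.179,
                                  c(C0 = 8.772, C1 = 2.297, C4 = 7.926)),
    almeida_c0c2c4 = lss_equation("almeida_c0c2c4", 46.062,
                                  c(C0 = 9.129, C2 = 2.768, C4 = 6.450)),
    lss_c0c4 = lss_equation("lss_c0c4", 36.18,
                            c(C0 = 11.53, C4 = 9.50)),
    lss_c0c1c4 = lss_equation("lss_c0c1c4", 26.0,
                              c(C0 = 11.27, C1 = 1.97, C4 = 8.13)),
    lss_c0c2c4 = lss_equation("lss_c0c2c4", 31.82,
                              c(C0 = 10.26, C2 = 1.73, C4 = 8.42)),
    lss_c0c1c2c4 = lss_equation("lss_c0c1c2c4", 26.30,
                                c(C0 = 10.95, C1 = 1.67, C2 = 0.49,
                                  C4 = 8.04)))
}

#' Apply a fixed LSS equation to concentration profiles
#'
#' @param eq an [lss_equation()].
#' @param profile named numeric vector or wide data.frame with the
#'   equation's time-point columns (ng/mL).
#' @return predicted AUC0-24 value(s), ng*h/mL.
#' @export
apply_external_equation <- function(eq, profile) {
  stopifnot(inherits(eq, "lss_equation"))
  predict_auc(eq, profile)
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `a - b` (method A = LSS-predicted, method B =
#' observed trapezoidal). Limits of agreement are
#' `mean(d) +/- 1.96 sd(d)` with the sample (n-1) standard deviation.
#'
#' @param a,b paired measurement vectors of equal length (n >= 2).
#' @return list with `mean_diff`, `sd_diff`, `loa_lower`, `loa_upper`, `n`
#'   and a `pairs` data.frame (`average`, `difference`) for plotting.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 pairs")
  d <- a - b
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, sd_diff = s,
       loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
       n = length(d),
       pairs = data.frame(average = (a + b) / 2, difference = d))
}

#' Subgroup consistency of an LSS equation
#'
#' Tests whether the predicted/observed relationship differs across
#' subgroups (brand, genotype, age group, ...): fits
#' `observed ~ predicted + group` (plus an optional covariate) and
#' F-tests the group terms against the reduced model without them.
#'
#' @param predicted LSS-predicted AUC0-24 values.
#' @param observed trapezoidal AUC0-24 values.
#' @param group subgroup labels (>= 2 groups, each with >= 2 members).
#' @param covariate optional numeric covariate included in both models.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
subgroup_consistency <- function(predicted, observed, group,
                                 covariate = NULL) {
  group <- factor(group)
  if (nlevels(group) < 2) stop("need at least 2 subgroups")
  if (any(table(group) < 2)) stop("each subgroup needs at least 2 members")
  d <- data.frame(observed = observed, predicted = predicted, group = group)
  if (!is.null(covariate)) {
    d$covariate <- covariate
    reduced <- stats::lm(observed ~ predicted + covariate, data = d)
    full <- stats::lm(observed ~ predicted + covariate + group, data = d)
  } else {
    reduced <- stats::lm(observed ~ predicted, data = d)
    full <- stats::lm(observed ~ predicted + group, data = d)
  }
  if (any(is.na(stats::coef(full)))) {
    stop("singular design in subgroup model (collinear terms)")
  }
  an <- stats::anova(reduced, full)
  list(F = an$F[2], df1 = an$Df[2], df2 = an$Res.Df[2], p = an$`Pr(>F)`[2])
}

#' Cross-validated out-of-sample APE for a predictor subset
#'
#' Deterministic k-fold cross-validation: fold assignment by a seeded
#' shuffle, stratified by an optional grouping (e.g. CYP3A5 expressor
#' status) to keep small cohorts balanced. Each fold is predicted by the
#' equation fitted on the remaining folds; APEs are pooled.
#'
#' @param data wide analysis table with `auc_0_24` and the predictor
#'   columns (e.g. `lss_fit$data`).
#' @param predictors character vector of time-point columns.
#' @param folds number of folds (>= 2, <= n).
#' @param seed integer seed controlling fold assignment.
#' @param strata optional vector used to stratify fold assignment.
#' @return list with `summary` ([mape_summary()] of pooled APEs),
#'   `apes` (per observation, in `data` order) and `fold` assignment.
#' @export
crossvalidate_lss <- function(data, predictors, folds = 5, seed = 1,
                              strata = NULL) {
  n <- nrow(data)
  if (folds < 2) stop("folds must be >= 2")
  if (folds > n) stop("more folds than observations")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  fold <- integer(n)
  groups <- if (is.null(strata)) rep(1, n) else strata
  for (g in unique(groups)) {
    idx <- which(groups == g)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(folds), length(idx))
  }
  apes <- numeric(n)
  for (f in seq_len(folds)) {
    test <- fold == f
    if (!any(test)) next
    fit <- fit_ols(data[!test, predictors, drop = FALSE],
                   data$auc_0_24[!test])
    pred <- predict_auc(fit, data[test, , drop = FALSE])
    apes[test] <- absolute_prediction_error(pred, data$auc_0_24[test])
  }
  list(summary = mape_summary(apes), apes = apes, fold = fold)
}

#' Validate a set of LSS equations against trapezoidal AUC0-24
#'
#' For each equation (fitted `lss_model` or fixed `lss_equation`),
#' computes per-patient APEs, the MAPE summary with the clinical
#' 15%-deviation fraction, and the Bland-Altman agreement of predicted
#' vs observed AUC0-24.
#'
#' @param equations named list of `lss_model` / `lss_equation` objects.
#' @param data wide analysis table with `auc_0_24` and the needed
#'   time-point columns.
#' @param ape_threshold clinical acceptability bound, percent.
#' @return list of class `lss_validation`: per equation a list with
#'   `predicted`, `apes`, `mape` and `bland_altman`; plus a `table`
#'   data.frame summarising all equations.
#' @export
validate_equations <- function(equations, data, ape_threshold = 15) {
  res <- lapply(equations, function(eq) {
    pred <- predict_auc(eq, data)
    apes <- absolute_prediction_error(pred, data$auc_0_24)
    list(predicted = pred, apes = apes,
         mape = mape_summary(apes, ape_threshold),
         bland_altman = bland_altman(pred, data$auc_0_24))
  })
  tab <- do.call(rbind, lapply(names(res), function(nm) {
    r <- res[[nm]]
    data.frame(equation = nm,
               mean_predicted = mean(r$predicted),
               mape_median = r$mape$median,
               mape_mean = r$mape$mean,
               mape_sd = r$mape$sd,
               fraction_above_threshold = r$mape$fraction_above,
               ba_mean_diff = r$bland_altman$mean_diff,
               ba_sd_diff = r$bland_altman$sd_diff,
               ba_loa_lower = r$bland_altman$loa_lower,
               ba_loa_upper = r$bland_altman$loa_upper,
               stringsAsFactors = FALSE)
  }))
  structure(c(res, list(table = tab)), class = "lss_validation")
}
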