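# Limited-sampling-strategy builder: exhaustive subset regression of
# trapezoidal AUC0-24 on early time-point concentrations, adjusted-r2
# retention, and AIC/BIC weight comparison.

#' Enumerate non-empty predictor subsets
#'
#' All `2^k - 1` non-empty subsets of the candidate time-points, ordered by
#' subset size and then lexicographically in the candidate order. For the
#' canonical candidates `C0, C1, C2, C4` this yields the conventional model
#' numbering 1--15 (singletons first, the full model last).
#'
#' @param candidates character vector of time-point labels (1 to 16).
#' @return named list of character vectors; names are the model numbers.
#' @export
enumerate_predictor_subsets <- function(candidates = c("C0", "C1", "C2", "C4")) {
  k <- length(candidates)
  if (k < 1) stop("candidate list must not be empty")
  if (k > 16) stop("at most 16 candidate time-points are supported")
  if (anyDuplicated(candidates)) stop("candidate labels must be unique")
  subsets <- list()
  for (size in seq_len(k)) {
    idx <- utils::combn(k, size, simplify = FALSE)
    subsets <- c(subsets, lapply(idx, function(i) candidates[i]))
  }
  names(subsets) <- seq_along(subsets)
  subsets
}

#' Fit one least-squares LSS candidate
#'
#' Ordinary least squares of AUC0-24 on the given concentration columns
#' (with intercept), via [stats::lm()]. Reports the coefficient vector,
#' fit statistics (r2, adjusted r2), Gaussian-form information criteria
#' and the in-sample median absolute prediction error.
#'
#' @param design data.frame of predictor columns (one per time-point).
#' @param response numeric AUC0-24 values.
#' @return object of class `lss_model`: list with `predictors`,
#'   `intercept`, `coefficients` (named, per predictor), `n`, `rss`, `r2`,
#'   `adj_r2`, `aic`, `bic`, `mape`, `fitted`, `se` (coefficient standard
#'   errors incl. intercept).
#' @export
fit_ols <- function(design, response) {
  design <- as.data.frame(design)
  p <- ncol(design)
  n <- length(response)
  if (p < 1) stop("at least one predictor column is required")
  if (nrow(design) != n) stop("design and response lengths differ")
  if (n <= p + 1) stop("need n > number of coefficients (p + 1)")
  mm <- cbind(`(Intercept)` = 1, as.matrix(design))
  qd <- qr(mm)
  if (qd$rank < ncol(mm)) {
    dropped <- colnames(mm)[qd$pivot[(qd$rank + 1):ncol(mm)]]
    stop("singular design: collinear column(s) ",
         paste(dropped, collapse = ", "))
  }
  dat <- cbind(.response = response, design)
  fit <- stats::lm(.response ~ ., data = dat)
  res <- stats::residuals(fit)
  rss <- sum(res^2)
  tss <- sum((response - mean(response))^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  co <- stats::coef(fit)
  ic <- information_criteria(n, rss, p)
  # SEs straight from the QR factorisation (summary.lm warns on exact fits)
  xtx_inv <- chol2inv(qr.R(qd))
  se <- sqrt(pmax(diag(xtx_inv), 0) * rss / (n - p - 1))
  names(se) <- colnames(mm)
  structure(
    list(predictors = colnames(design),
         intercept = unname(co[1]),
         coefficients = co[-1],
         n = n, rss = rss, r2 = r2,
         adj_r2 = adjusted_r2(r2, n, p),
         aic = ic$aic, bic = ic$bic,
         mape = stats::median(100 * abs(res) / response),
         fitted = unname(stats::fitted(fit)),
         se = se),
    class = "lss_model")
}

#' @export
print.lss_model <- function(x, ...) {
  cat(format_equation(x), "\n")
  cat(sprintf("  n = %d, r2 = %.4f, adj r2 = %.4f, MAPE = %.1f%%\n",
              x$n, x$r2, x$adj_r2, x$mape))
  invisible(x)
}

#' Adjusted r-squared
#'
#' `1 - (1 - r2) (n - 1) / (n - p - 1)`.
#'
#' @param r2 coefficient of determination.
#' @param n number of observations.
#' @param p number of predictors (excluding intercept).
#' @return adjusted r-squared.
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (n <= p + 1) stop("adjusted r2 undefined: need n > p + 1")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Gaussian-form information criteria
#'
#' `aic = n log(rss/n) + 2k` and `bic = n log(rss/n) + k log(n)` with
#' `k = p + 2` (intercept and residual variance counted as parameters).
#' Only differences across models fitted to the same response are
#' meaningful. A perfect fit (`rss = 0`) yields `-Inf` with a flag.
#'
#' @param n observations.
#' @param rss residual sum of squares.
#' @param p number of predictors (excluding intercept).
#' @return list with `aic`, `bic`, `k`, `perfect_fit`.
#' @export
information_criteria <- function(n, rss, p) {
  k <- p + 2
  if (rss < 0) stop("rss must be non-negative")
  if (rss == 0) {
    return(list(aic = -Inf, bic = -Inf, k = k, perfect_fit = TRUE))
  }
  list(aic = n * log(rss / n) + 2 * k,
       bic = n * log(rss / n) + k * log(n),
       k = k, perfect_fit = FALSE)
}

#' Akaike-style model weights
#'
#' `w_i = exp(-D_i / 2) / sum_j exp(-D_j / 2)` with `D_i` the difference to
#' the smallest criterion value; applied identically to AIC and BIC values.
#' Models with criterion `-Inf` (perfect fits) absorb all the weight.
#'
#' @param values numeric criterion values (at least one finite or `-Inf`).
#' @return numeric weights summing to 1.
#' @export
akaike_weights <- function(values) {
  if (length(values) == 0 || all(!is.finite(values) & values != -Inf)) {
    stop("at least one usable criterion value is required")
  }
  if (any(values == -Inf)) {
    w <- as.numeric(values == -Inf)
    return(w / sum(w))
  }
  delta <- values - min(values)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Retain models above an adjusted-r2 threshold and weight them
#'
#' Retention uses the strict inequality `adj_r2 > threshold`. AIC and BIC
#' weights are computed over the retained set only; if nothing is
#' retained, a warning is raised and the weights are computed over all
#' models with `all_models_used = TRUE`.
#'
#' @param models list of `lss_model` objects (e.g. from
#'   [build_lss_models()]).
#' @param threshold adjusted-r2 retention threshold in (0, 1).
#' @return data.frame of class `lss_comparison`: `model`, `predictors`,
#'   `n_predictors`, `adj_r2`, `mape`, `aic`, `bic`, `retained`,
#'   `aic_weight`, `bic_weight` (weights `NA` for non-retained models);
#'   attribute `all_models_used`.
#' @export
retain_models <- function(models, threshold = 0.799) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  adj <- vapply(models, function(m) m$adj_r2, numeric(1))
  out <- data.frame(
    model = as.integer(names(models) %||% seq_along(models)),
    predictors = vapply(models, function(m) paste(m$predictors, collapse = "+"),
                        character(1)),
    n_predictors = vapply(models, function(m) length(m$predictors), integer(1)),
    adj_r2 = adj,
    mape = vapply(models, function(m) m$mape, numeric(1)),
    aic = vapply(models, function(m) m$aic, numeric(1)),
    bic = vapply(models, function(m) m$bic, numeric(1)),
    retained = adj > threshold,
    aic_weight = NA_real_, bic_weight = NA_real_,
    stringsAsFactors = FALSE)
  all_models_used <- FALSE
  pool <- which(out$retained)
  if (length(pool) == 0) {
    warning("no model exceeds the adjusted-r2 threshold; ",
            "weights computed over all models")
    pool <- seq_len(nrow(out))
    all_models_used <- TRUE
  }
  out$aic_weight[pool] <- akaike_weights(out$aic[pool])
  out$bic_weight[pool] <- akaike_weights(out$bic[pool])
  rownames(out) <- NULL
  structure(out, all_models_used = all_models_used,
            class = c("lss_comparison", "data.frame"))
}

# Shared evaluator for fitted models and fixed published equations.
evaluate_linear_equation <- function(intercept, coefficients, profile) {
  profile <- as.data.frame(profile)
  missing_lab <- setdiff(names(coefficients), names(profile))
  if (length(missing_lab) > 0) {
    stop("profile is missing required time-point(s): ",
         paste(missing_lab, collapse = ", "))
  }
  vals <- rep(intercept, nrow(profile))
  for (lab in names(coefficients)) {
    vals <- vals + coefficients[[lab]] * profile[[lab]]
  }
  vals
}

#' Predict AUC0-24 from a fitted LSS model
#'
#' `AUC = intercept + sum(coefficient * concentration)` over the model's
#' time-points.
#'
#' @param model an `lss_model` (or `lss_equation`).
#' @param profile named numeric vector, one-row data.frame or wide
#'   data.frame with the model's time-point columns (ng/mL).
#' @return predicted AUC0-24 value(s), ng*h/mL.
#' @export
predict_auc <- function(model, profile) {
  if (is.numeric(profile) && !is.null(names(profile))) {
    profile <- as.data.frame(as.list(profile))
  }
  evaluate_linear_equation(model$intercept, as.list(model$coefficients), profile)
}

#' Fit all candidate LSS subsets on a cohort
#'
#' Builds the wide concentration matrix, fits every non-empty subset of
#' the candidate time-points against trapezoidal AUC0-24, and attaches the
#' retention/weight comparison.
#'
#' @param exposure exposure summary from [summarize_exposure()]
#'   (`patient_id`, `auc_0_24`).
#' @param concentrations long concentration table (`patient_id`, `label`,
#'   `conc_ng_ml`).
#' @param candidates candidate time-point labels.
#' @param threshold adjusted-r2 retention threshold.
#' @return list of class `lss_fit`: `models` (named list of `lss_model`),
#'   `comparison` (from [retain_models()]), `data` (the wide analysis
#'   table).
#' @export
build_lss_models <- function(exposure, concentrations,
                             candidates = c("C0", "C1", "C2", "C4"),
                             threshold = 0.799) {
  wide <- concentrations_wide(concentrations)
  missing_lab <- setdiff(candidates, names(wide))
  if (length(missing_lab) > 0) {
    stop("concentration table lacks label(s): ",
         paste(missing_lab, collapse = ", "))
  }
  d <- merge(exposure[, c("patient_id", "auc_0_24")], wide, by = "patient_id")
  subsets <- enumerate_predictor_subsets(candidates)
  models <- lapply(subsets, function(s) {
    fit_ols(d[, s, drop = FALSE], d$auc_0_24)
  })
  structure(list(models = models,
                 comparison = retain_models(models, threshold),
                 data = d),
            class = "lss_fit")
}

#' Reshape a long concentration table to wide
#'
#' @param concentrations long table with `patient_id`, `label`,
#'   `conc_ng_ml`.
#' @return data.frame with `patient_id` and one column per label.
#' @export
concentrations_wide <- function(concentrations) {
  labs <- unique(concentrations$label)
  rows <- lapply(split(concentrations, concentrations$patient_id), function(d) {
    out <- as.data.frame(as.list(stats::setNames(d$conc_ng_ml, d$label)))
    out$patient_id <- d$patient_id[1]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, c("patient_id", intersect(labs, names(out)))]
}

# Render "AUC = a + C0*b0 + ..." in the conventional reporting style.
format_equation <- function(model, digits = 2) {
  co <- model$coefficients
  terms <- paste(sprintf("%s*%.*f", names(co), digits, co), collapse = " + ")
  sprintf("AUC = %.*f + %s", digits, model$intercept, terms)
}
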