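# Observed exposure metrics from concentration-time profiles.

#' Linear trapezoidal AUC
#'
#' Area under the concentration-time curve by the linear trapezoidal rule
#' over the observed points, the reference ("gold standard") integration
#' for tacrolimus AUC0-24 profiles.
#'
#' @param time sampling times, h, strictly increasing.
#' @param conc concentrations, ng/mL, non-negative, same length as `time`.
#' @param patient optional patient id used in error messages.
#' @return AUC, ng*h/mL.
#' @export
trapezoidal_auc <- function(time, conc, patient = NULL) {
  who <- if (is.null(patient)) "" else sprintf(" (patient %s)", patient)
  if (length(time) < 2 || length(time) != length(conc)) {
    stop("profile needs >= 2 paired (time, concentration) points", who)
  }
  if (any(diff(time) <= 0)) stop("times must be strictly increasing", who)
  if (any(conc < 0)) stop("concentrations must be non-negative", who)
  pracma::trapz(time, conc)
}

#' Peak concentration and its time
#'
#' @inheritParams trapezoidal_auc
#' @return list with `cmax` (ng/mL) and `tmax` (h, earliest time attaining
#'   the maximum).
#' @export
cmax_tmax <- function(time, conc) {
  idx <- which.max(conc)  # which.max returns the earliest maximum
  list(cmax = conc[idx], tmax = time[idx])
}

#' Dose-normalized AUC
#'
#' AUC0-24 divided by the weight-normalized daily dose (TAC-D, mg/kg).
#'
#' @param auc AUC0-24, ng*h/mL.
#' @param tac_d daily dose per body weight, mg/kg; must be positive.
#' @return ng*h/mL per mg/kg.
#' @export
dose_normalized_auc <- function(auc, tac_d) {
  if (any(tac_d <= 0)) stop("tac_d must be positive")
  auc / tac_d
}

#' Apparent weight-normalized clearance
#'
#' `1000 * tac_d / auc`: the daily dose rate normalized by exposure, the
#' analogue of CL/F per kg (the factor 1000 converts mg and mL to ng and L).
#'
#' @param tac_d daily dose per body weight, mg/kg.
#' @param auc AUC0-24, ng*h/mL; must be positive.
#' @return apparent clearance, L/kg/h.
#' @export
apparent_clearance <- function(tac_d, auc) {
  if (any(auc <= 0)) stop("auc must be positive")
  1000 * tac_d / auc
}

#' Therapeutic-range flags
#'
#' Classifies trough and AUC against their target windows; boundaries are
#' inclusive ("within").
#'
#' @param c0 trough concentration(s), ng/mL.
#' @param auc AUC0-24 value(s), ng*h/mL.
#' @param c0_range trough target `(low, high)`, ng/mL.
#' @param auc_range AUC target `(low, high)`, ng*h/mL.
#' @return list with character vectors `c0_flag` and `auc_flag`, each one of
#'   `"below"`, `"within"`, `"above"`.
#' @export
range_flags <- function(c0, auc, c0_range = c(5, 7), auc_range = c(170, 250)) {
  flag <- function(x, rng) {
    if (rng[1] >= rng[2]) stop("range must satisfy low < high")
    ifelse(x < rng[1], "below", ifelse(x > rng[2], "above", "within"))
  }
  list(c0_flag = flag(c0, c0_range), auc_flag = flag(auc, auc_range))
}

#' Per-patient exposure summary
#'
#' Computes trapezoidal AUC0-24, Cmax/Tmax, trough, dose-normalized AUC,
#' apparent clearance and therapeutic-range flags for every complete
#' profile of a cohort.
#'
#' @param cohort a `tac_cohort` (or list with `concentrations` and
#'   `metadata` in the cohort file schema).
#' @param c0_range,auc_range therapeutic windows passed to [range_flags()].
#' @return data.frame with one row per patient: `patient_id`, `auc_0_24`,
#'   `cmax`, `tmax`, `c0`, `tac_d_mg_per_kg`, `auc_per_dose`,
#'   `cl_apparent`, `c0_flag`, `auc_flag`.
#' @export
summarize_exposure <- function(cohort, c0_range = c(5, 7),
                               auc_range = c(170, 250)) {
  conc <- cohort$concentrations
  meta <- cohort$metadata
  rows <- lapply(split(conc, conc$patient_id), function(d) {
    d <- d[order(d$time_h), ]
    auc <- trapezoidal_auc(d$time_h, d$conc_ng_ml, patient = d$patient_id[1])
    pk <- cmax_tmax(d$time_h, d$conc_ng_ml)
    data.frame(patient_id = d$patient_id[1], auc_0_24 = auc,
               cmax = pk$cmax, tmax = pk$tmax,
               c0 = d$conc_ng_ml[d$time_h == 0][1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- merge(out, meta[, c("patient_id", "tac_d_mg_per_kg")],
               by = "patient_id", sort = TRUE)
  out$auc_per_dose <- dose_normalized_auc(out$auc_0_24, out$tac_d_mg_per_kg)
  out$cl_apparent <- apparent_clearance(out$tac_d_mg_per_kg, out$auc_0_24)
  fl <- range_flags(out$c0, out$auc_0_24, c0_range, auc_range)
  out$c0_flag <- fl$c0_flag
  out$auc_flag <- fl$auc_flag
  rownames(out) <- NULL
  out
}
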