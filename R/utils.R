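# Internal helpers shared across modules.

# Round half away from zero (report style); base round() is banker's rounding.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a table as CSV with full double precision
#'
#' Doubles are serialised with 17 significant digits so that a write/read
#' round trip reproduces values exactly. An optional leading comment line
#' records the simulation seed; [read_csv_precise()] skips such lines.
#'
#' @param df data.frame to write.
#' @param path output file path.
#' @param seed optional integer recorded as a `# taclss seed=<seed>` header.
#' @return `path`, invisibly.
#' @export
write_csv_precise <- function(df, path, seed = NULL) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# taclss seed=%d", as.integer(seed)), con)
  utils::write.table(out, con, sep = ",", row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a CSV written by [write_csv_precise()]
#'
#' @param path file path.
#' @return data.frame with `"NA"` strings restored to missing values.
#' @export
read_csv_precise <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                  na.strings = c("NA", ""))
}

# Stable per-patient seed derived from the cohort seed: patient i is
# reproducible independently of n_patients. Kept strictly below 2^31.
patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 1e6) * 2111 + 104729 * i) %% 2147483647L
}
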