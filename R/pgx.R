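# CYP3A5 pharmacogenetic analyses: genotype classification, allele
# frequencies, Hardy-Weinberg goodness of fit, and group-difference tests
# for dose requirements and dose-normalized exposure.

#' Classify CYP3A5 genotypes into expression phenotypes
#'
#' Carriers of at least one functional *1 allele (`*1/*1`, `*1/*3`) are
#' expressors; `*3/*3` carriers are non-expressors. Missing genotypes map
#' to `"unknown"` and are excluded from downstream genetic analyses.
#'
#' @param genotype character vector of genotype labels (`"*1/*1"`,
#'   `"*1/*3"`, `"*3/*3"`, `"missing"` or `NA`).
#' @return character vector: `"expressor"`, `"non_expressor"`, `"unknown"`.
#' @export
classify_expressor <- function(genotype) {
  out <- character(length(genotype))
  known <- c("*1/*1", "*1/*3", "*3/*3", "missing")
  bad <- !is.na(genotype) & !(genotype %in% known)
  if (any(bad)) {
    stop("unrecognized genotype '", genotype[bad][1],
         "'; accepted tokens: ", paste(known, collapse = ", "), ", NA")
  }
  out[is.na(genotype) | genotype == "missing"] <- "unknown"
  out[!is.na(genotype) & genotype %in% c("*1/*1", "*1/*3")] <- "expressor"
  out[!is.na(genotype) & genotype == "*3/*3"] <- "non_expressor"
  out
}

#' Tally CYP3A5 genotype counts
#'
#' @param genotype character vector of genotype labels; missing/unknown
#'   entries are dropped.
#' @return named integer vector `c(n11, n13, n33)`.
#' @export
genotype_counts <- function(genotype) {
  keep <- classify_expressor(genotype) != "unknown"
  g <- genotype[keep]
  c(n11 = sum(g == "*1/*1"), n13 = sum(g == "*1/*3"), n33 = sum(g == "*3/*3"))
}

#' Allele frequencies from genotype counts
#'
#' For a biallelic locus, `freq3 = (n13 + 2 n33) / (2 n)` and
#' `freq1 = 1 - freq3`.
#'
#' @param counts numeric vector `(n11, n13, n33)` of genotype counts.
#' @return list with `freq1`, `freq3` and `n` (genotyped subjects).
#' @export
allele_frequencies <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 3 || any(counts < 0)) {
    stop("counts must be three non-negative genotype tallies (n11, n13, n33)")
  }
  n <- sum(counts)
  if (n == 0) stop("no genotyped subjects: all counts are zero")
  freq3 <- (counts[2] + 2 * counts[3]) / (2 * n)
  list(freq1 = 1 - freq3, freq3 = freq3, n = n)
}

#' Hardy-Weinberg chi-square goodness of fit
#'
#' Expected counts \eqn{n(p^2, 2pq, q^2)} use the allele frequencies
#' estimated from the observed counts; the statistic is
#' \eqn{\sum (O-E)^2/E} on 1 degree of freedom (3 genotype classes, minus
#' 1, minus 1 estimated allele frequency).
#'
#' @inheritParams allele_frequencies
#' @return list with `chi2`, `df` and `p`.
#' @export
hwe_chi_square <- function(counts) {
  fr <- allele_frequencies(counts)
  n <- fr$n
  expected <- n * c(fr$freq1^2, 2 * fr$freq1 * fr$freq3, fr$freq3^2)
  observed <- as.numeric(counts)
  if (any(expected == 0 & observed > 0)) {
    stop("degenerate counts: zero expected class with non-zero observations")
  }
  use <- expected > 0
  chi2 <- sum((observed[use] - expected[use])^2 / expected[use])
  list(chi2 = chi2, df = 1, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
       expected = expected)
}

as_grouped <- function(groups) {
  if (!is.list(groups) || is.null(names(groups))) {
    stop("groups must be a named list of numeric vectors")
  }
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2) stop("need at least 2 non-empty groups")
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups), lengths(groups))))
}

#' One-way analysis of variance
#'
#' Standard between/within sum-of-squares decomposition,
#' `F = MSB / MSW`, fitted via [stats::lm()].
#'
#' @param groups named list of numeric vectors, one per group.
#' @return list with `F`, `df1`, `df2`, `p`.
#' @export
one_way_anova <- function(groups) {
  d <- as_grouped(groups)
  k <- nlevels(d$group)
  if (nrow(d) <= k) stop("total n must exceed the number of groups")
  # exact degeneracy screen (lm residuals carry floating-point dust)
  mu_g <- stats::ave(d$value, d$group)
  ssw <- sum((d$value - mu_g)^2)
  ssb <- sum((mu_g - mean(d$value))^2)
  if (ssw == 0) {
    if (ssb == 0) return(list(F = 0, df1 = k - 1, df2 = nrow(d) - k, p = 1))
    return(list(F = Inf, df1 = k - 1, df2 = nrow(d) - k, p = 0,
                degenerate = "zero within-group variance"))
  }
  an <- stats::anova(stats::lm(value ~ group, data = d))
  list(F = an$`F value`[1], df1 = an$Df[1], df2 = an$Df[2], p = an$`Pr(>F)`[1])
}

#' Fligner-Killeen test of homogeneity of variances
#'
#' Median-centred absolute values are ranked across the pooled sample,
#' transformed by normal quantiles, and compared across groups by a
#' chi-square statistic on `groups - 1` degrees of freedom (wraps
#' [stats::fligner.test()]). A fully degenerate input (no dispersion
#' anywhere) returns statistic 0 with p = 1.
#'
#' @param groups named list of numeric vectors, each of length >= 2.
#' @return list with `statistic`, `df`, `p`.
#' @export
fligner_killeen <- function(groups) {
  d <- as_grouped(groups)
  if (any(tapply(d$value, d$group, length) < 2)) {
    stop("each group needs at least 2 observations")
  }
  centred <- abs(d$value - stats::ave(d$value, d$group, FUN = stats::median))
  if (all(centred == 0)) {
    return(list(statistic = 0, df = nlevels(d$group) - 1, p = 1))
  }
  ft <- stats::fligner.test(d$value, d$group)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p = ft$p.value)
}

#' Mann-Whitney U test
#'
#' U is computed from midrank sums (`U = R1 - n1(n1+1)/2`, the number of
#' pairs where `a` exceeds `b`, counting ties as half). The two-sided p
#' uses the exact null distribution when there are no ties and
#' `n1 * n2 <= 400`, otherwise the normal approximation with tie
#' correction.
#'
#' @param a,b numeric samples, both non-empty.
#' @return list with `U`, `p` and the `method` used.
#' @export
mann_whitney_u <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie_sizes <- table(c(a, b))
  has_ties <- any(tie_sizes > 1)
  if (!has_ties && n1 * n2 <= 400) {
    p_le <- stats::pwilcox(U, n1, n2)
    p_ge <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_sizes^3 - tie_sizes) / (N * (N - 1)))
    if (sig2 == 0) {
      p <- 1
    } else {
      p <- 2 * stats::pnorm(-abs(U - mu) / sqrt(sig2))
    }
    method <- "normal_approximation"
  }
  list(U = unname(U), p = min(1, p), method = method)
}

#' CYP3A5 pharmacogenetic report for a cohort
#'
#' Combines genotype tallies, allele frequencies (percentages rounded half
#' away from zero to one decimal), the Hardy-Weinberg goodness of fit, and
#' expressor vs non-expressor comparisons of TAC-D and dose-normalized AUC
#' by one-way ANOVA (with a Fligner-Killeen homogeneity check) and the
#' Mann-Whitney U test.
#'
#' @param metadata cohort metadata data.frame (`patient_id`, `genotype`,
#'   `tac_d_mg_per_kg`).
#' @param exposure exposure summary data.frame from [summarize_exposure()].
#' @return list of class `pgx_report`: `counts`, `percent` (one-decimal
#'   genotype percentages), `allele`, `hwe`, `group_means`, `tests`.
#' @export
pgx_report <- function(metadata, exposure) {
  counts <- genotype_counts(metadata$genotype)
  fr <- allele_frequencies(counts)
  hwe <- hwe_chi_square(counts)
  pct <- round_half_up(100 * counts / sum(counts), 1)
  d <- merge(metadata[, c("patient_id", "genotype", "tac_d_mg_per_kg")],
             exposure[, c("patient_id", "auc_per_dose")], by = "patient_id")
  d$phenotype <- classify_expressor(d$genotype)
  d <- d[d$phenotype != "unknown", ]
  split_by <- function(var) split(d[[var]], d$phenotype)
  tacd <- split_by("tac_d_mg_per_kg")
  aucd <- split_by("auc_per_dose")
  tests <- list(
    tac_d = list(anova = one_way_anova(tacd),
                 fligner = fligner_killeen(tacd),
                 mann_whitney = mann_whitney_u(tacd$expressor,
                                               tacd$non_expressor)),
    auc_per_dose = list(anova = one_way_anova(aucd),
                        fligner = fligner_killeen(aucd),
                        mann_whitney = mann_whitney_u(aucd$expressor,
                                                      aucd$non_expressor)))
  structure(
    list(counts = counts, percent = pct,
         allele = list(freq1 = fr$freq1, freq3 = fr$freq3, n = fr$n,
                       freq3_pct = round_half_up(100 * fr$freq3, 1)),
         hwe = hwe,
         group_means = list(
           tac_d = vapply(tacd, mean, numeric(1)),
           auc_per_dose = vapply(aucd, mean, numeric(1))),
         tests = tests),
    class = "pgx_report")
}

#' @export
print.pgx_report <- function(x, ...) {
  cat("CYP3A5 pharmacogenetic report\n")
  cat(sprintf("  genotypes *1/*1 %d (%.1f%%), *1/*3 %d (%.1f%%), *3/*3 %d (%.1f%%)\n",
              x$counts[1], x$percent[1], x$counts[2], x$percent[2],
              x$counts[3], x$percent[3]))
  cat(sprintf("  *3 allele frequency %.1f%%; HWE chi2 = %.2f, p = %.2f\n",
              x$allele$freq3_pct, x$hwe$chi2, x$hwe$p))
  cat(sprintf("  TAC-D mean: expressor %.3f vs non-expressor %.3f mg/kg (MW p = %.3g)\n",
              x$group_means$tac_d["expressor"],
              x$group_means$tac_d["non_expressor"],
              x$tests$tac_d$mann_whitney$p))
  invisible(x)
}

# Flatten a pgx_report into a tidy (metric, value) table for CSV output.
pgx_report_table <- function(report) {
  rbind(
    data.frame(metric = c("n_11", "n_13", "n_33",
                          "pct_11", "pct_13", "pct_33",
                          "freq_star3_pct", "hwe_chi2", "hwe_p",
                          "tac_d_mean_expressor", "tac_d_mean_non_expressor",
                          "auc_per_dose_mean_expressor",
                          "auc_per_dose_mean_non_expressor",
                          "tac_d_anova_F", "tac_d_anova_p",
                          "tac_d_fligner_stat", "tac_d_fligner_p",
                          "tac_d_mann_whitney_U", "tac_d_mann_whitney_p",
                          "auc_per_dose_anova_F", "auc_per_dose_anova_p",
                          "auc_per_dose_fligner_stat", "auc_per_dose_fligner_p",
                          "auc_per_dose_mann_whitney_U",
                          "auc_per_dose_mann_whitney_p"),
               value = c(report$counts, report$percent,
                         report$allele$freq3_pct,
                         report$hwe$chi2, report$hwe$p,
                         report$group_means$tac_d["expressor"],
                         report$group_means$tac_d["non_expressor"],
                         report$group_means$auc_per_dose["expressor"],
                         report$group_means$auc_per_dose["non_expressor"],
                         report$tests$tac_d$anova$F,
                         report$tests$tac_d$anova$p,
                         report$tests$tac_d$fligner$statistic,
                         report$tests$tac_d$fligner$p,
                         report$tests$tac_d$mann_whitney$U,
                         report$tests$tac_d$mann_whitney$p,
                         report$tests$auc_per_dose$anova$F,
                         report$tests$auc_per_dose$anova$p,
                         report$tests$auc_per_dose$fligner$statistic,
                         report$tests$auc_per_dose$fligner$p,
                         report$tests$auc_per_dose$mann_whitney$U,
                         report$tests$auc_per_dose$mann_whitney$p)))
}
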