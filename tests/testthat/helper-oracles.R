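# Independent oracle implementations and small fixture builders. These are
# deliberately written from first principles (sums, normal equations,
# enumeration) so they share no code path with the package functions they
# check.

oracle_trapezoid <- function(time, conc) {
  s <- 0
  for (i in seq_len(length(time) - 1)) {
    s <- s + 0.5 * (conc[i] + conc[i + 1]) * (time[i + 1] - time[i])
  }
  s
}

oracle_ols <- function(design, response) {
  X <- cbind(1, as.matrix(design))
  solve(t(X) %*% X, t(X) %*% response)[, 1]
}

oracle_anova_F <- function(groups) {
  all_vals <- unlist(groups)
  grand <- mean(all_vals)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1
  df2 <- length(all_vals) - length(groups)
  (ssb / df1) / (ssw / df2)
}

# Textbook Fligner-Killeen: normal scores of ranks of |x - group median|.
oracle_fligner <- function(groups) {
  centred <- lapply(groups, function(g) abs(g - median(g)))
  x <- unlist(centred)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  a <- qnorm((1 + rank(x) / (N + 1)) / 2)
  abar <- mean(a)
  v <- sum((a - abar)^2) / (N - 1)
  ni <- tabulate(g)
  Ai <- tapply(a, g, mean)
  sum(ni * (Ai - abar)^2) / v
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
oracle_mw_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  sets <- combn(n1 + n2, n1)
  us <- apply(sets, 2, function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# One-compartment oral steady-state curve (independent closed form).
oracle_one_compartment_ss <- function(cl, v, ka, dose, t, tau) {
  k <- cl / v
  1000 * dose * ka / (v * (ka - k)) *
    (exp(-k * t) / (1 - exp(-k * tau)) - exp(-ka * t) / (1 - exp(-ka * tau)))
}

# Fully deterministic: no between-subject, occasion or assay variability.
quiet_config <- function(...) {
  args <- utils::modifyList(
    list(iiv_cv = c(cl_f = 0, q_f = 0, vc_f = 0, vp_f = 0,
                    ka = 0, weight = 0),
         occasion_cv = 0, assay_cv = 0, assay_sd = 0),
    list(...))
  do.call(simulation_config, args)
}

# Measurement-noise-free but biologically variable cohort.
noisefree_config <- function(...) {
  args <- utils::modifyList(list(assay_cv = 0, assay_sd = 0), list(...))
  do.call(simulation_config, args)
}

six_point_profile <- function(conc) {
  list(time = c(0, 1, 2, 4, 12, 24), conc = conc)
}
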