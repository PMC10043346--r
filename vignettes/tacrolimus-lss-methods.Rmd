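---
title: "Methods: limited-sampling strategies for tacrolimus AUC0-24"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: limited-sampling strategies for tacrolimus AUC0-24}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taclss)
```

This vignette documents the statistical and pharmacokinetic machinery in
`taclss`: the models, their assumptions, the tunable parameters and their
defaults, the numerical conventions, and the choices made where the
design was genuinely open. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The estimation target

The exposure measure is the area under the whole-blood tacrolimus
concentration–time curve over one 24-hour dosing interval, AUC0–24
(ng·h/mL), computed by the linear trapezoidal rule over the six nominal
sampling times 0, 1, 2, 4, 12 and 24 h. The linear trapezoid is used as
the reference integration: down-slope log-trapezoid variants change the
result by far less than assay noise at this sampling density, and the
trapezoid has the useful property of being an exact linear functional of
the sampled concentrations (weights 0.5, 1, 1.5, 5, 10 and 6 h here),
which is what makes linear limited-sampling equations work so well.

A limited-sampling strategy (LSS) is an ordinary least-squares equation
`AUC = b0 + sum(b_j * C_j)` over a subset of the early time-points
{C0, C1, C2, C4}. C12 and C24 are excluded from the default candidate
set — the point of an LSS is to finish sampling within the morning
outpatient visit — but the candidate set is an argument everywhere.

## Model selection

All `2^k - 1` non-empty subsets of the candidates are fitted
(`enumerate_predictor_subsets()`, `fit_ols()`). Subsets are numbered by
size and then lexicographically, which makes "model 12" always the
C0+C1+C4 equation for the canonical four candidates. Retention uses the
strict rule `adj_r2 > 0.799`; the boundary case is excluded because the
criterion is expressed as "higher than". Retained models are compared by
Akaike and BIC weights on the Gaussian profile-likelihood criteria

```
aic = n log(rss/n) + 2k,   bic = n log(rss/n) + k log(n),   k = p + 2,
```

where `k` counts the intercept and the residual variance. Only
criterion *differences* matter for the weights, so additive constants of
the Gaussian likelihood are dropped; `k = p + 2` matches the convention
of the common model-comparison packages. A perfect fit (`rss = 0`)
yields `-Inf` and absorbs all weight, with a flag.

In-sample precision is summarised by the absolute prediction error,
`APE(%) = 100 |predicted - observed| / observed`. MAPE is reported as the
*median* APE, with the mean ± SD alongside, because both conventions are
common and they answer different questions (typical patient vs. moment
summary); `mape_summary()` labels each explicitly. The
clinical-acceptability fraction counts APEs *strictly above* 15%.

`crossvalidate_lss()` adds honest out-of-sample error estimation (the
historical validation practice for these equations is in-sample):
deterministic seeded k-fold assignment, stratified by CYP3A5 expressor
status so that small cohorts keep genotype balance across folds.

## Validation statistics

Bland–Altman agreement uses differences `predicted - observed`, the
sample (n−1) standard deviation, and 1.96·SD limits of agreement (the
95% convention). For an equation fitted in-sample by least squares the
mean difference is zero up to rounding, because OLS residuals sum to
zero — the test suite asserts this identity.

Subgroup consistency (brand, genotype, age group) is an ANCOVA-style
F-test: `observed ~ predicted + group` against `observed ~ predicted`,
with `group - 1` numerator degrees of freedom. The test suite calibrates
its type-I error by simulation (2,000 null replicates at n = 60) and its
power against a 50 ng·h/mL group offset at n = 200.

## CYP3A5 analyses

Genotypes at rs776746 are classified as expressors (*1/*1, *1/*3) and
non-expressors (*3/*3); missing genotypes are excluded from counts, so
frequencies refer to genotyped patients only. The *3 allele frequency is
`(n13 + 2 n33) / 2n`. The Hardy–Weinberg goodness of fit compares
observed genotype counts with `n(p², 2pq, q²)` on **1 degree of
freedom** (three classes, minus one, minus one allele frequency
estimated from the same data) — the standard choice for a biallelic
locus. Reported percentages are rounded half away from zero to one
decimal, the usual clinical-report style (base `round()` is
banker's rounding).

Group differences in TAC-D (daily dose / body weight, mg/kg) and in
dose-normalized AUC are tested by one-way ANOVA *and* the Mann–Whitney U
test, with a Fligner–Killeen homogeneity check; both tests are reported
because both are in routine use for such comparisons and they need not
agree on small samples. ANOVA degrees of freedom are reported as
computed from the design (k−1, n−k). The Mann–Whitney U is computed from
midrank sums; the p-value uses the exact null distribution when there
are no ties and `n1·n2 ≤ 400`, otherwise the normal approximation with
the usual tie correction.

## The synthetic cohort generator

No patient-level data ship with the package, so analyses run on
synthetic cohorts with the statistical structure the method assumes.

**Disposition model.** Two-compartment, first-order oral absorption, at
steady state under once-daily dosing. With apparent parameters CL/F,
Q/F, Vc/F, Vp/F and micro-constants `k10 = CL/Vc`, `k12 = Q/Vc`,
`k21 = Q/Vp`, the hybrid constants α, β solve `α+β = k10+k12+k21`,
`αβ = k10·k21` (β computed as `αβ/α` for stability when the compartments
decouple), and the steady-state curve is the superposition

```
C(t) = (1000 D ka / Vc) * sum_i  A_i exp(-λ_i t) / (1 - exp(-λ_i τ)),
λ = (α, β, ka),
```

with the standard two-compartment oral coefficients. Two identities
follow analytically and are asserted by the tests: periodicity
`C(0) = C(τ)`, and the dose–clearance mass balance
`∫₀^τ C dt = 1000·D/CL` (ng·h/mL). If a sampled `ka` collides with α or
β the constructor perturbs it by a relative 10⁻⁶ and records the fact.

**Population defaults.** Median CL/F 22 L/h, Q/F 100 L/h, Vc/F 250 L,
Vp/F 500 L, ka 1.2 h⁻¹, weight 40 kg. These were calibrated once so that
the noise-free median curve reproduces the magnitudes a maintenance-phase
pediatric extended-release cohort shows — trough ≈ 6 ng/mL at ≈ 4.8
mg/day (TAC-D ≈ 0.12 mg/kg), AUC0–24 ≈ 220 ng·h/mL, Cmax ≈ 16.5 ng/mL,
Tmax 1–2 h, peak-to-trough ratio ≈ 2.7 — rather than an immediate-release
shape (a narrower central volume gives Cmax/C0 near 6, which is not what
extended-release profiles look like). Between-subject variability is
log-normal per parameter with CV 0.30 (`median·exp(N(0, σ))`,
`σ = sqrt(log(1+CV²))`, so the configured value is the population
median). CYP3A5 expressors have CL/F multiplied by 1.6.

**Genetics.** Genotypes are drawn at Hardy–Weinberg proportions with *3
allele frequency 0.8125, the admixed-population value the cohort design
targets.

**Dose titration.** Therapeutic drug monitoring is mimicked on a 0.5 mg
dose grid in 0.5–30 mg/day: starting from a weight-based 0.1 mg/kg dose,
the titration picks the grid dose with the smallest adjustment whose
noise-free trough lands in the maintenance window 5–7 ng/mL (ties to the
lower dose); if the window is unreachable the dose closest to the window
midpoint is returned and flagged. Note that equal-trough dosing does
*not* scale doses exactly by the clearance multiplier: raising CL/F
steepens the terminal phase, so the trough falls more than
proportionally and the expressor:non-expressor dose ratio lands near the
top of the clinically described 1.5–2.0× range. The tests assert the
exact linearity identity (dose ratio = inverse ratio of
trough-per-unit-dose) instead of a fixed 1.6.

**Between-occasion drift (`occasion_cv`, default 0.25).** The dose is
titrated against the trough of an earlier monitoring visit; by the
profiling day the patient's clearance has drifted by a log-normal factor
with CV 0.25. Without this term the simulated troughs would sit almost
exactly inside the 5–7 ng/mL window and C0 would carry no information
about AUC — real maintenance cohorts show troughs dispersed around the
target (SD ≈ 2 ng/mL, most patients out of the strict window) and a
*partial* C0–AUC correlation, which is precisely the clinical argument
for an LSS. The default was set from that observed trough dispersion
(total CV ≈ 0.3 at the window midpoint, of which assay error explains
≈ 0.10) and then frozen. Ground-truth AUC refers to the profiling day.

**Assay model.** `measured = conc·(1+εp) + εa` with proportional CV 0.10
and additive SD 0.3 ng/mL — a typical immunoassay error envelope.
Values below the 0.5 ng/mL quantification limit are imputed as LLOQ/2
and flagged, keeping profiles complete for the trapezoid while marking
the censoring.

**Reproducibility.** All randomness flows from one integer seed;
patient `i` uses a counter-derived substream, so a patient's data do not
change when the cohort grows. Two runs with the same seed are
byte-identical, including the written CSVs.

**What the generator does not emulate.** Nominal sampling times only (no
actual-time jitter); no intra-occasion variability, no adherence
modelling, no brand effects on kinetics (brand is a grouping label
only), no nonlinear-mixed-effects estimation (the module is generative
only). Passing tests therefore show that the pipeline recovers what this
generator encodes — genotype-dependent clearance, titration, occasion
drift, assay noise — not that it would reproduce any particular real
cohort's coefficients, which depend on patient-level data.

## Numerical conventions and degenerate inputs

- Tmax ties resolve to the earliest time attaining the maximum.
- Therapeutic-range boundaries are inclusive ("within"), the
  conservative monitoring reading.
- CSV outputs store doubles at 17 significant digits so a write/read
  round trip is exact; display rounding happens only in the rendered
  report. Every written CSV carries a `# taclss seed=<seed>` header
  comment recording provenance; the package readers skip comment lines.
- One-way ANOVA screens degenerate inputs with exact group sums of
  squares before delegating to `lm`: identical groups give F = 0, zero
  within-group variance with distinct means gives F = +Inf with a flag.
- Fligner–Killeen on fully dispersion-free input returns statistic 0,
  p = 1.
- `retain_models()` with an empty retained set warns and weights all
  models, flagged, rather than failing.
- Patients whose profile misses any of the six nominal labels are
  excluded from AUC analyses with a logged reason; duplicate
  (patient, time-point) rows are a hard error naming the row.

## Problem sizes in the test suite

The suite exercises the pipeline at the cohort sizes the analysis is
designed for: n = 51 for cohort-level checks, n = 200 for coefficient
recovery against a constructed linear ground truth, n = 500 (noise-free)
for the structural-fidelity check of the three-point equations, 100
seeds for the adjusted-r² ordering frequency, and 2,000 null replicates
for the subgroup-test calibration. On the noise-free n = 500 cohort the
three- and four-point models (C0+C1+C4, C0+C2+C4, C0+C1+C2+C4) describe
the trapezoidal AUC to a median APE below 2%; weaker two-point subsets
can clear the 0.799 retention threshold on noise-free data while
remaining structurally biased, which is why that fidelity check is tied
to the clinically retained combinations rather than to everything the
threshold admits.

## Known limitations

- The simulator's parameter values are calibrated to summary magnitudes,
  not estimated from patient-level data; absolute regression
  coefficients from simulated cohorts are not comparable to published
  ones, only their qualitative structure (orderings, recovery, error
  envelopes) is.
- The LSS form is strictly linear; Bayesian MAP or population-PK
  estimators of AUC are out of scope.
- Clinical outcomes (rejection, toxicity) are not modelled; the package
  stops at exposure statistics and flags.

```{r session, echo = FALSE}
sessionInfo()
```
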