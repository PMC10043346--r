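Package: taclss
Title: Limited Sampling Strategies for Tacrolimus AUC0-24 in Pediatric
    Kidney Transplantation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Development and validation of limited sampling strategies (LSS)
    to estimate the 24-hour tacrolimus area under the concentration-time
    curve (AUC0-24) in pediatric kidney transplant recipients on
    extended-release tacrolimus. Provides a two-compartment steady-state
    cohort simulator with CYP3A5 genotype-dependent clearance and
    trough-targeted dose titration; trapezoidal AUC0-24, Cmax/Tmax,
    dose-normalized exposure and apparent clearance; CYP3A5 allele
    frequencies, Hardy-Weinberg goodness of fit and expressor group
    comparisons; exhaustive subset regression of AUC0-24 on early
    time-point concentrations with adjusted r-squared retention and
    AIC/BIC weights; and clinical validation via absolute prediction
    error, Bland-Altman agreement, subgroup-consistency tests and
    cross-validation, including published pediatric three-point equations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
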