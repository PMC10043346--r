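# taclss

Limited-sampling strategies (LSS) for estimating the 24-hour tacrolimus
exposure, AUC0–24, in pediatric kidney transplant recipients on
extended-release tacrolimus — together with the CYP3A5 pharmacogenetic
analyses that explain dose requirements.

## The problem

Tacrolimus has a narrow therapeutic window and is routinely monitored by
trough levels (C0), but C0 correlates poorly with the true exposure, the
area under the concentration–time curve over one dosing interval
(AUC0–24). Measuring the full curve needs six blood draws over 24 h
(C0, C1, C2, C4, C12, C24), which is impractical in children. A
limited-sampling strategy replaces it with a linear equation on a few
early time-points,

    AUC0-24 ≈ b0 + b1·C0 + b2·C1 + b3·C4 ,

fitted by exhaustive subset regression of the trapezoidal AUC0–24 on
{C0, C1, C2, C4}. Candidate models are retained when their adjusted r²
exceeds 0.799, compared by Akaike/BIC weights
(w_i = exp(−Δ_i/2)/Σ exp(−Δ_j/2)), and validated clinically by the
absolute prediction error APE(%) = 100·|AUC_LSS − AUC_trap|/AUC_trap
(acceptable below 15%) and Bland–Altman limits of agreement
(mean difference ± 1.96 SD).

Dose requirements depend strongly on the CYP3A5 genotype (SNP rs776746):
expressors (*1/*1, *1/*3) clear the drug faster and need ~1.5–2× higher
weight-normalized daily doses (TAC-D, mg/kg) than non-expressors (*3/*3).
The package computes allele frequencies, the Hardy–Weinberg chi-square
goodness of fit, and expressor/non-expressor comparisons (ANOVA,
Fligner–Killeen, Mann–Whitney U).

Because patient-level data are not bundled, the package ships a
first-class synthetic cohort generator: a two-compartment oral
steady-state model with log-normal between-subject variability,
genotype-dependent clearance, trough-targeted dose titration with
between-occasion clearance drift, and immunoassay noise with an LLOQ
rule. It provides analytic ground-truth AUC (AUC_ss = 1000·dose/CL·F⁻¹)
for recovery tests.

## Worked example

```r
library(taclss)

cfg <- pipeline_config(simulation = simulation_config(n_patients = 51),
                       seed = 7, out_dir = tempfile())
manifest <- run_pipeline(cfg)
res <- attr(manifest, "results")

print(res$pgx)
#> CYP3A5 pharmacogenetic report
#>   genotypes *1/*1 3 (5.9%), *1/*3 16 (31.4%), *3/*3 32 (62.7%)
#>   *3 allele frequency 78.4%; HWE chi2 = 0.27, p = 0.60
#>   TAC-D mean: expressor 0.244 vs non-expressor 0.158 mg/kg (MW p = 0.0194)

print(res$lss$models[["12"]])
#> AUC = 0.44 + C0*14.64 + C1*1.86 + C4*8.72
#>   n = 51, r2 = 0.9757, adj r2 = 0.9741, MAPE = 3.5%
```

The genotype tallies sit at Hardy–Weinberg proportions for a *3 allele
frequency near 0.8; expressors need ~1.6× more drug per kilogram for the
same trough window. Model "12" is the three-point equation on C0, C1 and
C4: on this simulated cohort it explains ~97% of AUC variance and its
in-sample median absolute prediction error is 3.5%, with no patient
deviating by more than 15% (`res$validation$table`). The two published
pediatric three-point equations evaluated on the same cohort give MAPEs
of 6.5% and 6.8%. `render_report(manifest)` emits a markdown report with
the cohort summary, the 15-model table, retained equations and the
validation section; all tables are also written as CSV next to
`manifest.json` in `cfg$out_dir`.

A thin command-line front end is installed with the package
(`system.file("cli", "taclss", package = "taclss")`) with subcommands
`simulate`, `exposure`, `pgx`, `fit` and `run`.

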