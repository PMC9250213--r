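# csfclear

Population pharmacokinetics of cerebrospinal-fluid-to-blood tracer
clearance.

## What this package is for

After a lumbar intrathecal injection, a hydrophilic MRI contrast agent
(gadobutrol) cannot cross the blood–brain barrier, so its appearance in
venous blood measures clearance from the cerebrospinal fluid (CSF) along
extra-vascular routes. `csfclear` turns sparse venous sampling (a handful
of samples over ~48 h) into individual clearance estimates, for
pharmacologists and clinical researchers studying CSF disorders
(hydrocephalus, intracranial hyper-/hypotension, cysts) or planning
intrathecal drug dosing.

The model is a linear depot–central–peripheral system with absorption lag:

    dAd/dt = -Ka Ad
    dAc/dt =  Ka Ad - (Ke + Kcp) Ac + Kpc Ap,   C(t) = Ac/V,  C(t <= Tlag) = 0
    dAp/dt =  Kcp Ac - Kpc Ap

solved in closed form. The population distribution of (Ka, Tlag, V, ...) is
estimated **nonparametrically** as weighted support points by an
adaptive-grid maximum-likelihood search (`npml_fit()`), with the shared
elimination rate profiled out (`profile_ke_fit()`) because single-route
sparse data cannot separate absorption from elimination per subject
(flip-flop). Bayesian posterior individual estimates
(`posterior_individual()`) feed the derived metrics: absorption half-life
T1/2,abs = ln2/Ka (the clearance surrogate), Tlag, Tmax, Cmax,
AUC(0-inf) by trapezoid with log-linear tail, and dose-normalised forms
(`derive_all()`). A calibrated synthetic cohort generator
(`default_study_config()`, `simulate_cohort()`) reproduces the published
study design — 161 subjects, 8 diagnosis groups, 0.10/0.25/0.50 mmol dose
arms, 8 ± 2 samples per subject, 1.35 nM quantification limit — and the
statistics layer (`compare_groups()`, `dose_linearity_test()`,
`covariate_correlations()`, `run_pipeline()`) mirrors the study's group
comparisons. See the methods vignette
(`vignettes/csf-clearance-methods.Rmd`) for the model, estimator and every
calibration decision.

## Worked example

Simulate a small reference cohort, fit the population model and derive
per-subject clearance metrics:

```r
library(csfclear)
config <- default_study_config(seed = 42)
g <- config$groups$REF
g$n_subjects <- 8L
g$dose_allocation <- c("0.1" = 0L, "0.25" = 0L, "0.5" = 8L)
cohort <- simulate_cohort(cohort_config(groups = list(REF = g), seed = 42))

fit <- profile_ke_fit(cohort$subjects, config$noise, "two_compartment",
                      ke_grid = c(0.08, 0.16, 0.32), refine_steps = 1,
                      profile_n_initial = 120, profile_max_cycles = 30,
                      final_n_initial = 200, final_max_cycles = 60, seed = 42)
posteriors <- lapply(cohort$subjects, posterior_individual, model = fit$model)
metrics <- derive_metrics_table(cohort$subjects, posteriors)
round(metrics[, c("t_half_abs_h", "t_max_h", "c_max_dn_uM", "t_lag_h", "auc_dn_uMh")], 2)
#>   t_half_abs_h t_max_h c_max_dn_uM t_lag_h auc_dn_uMh
#> 1         9.78    7.95        0.39    0.30      13.91
#> 2         5.05    5.90        0.57    0.36      13.30
#> 3         0.51    2.23        1.21    0.71      11.20
#> 4         7.01    7.52        0.56    1.01      15.93
#> 5         1.18    3.22        0.92    0.68      10.90
#> 6         3.13    5.23        0.61    0.90      11.08
#> 7         1.47    3.78        1.04    0.91      13.41
#> 8         2.24    4.27        0.61    0.63      9.45
```

Each row is one subject: `t_half_abs_h` is the absorption half-life (hours
for half the tracer to clear CSF to blood — the clearance readout; shorter
means faster clearance), `t_max_h`/`c_max_dn_uM` locate the blood peak,
`t_lag_h` is the delay before absorption starts, and `auc_dn_uMh` is the
systemic exposure, with Cmax and AUC normalised to the 0.50 mmol reference
dose. Here the profiled shared elimination rate came out at 0.160 /h and
the cohort-mean half-life was estimated at 3.80 h against a realised
simulation truth of 3.66 h.

The full-cohort analysis (simulation, blood/plasma cross-calibration,
structure selection, group statistics) is scripted in order under
`analysis/`; each script prints what it found and writes its tables under
`results/`.

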