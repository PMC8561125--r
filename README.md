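# cvhseg

Segmented linear mixed models for longitudinal clinical cardiovascular
health (CVH) scores: find the ages at which population-level CVH decline
accelerates.

## Who this is for

Epidemiologists and biostatisticians analyzing repeated clinical
examinations across childhood-to-midlife cohorts. The package covers the
whole workflow: AHA-criteria clinical CVH scoring, change-point estimation
in a longitudinal framework, model selection, sex-interaction contrasts,
descriptive tables — plus a calibrated synthetic multi-cohort generator so
every stage is testable without access to confidential cohort data.

## The model

Each examination is scored 0–8: BMI, blood pressure, total cholesterol and
fasting glucose each contribute 0 (poor), 1 (intermediate) or 2 (ideal)
points under the AHA clinical criteria (pediatric BMI/BP use percentiles).
The score trajectory is modeled as a segmented linear mixed model,

y_ij = β₀ + β₁(a_ij − 8) + Σ_k δ_k (a_ij − ψ_k)₊ + x_ijᵀη
       + b_0j + b_1j (a_ij − 8) + ε_ij,

with change points ψ_k estimated by maximum likelihood through iterative
U/V linearization: working covariates U = (a − ψ̃)₊ and V = −1{a > ψ̃} are
added at the current guess and ψ is updated by γ̂/δ̂ (gap over
slope-increment coefficient) with step-halving and an admissibility
projection, until the update is below tolerance. Confidence intervals for ψ
come from the ratio delta method; segment slopes telescope as
s_k = β₁ + Σ_{j<k} δ_j. A brute-force profile-likelihood grid search
(`profile_grid_oracle`) independently verifies the iterative estimator.

## Worked example

```r
library(cvhseg)

cfg <- cvh_preset("paper2021", seed = 11)      # calibrated 5-cohort preset
scored <- score_dataset(generate_cvh_scores(cfg))
scored
#> Clinical CVH scored dataset
#>   examinations: 16159 of 16159 complete (all 4 factors)
#>   subjects:     2000 of 2000 retained (>= 1 complete exam)

fit <- fit_segmented(scored$data, n_changepoints = 2,
                     covariates = c("race", "sex", "cohort"))
fit
#> Segmented linear mixed model: 2 change point(s), converged
#> Change points (years):
#>   estimate    se  lower  upper
#> 1   17.005 0.357 16.306 17.704
#> 2   37.179 2.555 32.170 42.187
#> Segment slopes (points/year):
#>   segment   from     to  slope    se  lower  upper
#> 1       1  8.005 17.005  0.017 0.004  0.009  0.026
#> 2       2 17.005 37.179 -0.069 0.001 -0.071 -0.067
#> 3       3 37.179 55.969 -0.078 0.002 -0.082 -0.075
#> logLik -20422.201 | AIC 40876.4 | BIC 40999.4 | iterations 16
```

The preset's ground truth places change points at 16.9 and 37.2 years with
segment slopes 0.01 / −0.07 / −0.08 points/year; the fit recovers them
within sampling error — CVH holds roughly steady through adolescence, then
declines about 0.07 points/year to age ~37 and slightly faster afterwards.
The wide interval on the second change point reflects its small slope
change (−0.01 points/year).

Downstream steps:

```r
compare_models(scored$data, covariates = c("race", "sex", "cohort"))
# AIC/BIC across linear/quadratic/cubic/segmented-1/segmented-2 (ML),
# LRTs for nested pairs (Davies-flagged where psi is unidentified)

fit_piecewise_interaction(scored$data, knots = c(17, 37), group = "sex")
# per-sex segment slopes, male - female differences, total change per segment

baseline_table(scored$data)   # first-exam descriptives by sex
```

`run_pipeline(run_config(preset = "paper2021", out_dir = "run1"))` chains
everything into a run directory (scored CSV, JSON fits, comparison and
descriptive tables, manifest); a thin CLI lives at `inst/cli/cvhseg.R`.

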