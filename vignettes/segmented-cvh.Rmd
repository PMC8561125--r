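---
title: "Detecting influential age windows in cardiovascular health trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting influential age windows in cardiovascular health trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvhseg)
```

## The problem

Clinical cardiovascular health (CVH) can be summarized at any examination by
a 0–8 score: body mass index, blood pressure, total cholesterol and fasting
glucose are each graded poor (0), intermediate (1) or ideal (2) against the
American Heart Association clinical criteria and the points are summed.
Population mean CVH declines with age, but not at a constant rate. The
scientific question this package addresses is *where* the decline
accelerates: the ages ψ at which the population-mean slope of the score
changes. Locating those change points in longitudinal, multi-cohort data —
subjects observed repeatedly over partially overlapping age windows —
requires a segmented (broken-line) **linear mixed model**:

\[
y_{ij} = \beta_0 + \beta_1 (a_{ij} - 8)
  + \sum_{k} \delta_k (a_{ij} - \psi_k)_+
  + \mathbf{x}_{ij}^\top \boldsymbol\eta
  + b_{0j} + b_{1j} (a_{ij} - 8) + \varepsilon_{ij},
\]

where \(a_{ij}\) is the age of subject \(j\) at visit \(i\),
\((u)_+ = \max(u, 0)\), \(\delta_k\) is the slope change at the k-th change
point \(\psi_k\), \(\mathbf{x}_{ij}\) holds categorical adjustment
covariates (sex, race, cohort), \((b_{0j}, b_{1j})\) is a bivariate normal
random intercept and slope, and \(\varepsilon_{ij}\) is Gaussian noise. The
slope of segment \(k\) telescopes: \(s_k = \beta_1 + \sum_{j<k}\delta_j\).
All models are fit by maximum likelihood (not REML) because model selection
compares mean structures.

## Change-point estimation

\(\psi\) enters the mean nonlinearly. Estimation uses iterative
linearization: a first-order expansion of \((a - \psi)_+\) around the
current guess \(\tilde\psi\) adds, per change point, the working covariates
\(U = (a - \tilde\psi)_+\) (coefficient \(\delta\)) and
\(V = -\mathbf{1}\{a > \tilde\psi\}\) (gap coefficient \(\gamma\)). After
each mixed-model fit the update is
\(\psi \leftarrow \tilde\psi + \hat\gamma/\hat\delta\); at a fixed point the
gap coefficient vanishes and the broken line is continuous. `fit_segmented()`
iterates `muggeo_step()` until the largest update falls below `tol_psi`.

Numerical safeguards, all tunable through `fit_segmented()` arguments:

* **Admissible region.** Proposals are projected into
  `[min(age) + min_gap, max(age) - min_gap]`, kept sorted, and two change
  points are kept at least `min_gap` apart (default 3 years). This prevents
  the two-break model from collapsing onto one break or drifting into a data
  edge where a segment would contain almost no observations.
* **Step halving.** The objective is the fixed-knot profile log-likelihood
  \(\ell(\psi)\) (the model *without* gap terms, refit at the proposal). A
  proposal that lowers \(\ell\) is halved toward the current value up to six
  times; if no improvement is possible the iteration stops. Accepted
  iterations therefore never decrease \(\ell\).
* **Initialization.** Broken-line profile likelihoods can be multimodal, so
  `psi_init = "auto"` is profile-seeded rather than a single quantile start:
  for one break the mixed-model profile itself is scanned on a coarse
  (2.5-year) grid, warm-starting each fit's variance components from its
  neighbor; for two breaks the pair lattice is ranked by a fast OLS profile
  (clustering ignored — it only ranks starting values) and a spread of the
  best candidates is re-scored under the mixed model. Iteration begins at
  the best candidate.
* **Local polish.** Near the optimum the profile is ragged at the scale of
  individual data ages, with near-tied micro-modes a fraction of a year
  apart; the linearized update only finds the mode of the basin it starts
  in. After convergence the fixed-knot likelihood is scanned on a small
  lattice around the estimate, the iteration is re-launched from promising
  near-tied candidates, and the best refined point by fixed-knot likelihood
  is reported (a basin-hopping polish).
* **Convergence.** `tol_psi = 1e-3` years and `max_iter = 50`; change points
  are reported to 0.1-year precision, so the tolerance is comfortably below
  reporting resolution.
* **Flat kinks.** If a slope-increment estimate is numerically zero the
  update \(\gamma/\delta\) is undefined; the step aborts with an
  instruction to re-initialize rather than returning an arbitrary ratio.

Reported parameters come from a final fixed-knot refit at \(\hat\psi\)
(no \(V\) terms). The standard error of \(\hat\psi_k\) uses the ratio delta
method on a final working fit at \(\hat\psi\):
\(\operatorname{Var}(\hat\gamma/\hat\delta) \approx
[\operatorname{Var}\hat\gamma - 2r\operatorname{Cov}(\hat\gamma,\hat\delta)
+ r^2 \operatorname{Var}\hat\delta]/\hat\delta^2\) with
\(r = \hat\gamma/\hat\delta \approx 0\) at convergence, so the interval is
essentially \(\hat\psi \pm 1.96\,\widehat{\mathrm{SE}}(\hat\gamma)/|\hat\delta|\).
A weak break (small \(|\delta|\)) therefore correctly yields a wide
interval.

As an independent check, `profile_grid_oracle()` maximizes the same profile
likelihood by brute force over a grid (an ordered-pair lattice for two
breaks). The test suite requires the iterative estimator and the oracle to
agree within one grid cell on seeded fixtures.

Mixed-model fitting itself is delegated to `lme4::lmer` (ML); the
change-point machinery, contrasts and intervals are implemented here.

## Scoring rules and their edge cases

`score_exams()` applies the clinical criteria literally: BMI uses kg/m² at
ages ≥ 20 and the BMI-for-age percentile below 20; blood pressure uses
mm Hg at ages ≥ 18 and the pediatric percentile below 18 (the two age
cutoffs intentionally differ). Interval endpoints follow the printed
criteria: BMI 25.0 and 29.99 are intermediate, 30.0 poor; cholesterol 185
and 219 intermediate, 220 poor; glucose 100 and 125 intermediate, 126 poor;
SBP 120 / DBP 80 open intermediate, SBP 140 / DBP 90 poor; pediatric
percentiles 85–95 (BMI) and 90–95 (BP) are intermediate-inclusive. Two
conventions deserve note. First, a pediatric BP below the 90th percentile is
demoted from ideal when the absolute pressure reaches 120/80 — the criteria
list the absolute clause only in the intermediate row, and we read it as
taking precedence over the percentile. Second, the pediatric BP rows carry
no medication clause, so antihypertensive treatment affects only the adult
category; missing medication flags are treated as unmedicated. Pediatric
percentiles are accepted as inputs (a pluggable `percentile_provider` hook
exists for external CDC/AAP reference implementations); the synthetic
generator emits them directly, so no external reference tables are bundled.

A visit contributes a score only when all four factors are categorizable;
`score_dataset()` drops incomplete examinations and subjects with no
complete examination, and reports the attrition.

## What the synthetic generator emulates

Real pooled-cohort data of this kind are confidential, so the package ships
a generator whose defaults encode the study conditions the analysis
assumes. The `"paper2021"` preset pools five cohorts with overlapping
baseline age windows (total ≈ 2,000 subjects; about half from a
child-to-midlife cohort, a quarter from a young-adult cohort followed to
age 55.99, the rest from three smaller pediatric cohorts), fixed per-cohort
visit schedules, and ground truth ψ = (16.9, 37.2) years with segment
slopes (0.01, −0.07, −0.08) points/year and small additive sex, race and
cohort effects. Baseline ages are uniform within each cohort window;
visits are evenly spaced and truncated at age 55.99.

The variance components are calibration choices, not published values:
`re_sd_intercept = 0.95`, `re_sd_slope = 0.02` (correlation −0.2) and
`resid_sd = 0.7` were chosen once so that the first-visit score
distribution has mean ≈ 6.9 and SD ≈ 1.2, the descriptive anchor for this
design. The random intercept (and the reported fixed intercept) refer to
age 8, the entry age — a pure reparameterization of the usual age-0
intercept that keeps the calibration interpretable.

The generator's latent score is continuous; the mixed model treats the 0–8
score as continuous, so parameter recovery is exact in expectation under
the default. `discretize = TRUE` clamps to [0, 8] and rounds, for realism
experiments. Raw-metric mode instead emits BMI, SBP/DBP, cholesterol and
glucose around sex-specific piecewise-linear mean trajectories anchored at
ages 8/17/37/55 (flat outside), with half the age-specific dispersion
assigned to a subject-level effect and half to visit noise, and pediatric
percentiles computed from the simulated within-age rank.

What the generator does **not** emulate: integer scores by default, cohort-
or period-specific measurement drift, informative missingness (missing
examinations are completely at random), medication use (flags are all
false), behavior metrics, or menopause-related changes. Passing tests
therefore demonstrate that the estimation machinery recovers a known truth
under the assumed model — not that the model is correct for any particular
real cohort.

## Model selection and the fixed-knot interaction analysis

`compare_models()` fits linear, quadratic, cubic and segmented (1 and 2
breaks) mean structures by ML on identical data and tabulates AIC/BIC
(each estimated change point counts as one parameter). Likelihood-ratio
tests are printed for the polynomial nestings; tests against segmented
alternatives are flagged approximate because ψ is unidentified under the
null (the Davies problem), so AIC/BIC carry the default verdict.

After change points are estimated, sex differences in slopes are assessed
with `fit_piecewise_interaction()`: knots fixed at the rounded estimates
(default 17 and 37 years), the full spline basis interacted with sex,
adjustment covariates as main effects, random intercept and slope retained.
Contrasts give per-sex segment slopes, male-minus-female differences with
Wald tests, and the cumulative change over a segment (`total_delta()` =
slope × width, widths taken from the rounded window bounds 8–17–37–55.9;
products are computed on unrounded slopes and rounded last, which is why a
printed difference can disagree in the last digit with the product of
printed roundings). `interaction_screen()` provides the age × race × sex
Wald screen used to justify sex stratification, and
`mean_difference_test()` the Welch comparisons of raw metric means at the
influential ages. `baseline_table()` summarizes first complete
examinations by sex.

## A worked run

```{r example, eval = FALSE}
cfg <- cvh_preset("paper2021", seed = 1)
scored <- score_dataset(generate_cvh_scores(cfg))
fit <- fit_segmented(scored$data, n_changepoints = 2,
                     covariates = c("race", "sex", "cohort"))
fit
compare_models(scored$data, covariates = c("race", "sex", "cohort"))
fit_piecewise_interaction(scored$data, knots = round(fit$psi$estimate))
```

`run_pipeline()` chains the stages (simulate-or-load → score → segmented
fit → model comparison → interaction model → descriptives) into a run
directory with JSON/CSV outputs and a manifest; reruns with the same
config are byte-identical.

## Problem sizes and verification

The test suite exercises the estimator at sizes chosen to balance
Monte-Carlo precision against desk-scale runtimes: exact recovery on
noiseless fixtures; likelihood agreement (±1e−4) with an independent,
from-scratch marginal-likelihood maximizer at n = 300 subjects; oracle
agreement within one 0.5-year grid cell at n = 150; coverage of the
delta-method 95% interval over 200 one-break simulations at n = 300
(accepted band 90–98%, reflecting asymptotic approximation error); bias
below 0.2 years at n = 1,000 across 12 replicates; and full parameter
recovery on 20 replicates of the ≈ 2,000-subject pooled preset. Slope
contrast standard errors are cross-checked against a 200-resample subject
bootstrap (25% agreement band).

## Known limitations

* At most two change points; no subject-specific (random) change points and
  no smooth-transition alternative.
* The delta-method interval relies on asymptotic normality of
  \(\hat\gamma/\hat\delta\); with a very weak break and modest data beyond
  it the interval can be wide and its coverage approximate — visible in the
  second change point, whose slope change is only −0.01 points/year.
* The profile likelihood can be multimodal on null (no-break) data; the
  iterative estimator then converges to a local mode and the AIC/BIC
  comparison, not the LRT, should arbitrate.
* Scoring follows the clinical criteria exactly as printed; other CVH
  scoring variants (behavior metrics, 14-point scores) are out of scope.
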