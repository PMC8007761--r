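---
title: "Comparing lipid parameters for MACE prediction: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing lipid parameters for MACE prediction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidmace)
```

## The scientific question

After percutaneous coronary intervention (PCI), which baseline lipid
parameter best predicts major adverse cardiovascular events (MACE:
cardiovascular death, stroke, myocardial infarction, or ischemia-driven
revascularization)? LDL-C is the guideline anchor, but several derived
indices — non-HDL-C, the atherosclerosis index (AI), the atherogenic index
of plasma (AIP), the lipoprotein combine index (LCI), LDL-C/HDL-C, and
apoB/apoA-I — are candidate refinements. `lipidmace` implements the full
comparison pipeline: tertile exposure coding, adjusted Cox
proportional-hazards models, and a ratio-of-hazard-ratios (RHR) statistic
with paired percentile-bootstrap confidence intervals, together with a
calibrated synthetic cohort generator so that every stage can be exercised
and tested without patient-level data.

## Derived quantities

From a standard panel (TC, TG, HDL-C, LDL-C in mmol/L):

* non-HDL-C $= TC - HDL$
* AI $= (TC - HDL)/HDL$ (identically non-HDL-C / HDL)
* AIP $= \log_{10}(TG/HDL)$
* LCI $= TC \cdot TG \cdot LDL / HDL$
* LDL/HDL and apoB/apoA-I as plain ratios.

Renal function uses the 2009 CKD-EPI creatinine equation (creatinine
converted from µmol/L at 88.4 per mg/dL); the race coefficient is omitted
because the targeted cohorts exercise only the non-Black branch. CKD is a
strict eGFR < 60 mL/min/1.73 m² flag. BMI is weight/height². Follow-up
time runs from discharge to the first endpoint (or last contact), with day
differences divided by 30.4375 — the mean Gregorian month — because
month-scale reporting does not otherwise define the conversion.

## Exposure coding and the Cox engine

Each lipid parameter is split at its empirical 1/3 and 2/3 quantiles
(linear-interpolation definition, `type = 7`); ties at a cutpoint fall to
the lower tertile. The model is a multivariate Cox proportional-hazards
regression of time to first MACE on two tertile dummies (T2 and T3 vs T1)
adjusted for age, sex, BMI, diabetes, hypertension, and Gensini score.
The reported contrast is the highest-vs-lowest tertile hazard ratio
$\exp(\beta_{T3})$ with a Wald 95% interval $\exp(\beta \pm 1.959964\,se)$.
The middle-tertile HR is estimated in the same model and carried in the
output for completeness.

The partial likelihood is maximized by Newton-Raphson with step-halving
from $\beta = 0$, with Efron's correction for tied event times — ties are
guaranteed at day resolution, and Efron is the better default under ties.
The score and observed information are accumulated in compiled code over
the risk sets in a single pass (subjects sorted by decreasing time).
Convergence requires a log-likelihood change below 1e-9, a gradient
max-norm below 1e-6, *and* a Newton increment below 1e-4: the last
condition is what separates a true optimum from a monotone likelihood,
where the gradient becomes numerically tiny while the step stays O(1). A
coefficient passing |β| > 50, a singular information matrix, or exhausted
step-halving all yield a non-convergence flag with a diagnostic rather
than a silent estimate. The variance is the inverse observed information;
the unit tests check the fitter against golden-section maximization of a
hand-written Efron likelihood on small tied datasets and against an
independent reference implementation on simulated cohorts.

## The RHR statistic

For each non-LDL-C parameter the association strengths are compared as
RHR = HR(parameter, T3 vs T1) / HR(LDL-C, T3 vs T1), both from adjusted
fits on the same cohort. Uncertainty comes from a paired bootstrap:
patients are resampled with replacement; both models are refitted on the
same resample; and the 2.5th/97.5th percentiles of the resampled ratios
form the 95% interval (the study-default is 5000 resamples). Two design
choices were genuinely open:

* **Tertile cutpoints are re-derived inside each resample** (default).
  The tertile construction is part of the estimator, so its sampling
  variability belongs in the interval. `recut_tertiles = FALSE` freezes
  the full-cohort cutpoints for sensitivity analysis.
* **Resampling is paired, never independent**: the two HRs entering each
  ratio always come from the same resample, which is what makes the
  ratio's correlation structure honest.

Resamples where a fit fails to converge or an exposure degenerates are
discarded and redrawn (cap: 10× extra draws; a discard fraction above 20%
is a hard error with diagnostics). One `set.seed()` governs each
bootstrap; results are bit-identical for a fixed seed.

## The synthetic cohort generator

Because the motivating study's raw data are not deposited, the generator
is a first-class module that emulates the published cohort structure:

* **Lipids**: multivariate log-normal on (TC, TG, HDL, LDL) with medians
  5.1 / 1.8 / 1.1 / 3.2 mmol/L and log-scale spreads back-solved from the
  published interquartile ranges; the correlation matrix (TC–LDL 0.85,
  TG–HDL −0.40, etc.) reflects standard lipid physiology. Rows with
  LDL ≥ TC or HDL ≥ TC are redrawn (bounded rejection). ApoB and apoA-I
  are conditionally log-normal on LDL and HDL; Lp(a) is a wide
  independent log-normal (median 196 mg/dL, passed through in the units
  given).
* **Covariates**: age 65 ± 8.9, 72.1% male, 19.8% diabetes, 53.3%
  hypertension, BMI 24.1 ± 3.3, log-normal Gensini (median 37) and
  creatinine with a sex shift.
* **Events**: Weibull proportional hazards (default shape 1, i.e.
  exponential) with linear predictor `sum(log_hr * covariate)`;
  continuous covariates are standardized with theoretical moments frozen
  into the cohort's `truth` attribute. The default effect map places the
  largest effects on LDL-C, diabetes, and Gensini score. The linear
  predictor is centred by the cohort-average relative hazard, so
  `weibull_scale` (245 months) controls the *marginal* event rate — about
  13.5% at n = 445 — independently of the configured effects; effects
  then redistribute risk across patients rather than inflating the
  marginal rate.
* **Censoring**: uniform accrual over 24 months with an administrative
  cutoff at 48 months, giving a median potential follow-up near 36
  months; censoring is independent of covariates, matching the Cox
  model's assumption.
* **Exchangeable null**: `null_copy_parameter = TRUE` adds an independent
  replicate of the LDL-C marginal with zero hazard effect, which is the
  basis of the bootstrap-coverage checks.

What the generator does *not* emulate: informative censoring, statin
initiation after PCI, time-varying lipid levels, measurement error in the
Gensini score, or site effects. Passing tests therefore demonstrate the
statistical machinery is correct under the stated generative model, not
that the clinical conclusions transfer to any particular real cohort.

Tertile-scale "truth" has no closed form under this generator (effects
are imposed on continuous values), so `recover_parameters()` defines it
operationally by fitting one very large cohort — 100,000 patients by
default, at which the Monte Carlo error of the truth coefficient (~0.02)
is negligible against the recovery tolerances — and then measures bias
and Wald-CI coverage across replicate cohorts of the configured size.

## Descriptive comparisons

The baseline table compares MACE vs non-MACE groups. Categorical
variables: counts (%) with a chi-square test without continuity
correction, falling back to Fisher's exact test when any expected cell is
below 5 (small synthetic cohorts reach that regime quickly). Continuous
variables: a Kolmogorov–Smirnov normality check in each group — the
common applied reading uses a normal with moment-estimated parameters;
the Lilliefors-corrected variant is available via `ks_variant` — routing
to mean ± SD with a Welch t-test when both groups look normal (p ≥ 0.05)
and to median (IQR) with a Mann–Whitney U test otherwise. Groups with
fewer than 3 continuous observations make normality undecidable and fall
back to Mann–Whitney with a warning.

## Numerical and interface choices

* Sex is coded female = 0, male = 1 in design matrices.
* Dates are ISO-8601; any other dialect must be mapped before loading.
* Complete-case handling is per model: a patient missing apoB still
  contributes to the LDL-C model, which maximizes usable n and matches
  per-parameter analysis.
* Bootstrap and simulation RNG is R's default Mersenne-Twister stream
  under a single mandatory seed per call; determinism is part of the
  tested contract.
* The analysis surface is functional: `simulate_cohort()`,
  `load_cohort()`, `prepare_cohort()`, `table_one()`,
  `fit_tertile_cox()`, `bootstrap_rhr()` and the `run_full_analysis()`
  orchestrator, plus JSON writers (`write_report()`, `write_cohort()`)
  for machine-readable outputs.

## Problem sizes used in the test suite

The shipped tests exercise: oracle equivalence of the Cox engine on
enumerable single-covariate datasets (n ≤ 8, with ties); agreement with an
independent Cox implementation on 50 cohorts of n = 300; bootstrap
coverage of the exchangeable null over 100 cohorts (n = 300, B = 200);
recovery of a log(2) LDL-C effect over 50 cohorts of n = 2000 against the
large-n truth; and generator calibration over 50 cohorts at the study
size n = 445. These sizes keep the full suite comfortably reproducible on
a laptop while leaving the Monte Carlo error well inside each check's
tolerance.

## A worked example

```{r example, eval = FALSE}
raw <- simulate_cohort(sim_config(), seed = 1)
report <- run_full_analysis(raw, B = 1000, seed = 1001)
print(report)
```

## Known limitations

No proportional-hazards diagnostics, time-varying covariates,
competing-risks models, or stratified baselines; no BCa or studentized
bootstrap and no bootstrap p-values; no multiplicity correction across
parameters (none is applied in the motivating analysis); no imputation of
missing labs. Negative non-HDL-C (TC < HDL) warns rather than errors so a
noisy synthetic panel cannot abort a pipeline run.
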