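# lipidmace

Which baseline lipid parameter best predicts major adverse cardiovascular
events (MACE — cardiovascular death, stroke, myocardial infarction, or
ischemia-driven revascularization) in statin-naïve patients after
percutaneous coronary intervention (PCI)? `lipidmace` implements the full
comparison pipeline for that question, aimed at cardiovascular
epidemiologists and biostatisticians:

* **Derived lipid indices** from a standard panel (mmol/L): non-HDL-C
  = TC − HDL-C; atherosclerosis index AI = (TC − HDL-C)/HDL-C; atherogenic
  index of plasma AIP = log₁₀(TG/HDL-C); lipoprotein combine index
  LCI = TC·TG·LDL-C/HDL-C; LDL-C/HDL-C; apoB/apoA-I — plus CKD-EPI eGFR,
  a CKD flag, and BMI.
* **Tertile exposure coding** of each parameter and a **from-scratch Cox
  proportional-hazards fitter** (Newton–Raphson with step-halving, Efron
  tie correction, compiled score/information accumulation) reporting the
  highest-vs-lowest tertile hazard ratio exp(β_T3) with Wald 95% CIs,
  adjusted for age, sex, BMI, diabetes, hypertension, and Gensini score.
* **The ratio of hazard ratios (RHR)** — HR(parameter)/HR(LDL-C) from
  paired fits on the same cohort — with percentile-bootstrap confidence
  intervals (2.5th/97.5th percentiles of the ratio across resamples, both
  models refitted and tertiles recut within each resample).
* **Table-1 style descriptives** with Kolmogorov–Smirnov-driven test
  selection (Welch t / Mann–Whitney U / chi-square with Fisher fallback).
* **A calibrated synthetic cohort generator** (correlated log-normal
  lipids, Weibull proportional-hazards events, accrual + administrative
  censoring) so the whole pipeline is testable end to end without
  patient-level data.

## Worked example

```r
library(lipidmace)

raw    <- simulate_cohort(sim_config(), seed = 1)   # 445 synthetic patients
report <- run_full_analysis(raw,
                            parameters = c("ldl_c", "non_hdl", "ai", "ldl_hdl"),
                            B = 500, seed = 1001)
print(report)
```

```
Cohort: n = 445, MACE = 56 (12.6%), median follow-up 34.1 months, 4.5 events/100 person-years

Top- vs bottom-tertile adjusted HRs:
  ldl_c       HR 1.34 (0.69 to 2.58), P = 0.384
  non_hdl     HR 2.67 (1.31 to 5.42), P = 0.00667
  ai          HR 3.50 (1.58 to 7.75), P = 0.00201
  ldl_hdl     HR 3.25 (1.53 to 6.92), P = 0.00218

RHR vs ldl_c (percentile bootstrap, B = 500):
  non_hdl     RHR 1.99 (95% CI 1.01 to 3.86)
  ai          RHR 2.61 (95% CI 0.98 to 6.63)
  ldl_hdl     RHR 2.43 (95% CI 1.21 to 5.57)
```

The cohort line gives the simulated cohort's size, event count and
proportion, median follow-up in months, and the event incidence per 100
person-years. Each HR row is the adjusted hazard of MACE in the highest
tertile of that parameter relative to its lowest tertile; an RHR above 1
means the parameter's top-tertile association is stronger than LDL-C's on
this cohort, with the percentile-bootstrap interval quantifying the
pairing's sampling uncertainty. (This is one synthetic replicate — tertile
HRs at n = 445 with ~56 events are noisy by design.)

`write_report(report, "report.json")` serializes everything;
`write_cohort()` emits a validated cohort CSV plus a JSON validation
report. See `vignette("lipidmace-methods")` for the model, generator
calibration, and the numerical design choices.

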