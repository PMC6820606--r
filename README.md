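# atezodose

Model-informed evaluation of alternative flat dosing regimens for
**atezolizumab**, an anti-PD-L1 monoclonal antibody. The package is aimed
at pharmacometricians and clinical pharmacology analysts who want to
reproduce, stress-test or extend the *exposure-matching* argument behind
interchangeable dosing regimens (840 mg q2w, 1200 mg q3w, 1680 mg q4w,
20 mg/kg q3w): a new regimen is supportable when its predicted exposure
lies within the exposure range of regimens with established efficacy and
safety, and no exposure–response (ER) relationship exists within that
range.

## What it implements

* **popPK engine** — closed-form two-compartment IV-infusion model
  (time in days, doses in mg, volumes in L, concentrations in µg/mL):

  `C(t) = (R0/V1) Σᵢ (Aᵢ/λᵢ) · [infusion / post-infusion exponential terms]`

  with covariate effects (power functions of weight, albumin, tumor size;
  fold-changes for sex and ADA status), multivariate log-normal
  between-patient variability, superposition over doses and an analytic
  steady state. The packaged default model is calibrated to the published
  atezolizumab summary: CL 0.2 L/day, Vss 6.9 L, terminal half-life
  ≈27 days.
* **Regimen simulation** — Monte Carlo exposure metrics (cycle-1 and
  steady-state Cmax, Cmin, AUC, weekly AUC) over the 500-patient reference
  population (1:1 sex at 85/64 kg) and body-weight-quartile populations;
  geometric means with empirical 90% prediction intervals; percent
  comparisons between regimens.
* **ER analysis** — logistic regression of binary endpoints (ORR,
  grade ≥3 AEs, AESIs) on cycle-1 exposure with Wald tests,
  exposure-quartile summaries with Clopper–Pearson CIs, tumor-type pooling
  checks, and subgroup safety tabulations.
* **TGI / TGI-OS** — biexponential tumor-size model
  `SLD(t) = BSLD·(e^(−KS·t) + e^(KG·t) − 1)`, per-patient MAP estimation
  of shrinkage (KS) and growth (KG) rates, accelerated-failure-time
  survival regression of OS on log(KG) and baseline prognostic factors,
  exposure testing at α = 0.01, and simulation-based hazard-ratio
  validation by exposure quartile (1000 replicates).
* **pcVPC** — prediction-corrected visual predictive check against
  NONMEM-dialect event records.
* **Synthetic trials** — a generator producing complete virtual trials
  (covariates, PK records, SLD series, survival, binary endpoints, plus
  ground truth) with the statistical structure the analyses assume,
  including the exposure–KG confounding and a flat (zero-slope) ER default.

The numbered drivers under `analysis/` run the four stages over synthetic
data and write their tables to `results/`.

## Worked example

```r
library(atezodose)

model <- default_model()
pop   <- build_reference_population(model, n = 500, seed = 1)
q3w   <- simulate_regimen(model, pop, dosing_regimen(1200, 21, n_doses = 16))
q2w   <- simulate_regimen(model, pop, dosing_regimen(840, 14, n_doses = 24))

q3w$summary[q3w$summary$metric %in%
            c("cmax_c1", "cmin_c1", "cmin_ss", "auc_week_ss"), ]
#>        metric geo_mean pi_lo pi_hi   n
#> 1     cmax_c1    388.2   261   598 500
#> 2     cmin_c1     85.4    54   126 500
#> 6     cmin_ss    214.2   109   396 500
#> 8 auc_week_ss   2223.2  1332  3657 500

100 * mean(q3w$metrics$cmin_c1 > 6)
#> [1] 100
```

The 1200 mg q3w geometric-mean cycle-1 trough (85.4 µg/mL) sits inside the
published 90% interval (55–133 µg/mL) and every simulated patient exceeds
the 6 µg/mL efficacious target trough. Comparing regimens on the same
virtual patients:

```r
cmp <- compare_regimens(q2w$summary, q3w$summary)
cmp[cmp$metric %in% c("cmin_c1", "cmin_ss", "auc_week_ss"), ]
#>        metric test reference   pct pct_1dp pct_int
#> 2     cmin_c1   73      85.4 -14.5   -14.5     -14
#> 6     cmin_ss  249     214.2  16.2    16.2      16
#> 8 auc_week_ss 2334    2223.2   5.0     5.0       5
```

840 mg q2w gives a lower cycle-1 trough (−14%), a higher steady-state
trough (+16%), and — exactly, on common random draws — a +5.0% steady-state
weekly AUC, since weekly AUC at steady state is weekly dose divided by
clearance (420 vs 400 mg/week). Published comparisons from independent
500-patient replicates scatter around this analytic value (+3.5%); the
printed reference summaries are shipped in
`exposure_reference()` and the comparison arithmetic is checked against
them in the test suite.

## Notes

The patient-level data of the source trials are not public. All
patient-level inputs here are synthetic, the popPK covariate coefficients
and variability terms are calibration defaults rather than published
estimates, and quantities that depend on real patient data (e.g. actual
TGI-OS coefficient values) are out of scope. See the methods vignette
(`vignettes/exposure-matching-methods.Rmd`) for the models, assumptions,
calibration choices and known limitations.
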