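# mmidose

Multi-model inference for radiation dose–response in grouped cohort
mortality data.

## What problem this solves, and for whom

Radiation-epidemiology cohorts — the Life Span Study (LSS) of the
Hiroshima/Nagasaki atomic-bomb survivors being the canonical example —
are analysed as grouped *person-year tables*: cells cross-classified by
city, sex, age at exposure, attained age, calendar period and dose
category, each carrying person-year-weighted covariate means,
person-years at risk and cause-specific death counts.  Whether the
excess risk at low doses is linear, curved, thresholded or hormetic
cannot be decided by fitting one model of choice: several shapes fit
such data almost equally well.  This package is for analysts who want
to fit the whole candidate family and combine it honestly.

It implements:

* **Hazard models** `h = h0 (1 + err(D) ε)` (excess relative risk, ERR)
  and `h = h0 + ear(D) ε` (excess absolute risk, EAR), with a
  configurable piecewise log-linear baseline `h0` in `ln(attained age)`
  (city/sex/birth-cohort terms, fixed or free age knots) and the
  standard dose-effect modifier
  `ε = exp(θ_s) (a/70)^η exp(γ(e−30)/10)`.
* **Eleven dose-response shapes**: linear no-threshold `err·D`;
  quadratic `1.12·err·D²`; linear-quadratic; linear-exponential;
  linear threshold `err·(D−D_th)`; a tanh-smoothed step
  `0.5·scale·[tanh(s_t(D−D_th))+1]`; two step-with-slope variants; two
  hormesis-like shapes (exactly zero below 5 mGy); and a 3-step
  categorical model.
* **Grouped Poisson regression**: deviance minimization with perturbed
  restarts, Wald covariance from the finite-difference deviance
  Hessian, threshold profiling over the conventional 27-value
  0.0001–2 Gy grid, likelihood-ratio testing (`Δdev ≥ 3.84` per
  parameter at the 95% level), backward-elimination baseline
  streamlining with a full audit trail, and deviance decomposition by
  dose/age strata.
* **Model selection and MMI**: `AIC = dev + 2 N_par`, Akaike weights
  `p_m = exp(−ΔAIC_m/2)/Σ_j exp(−ΔAIC_j/2)`, Latin-hypercube
  propagation of the Wald parameter uncertainty (10⁴ realizations),
  and weight-proportional pooling of the per-model risk distributions
  into a single ERR/EAR distribution with percentile intervals.
* **A synthetic cohort generator** with the scale and structure of the
  LSS non-cancer follow-up (~1.2 million person-years, ~4,000 deaths
  per endpoint, person-years concentrated at low doses) under any known
  true model, so the entire chain is testable end to end.

## Worked example

Simulate an LSS-like cohort under a true linear ERR of 0.2 per Gy, fit
linear, quadratic and smoothed-step candidates (the step threshold is
profiled over the grid), and pool by Akaike weight:

```r
library(mmidose)

sc <- generate_table(synthetic_config(), seed = 20)
bl <- list(intercept = log(3e-3), log_age_slope = 4)
models <- list(
  lnt  = risk_model("ERR", 1, baseline = bl,
                    dose_response = list(err = 0.1)),
  quad = risk_model("ERR", 2, baseline = bl,
                    dose_response = list(err = 0.05)),
  step = risk_model("ERR", 6, baseline = bl,
                    dose_response = list(scale = 0.2, D_th = 0.3)))
pb <- run_pipeline(sc, models, "cvd", doses = 1, total_n = 1e4, seed = 101)
pb$scores
#>      model deviance n_par  aic delta_aic  weight
#> lnt    lnt     1347     3 1353    0.2155 0.44549
#> quad  quad     1351     3 1357    4.2812 0.05834
#> step  step     1346     3 1352    0.0000 0.49617
pb$risk_table[, c("dose", "model", "weight",
                  "ERR_mean", "ERR_lower", "ERR_upper")]
#>   dose model weight ERR_mean ERR_lower ERR_upper
#> 1    1   lnt 0.4455   0.1828    0.0976     0.268
#> 2    1  quad 0.0583   0.0798    0.0357     0.124
#> 3    1  step 0.4962   0.2333    0.1275     0.339
#> 4    1   MMI 1.0000   0.2015    0.0836     0.315
```

Reading the output: the linear and step models fit this realization
about equally well (Akaike weights 0.45 and 0.50; the quadratic is
nearly excluded), so single-model inference would be a coin flip.  The
pooled (MMI) row combines 10⁴ Latin-hypercube risk realizations in
those proportions: the pooled mean ERR at 1 Gy is 0.20 — matching the
simulation truth of 0.2 — with a 90% percentile interval of
[0.08, 0.31] that reflects both parameter uncertainty and model
uncertainty.

The numbered drivers under `analysis/` tell the same story as a
narrative workflow — `01_simulate_cohort.R` (cohort construction),
`02_streamline_and_fit.R` (baseline streamlining and candidate fits),
`03_mmi_risk.R` (pooled risks and the pooled dose-response curve),
`04_published_selection.R` (the published selection arithmetic) — each
writing its tables under `results/`.

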