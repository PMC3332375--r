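---
title: "Dose-response modelling and multi-model inference for grouped cohort mortality data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response modelling and multi-model inference for grouped cohort mortality data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmidose)
```

## The problem

Radiation-epidemiology cohorts such as the Life Span Study (LSS) of the
Hiroshima and Nagasaki atomic-bomb survivors are distributed as *grouped
person-year tables*: one row per cell of the cross-classification by
city, sex, age at exposure, attained age, calendar period and dose
category, carrying person-year-weighted covariate means, person-years at
risk and death counts per cause.  The scientific question — whether the
excess mortality risk from radiation is linear in dose, curved,
thresholded, or even protective at low doses — cannot be settled by
fitting a single model of choice: several qualitatively different
dose-response shapes describe such data almost equally well.  This
package implements the full inference chain for that situation: grouped
Poisson regression of excess-risk hazard models over a family of eleven
candidate dose-response shapes, likelihood-ratio streamlining of the
baseline, AIC-based model selection, and multi-model inference (MMI)
that pools risk estimates and their uncertainty distributions across
the surviving models in proportion to their Akaike weights.

## The hazard model

For each cell with covariates (city, sex $s$, attained age $a$, age at
exposure $e$) and weighted colon dose $D$ (Gy), the total hazard is

* ERR transfer: $h = h_0(\text{city}, s, a, e)\,\bigl(1 + err(D)\,\varepsilon(s, a, e)\bigr)$
* EAR transfer: $h = h_0(\text{city}, s, a, e) + ear(D)\,\varepsilon(s, a, e)$

and expected deaths are $\lambda = h \times \text{person-years}$, with
death counts Poisson.  Risk estimates follow directly from the hazard:
$ERR = h/h_0 - 1$ and $EAR = h - h_0$; consequently the EAR implied by an
ERR-transfer model is $h_0 \times ERR$ and inherits the baseline's city
and sex dependence (the `group_conversion_factor()` utility converts
such estimates across groups by person-year-weighted baseline ratios).

### Baseline

$\ln h_0$ is piecewise linear in $\ln a$ (continuous at every knot by
construction, since slope changes act through
$\max(0, \ln a - \ln \text{knot})$), with additive city, sex and
age-at-exposure terms on the log scale.  This reproduces the structure
of published LSS baselines — age knots, city/sex intercepts, birth-cohort
trends — without committing to any published coefficient set, which this
package deliberately does not reproduce: the baseline family is
configurable and every term can be included, excluded, fixed or freed.
Free knot positions enter the optimizer as ordinary parameters; ordering
is enforced by returning a large penalized deviance for disordered
knots rather than by reparameterization, which keeps Wald errors
directly interpretable on the knot ages.  Knots rarely approach one
another in practice; if they do, the penalty boundary shows up as a
non-convergence flag rather than a silent reparameterized optimum.

### The eleven dose-response shapes

`dose_response_value()` evaluates, for shape ids 1–11: linear
no-threshold ($err \cdot D$); quadratic ($1.12\,err\,D^2$);
linear-quadratic; linear-exponential
($(err_1 + err_2 D)\,e^{-err_3 D^2}$); linear threshold
($err\,(D - D_{th})$ above $D_{th}$, zero below); a smoothed step
$0.5\,scale\,[\tanh(s_t(D - D_{th})) + 1]$; two step-with-slope variants;
two hormesis-like shapes that are exactly zero below a fixed 0.005 Gy
floor and allow a negative plateau; and a three-step categorical model.
Conventions worth noting:

* The dose-squared adjustment 1.12 (alternative 1.15) compensates
  dosimetric random error and multiplies the quadratic coefficient in
  shapes 2 and 3.
* The smoothed-step slope $s_t$ (named `tanh_slope` to avoid the
  field's symbol collision with sex) defaults to a fixed $10^5$ Gy$^{-1}$,
  at which the shape is numerically a hard step (difference below
  $10^{-6}$ everywhere at least 1 mGy from the threshold) while keeping
  the fit differentiable; it can be freed.
* The categorical shape is purely categorical by default — not
  multiplied by the dose-effect modifier — since the convention is
  ambiguous; `modifier_on_categorical = TRUE` switches this.  Its
  default boundaries (0.62, 1, 1.5 Gy) are configurable.

### Dose-effect modifier

$\varepsilon(s, a, e) = e^{\theta_s 1[\text{female}]}\,(a/70)^\eta\,
e^{\gamma (e-30)/10}$, each term present only when included, identically
1 otherwise.  This is the standard LSS parameterization (modifiers
centred at $a = 70$, $e = 30$); other forms would slot in behind the
same interface.

## Fitting

`fit_risk_model()` minimizes the grouped Poisson deviance
$2\sum_i [d_i \ln(d_i/\lambda_i) - (d_i - \lambda_i)]$ (the
$d\ln(d/\lambda)$ term is 0 at $d = 0$, the standard saturated-model
limit) with `stats::nlminb`, then three deterministic perturbed restarts
keep the best optimum.  Inadmissible regions — non-positive hazards,
$1 + err\,\varepsilon \le 0$ under ERR transfer, disordered knots or
categorical boundaries — return a large penalty value, which keeps the
optimizer inside the admissible set without constrained programming.
The Wald covariance is $2 H^{-1}$ with $H$ the central-finite-difference
Hessian of the deviance (step $10^{-4}\max(|\theta|, 1)$); a singular or
non-positive result flags the covariance unavailable rather than
failing.

Threshold doses are profiled over the conventional 27-value grid
(0.0001–2 Gy, `default_dth_grid()`); for the linear threshold shape the
search continues from the best grid point with $D_{th}$ free, since that
shape's threshold is conventionally adjusted in the fit.  On grouped
doses the threshold is only identified up to the interval between
adjacent dose-category means, and a freely fitted $D_{th}$ can sit on
the kink at a category mean with an over-confident Wald error — the
grid-then-refine protocol exists precisely to tame this multimodality.

`lrt_improves()` applies the nested-model rule: an added parameter must
lower the deviance by the $\chi^2$ quantile (3.84 points at the 95%
level for one parameter).  The boundary is inclusive with a 0.1%
relative tolerance so a drop of exactly the conventional rounded 3.84
counts as an improvement even though the exact quantile is 3.8415.
`streamline_baseline()` runs backward elimination to a fixed point —
each eliminable coefficient is set to its null value and everything else
refit; the least significant is removed if removal costs less than the
critical value; one removal per sweep — then tries freeing fixed knot
positions, keeping each only if it buys at least the critical value.
Single-pass elimination would also be defensible; iteration to a fixed
point was chosen because it leaves no removable parameter behind, and
the audit trail records every test either way.

## Selection and multi-model inference

`aic_score()` is $dev + 2 N_{par}$ and `akaike_weights()` is
$p_m = e^{-\Delta AIC_m/2} / \sum_j e^{-\Delta AIC_j/2}$ (equal model
priors).  Evaluating this equation on the published cardiovascular
$\Delta$AIC values (0, 0.32, 1.27, 1.93) yields weights (0.3619, 0.3084,
0.1918, 0.1379); the published table pairs the middle two the other way
round.  The package follows the equation and documents the discrepancy
rather than resolving it silently.

Uncertainty is propagated by Latin hypercube sampling
(`lhs_parameter_samples()`, stratified uniforms from the `lhs` package):
each parameter's marginal is stratified into $n$ equiprobable normal
bins, and correlation is induced by the eigen-decomposition transform of
the Wald covariance (negative eigenvalues clipped at zero and logged).
Gridded threshold parameters stay fixed at their selected value during
sampling — their grid uncertainty is not propagated, mirroring the
fixed-threshold step fits.  Realizations violating hazard positivity are
regenerated; more than 10% inadmissible draws aborts with an
unstable-fit error.

`mmi_pool()` allocates the $10^4$ pooled realizations across models by
largest-remainder rounding of weight $\times\,10^4$ (so counts sum
exactly), merges the per-model distributions, and reports mean, median
and percentile bounds; a "90% CI" is the [5th, 95th] percentile range
with type-7 interpolation (the interpolation rule is a convention the
source material leaves open).  When a threshold model holds weight at a
sub-threshold dose, the pooled lower bound is structurally zero — the
qualitative signature of MMI in this setting.  `mmi_dose_response()`
gives the weight-combined point curve $\sum_m p_m\,err_m(D)$, which can
itself be scored against data through `poisson_deviance()` because it
contains no free parameters.

## The synthetic cohort generator

`synthetic_config()` / `generate_table()` simulate grouped tables with
every statistical feature the pipeline relies on, under a fully known
truth.  Defaults were chosen once to emulate the published cohort's
conditions and are not tuned per analysis:

* total person-years $1.2 \times 10^6$; expected baseline deaths
  calibrated to 4,000 per endpoint (the generator solves for the true
  intercept analytically);
* dose-category means (0.0025, 0.03, 0.2, 0.75, 1.5, 2.5) Gy with
  person-year weights (0.55, 0.25, 0.12, 0.05, 0.02, 0.01) — the
  low-dose concentration that drives both baseline dominance and the
  weak identifiability of thresholds;
* a baseline rising with slope 5 in $\ln a$, women carrying the larger
  person-year share, and attained age at least 23 years above age at
  exposure (follow-up beginning 23 years after exposure);
* cell means jittered around band midpoints (uniform, ±1 year) from a
  seed sub-stream separate from the death-count stream, so toggling one
  randomness source does not shift the other.

What the generator does **not** emulate: dosimetric measurement error
(the emulated inputs have those adjustments already applied), the
healthy-survivor selection effect (handled in the source setting by
cohort restriction, not modelled here), within-cell covariate
heterogeneity beyond the jitter, and any correlation between causes.
Passing recovery and coverage tests on these tables therefore validates
the estimation machinery, not the epidemiology of any real cohort.

## Problem sizes and test design

The package's validation suites run on a reduced strata grid (about 140
cells at the full cohort scale of $1.2 \times 10^6$ person-years and
4,000 deaths), which keeps each Poisson fit in the tens of milliseconds
while preserving the death-count statistics that determine estimator
behaviour.  Chosen sizes: 20 replicates per shape for the
3-Wald-SE recovery batteries (shapes 1, 2, 5, 6); 200 replicates for the
90% interval coverage check; 500 replicates for the null type-I-error
check of the 1-df likelihood-ratio test (binomial 3-sigma band around
5%); 30–50 replicates for the streamlining elimination/retention
simulations.  The MMI pooled sample size is $10^4$ throughout, matching
the method's convention.

## Known limitations

* Thresholds are identified only up to the spacing of dose-category
  means; Wald errors for a threshold sitting on a category kink are
  over-confident.  The grid profile should always be inspected.
* Wald/LHS intervals are symmetric-normal in the parameters; strongly
  skewed likelihoods (small counts in high-dose cells) are better served
  by profile likelihood, which this package does not implement.
* The deviance-based AIC is valid for model comparison on a fixed table;
  deviances are not comparable across different groupings of the same
  underlying cohort.
* Backward elimination tests parameters marginally, one per sweep;
  strongly collinear baseline terms can mask one another, which is why
  the audit trail records every test rather than only removals.
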