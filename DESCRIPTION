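Package: mmidose
Title: Multi-Model Inference for Radiation Dose-Response in Grouped
    Cohort Mortality Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Grouped Poisson regression of excess relative risk (ERR) and
    excess absolute risk (EAR) hazard models for cohort mortality data in
    person-year table form, with a family of eleven candidate dose-response
    shapes (linear, quadratic, linear-quadratic, linear-exponential,
    threshold, smoothed step, step-with-slope, hormesis-like and
    categorical), likelihood-ratio streamlining of log-linear baseline
    hazard models, AIC-based model selection with Akaike weights, and
    multi-model inference that pools risk distributions propagated by
    Latin hypercube sampling of the fitted parameter uncertainty.
    Includes a generator of Life-Span-Study-like synthetic cohorts with
    known truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lhs
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
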