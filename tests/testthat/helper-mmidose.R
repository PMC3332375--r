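# shared fixtures: all built in code, no files

# fast fitting options for simulation loops
quick_opts <- fit_options(restarts = 0L, hessian = TRUE)
quick_nohess <- fit_options(restarts = 0L, hessian = FALSE)

# reduced strata grid: same cohort scale (1.2e6 PY, ~4000 deaths) over
# fewer cells, so simulation batteries stay cheap
small_config <- function(true_model = NULL, target_deaths = 4000,
                         dose_means = c(0.0025, 0.03, 0.2, 0.75, 1.5, 2.5),
                         dose_weights = c(0.55, 0.25, 0.12, 0.05, 0.02,
                                          0.01)) {
  synthetic_config(
    agex_breaks = c(0, 20, 40), agex_weights = c(0.5, 0.5),
    age_breaks = c(40, 55, 70, 90), age_weights = c(0.3, 0.4, 0.3),
    n_periods = 1L,
    dose_means = dose_means, dose_weights = dose_weights,
    target_deaths = target_deaths,
    true_model = true_model)
}

# default fit spec matching the small config's truth structure
lnt_spec <- function(err = 0.1) {
  risk_model("ERR", 1,
             baseline = list(intercept = log(3e-3), log_age_slope = 4),
             dose_response = list(err = err), label = "lnt")
}

# three handmade valid cells
tiny_cells <- function() {
  data.frame(
    city = c("Hiroshima", "Hiroshima", "Nagasaki"),
    sex = c("male", "female", "male"),
    agexcat = c(1L, 1L, 2L), agecat = c(1L, 2L, 2L),
    periodcat = 1L, dosecat = c(1L, 2L, 3L),
    mean_age = c(55, 62.5, 70), mean_agex = c(20, 25, 30),
    mean_dose_gy = c(0.005, 0.2, 1.2),
    pyr = c(1000, 2000, 500),
    deaths_cvd = c(3, 10, 4))
}

# a fit object with prescribed estimates/covariance, for exercising the
# uncertainty-propagation contract in isolation
fake_fit <- function(estimates, covariance, model = NULL) {
  k <- length(estimates)
  covariance <- matrix(covariance, k, k,
                       dimnames = list(names(estimates), names(estimates)))
  structure(list(model = model, estimates = estimates,
                 wald_se = sqrt(diag(covariance)),
                 covariance = covariance, deviance = 0, n_par = k,
                 converged = TRUE, cov_ok = TRUE, n_evaluations = 0L,
                 cause = "cvd", label = "fake"),
            class = "mmidose_fit")
}
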