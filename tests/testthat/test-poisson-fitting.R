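test_that("the Poisson deviance matches its closed forms", {
  # single cell, d = 2, lambda = 1: 2 (2 ln 2 - 1)
  cells <- tiny_cells()[1, ]
  cells$pyr <- 1000
  cells$deaths_cvd <- 2
  tab <- person_year_table(cells)
  m <- risk_model("ERR", 1,
                  baseline = list(intercept = log(1 / 1000),
                                  log_age_slope = 0),
                  dose_response = list(err = 0))
  expect_equal(poisson_deviance(tab, m, "cvd"), 2 * (2 * log(2) - 1))
  # d = 0, lambda = 3: reduces to 2 lambda
  cells$deaths_cvd <- 0
  m3 <- risk_model("ERR", 1,
                   baseline = list(intercept = log(3 / 1000),
                                   log_age_slope = 0),
                   dose_response = list(err = 0))
  expect_equal(poisson_deviance(person_year_table(cells), m3, "cvd"), 6)
  # saturated model: lambda_i = d_i everywhere gives exactly zero
  sc <- generate_table(small_config(), seed = 21)
  tab <- sc$table
  lam_sat <- pmax(tab$deaths_cvd, 1e-9)
  d <- tab$deaths_cvd
  dev_sat <- 2 * sum(ifelse(d > 0, d * log(d / lam_sat), 0) - (d - lam_sat))
  expect_equal(dev_sat, 2 * sum(lam_sat[d == 0]))
})

test_that("a one-parameter fit lands on the analytic optimum", {
  # one cell, intercept-only: deviance is minimized at lambda = d,
  # i.e. intercept = log(d / pyr)
  cells <- tiny_cells()[1, ]
  cells$pyr <- 2000
  cells$deaths_cvd <- 7
  tab <- person_year_table(cells)
  m <- risk_model("ERR", 1,
                  baseline = list(intercept = log(1e-3), log_age_slope = 0),
                  dose_response = list(err = 0),
                  fixed = c("bl.log_age_slope", "dr.err"))
  f <- fit_risk_model(tab, m, "cvd", options = quick_opts)
  expect_equal(unname(f$estimates[["bl.intercept"]]), log(7 / 2000),
               tolerance = 1e-5)
  expect_equal(f$deviance, 0, tolerance = 1e-8)
  # Wald SE of the log rate for a single Poisson count is 1/sqrt(d)
  expect_equal(unname(f$wald_se[["bl.intercept"]]), 1 / sqrt(7),
               tolerance = 1e-3)
})

test_that("a fully fixed model returns its evaluated deviance", {
  tab <- generate_table(small_config(), seed = 2)$table
  m <- lnt_spec()
  m$params$free[] <- FALSE
  f <- fit_risk_model(tab, m, "cvd")
  expect_equal(f$n_par, 0L)
  expect_equal(f$deviance, poisson_deviance(tab, m, "cvd"))
})

test_that("the fit recovers a known linear slope within 3 Wald SE", {
  cfg <- small_config()  # truth: ERR-linear, err = 0.2
  sc <- generate_table(cfg, seed = 31)
  f <- fit_risk_model(sc$table, lnt_spec(), "cvd", options = quick_opts)
  expect_true(f$converged)
  expect_true(f$cov_ok)
  expect_lt(abs(f$estimates[["dr.err"]] - 0.2),
            3 * f$wald_se[["dr.err"]])
  # deviance at the optimum does not exceed the deviance at the start
  expect_lte(f$deviance, poisson_deviance(sc$table, lnt_spec(), "cvd"))
})

test_that("Wald errors shrink as one over the square root of cohort size", {
  base <- small_config()
  big <- small_config(target_deaths = 4000 * 9)
  big$total_py <- 1.2e6 * 9
  f1 <- fit_risk_model(generate_table(base, seed = 41)$table, lnt_spec(),
                       "cvd", options = quick_opts)
  f9 <- fit_risk_model(generate_table(big, seed = 41)$table, lnt_spec(),
                       "cvd", options = quick_opts)
  ratio <- f1$wald_se[["dr.err"]] / f9$wald_se[["dr.err"]]
  expect_equal(unname(ratio), 3, tolerance = 0.15)
})

test_that("slope estimates are unbiased and Wald errors calibrated", {
  cfg <- small_config()
  est <- se <- numeric(100)
  for (r in 1:100) {
    tab <- generate_table(cfg, seed = 5000 + r)$table
    f <- fit_risk_model(tab, lnt_spec(), "cvd", options = quick_opts)
    est[r] <- f$estimates[["dr.err"]]
    se[r] <- f$wald_se[["dr.err"]]
  }
  # mean recovered slope within Monte-Carlo error of the truth
  expect_lt(abs(mean(est) - 0.2), 3 * sd(est) / sqrt(100))
  # empirical spread within 25% of the mean Wald error
  expect_lt(abs(sd(est) - mean(se)) / mean(se), 0.25)
})

test_that("the default threshold grid enumerates 27 doses", {
  g <- default_dth_grid()
  expect_length(g, 27L)
  expect_false(is.unsorted(g, strictly = TRUE))
  expect_equal(g[1], 1e-4)
  expect_equal(g[length(g)], 2)
  expect_true(all(c(5e-4, 1e-3, 5e-3, 0.01, 0.09, 0.1, 0.9, 1) %in% g))
})

test_that("a flat deviance profile emerges from zero-excess data", {
  cfg <- small_config(true_model = risk_model(
    "ERR", 1, baseline = list(intercept = log(3.3e-3), log_age_slope = 5),
    dose_response = list(err = 0), label = "null"))
  sc <- generate_table(cfg, seed = 17)
  m6 <- risk_model("ERR", 6,
                   baseline = list(intercept = log(3e-3),
                                   log_age_slope = 4),
                   dose_response = list(scale = 0.05, D_th = 0.1))
  pr <- profile_threshold(sc$table, m6, "cvd",
                          grid = c(0.01, 0.05, 0.1, 0.3, 0.5, 0.7, 1, 2),
                          options = quick_nohess)
  expect_lt(diff(range(pr$profile$deviance)), 3.84)
})

test_that("the likelihood-ratio rule matches chi-square quantiles", {
  b <- lrt_improves(100, 103.84, 1)
  expect_true(b$improves)  # the boundary counts as an improvement
  expect_equal(b$critical, qchisq(0.95, 1))
  expect_false(lrt_improves(100, 103.83, 1)$improves)
  expect_false(lrt_improves(100, 100, 1)$improves)
  expect_equal(lrt_improves(100, 108, 2)$critical, qchisq(0.95, 2))
  expect_equal(qchisq(0.95, 2), 5.99, tolerance = 1e-3)
  expect_equal(lrt_improves(100, 103.84, 1)$p_value,
               pchisq(3.84, 1, lower.tail = FALSE))
  expect_error(lrt_improves(100, 99, 1), "smaller deviance")
})

test_that("backward elimination drops a null term and keeps a real one", {
  truth <- risk_model(
    "ERR", 1,
    baseline = list(intercept = log(3.3e-3), log_age_slope = 5,
                    city = 0, sex = log(1.6)),
    dose_response = list(err = 0.2), label = "truth")
  cfg <- small_config(true_model = truth)
  spec <- risk_model(
    "ERR", 1,
    baseline = list(intercept = log(3e-3), log_age_slope = 4,
                    city = 0, sex = 0),
    dose_response = list(err = 0.1))
  dropped_city <- kept_sex <- logical(30)
  for (r in 1:30) {
    sc <- generate_table(cfg, seed = 7000 + r)
    sl <- streamline_baseline(sc$table, spec, "cvd",
                              options = quick_nohess)
    final <- sl$model$params
    dropped_city[r] <- !final$free[final$name == "bl.city"]
    kept_sex[r] <- final$free[final$name == "bl.sex"]
  }
  expect_gte(mean(dropped_city), 0.9)  # type-I-style: null city term out
  expect_equal(mean(kept_sex), 1)      # strong sex effect always retained
})

test_that("a one-parameter baseline yields a one-test audit trail", {
  cells <- tiny_cells()
  tab <- person_year_table(cells)
  m <- risk_model("ERR", 1,
                  baseline = list(intercept = log(3e-3), log_age_slope = 1),
                  dose_response = list(err = 0), fixed = "dr.err")
  sl <- streamline_baseline(tab, m, "cvd", options = quick_nohess)
  # only bl.log_age_slope is eliminable (intercept has no null value)
  expect_equal(nrow(sl$audit), 1L)
  expect_equal(sl$audit$parameter, "bl.log_age_slope")
  expect_true(sl$audit$decision %in% c("removed", "kept"))
})

test_that("deviance decomposition sums exactly to the total", {
  sc <- generate_table(small_config(), seed = 23)
  m <- lnt_spec(err = 0.25)
  dose_bins <- c(0, 0.1, 0.5, Inf)
  age_bins <- c(20, 60, 75, 100)
  dec <- deviance_decomposition(sc$table, m, "cvd", dose_bins, age_bins)
  expect_equal(sum(dec$deviance), poisson_deviance(sc$table, m, "cvd"))
  # one all-covering group equals the total
  dec1 <- deviance_decomposition(sc$table, m, "cvd", c(0, Inf), c(0, Inf))
  expect_equal(nrow(dec1), 1L)
  expect_equal(dec1$deviance, poisson_deviance(sc$table, m, "cvd"))
  # brute-force per-cell accumulation oracle
  tab <- sc$table
  lam <- expected_deaths(m, tab)
  d <- tab$deaths_cvd
  terms <- 2 * (ifelse(d > 0, d * log(d / lam), 0) - (d - lam))
  pick <- tab$mean_dose_gy >= 0.1 & tab$mean_dose_gy < 0.5 &
    tab$mean_age >= 60 & tab$mean_age < 75
  row <- dec[dec$dose_bin == "[0.1,0.5)" & dec$age_bin == "[60,75)", ]
  expect_equal(row$deviance, sum(terms[pick]))
  expect_equal(row$n_cells, sum(pick))
})

test_that("nested shapes never fit worse than their restrictions", {
  sc <- generate_table(small_config(), seed = 51)
  bl <- list(intercept = log(3e-3), log_age_slope = 4)
  f1 <- fit_risk_model(sc$table,
                       risk_model("ERR", 1, baseline = bl,
                                  dose_response = list(err = 0.1)),
                       "cvd", options = quick_nohess)
  f2 <- fit_risk_model(sc$table,
                       risk_model("ERR", 2, baseline = bl,
                                  dose_response = list(err = 0.05)),
                       "cvd", options = quick_nohess)
  f3 <- fit_risk_model(sc$table,
                       risk_model("ERR", 3, baseline = bl,
                                  dose_response = list(err1 = 0.1,
                                                       err2 = 0.01)),
                       "cvd", options = quick_nohess)
  tol <- 1e-4
  expect_lte(f3$deviance, f1$deviance + tol)
  expect_lte(f3$deviance, f2$deviance + tol)
})
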