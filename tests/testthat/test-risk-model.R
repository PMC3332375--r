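test_that("all-zero coefficients give unit baseline hazard", {
  m <- risk_model("ERR", 1,
                  baseline = list(intercept = 0, log_age_slope = 0,
                                  city = 0, sex = 0, agex = 0))
  expect_equal(baseline_hazard(m, "Hiroshima", "male", 70, 30), 1)
  expect_equal(baseline_hazard(m, "Nagasaki", "female", 45, 10), 1)
})

test_that("baseline log-hazard is continuous at knots", {
  m <- risk_model("ERR", 1,
                  baseline = list(intercept = 0, log_age_slope = 1,
                                  knots = 70, knot_slopes = 1))
  lo <- baseline_hazard(m, "Hiroshima", "male", 70 - 1e-9, 30)
  hi <- baseline_hazard(m, "Hiroshima", "male", 70 + 1e-9, 30)
  expect_equal(lo, hi, tolerance = 1e-7)
  expect_error(baseline_hazard(m, "Hiroshima", "male", -1, 30),
               "attained age")
})

test_that("baseline matches direct evaluation of the log-linear formula", {
  set.seed(101)
  for (rep in 1:5) {
    co <- rnorm(6, sd = 0.5)
    knots <- sort(runif(2, 50, 80))
    ks <- rnorm(2, sd = 0.3)
    m <- risk_model("ERR", 1,
                    baseline = list(intercept = co[1], log_age_slope = co[2],
                                    city = co[3], sex = co[4], agex = co[5],
                                    knots = knots, knot_slopes = ks))
    a <- runif(10, 30, 95); e <- runif(10, 5, 40)
    city <- sample(c("Hiroshima", "Nagasaki"), 10, replace = TRUE)
    sex <- sample(c("male", "female"), 10, replace = TRUE)
    # independent re-evaluation written out long-hand
    expect_lh <- co[1] + co[2] * log(a / 70) +
      co[3] * (city == "Nagasaki") + co[4] * (sex == "female") +
      co[5] * (e - 30) / 10 +
      ks[1] * pmax(0, log(a) - log(knots[1])) +
      ks[2] * pmax(0, log(a) - log(knots[2]))
    expect_equal(baseline_hazard(m, city, sex, a, e), exp(expect_lh))
  }
})

test_that("each shape evaluates its printed formula", {
  # linear no-threshold at the published CVD slope
  expect_equal(dose_response_value(1, c(err = 0.124), c(1, 0.2)),
               c(0.124, 0.0248))
  # quadratic: 1.12 * err * D^2, with err chosen so the 1 Gy value is 0.071
  err_q <- 0.071 / 1.12
  expect_equal(dose_response_value(2, c(err = err_q), c(1, 0.2)),
               c(0.071, 2.84e-3))
  # alternative dose-squared adjustment factor is honoured
  expect_equal(dose_response_value(2, c(err = 1), 1,
                                   dose2_adjustment = 1.15), 1.15)
  # smoothed step at the published reanalysis estimates
  p6 <- c(scale = 0.204, tanh_slope = 1e5, D_th = 0.64)
  expect_equal(dose_response_value(6, p6, 1), 0.204)
  expect_equal(dose_response_value(6, p6, 0.3), 0)
  expect_equal(dose_response_value(6, p6, 0.64), 0.102)
  # linear-exponential, long-hand oracle
  p4 <- c(err1 = 0.05, err2 = 0.2, err3 = 0.3)
  D <- c(0, 0.5, 1, 2)
  expect_equal(dose_response_value(4, p4, D),
               (0.05 + 0.2 * D) * exp(-0.3 * D^2))
  # step with slope jumps by err * D_th at the threshold
  p7 <- c(err = 0.3, D_th = 0.5)
  expect_equal(dose_response_value(7, p7, 0.5 - 1e-12), 0)
  expect_equal(dose_response_value(7, p7, 0.5), 0.15)
  # step with slope and offset
  p8 <- c(err1 = 0.1, err2 = 0.2, D_th = 0.5)
  expect_equal(dose_response_value(8, p8, c(0.4, 0.5, 1)),
               c(0, 0.1, 0.1 + 0.2 * 0.5))
  # hormesis-like: exactly zero below the 5 mGy floor
  p9 <- c(err1 = -0.05, err2 = 0.2, D_th = 0.5)
  expect_equal(dose_response_value(9, p9, c(0.004, 0.1, 0.9)),
               c(0, -0.05, 0.2))
  p10 <- c(err1 = -0.05, err2 = 0.2, D_th = 0.5)
  expect_equal(dose_response_value(10, p10, c(0.004, 0.1, 0.5, 1)),
               c(0, -0.05, -0.05, -0.05 + 0.2 * 0.5))
  # categorical
  p11 <- c(err1 = 0.01, err2 = 0.1, err3 = 0.2, err4 = 0.3,
           D1 = 0.62, D2 = 1, D3 = 1.5)
  expect_equal(dose_response_value(11, p11, c(0, 0.62, 1.2, 2)),
               c(0.01, 0.1, 0.2, 0.3))
  # zero dose gives zero excess for shapes 1-10 (11 returns err1)
  for (sh in 1:2) {
    expect_equal(dose_response_value(sh, c(err = 0.5), 0), 0)
  }
  expect_equal(dose_response_value(5, c(err = 0.5, D_th = 0.3), 0), 0)
  expect_equal(dose_response_value(9, p9, 0), 0)
  expect_error(dose_response_value(1, c(scale = 1), 1), "requires")
  expect_error(dose_response_value(1, c(err = 1), -0.1), "dose")
})

test_that("shape nesting restrictions agree exactly", {
  D <- c(0, 0.1, 0.5, 1, 2)
  expect_equal(dose_response_value(3, c(err1 = 0.2, err2 = 0), D),
               dose_response_value(1, c(err = 0.2), D))
  expect_equal(dose_response_value(3, c(err1 = 0, err2 = 0.1), D),
               dose_response_value(2, c(err = 0.1), D))
  expect_equal(dose_response_value(5, c(err = 0.2, D_th = 0), D),
               dose_response_value(1, c(err = 0.2), D))
})

test_that("shape 5 and 10 are continuous at the threshold, 7 is not", {
  eps <- 1e-9
  p5 <- c(err = 0.4, D_th = 0.6)
  expect_equal(dose_response_value(5, p5, 0.6 + eps),
               dose_response_value(5, p5, 0.6 - eps), tolerance = 1e-6)
  expect_equal(dose_response_value(5, p5, 0.6), 0)
  p10 <- c(err1 = -0.03, err2 = 0.4, D_th = 0.6)
  expect_equal(dose_response_value(10, p10, 0.6 + eps),
               dose_response_value(10, p10, 0.6 - eps), tolerance = 1e-6)
  p7 <- c(err = 0.4, D_th = 0.6)
  jump <- dose_response_value(7, p7, 0.6) -
    dose_response_value(7, p7, 0.6 - eps)
  expect_equal(jump, 0.4 * 0.6, tolerance = 1e-6)
})

test_that("steep tanh matches a hard step away from the threshold", {
  p6 <- c(scale = 0.3, tanh_slope = 1e5, D_th = 0.62)
  D <- c(seq(0, 0.619, by = 0.01), seq(0.621, 2, by = 0.01))
  hard <- ifelse(D < 0.62, 0, 0.3)
  expect_lt(max(abs(dose_response_value(6, p6, D) - hard)), 1e-6)
})

test_that("modifier terms multiply and default to one", {
  m0 <- risk_model("ERR", 1)
  expect_equal(modifier_value(m0, "female", 45, 10), 1)
  m <- risk_model("ERR", 1,
                  modifier = list(sex = log(2), log_age = 2, agex = -0.1))
  expect_equal(modifier_value(m, "male", 70, 30), 1)  # centred covariates
  expect_equal(modifier_value(m, "female", 70, 30) /
                 modifier_value(m, "male", 70, 30), 2)
  # long-hand oracle
  expect_equal(modifier_value(m, "female", 56, 40),
               exp(log(2)) * (56 / 70)^2 * exp(-0.1 * (40 - 30) / 10))
  expect_gt(modifier_value(m, "female", 30, 5), 0)
})

test_that("total hazard composes ERR and EAR transfers", {
  bl <- list(intercept = log(2e-3), log_age_slope = 0)
  m_err <- risk_model("ERR", 1, baseline = bl,
                      dose_response = list(err = 0.165))
  expect_equal(total_hazard(m_err, "Hiroshima", "male", 70, 30, 1),
               2e-3 * 1.165)
  m_ear <- risk_model("EAR", 1, baseline = bl,
                      dose_response = list(err = 5e-4))
  expect_equal(total_hazard(m_ear, "Hiroshima", "male", 70, 30, 1), 2.5e-3)
  # null excess reduces both transfers to the baseline
  m0 <- risk_model("EAR", 1, baseline = bl, dose_response = list(err = 0))
  expect_equal(total_hazard(m0, "Hiroshima", "male", 70, 30, 2), 2e-3)
  # inadmissible ERR raises
  m_neg <- risk_model("ERR", 1, baseline = bl,
                      dose_response = list(err = -2))
  expect_error(total_hazard(m_neg, "Hiroshima", "male", 70, 30, 1),
               "non-positive")
})

test_that("risk estimates follow ERR = h/h0 - 1 and EAR = h - h0", {
  bl <- list(intercept = log(2e-3), log_age_slope = 0)
  m <- risk_model("ERR", 1, baseline = bl,
                  dose_response = list(err = 0.165))
  r <- risk_estimates(m, "Hiroshima", "male", 70, 30, 1)
  expect_equal(r$ERR, 0.165)
  expect_equal(r$EAR, 2e-3 * 0.165)
  r0 <- risk_estimates(m, "Hiroshima", "male", 70, 30, 0)
  expect_equal(r0$ERR, 0)
  expect_equal(r0$EAR, 0)
  # EAR transfer: implied ERR is EAR / h0 (8.8 vs 51.5 per 1e4 PY)
  m2 <- risk_model("EAR", 1,
                   baseline = list(intercept = log(51.5e-4),
                                   log_age_slope = 0),
                   dose_response = list(err = 8.8e-4))
  r2 <- risk_estimates(m2, "Hiroshima", "male", 70, 30, 1)
  expect_equal(r2$ERR, 8.8 / 51.5, tolerance = 1e-12)
})

test_that("group conversion factors are baseline hazard ratios", {
  # jitter-free grid so age distributions match exactly across groups
  tab <- generate_table(synthetic_config(age_jitter_sd = 0), seed = 9)$table
  m_nosex <- risk_model("ERR", 1,
                        baseline = list(intercept = log(3e-3),
                                        log_age_slope = 4))
  expect_equal(group_conversion_factor(m_nosex, tab,
                                       from = list(sex = "male"),
                                       to = list(sex = "male")), 1)
  # no city term and a city-balanced grid: Hiroshima -> all is exactly 1
  expect_equal(group_conversion_factor(m_nosex, tab,
                                       from = list(city = "Hiroshima"),
                                       to = list()), 1)
  # a pure female log-offset of ln(0.6) converts male to female by 0.6
  m_sex <- risk_model("ERR", 1,
                      baseline = list(intercept = log(3e-3),
                                      log_age_slope = 4, sex = log(0.6)))
  expect_equal(group_conversion_factor(m_sex, tab,
                                       from = list(sex = "male"),
                                       to = list(sex = "female")), 0.6)
  expect_error(group_conversion_factor(m_sex, tab,
                                       from = list(city = "Kyoto"),
                                       to = list()), "empty")
})

test_that("model construction validates shape parameters", {
  expect_error(risk_model("ERR", 6, dose_response = list(tanh_slope = -1)),
               "tanh_slope")
  expect_error(risk_model("ERR", 11,
                          dose_response = list(D1 = 1, D2 = 0.5, D3 = 2)),
               "D1 < D2 < D3")
  expect_error(risk_model("ERR", 1, dose_response = list(scale = 1)),
               "do not belong")
  m <- risk_model("ERR", 5, dose_response = list(err = 0.1, D_th = 0.2))
  expect_false(m$params$free[m$params$name == "dr.D_th"])
  v <- param_values(m)
  expect_equal(unname(v[["dr.D_th"]]), 0.2)
  m2 <- set_param_values(m, c(dr.err = 0.5))
  expect_equal(unname(param_values(m2)[["dr.err"]]), 0.5)
  expect_error(set_param_values(m, c(nope = 1)), "unknown parameter")
})
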