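#' Configure a synthetic LSS-like cohort
#'
#' Describes the strata grid, the person-year allocation and the true
#' hazard from which a grouped person-year mortality table is simulated.
#' The defaults emulate the published cohort's scale and structure:
#' about 1.2 million person-years spread over two cities, two sexes,
#' age-at-exposure and attained-age bands and calendar periods; a dose
#' distribution heavily concentrated at low doses (category means
#' 0.0025-2.5 Gy with person-year weights 0.55 down to 0.01); and a
#' baseline hazard rising log-linearly in `ln(attained age)` scaled so
#' that the expected death count per endpoint is about 4,000.
#'
#' @param cities,city_weights city labels and person-year shares.
#' @param sexes,sex_weights sex labels and person-year shares (women
#'   carry the larger share, as in the cohort emulated).
#' @param agex_breaks age-at-exposure band boundaries (years).
#' @param agex_weights person-year share per age-at-exposure band.
#' @param age_breaks attained-age band boundaries (years).
#' @param age_weights person-year share per attained-age band.
#' @param n_periods number of calendar periods (uniform shares).
#' @param dose_means representative mean dose (Gy) per dose category,
#'   ascending, non-negative.
#' @param dose_weights person-year share per dose category.
#' @param total_py total person-years across all cells.
#' @param target_deaths expected baseline death count the true intercept
#'   is calibrated to (per cause).
#' @param true_model the true [risk_model()] generating the death counts.
#' @param causes cause labels (every cause uses the same true hazard).
#' @param min_latency years between exposure and the start of follow-up;
#'   strata combinations with attained age below age at exposure plus
#'   this latency are dropped (keeps `mean_agex <= mean_age`).
#' @param age_jitter_sd uniform half-width (years) of the jitter applied
#'   to cell mean ages, emulating person-year-weighted means that do not
#'   sit exactly at band midpoints.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(cities = c("Hiroshima", "Nagasaki"),
                             city_weights = c(0.65, 0.35),
                             sexes = c("male", "female"),
                             sex_weights = c(0.38, 0.62),
                             agex_breaks = c(0, 10, 20, 30, 40, 60),
                             agex_weights = c(0.25, 0.25, 0.2, 0.2, 0.1),
                             age_breaks = c(25, 40, 50, 60, 70, 80, 95),
                             age_weights = c(0.08, 0.15, 0.2, 0.25, 0.2,
                                             0.12),
                             n_periods = 3L,
                             dose_means = c(0.0025, 0.03, 0.2, 0.75, 1.5,
                                            2.5),
                             dose_weights = c(0.55, 0.25, 0.12, 0.05, 0.02,
                                              0.01),
                             total_py = 1.2e6,
                             target_deaths = 4000,
                             true_model = NULL,
                             causes = "cvd",
                             min_latency = 23,
                             age_jitter_sd = 1) {
  stopifnot(length(cities) == length(city_weights),
            length(sexes) == length(sex_weights),
            length(agex_breaks) == length(agex_weights) + 1L,
            length(age_breaks) == length(age_weights) + 1L,
            length(dose_means) == length(dose_weights),
            all(dose_means >= 0), !is.unsorted(dose_means, strictly = TRUE),
            total_py > 0, target_deaths > 0, n_periods >= 1L)
  norm <- function(w) {
    stopifnot(all(w > 0))
    w / sum(w)
  }
  if (is.null(true_model)) {
    true_model <- risk_model(
      transfer = "ERR", shape = 1L,
      baseline = list(intercept = log(3.3e-3), log_age_slope = 5,
                      city = 0, sex = 0),
      dose_response = list(err = 0.2),
      label = "truth")
  }
  structure(list(cities = cities, city_weights = norm(city_weights),
                 sexes = sexes, sex_weights = norm(sex_weights),
                 agex_breaks = agex_breaks, agex_weights = norm(agex_weights),
                 age_breaks = age_breaks, age_weights = norm(age_weights),
                 n_periods = as.integer(n_periods),
                 dose_means = dose_means, dose_weights = norm(dose_weights),
                 total_py = total_py, target_deaths = target_deaths,
                 true_model = true_model, causes = causes,
                 min_latency = min_latency, age_jitter_sd = age_jitter_sd),
            class = "synthetic_config")
}

.mids <- function(breaks) (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2

# deterministic strata grid with person-year allocation (no randomness)
.synthetic_grid <- function(config) {
  c_ <- config
  grid <- expand.grid(
    dosecat = seq_along(c_$dose_means),
    periodcat = seq_len(c_$n_periods),
    agecat = seq_along(c_$age_weights),
    agexcat = seq_along(c_$agex_weights),
    sex = c_$sexes, city = c_$cities,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  agex_mid <- .mids(c_$agex_breaks)
  age_mid <- .mids(c_$age_breaks)
  grid$mean_agex <- agex_mid[grid$agexcat]
  grid$mean_age <- age_mid[grid$agecat]
  grid <- grid[grid$mean_age >= grid$mean_agex + c_$min_latency, ,
               drop = FALSE]
  w <- c_$city_weights[match(grid$city, c_$cities)] *
    c_$sex_weights[match(grid$sex, c_$sexes)] *
    c_$agex_weights[grid$agexcat] *
    c_$age_weights[grid$agecat] *
    c_$dose_weights[grid$dosecat] / c_$n_periods
  grid$pyr <- c_$total_py * w / sum(w)
  grid$mean_dose_gy <- c_$dose_means[grid$dosecat]
  rownames(grid) <- NULL
  grid
}

#' Generate a synthetic grouped person-year table with known truth
#'
#' Builds the strata grid deterministically, allocates person-years from
#' the configured weights, jitters the cell mean ages (sub-streamed from
#' the seed so jitter and death draws are independent), calibrates the
#' true baseline intercept so the expected baseline death count matches
#' `target_deaths`, and draws death counts `Poisson(h_true * pyr)` per
#' cause.  A fixed seed reproduces the table exactly.
#'
#' @param config a [synthetic_config()].
#' @param seed integer seed.
#' @return list of class `synthetic_cohort` with `table` (a
#'   [person_year_table()]), `truth` (list: calibrated `model`, per-cell
#'   expected deaths `lambda`, `expected_total`, `seed`), and `config`.
#' @export
generate_table <- function(config, seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  grid <- .synthetic_grid(config)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 2L)

  set.seed(sub[1])  # jitter sub-stream
  j <- config$age_jitter_sd
  grid$mean_age <- grid$mean_age + stats::runif(nrow(grid), -j, j)
  grid$mean_agex <- pmax(0.5, grid$mean_agex + stats::runif(nrow(grid), -j, j))
  grid$mean_agex <- pmin(grid$mean_agex,
                         grid$mean_age - config$min_latency)

  truth <- .calibrate_truth(config, grid)
  lambda <- expected_deaths(truth, grid)
  if (sum(lambda) < 1) {
    warning("aggregate expected deaths below 1; fits will be unstable",
            call. = FALSE)
  }

  set.seed(sub[2])  # death-count sub-stream
  for (cause in config$causes) {
    grid[[paste0("deaths_", cause)]] <- stats::rpois(nrow(grid), lambda)
  }
  table <- person_year_table(
    grid[, c(.pyt_key_cols, .pyt_num_cols,
             paste0("deaths_", config$causes))],
    causes = config$causes,
    provenance = paste0("synthetic cohort, seed ", seed))
  structure(list(table = table,
                 truth = list(model = truth, lambda = lambda,
                              expected_total = sum(lambda), seed = seed),
                 config = config),
            class = "synthetic_cohort")
}

# scale the true intercept so expected *baseline* deaths hit the target
.calibrate_truth <- function(config, grid) {
  m <- config$true_model
  h0 <- baseline_hazard(m, grid$city, grid$sex, grid$mean_age,
                        grid$mean_agex)
  shift <- log(config$target_deaths / sum(h0 * grid$pyr))
  set_param_values(m, c(bl.intercept =
                          unname(param_values(m)[["bl.intercept"]]) + shift))
}

#' Expected death counts under a hazard model
#'
#' The generator's Poisson mean per cell, `h(cell) * pyr`, exposed for
#' oracle testing: summing it over cells gives the aggregate expectation
#' that [generate_table()]'s draws fluctuate around.
#'
#' @param model a `risk_model` (e.g. the calibrated truth from
#'   [generate_table()]).
#' @param table a person-year table or cell data frame with the canonical
#'   columns.
#' @return vector of expected deaths per cell.
#' @export
expected_deaths <- function(model, table) {
  .cell_lambda(model, .as_parlist(param_values(model)), table)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort (seed ", x$truth$seed, ")\n", sep = "")
  print(x$table)
  cat("  expected deaths under truth: ",
      format(x$truth$expected_total, digits = 6), "\n", sep = "")
  invisible(x)
}
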