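#' Hazard models for radiation dose-response analysis
#'
#' A risk model composes a log-linear baseline hazard `h0(city, sex, a, e)`
#' with an excess term built from one of eleven candidate dose-response
#' shapes and an optional dose-effect modifier `eps(sex, a, e)`:
#'
#' * ERR transfer: `h = h0 * (1 + err(D) * eps)`
#' * EAR transfer: `h = h0 + ear(D) * eps`
#'
#' The baseline is piecewise log-linear in `ln(attained age)` (continuous
#' at every knot by construction), with additive city, sex and
#' age-at-exposure terms on the log scale.  All parameters live in a flat
#' named table with free/fixed flags and null values, which is what the
#' fitting and streamlining machinery operates on.
#'
#' @name risk_model_family
NULL

.dr_par_names <- list(
  `1` = "dr.err",
  `2` = "dr.err",
  `3` = c("dr.err1", "dr.err2"),
  `4` = c("dr.err1", "dr.err2", "dr.err3"),
  `5` = c("dr.err", "dr.D_th"),
  `6` = c("dr.scale", "dr.tanh_slope", "dr.D_th"),
  `7` = c("dr.err", "dr.D_th"),
  `8` = c("dr.err1", "dr.err2", "dr.D_th"),
  `9` = c("dr.err1", "dr.err2", "dr.D_th"),
  `10` = c("dr.err1", "dr.err2", "dr.D_th"),
  `11` = c("dr.err1", "dr.err2", "dr.err3", "dr.err4",
           "dr.D1", "dr.D2", "dr.D3")
)

.dr_defaults <- c(dr.err = 0.1, dr.err1 = 0.1, dr.err2 = 0.05,
                  dr.err3 = 0.1, dr.err4 = 0.1, dr.scale = 0.2,
                  dr.tanh_slope = 1e5, dr.D_th = 0.1,
                  dr.D1 = 0.62, dr.D2 = 1, dr.D3 = 1.5)

# parameters never adjusted by the optimizer unless explicitly freed
.default_fixed <- c("dr.tanh_slope", "dr.D_th", "dr.D1", "dr.D2", "dr.D3")

#' Specify a risk model
#'
#' @param transfer `"ERR"` (multiplicative excess) or `"EAR"` (additive
#'   excess).
#' @param shape dose-response shape id, 1-11: 1 linear no-threshold,
#'   2 quadratic, 3 linear-quadratic, 4 linear-exponential, 5 linear
#'   threshold, 6 tanh-smoothed step, 7 step with slope through the
#'   origin, 8 step with slope and offset, 9 hormesis-like step,
#'   10 hormesis-like with slope, 11 three-step categorical.
#' @param baseline named list of baseline terms.  `intercept` (log hazard
#'   at the reference covariates, always present) and `log_age_slope`
#'   (slope on `ln(a/70)`) default in; optional terms are `city` (additive
#'   log-hazard offset for the second city), `sex` (offset for females),
#'   `agex` (coefficient per decade of `(e - 30)`), `knots` (vector of
#'   knot ages in years) and `knot_slopes` (slope changes above each
#'   knot).  Supplying a value includes the term with that initial value.
#' @param dose_response named list of dose-response parameter initial
#'   values; unnamed shapes get documented defaults.  Names without the
#'   `dr.` prefix: `err`, `err1`..`err4`, `scale`, `tanh_slope` (Gy^-1,
#'   default 1e5), `D_th` (Gy), `D1` < `D2` < `D3` (Gy).
#' @param modifier named list of dose-effect modifier terms, each included
#'   only if supplied: `sex` (log factor for females), `log_age` (power
#'   `eta` on `a/70`), `agex` (coefficient per decade of `(e - 30)`).
#' @param fixed character vector of parameter names to hold fixed during
#'   fitting (in addition to the defaults: `dr.tanh_slope`, `dr.D_th`,
#'   `dr.D1`..`dr.D3`, and all knot positions).
#' @param free character vector of parameter names to force free.
#' @param dose2_adjustment multiplier on the dose-squared coefficient in
#'   shapes 2 and 3 compensating dosimetric random error; 1.12 by
#'   convention (1.15 is the published alternative).
#' @param hormesis_floor Gy below which shapes 9 and 10 return exactly 0;
#'   fixed at 0.005 Gy.
#' @param modifier_on_categorical logical; whether shape 11 is multiplied
#'   by the modifier (default `FALSE`: purely categorical).
#' @param label optional model label used in score tables.
#' @return an object of class `risk_model`.
#' @export
risk_model <- function(transfer = c("ERR", "EAR"),
                       shape = 1L,
                       baseline = list(),
                       dose_response = list(),
                       modifier = list(),
                       fixed = character(),
                       free = character(),
                       dose2_adjustment = 1.12,
                       hormesis_floor = 0.005,
                       modifier_on_categorical = FALSE,
                       label = NULL) {
  transfer <- match.arg(transfer)
  shape <- as.integer(shape)
  stopifnot(shape >= 1L, shape <= 11L)

  rows <- list()
  add <- function(name, value, free = TRUE, null = 0, component) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, value = as.numeric(value), free = free,
      null = as.numeric(null), component = component,
      stringsAsFactors = FALSE)
  }

  bl <- utils::modifyList(list(intercept = log(3e-3), log_age_slope = 5),
                          baseline)
  add("bl.intercept", bl$intercept, TRUE, NA_real_, "baseline")
  add("bl.log_age_slope", bl$log_age_slope, TRUE, 0, "baseline")
  for (term in c("city", "sex", "agex")) {
    if (!is.null(bl[[term]])) add(paste0("bl.", term), bl[[term]], TRUE, 0,
                                  "baseline")
  }
  n_knots <- length(bl$knots %||% numeric(0))
  if (n_knots > 0L) {
    slopes <- bl$knot_slopes %||% rep(0, n_knots)
    stopifnot(length(slopes) == n_knots)
    if (is.unsorted(bl$knots, strictly = TRUE) || any(bl$knots <= 0)) {
      stop("baseline knots must be positive and strictly increasing",
           call. = FALSE)
    }
    for (j in seq_len(n_knots)) {
      add(paste0("bl.knot", j), bl$knots[j], FALSE, NA_real_, "baseline")
      add(paste0("bl.knot_slope", j), slopes[j], TRUE, 0, "baseline")
    }
  }

  for (term in c("sex", "log_age", "agex")) {
    if (!is.null(modifier[[term]])) {
      add(paste0("mod.", term), modifier[[term]], TRUE, 0, "modifier")
    }
  }

  dr_names <- .dr_par_names[[as.character(shape)]]
  dr_in <- dose_response
  if (length(dr_in) > 0L) {
    names(dr_in) <- ifelse(grepl("^dr\\.", names(dr_in)), names(dr_in),
                           paste0("dr.", names(dr_in)))
  }
  unknown <- setdiff(names(dr_in), dr_names)
  if (length(unknown) > 0L) {
    stop("dose-response parameter(s) ", paste(unknown, collapse = ", "),
         " do not belong to shape #", shape, call. = FALSE)
  }
  for (nm in dr_names) {
    val <- if (nm %in% names(dr_in)) dr_in[[nm]] else .dr_defaults[[nm]]
    add(nm, val, !(nm %in% .default_fixed), 0, "dose")
  }

  params <- do.call(rbind, rows)
  params$free[params$name %in% fixed] <- FALSE
  params$free[params$name %in% free] <- TRUE

  m <- structure(
    list(transfer = transfer, shape = shape, params = params,
         n_knots = n_knots, dose2_adjustment = dose2_adjustment,
         hormesis_floor = hormesis_floor,
         modifier_on_categorical = modifier_on_categorical,
         label = label %||% paste0(transfer, "-shape", shape)),
    class = "risk_model")
  .check_structural(m)
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_structural <- function(m) {
  p <- param_values(m)
  if (m$shape %in% c(5:10) && .pg(p, "dr.D_th") < 0) {
    stop("D_th must be >= 0", call. = FALSE)
  }
  if (m$shape == 6L && .pg(p, "dr.tanh_slope") <= 0) {
    stop("tanh_slope must be > 0", call. = FALSE)
  }
  if (m$shape == 11L) {
    b <- c(.pg(p, "dr.D1"), .pg(p, "dr.D2"), .pg(p, "dr.D3"))
    if (is.unsorted(b, strictly = TRUE)) {
      stop("categorical boundaries must satisfy D1 < D2 < D3", call. = FALSE)
    }
  }
  invisible(m)
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Risk model '", x$label, "': ", x$transfer, " transfer, shape #",
      x$shape, "\n", sep = "")
  p <- x$params
  cat(sprintf("  %-18s %12s  %s\n", "parameter", "value", "free"))
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %-18s %12.6g  %s\n", p$name[i], p$value[i],
                if (p$free[i]) "free" else "fixed"))
  }
  invisible(x)
}

#' Extract the flat parameter vector of a model
#'
#' @param model a `risk_model`.
#' @param free_only return only free parameters.
#' @return named numeric vector.
#' @export
param_values <- function(model, free_only = FALSE) {
  p <- model$params
  if (free_only) p <- p[p$free, , drop = FALSE]
  stats::setNames(p$value, p$name)
}

#' Replace parameter values in a model
#'
#' @param model a `risk_model`.
#' @param values named numeric vector; names must be existing parameters.
#' @return the updated model.
#' @export
set_param_values <- function(model, values) {
  idx <- match(names(values), model$params$name)
  if (anyNA(idx)) {
    stop("unknown parameter(s): ",
         paste(names(values)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  model$params$value[idx] <- as.numeric(values)
  model
}

# `pars` below is a named list/vector whose elements may be scalars or
# vectors (one entry per posterior draw); arithmetic recycles against the
# covariates, so the same evaluators serve cell-wise fitting (scalar
# parameters, vector covariates) and draw-wise uncertainty propagation
# (vector parameters, scalar covariates).
.pg <- function(pars, name, default = NULL) {
  if (name %in% names(pars)) {
    v <- pars[[name]]
    if (is.null(v)) default else v
  } else default
}

.as_parlist <- function(x) {
  if (is.list(x)) x else as.list(x)
}

.log_baseline <- function(model, pars, city, sex, a, e) {
  if (any(a <= 0)) stop("attained age must be > 0", call. = FALSE)
  lh <- .pg(pars, "bl.intercept") +
    .pg(pars, "bl.log_age_slope", 0) * log(a / 70)
  cty <- .pg(pars, "bl.city")
  if (!is.null(cty)) lh <- lh + cty * (city == "Nagasaki")
  sx <- .pg(pars, "bl.sex")
  if (!is.null(sx)) lh <- lh + sx * (sex == "female")
  gx <- .pg(pars, "bl.agex")
  if (!is.null(gx)) lh <- lh + gx * (e - 30) / 10
  if (model$n_knots > 0L) {
    for (j in seq_len(model$n_knots)) {
      kj <- .pg(pars, paste0("bl.knot", j))
      sj <- .pg(pars, paste0("bl.knot_slope", j))
      lh <- lh + sj * pmax(0, log(a) - log(kj))
    }
  }
  lh
}

#' Baseline hazard
#'
#' Evaluates the log-linear baseline `h0`: piecewise linear in
#' `ln(attained age)` and continuous at every knot, with additive city,
#' sex and age-at-exposure terms on the log scale.  Strictly positive by
#' construction.
#'
#' @param model a `risk_model`.
#' @param city,sex covariate values (`"Hiroshima"`/`"Nagasaki"`,
#'   `"male"`/`"female"`); vectors recycle.
#' @param a attained age in years (> 0).
#' @param e age at exposure in years.
#' @return hazard in deaths per person-year.
#' @export
baseline_hazard <- function(model, city, sex, a, e) {
  exp(.log_baseline(model, .as_parlist(param_values(model)), city, sex, a, e))
}

#' Dose-effect modifier
#'
#' The multiplicative modifier
#' `eps(s, a, e) = exp(theta_s 1[female]) * (a/70)^eta * exp(gamma (e-30)/10)`
#' with each term present only if included in the model; identically 1
#' when all are excluded.  Always strictly positive.
#'
#' @inheritParams baseline_hazard
#' @return positive dimensionless factor.
#' @export
modifier_value <- function(model, sex, a, e) {
  .modifier(model, .as_parlist(param_values(model)), sex, a, e)
}

.modifier <- function(model, pars, sex, a, e) {
  eps <- 1
  th <- .pg(pars, "mod.sex")
  if (!is.null(th)) eps <- eps * exp(th * (sex == "female"))
  eta <- .pg(pars, "mod.log_age")
  if (!is.null(eta)) eps <- eps * (a / 70)^eta
  g <- .pg(pars, "mod.agex")
  if (!is.null(g)) eps <- eps * exp(g * (e - 30) / 10)
  eps
}

#' Evaluate a dose-response shape
#'
#' The excess term `err(D)` (or `ear(D)`) for the eleven candidate
#' shapes.  This is the workhorse behind [excess_dose_response()] and is
#' exported so shapes can be evaluated from bare parameter sets (e.g.
#' published point estimates) without building a full hazard model.
#'
#' @param shape shape id 1-11 (see [risk_model()]).
#' @param pars named list or vector of shape parameters (`err`,
#'   `err1`..`err4`, `scale`, `tanh_slope`, `D_th`, `D1`..`D3`; the `dr.`
#'   prefix is optional).
#' @param D dose in Gy (vector allowed, >= 0).
#' @param dose2_adjustment dose-squared adjustment factor (shapes 2, 3).
#' @param hormesis_floor Gy below which shapes 9 and 10 are exactly 0.
#' @return dimensionless excess, same length as `D` (after recycling
#'   against vector-valued parameters).
#' @export
dose_response_value <- function(shape, pars, D, dose2_adjustment = 1.12,
                                hormesis_floor = 0.005) {
  if (any(D < 0)) stop("dose must be >= 0", call. = FALSE)
  pars <- .as_parlist(pars)
  names(pars) <- ifelse(grepl("^dr\\.", names(pars)), names(pars),
                        paste0("dr.", names(pars)))
  g <- function(nm) {
    v <- .pg(pars, nm)
    if (is.null(v)) stop("shape #", shape, " requires parameter '",
                         sub("^dr\\.", "", nm), "'", call. = FALSE)
    v
  }
  switch(as.character(shape),
    "1" = g("dr.err") * D,
    "2" = dose2_adjustment * g("dr.err") * D^2,
    "3" = g("dr.err1") * D + dose2_adjustment * g("dr.err2") * D^2,
    "4" = (g("dr.err1") + g("dr.err2") * D) * exp(-g("dr.err3") * D^2),
    "5" = ifelse(D < g("dr.D_th"), 0, g("dr.err") * (D - g("dr.D_th"))),
    "6" = 0.5 * g("dr.scale") *
      (tanh(g("dr.tanh_slope") * (D - g("dr.D_th"))) + 1),
    "7" = ifelse(D < g("dr.D_th"), 0, g("dr.err") * D),
    "8" = ifelse(D < g("dr.D_th"), 0,
                 g("dr.err1") + g("dr.err2") * (D - g("dr.D_th"))),
    "9" = ifelse(D < hormesis_floor, 0,
                 ifelse(D < g("dr.D_th"), g("dr.err1"), g("dr.err2"))),
    "10" = ifelse(D < hormesis_floor, 0,
                  ifelse(D < g("dr.D_th"), g("dr.err1"),
                         g("dr.err1") + g("dr.err2") * (D - g("dr.D_th")))),
    "11" = ifelse(D < g("dr.D1"), g("dr.err1"),
                  ifelse(D < g("dr.D2"), g("dr.err2"),
                         ifelse(D < g("dr.D3"), g("dr.err3"),
                                g("dr.err4")))),
    stop("unknown shape id: ", shape, call. = FALSE))
}

#' Excess dose-response of a model
#'
#' @param model a `risk_model`.
#' @param D dose in Gy (vector allowed).
#' @return `err(D)` or `ear(D)` at the model's current parameter values.
#' @export
excess_dose_response <- function(model, D) {
  .excess(model, .as_parlist(param_values(model)), D)
}

.excess <- function(model, pars, D) {
  dose_response_value(model$shape, pars, D,
                      dose2_adjustment = model$dose2_adjustment,
                      hormesis_floor = model$hormesis_floor)
}

.total_hazard <- function(model, pars, city, sex, a, e, D) {
  h0 <- exp(.log_baseline(model, pars, city, sex, a, e))
  ex <- .excess(model, pars, D)
  eps <- if (model$shape == 11L && !model$modifier_on_categorical) 1
         else .modifier(model, pars, sex, a, e)
  if (model$transfer == "ERR") h0 * (1 + ex * eps) else h0 + ex * eps
}

#' Total hazard
#'
#' `h = h0 (1 + err(D) eps)` for ERR transfer, `h = h0 + ear(D) eps` for
#' EAR transfer.  A non-positive result signals inadmissible parameters
#' and raises an error.
#'
#' @inheritParams baseline_hazard
#' @param D dose in Gy.
#' @return hazard in deaths per person-year.
#' @export
total_hazard <- function(model, city, sex, a, e, D) {
  h <- .total_hazard(model, .as_parlist(param_values(model)),
                     city, sex, a, e, D)
  if (any(h <= 0)) {
    stop("total hazard is non-positive: inadmissible parameters",
         call. = FALSE)
  }
  h
}

#' Excess relative and absolute risk at given covariates
#'
#' `ERR = h/h0 - 1` and `EAR = h - h0`.  For an ERR-transfer model the
#' implied EAR is `h0 * ERR` and therefore depends on city and sex through
#' the baseline; for an EAR-transfer model the implied ERR is `EAR / h0`.
#'
#' @inheritParams total_hazard
#' @return list with vectors `ERR` (dimensionless) and `EAR` (per
#'   person-year).
#' @export
risk_estimates <- function(model, city, sex, a, e, D) {
  pars <- .as_parlist(param_values(model))
  .risk_estimates(model, pars, city, sex, a, e, D)
}

.risk_estimates <- function(model, pars, city, sex, a, e, D) {
  h0 <- exp(.log_baseline(model, pars, city, sex, a, e))
  h <- .total_hazard(model, pars, city, sex, a, e, D)
  list(ERR = h / h0 - 1, EAR = h - h0)
}

#' Baseline conversion factor between covariate groups
#'
#' Person-year-weighted ratio of mean baseline hazard between two cell
#' groups of a person-year table, used to convert EAR estimates from an
#' ERR-transfer model (or ERR from an EAR model) across city or sex, as in
#' the "multiply by a factor of ..." footnotes of published risk tables.
#'
#' @param model a `risk_model` (its baseline is used).
#' @param table a [person_year_table()].
#' @param from,to named lists selecting cells by equality on table
#'   columns, e.g. `list(sex = "male")`; an empty list selects all cells.
#' @return dimensionless factor: weighted mean `h0` in `to` divided by
#'   weighted mean `h0` in `from`.
#' @export
group_conversion_factor <- function(model, table, from, to) {
  stopifnot(inherits(table, "pyt"))
  sel <- function(group) {
    keep <- rep(TRUE, nrow(table))
    for (nm in names(group)) keep <- keep & (table[[nm]] %in% group[[nm]])
    if (!any(keep)) stop("empty cell group", call. = FALSE)
    keep
  }
  wmean_h0 <- function(keep) {
    h0 <- baseline_hazard(model, table$city[keep], table$sex[keep],
                          table$mean_age[keep], table$mean_agex[keep])
    sum(h0 * table$pyr[keep]) / sum(table$pyr[keep])
  }
  wmean_h0(sel(to)) / wmean_h0(sel(from))
}
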