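#' Grouped Poisson deviance
#'
#' The fitting objective: `dev = 2 sum_i [ d_i ln(d_i / lambda_i) -
#' (d_i - lambda_i) ]` with expected deaths `lambda_i = h(cell_i) * pyr_i`
#' and the `d ln(d/lambda)` term taken as 0 when `d = 0` (the saturated
#' Poisson convention).  Zero iff the model reproduces every cell count
#' exactly.
#'
#' @param table a [person_year_table()].
#' @param model a [risk_model()].
#' @param cause cause label.
#' @return non-negative deviance.
#' @export
poisson_deviance <- function(table, model, cause) {
  lam <- .cell_lambda(model, .as_parlist(param_values(model)), table)
  if (any(!is.finite(lam)) || any(lam <= 0)) {
    stop("expected deaths must be positive in every cell", call. = FALSE)
  }
  .dev_from_lambda(table[[paste0("deaths_", cause)]], lam)
}

.cell_lambda <- function(model, pars, table) {
  .total_hazard(model, pars, table$city, table$sex,
                table$mean_age, table$mean_agex, table$mean_dose_gy) *
    table$pyr
}

.dev_from_lambda <- function(d, lam) {
  term <- ifelse(d > 0, d * log(d / lam), 0) - (d - lam)
  2 * sum(term)
}

.dev_terms <- function(d, lam) {
  2 * (ifelse(d > 0, d * log(d / lam), 0) - (d - lam))
}

# admissibility of a raw parameter vector: ordered positive knots, positive
# tanh slope, non-negative thresholds, ordered categorical boundaries
.admissible <- function(model, pars) {
  if (model$n_knots > 0L) {
    k <- vapply(seq_len(model$n_knots),
                function(j) .pg(pars, paste0("bl.knot", j)), numeric(1))
    if (any(k <= 0) || is.unsorted(k, strictly = TRUE)) return(FALSE)
  }
  if (model$shape %in% 5:10) {
    dth <- .pg(pars, "dr.D_th")
    if (!is.null(dth) && dth < 0) return(FALSE)
  }
  if (model$shape == 6L && .pg(pars, "dr.tanh_slope") <= 0) return(FALSE)
  if (model$shape == 11L) {
    b <- c(.pg(pars, "dr.D1"), .pg(pars, "dr.D2"), .pg(pars, "dr.D3"))
    if (is.unsorted(b, strictly = TRUE)) return(FALSE)
  }
  TRUE
}

.PENALTY <- 1e10

#' Fitting options
#'
#' @param restarts number of deterministic perturbed restarts after the
#'   initial minimization (the best optimum is kept).
#' @param rel_tol relative convergence tolerance on the deviance.
#' @param max_eval maximum deviance evaluations per start.
#' @param hessian compute the finite-difference Hessian and Wald
#'   covariance (can be disabled for bulk refits where only the deviance
#'   is needed, e.g. inside streamlining sweeps).
#' @return options list for [fit_risk_model()].
#' @export
fit_options <- function(restarts = 3L, rel_tol = 1e-10, max_eval = 1e4,
                        hessian = TRUE) {
  list(restarts = restarts, rel_tol = rel_tol, max_eval = max_eval,
       hessian = hessian)
}

#' Fit a risk model to a person-year table by Poisson regression
#'
#' Minimizes the grouped Poisson deviance over the model's free
#' parameters (quasi-Newton, with deterministic perturbed restarts; the
#' best optimum is kept).  Inadmissible parameter regions (non-positive
#' hazards, `1 + err * eps <= 0` under ERR transfer, disordered knots or
#' categorical boundaries) return a large penalized deviance, which keeps
#' the optimizer inside the admissible set.  Wald standard errors come
#' from twice the inverse of the central-finite-difference Hessian of the
#' deviance at the optimum (observed information).
#'
#' @inheritParams poisson_deviance
#' @param options see [fit_options()].
#' @return object of class `mmidose_fit`: list with `model` (parameters
#'   updated to the estimates), `estimates` (free parameters), `wald_se`,
#'   `covariance` (`2 * solve(H)`), `deviance`, `n_par`, `converged`,
#'   `cov_ok`, `n_evaluations`, `cause`, `label`.
#' @export
fit_risk_model <- function(table, model, cause, options = fit_options()) {
  stopifnot(inherits(table, "pyt"), inherits(model, "risk_model"))
  dcol <- paste0("deaths_", cause)
  if (!dcol %in% names(table)) stop("unknown cause: ", cause, call. = FALSE)
  d <- table[[dcol]]
  p <- model$params
  free <- p$name[p$free]
  base_pars <- .as_parlist(stats::setNames(p$value, p$name))
  n_eval <- 0L

  objective <- function(theta) {
    n_eval <<- n_eval + 1L
    pars <- base_pars
    pars[free] <- theta
    if (!.admissible(model, pars)) return(.PENALTY)
    lam <- tryCatch(.cell_lambda(model, pars, table), error = function(e) NULL)
    if (is.null(lam) || any(!is.finite(lam)) || any(lam <= 0)) {
      return(.PENALTY)
    }
    .dev_from_lambda(d, lam)
  }

  if (length(free) == 0L) {
    dev0 <- poisson_deviance(table, model, cause)
    return(structure(list(model = model, estimates = numeric(0),
                          wald_se = numeric(0),
                          covariance = matrix(numeric(0), 0, 0),
                          deviance = dev0, n_par = 0L, converged = TRUE,
                          cov_ok = TRUE, n_evaluations = 1L, cause = cause,
                          label = model$label),
                     class = "mmidose_fit"))
  }

  start <- stats::setNames(p$value[p$free], free)
  ctrl <- list(eval.max = options$max_eval, iter.max = options$max_eval,
               rel.tol = options$rel_tol)
  run <- function(s) {
    ans <- tryCatch(stats::nlminb(s, objective, control = ctrl),
                    error = function(e) NULL)
    if (is.null(ans)) list(par = s, objective = objective(s),
                           convergence = 1L)
    else ans
  }
  best <- run(start)
  # deterministic perturbations: alternating relative + absolute nudges
  if (options$restarts > 0L) {
    for (r in seq_len(options$restarts)) {
      sgn <- (-1)^(r + seq_along(start))
      s_r <- best$par * (1 + 0.1 * sgn) + 0.02 * sgn
      cand <- run(s_r)
      if (is.finite(cand$objective) && cand$objective < best$objective) {
        best <- cand
      }
    }
  }
  est <- stats::setNames(best$par, free)
  converged <- isTRUE(best$convergence == 0) && best$objective < .PENALTY

  covariance <- matrix(NA_real_, length(free), length(free),
                       dimnames = list(free, free))
  wald_se <- stats::setNames(rep(NA_real_, length(free)), free)
  cov_ok <- FALSE
  if (options$hessian) {
    H <- .fd_hessian(objective, est)
    cv <- tryCatch(2 * solve(H), error = function(e) NULL)
    if (!is.null(cv) && all(is.finite(cv)) && all(diag(cv) >= 0)) {
      cv <- (cv + t(cv)) / 2
      dimnames(cv) <- list(free, free)
      covariance <- cv
      wald_se <- sqrt(diag(cv))
      cov_ok <- TRUE
    }
  }

  fitted_model <- set_param_values(model, est)
  structure(list(model = fitted_model, estimates = est, wald_se = wald_se,
                 covariance = covariance, deviance = best$objective,
                 n_par = length(free), converged = converged,
                 cov_ok = cov_ok, n_evaluations = n_eval, cause = cause,
                 label = model$label),
            class = "mmidose_fit")
}

#' @export
print.mmidose_fit <- function(x, ...) {
  cat("Poisson fit '", x$label, "' (cause: ", x$cause, ")\n", sep = "")
  cat("  deviance ", format(x$deviance, digits = 8), ", ", x$n_par,
      " free parameter(s), ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  if (x$n_par > 0L) {
    for (nm in names(x$estimates)) {
      cat(sprintf("  %-18s %12.6g  (SE %.4g)\n", nm, x$estimates[[nm]],
                  x$wald_se[[nm]]))
    }
  }
  invisible(x)
}

# central finite differences, step 1e-4 * max(|theta|, 1) per coordinate
.fd_hessian <- function(f, theta) {
  k <- length(theta)
  h <- 1e-4 * pmax(abs(theta), 1)
  H <- matrix(NA_real_, k, k)
  f0 <- f(theta)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(theta + ei) - 2 * f0 + f(theta - ei)) / h[i]^2
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        ej <- replace(numeric(k), j, h[j])
        H[i, j] <- H[j, i] <-
          (f(theta + ei + ej) - f(theta + ei - ej) -
             f(theta - ei + ej) + f(theta - ei - ej)) / (4 * h[i] * h[j])
      }
    }
  }
  H
}

#' Default threshold-dose grid
#'
#' The 27-point search grid for `D_th`: 0.0001-0.0005 Gy in steps of
#' 0.0001, then 0.001, 0.005, 0.01-0.09 in steps of 0.01, 0.1-0.9 in
#' steps of 0.1, 1 and 2 Gy.
#'
#' @return ascending numeric vector of length 27 (Gy).
#' @export
default_dth_grid <- function() {
  c(seq(1e-4, 5e-4, by = 1e-4), 1e-3, 5e-3,
    seq(0.01, 0.09, by = 0.01), seq(0.1, 0.9, by = 0.1), 1, 2)
}

#' Profile the threshold dose over a grid
#'
#' Refits all other free parameters at each candidate `D_th` and returns
#' the grid value with the smallest deviance.  For the linear threshold
#' shape (#5) the search can continue from the best grid point with
#' `D_th` free in the fit (`refine = TRUE`), mirroring how that model's
#' threshold is adjusted rather than gridded.
#'
#' @inheritParams fit_risk_model
#' @param grid ascending Gy values to try (default [default_dth_grid()]).
#' @param refine free `D_th` from the best grid point and refit (default:
#'   only for shape #5).
#' @return list with `D_th` (best value), `fit` (fit at the best value),
#'   and `profile` (data frame `D_th`, `deviance`, `converged`).
#' @export
profile_threshold <- function(table, model, cause,
                              grid = default_dth_grid(),
                              refine = model$shape == 5L,
                              options = fit_options()) {
  stopifnot(length(grid) > 0L, !is.unsorted(grid, strictly = TRUE))
  if (!"dr.D_th" %in% model$params$name) {
    stop("model shape #", model$shape, " has no threshold dose", call. = FALSE)
  }
  prof <- data.frame(D_th = grid, deviance = NA_real_, converged = NA)
  fits <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    m_i <- set_param_values(model, c(dr.D_th = grid[i]))
    m_i$params$free[m_i$params$name == "dr.D_th"] <- FALSE
    f_i <- tryCatch(
      fit_risk_model(table, m_i, cause,
                     options = utils::modifyList(options,
                                                 list(hessian = FALSE))),
      error = function(e) NULL)
    if (!is.null(f_i)) {
      prof$deviance[i] <- f_i$deviance
      prof$converged[i] <- f_i$converged
      fits[[i]] <- f_i
    }
  }
  if (all(is.na(prof$deviance))) {
    stop("no grid point could be fitted", call. = FALSE)
  }
  best_i <- which.min(prof$deviance)
  best_model <- fits[[best_i]]$model
  if (refine) {
    best_model$params$free[best_model$params$name == "dr.D_th"] <- TRUE
  } else {
    best_model$params$free[best_model$params$name == "dr.D_th"] <- FALSE
  }
  best_fit <- fit_risk_model(table, best_model, cause, options = options)
  list(D_th = unname(param_values(best_fit$model)[["dr.D_th"]]),
       fit = best_fit, profile = prof)
}

#' Likelihood-ratio improvement test for nested Poisson models
#'
#' For nested models the deviance difference is chi-square distributed
#' with as many degrees of freedom as added parameters.  A model is an
#' improvement if the deviance drops by at least the chi-square quantile
#' at `1 - alpha` -- 3.84 points per single parameter at `alpha = 0.05`
#' (the boundary counts as an improvement).
#'
#' @param dev_full deviance of the larger model.
#' @param dev_reduced deviance of the reduced model (>= `dev_full` up to
#'   optimizer tolerance).
#' @param extra_par number of additional parameters in the full model.
#' @param alpha significance level.
#' @param tol tolerance for a slightly negative deviance difference from
#'   the optimizer.
#' @return list with `improves` (logical), `delta_dev`, `critical`,
#'   `p_value`, `df`.
#' @details The boundary is inclusive with a 0.1% relative tolerance on
#'   the critical value, so a deviance drop of exactly the conventional
#'   rounded criterion (3.84 points for one parameter at the 95% level)
#'   counts as an improvement even though `qchisq(0.95, 1)` is 3.8415.
#' @export
lrt_improves <- function(dev_full, dev_reduced, extra_par, alpha = 0.05,
                         tol = 1e-6) {
  stopifnot(extra_par >= 1L)
  delta <- dev_reduced - dev_full
  if (delta < -tol) {
    stop("reduced model has smaller deviance than the full model ",
         "beyond tolerance (delta = ", format(delta), ")", call. = FALSE)
  }
  delta <- max(delta, 0)
  critical <- stats::qchisq(1 - alpha, df = extra_par)
  list(improves = delta >= critical * (1 - 1e-3), delta_dev = delta,
       critical = critical,
       p_value = stats::pchisq(delta, df = extra_par, lower.tail = FALSE),
       df = as.integer(extra_par))
}

#' Streamline a baseline model by backward elimination
#'
#' Iteratively tests every eliminable baseline coefficient by setting it
#' to its null value and refitting all other parameters; the least
#' significant parameter (smallest deviance change) is removed if its
#' removal costs less than the chi-square critical value, and the sweep
#' repeats until no parameter can be removed.  Afterwards each fixed knot
#' position in `knot_candidates` is freed and retained only if the fit
#' improves by at least the critical value per added parameter.  Every
#' test is recorded in an audit trail.
#'
#' @inheritParams fit_risk_model
#' @param alpha significance level of each likelihood-ratio test.
#' @param knot_candidates names of fixed knot-position parameters (e.g.
#'   `"bl.knot1"`) to try freeing after elimination; default: all fixed
#'   knot positions.
#' @return list with `model` (streamlined spec at its estimates), `fit`
#'   (final fit with covariance), and `audit` (data frame: `phase`,
#'   `sweep`, `parameter`, `delta_dev`, `critical`, `p_value`,
#'   `decision`).
#' @export
streamline_baseline <- function(table, model, cause, alpha = 0.05,
                                knot_candidates = NULL,
                                options = fit_options()) {
  quick <- utils::modifyList(options, list(hessian = FALSE))
  current <- fit_risk_model(table, model, cause, options = quick)
  audit <- list()
  note <- function(phase, sweep, parameter, lrt, decision) {
    audit[[length(audit) + 1L]] <<- data.frame(
      phase = phase, sweep = sweep, parameter = parameter,
      delta_dev = lrt$delta_dev, critical = lrt$critical,
      p_value = lrt$p_value, decision = decision, stringsAsFactors = FALSE)
  }
  eliminable <- function(m) {
    p <- m$params
    p$name[p$free & p$component == "baseline" & !is.na(p$null)]
  }
  crit1 <- stats::qchisq(1 - alpha, df = 1)
  sweep <- 0L
  repeat {
    sweep <- sweep + 1L
    cand <- eliminable(current$model)
    if (length(cand) == 0L) break
    trials <- lapply(cand, function(nm) {
      m_red <- current$model
      i <- match(nm, m_red$params$name)
      m_red$params$value[i] <- m_red$params$null[i]
      m_red$params$free[i] <- FALSE
      f <- tryCatch(fit_risk_model(table, m_red, cause, options = quick),
                    error = function(e) NULL)
      if (is.null(f)) return(NULL)
      list(name = nm, fit = f,
           lrt = lrt_improves(current$deviance, f$deviance, 1L, alpha))
    })
    trials <- Filter(Negate(is.null), trials)
    if (length(trials) == 0L) break
    ddev <- vapply(trials, function(t) t$lrt$delta_dev, numeric(1))
    weakest <- trials[[which.min(ddev)]]
    for (t in trials) {
      note("eliminate", sweep, t$name, t$lrt,
           if (identical(t$name, weakest$name) && !weakest$lrt$improves)
             "removed" else if (t$lrt$improves) "kept" else "candidate")
    }
    if (weakest$lrt$improves) break  # even the weakest is significant
    current <- weakest$fit
  }
  if (is.null(knot_candidates)) {
    p <- current$model$params
    knot_candidates <- p$name[grepl("^bl\\.knot[0-9]+$", p$name) & !p$free]
  }
  for (nm in knot_candidates) {
    m_free <- current$model
    i <- match(nm, m_free$params$name)
    if (is.na(i) || m_free$params$free[i]) next
    m_free$params$free[i] <- TRUE
    f <- tryCatch(fit_risk_model(table, m_free, cause, options = quick),
                  error = function(e) NULL)
    if (is.null(f)) next
    lrt <- lrt_improves(f$deviance, current$deviance, 1L, alpha)
    if (lrt$improves) {
      note("free_knot", sweep, nm, lrt, "freed")
      current <- f
    } else {
      note("free_knot", sweep, nm, lrt, "not_freed")
    }
  }
  final <- fit_risk_model(table, current$model, cause, options = options)
  list(model = final$model, fit = final,
       audit = if (length(audit) > 0L) do.call(rbind, audit)
               else data.frame(phase = character(), sweep = integer(),
                               parameter = character(),
                               delta_dev = numeric(), critical = numeric(),
                               p_value = numeric(), decision = character(),
                               stringsAsFactors = FALSE))
}

#' Deviance decomposition by dose and attained-age groups
#'
#' Assigns each cell's deviance contribution to a (dose x age) group; the
#' group sums add exactly to [poisson_deviance()].  Used to locate which
#' strata drive deviance differences between models.
#'
#' @inheritParams poisson_deviance
#' @inheritParams stratify_totals
#' @return data frame `dose_bin`, `age_bin`, `deviance`, `n_cells`.
#' @export
deviance_decomposition <- function(table, model, cause, dose_bins, age_bins,
                                   right_closed = FALSE) {
  d <- table[[paste0("deaths_", cause)]]
  lam <- .cell_lambda(model, .as_parlist(param_values(model)), table)
  if (any(!is.finite(lam)) || any(lam <= 0)) {
    stop("expected deaths must be positive in every cell", call. = FALSE)
  }
  terms <- .dev_terms(d, lam)
  di <- .pyt_group_index(table$mean_dose_gy, dose_bins, right_closed, "dose")
  ai <- .pyt_group_index(table$mean_age, age_bins, right_closed, "age")
  dl <- factor(di, levels = seq_len(length(dose_bins) - 1L),
               labels = .bin_labels(dose_bins, right_closed))
  al <- factor(ai, levels = seq_len(length(age_bins) - 1L),
               labels = .bin_labels(age_bins, right_closed))
  agg <- aggregate(cbind(deviance = terms, n_cells = 1),
                   by = list(dose_bin = dl, age_bin = al),
                   FUN = sum, drop = FALSE)
  agg$deviance[is.na(agg$deviance)] <- 0
  agg$n_cells[is.na(agg$n_cells)] <- 0
  agg[order(agg$dose_bin, agg$age_bin), , drop = FALSE]
}
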