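#' Run the full selection-and-MMI workflow
#'
#' Ties the stages together the way the analysis is meant to be run:
#' optional baseline streamlining on a reference model (the streamlined
#' baseline is transplanted into every candidate), per-model fitting with
#' threshold-grid profiling where the shape carries a fixed `D_th`, an
#' AIC score table with Akaike weights, and pooled multi-model risk
#' distributions at the requested doses and covariates.  Every number in
#' the returned bundle is recomputable from its machine-readable parts,
#' and identical configuration plus seed reproduces the bundle exactly.
#'
#' @param table a [person_year_table()] (or a `synthetic_cohort`, whose
#'   table is used).
#' @param models named list of [risk_model()] specifications.
#' @param cause cause label to fit.
#' @param doses dose values (Gy) at which pooled risks are computed.
#' @param covariates list with scalar `city`, `sex`, `a`, `e` at which
#'   risks are evaluated.
#' @param streamline logical; streamline the baseline of
#'   `reference_model` first and transplant the result into all models.
#' @param reference_model name of the model used for streamlining
#'   (default: first).
#' @param profile_grid `D_th` grid for threshold shapes (default
#'   [default_dth_grid()]); set to `NULL` to fit at the fixed `D_th`.
#' @param alpha significance level of streamlining tests.
#' @param total_n pooled MMI sample size.
#' @param level confidence level of the percentile intervals.
#' @param seed integer seed driving all Latin hypercube draws.
#' @param options [fit_options()] for every fit.
#' @return object of class `mmidose_pipeline`: list with `scores`,
#'   `fits`, `profiles`, `mmi` (one [mmi_pool()] result per dose),
#'   `risk_table` (long data frame over models and MMI), `audit`
#'   (streamlining trail or `NULL`), `logs`, `covariates`, `seed`.
#' @export
run_pipeline <- function(table, models, cause,
                         doses = c(0.2, 1),
                         covariates = list(city = "Hiroshima",
                                           sex = "male", a = 70, e = 30),
                         streamline = FALSE,
                         reference_model = names(models)[1],
                         profile_grid = default_dth_grid(),
                         alpha = 0.05,
                         total_n = 1e4, level = 0.90, seed = 1L,
                         options = fit_options()) {
  if (inherits(table, "synthetic_cohort")) table <- table$table
  stopifnot(inherits(table, "pyt"), length(models) >= 1L)
  if (is.null(names(models)) || anyDuplicated(names(models))) {
    stop("models must be a uniquely named list", call. = FALSE)
  }
  logs <- character(0)
  say <- function(...) logs <<- c(logs, paste0(...))

  audit <- NULL
  if (isTRUE(streamline)) {
    say("streamlining baseline of '", reference_model, "' at alpha = ",
        alpha)
    sl <- streamline_baseline(table, models[[reference_model]], cause,
                              alpha = alpha, options = options)
    audit <- sl$audit
    for (i in seq_len(nrow(audit))) {
      say("  [", audit$phase[i], "] ", audit$parameter[i],
          ": ddev = ", format(audit$delta_dev[i], digits = 4),
          " -> ", audit$decision[i])
    }
    models <- lapply(models, transplant_baseline, source = sl$model)
  }

  fits <- list()
  profiles <- list()
  for (nm in names(models)) {
    m <- models[[nm]]
    m$label <- nm
    has_dth <- "dr.D_th" %in% m$params$name
    dth_fixed <- has_dth && !m$params$free[m$params$name == "dr.D_th"]
    if (has_dth && dth_fixed && !is.null(profile_grid)) {
      say("profiling D_th for '", nm, "' over ", length(profile_grid),
          " grid values")
      pr <- profile_threshold(table, m, cause, grid = profile_grid,
                              options = options)
      fits[[nm]] <- pr$fit
      profiles[[nm]] <- pr$profile
      say("  best D_th = ", format(pr$D_th, digits = 4), " Gy, deviance ",
          format(pr$fit$deviance, digits = 8))
    } else {
      fits[[nm]] <- fit_risk_model(table, m, cause, options = options)
      say("fitted '", nm, "': deviance ",
          format(fits[[nm]]$deviance, digits = 8), ", ",
          fits[[nm]]$n_par, " parameters")
    }
  }

  scores <- model_score_table(fits)
  say("score table: weights ",
      paste(format(scores$weight, digits = 4), collapse = ", "))

  mmi <- list()
  risk_rows <- list()
  for (di in seq_along(doses)) {
    D <- doses[di]
    dists <- list()
    for (mi in seq_along(fits)) {
      nm <- names(fits)[mi]
      sub_seed <- (seed + 7919L * di + 104729L * mi) %% .Machine$integer.max
      dists[[nm]] <- risk_distribution(fits[[nm]], covariates$city,
                                       covariates$sex, covariates$a,
                                       covariates$e, D,
                                       n = total_n, seed = sub_seed)
      s <- .dist_summary(dists[[nm]], level)
      risk_rows[[length(risk_rows) + 1L]] <-
        cbind(data.frame(dose = D, model = nm,
                         weight = scores$weight[scores$model == nm]), s)
    }
    mmi[[as.character(D)]] <- mmi_pool(scores, dists, total_n = total_n,
                                       level = level)
    s <- .dist_summary(mmi[[as.character(D)]]$realizations, level)
    risk_rows[[length(risk_rows) + 1L]] <-
      cbind(data.frame(dose = D, model = "MMI", weight = 1), s)
    say("pooled risk at ", D, " Gy: ERR mean ",
        format(s$ERR_mean, digits = 4))
  }

  structure(list(scores = scores, fits = fits, profiles = profiles,
                 mmi = mmi, risk_table = do.call(rbind, risk_rows),
                 audit = audit, logs = logs, covariates = covariates,
                 doses = doses, level = level, seed = seed),
            class = "mmidose_pipeline")
}

.dist_summary <- function(d, level) {
  probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  f <- function(x) {
    q <- stats::quantile(x, probs = probs, type = 7, names = FALSE)
    c(mean(x), q[2], q[1], q[3])
  }
  e <- f(d$ERR)
  a <- f(d$EAR)
  data.frame(ERR_mean = e[1], ERR_median = e[2], ERR_lower = e[3],
             ERR_upper = e[4], EAR_mean = a[1], EAR_median = a[2],
             EAR_lower = a[3], EAR_upper = a[4])
}

#' Carry a streamlined baseline into another model specification
#'
#' Copies baseline parameter values and free/fixed flags from a
#' (typically streamlined) model into a candidate spec sharing the same
#' baseline structure, so every candidate is fitted on the same reduced
#' baseline.
#'
#' @param target the model receiving the baseline.
#' @param source the model providing it.
#' @return `target` with the transplanted baseline.
#' @export
transplant_baseline <- function(target, source) {
  src <- source$params[source$params$component == "baseline", ,
                       drop = FALSE]
  for (i in seq_len(nrow(src))) {
    j <- match(src$name[i], target$params$name)
    if (!is.na(j)) {
      target$params$value[j] <- src$value[i]
      target$params$free[j] <- src$free[i]
    }
  }
  target
}

#' @export
print.mmidose_pipeline <- function(x, ...) {
  cat("mmidose pipeline bundle\n")
  cat("-- model scores --\n")
  print(x$scores, digits = 4)
  cat("-- pooled risks --\n")
  print(x$risk_table, digits = 4)
  invisible(x)
}
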