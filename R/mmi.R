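#' Akaike information criterion for a Poisson deviance fit
#'
#' `AIC = dev + 2 N_par` (the deviance differs from minus twice the
#' log-likelihood only by a model-independent saturated term, so AIC
#' differences are unaffected).
#'
#' @param deviance fitted deviance(s).
#' @param n_par number(s) of free parameters.
#' @return AIC value(s).
#' @export
aic_score <- function(deviance, n_par) {
  stopifnot(all(n_par >= 0))
  deviance + 2 * n_par
}

#' Akaike weights
#'
#' `p_m = exp(-dAIC_m / 2) / sum_j exp(-dAIC_j / 2)` with
#' `dAIC_m = AIC_m - min(AIC)`.  Shift-invariant and normalized to 1.
#'
#' @param aic numeric vector of AIC values (finite, length >= 1).
#' @return weights summing to 1.
#' @export
akaike_weights <- function(aic) {
  stopifnot(length(aic) >= 1L, all(is.finite(aic)))
  w <- exp(-(aic - min(aic)) / 2)
  w / sum(w)
}

#' Model score table
#'
#' Tabulates deviance, parameter count, AIC, delta-AIC and Akaike weight
#' for a set of fitted models, in the layout of a published model-selection
#' table.
#'
#' @param fits list of `mmidose_fit` objects, or `NULL` if `deviance` and
#'   `n_par` are given directly.
#' @param labels model labels (default: fit labels).
#' @param deviance,n_par numeric vectors used instead of `fits`.
#' @return data frame: `model`, `deviance`, `n_par`, `aic`, `delta_aic`,
#'   `weight`.
#' @export
model_score_table <- function(fits = NULL, labels = NULL, deviance = NULL,
                              n_par = NULL) {
  if (!is.null(fits)) {
    deviance <- vapply(fits, `[[`, numeric(1), "deviance")
    n_par <- vapply(fits, `[[`, numeric(1), "n_par")
    if (is.null(labels)) labels <- vapply(fits, `[[`, character(1), "label")
  }
  stopifnot(length(deviance) == length(n_par))
  if (is.null(labels)) labels <- paste0("model", seq_along(deviance))
  aic <- aic_score(deviance, n_par)
  data.frame(model = labels, deviance = deviance, n_par = as.integer(n_par),
             aic = aic, delta_aic = aic - min(aic),
             weight = akaike_weights(aic), stringsAsFactors = FALSE)
}

#' Latin hypercube samples of fitted parameters
#'
#' Draws `n` parameter vectors from a multivariate normal centred at the
#' estimates with the fitted Wald covariance.  Marginals are stratified
#' (one draw per equiprobable bin per parameter -- the Latin hypercube
#' property); correlation is induced by a linear transform of the
#' stratified standard normals, so marginal stratification is exact for
#' uncorrelated parameters and approximate otherwise.  A non-PSD
#' covariance is repaired by clipping negative eigenvalues at zero (the
#' number clipped is attached as attribute `n_clipped`).
#'
#' @param fit an `mmidose_fit` with available covariance.
#' @param n number of samples.
#' @param seed integer seed.
#' @return `n x n_par` matrix with parameter-named columns.
#' @export
lhs_parameter_samples <- function(fit, n, seed = 1L) {
  stopifnot(inherits(fit, "mmidose_fit"))
  k <- fit$n_par
  if (k == 0L) return(matrix(numeric(0), nrow = n, ncol = 0L))
  if (!fit$cov_ok) {
    stop("fit has no usable covariance; cannot propagate uncertainty",
         call. = FALSE)
  }
  eg <- eigen((fit$covariance + t(fit$covariance)) / 2, symmetric = TRUE)
  n_clipped <- sum(eg$values < 0)
  A <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), k)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  Z <- stats::qnorm(lhs::randomLHS(n, k))
  X <- Z %*% t(A)
  X <- sweep(X, 2L, fit$estimates, `+`)
  colnames(X) <- names(fit$estimates)
  attr(X, "n_clipped") <- n_clipped
  X
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Risk realizations from propagated parameter uncertainty
#'
#' Pushes Latin hypercube parameter samples through the hazard model and
#' evaluates ERR and EAR at the requested covariates and dose.
#' Realizations violating hazard positivity (or `1 + err * eps > 0` under
#' ERR transfer) are regenerated from fresh stratified draws; if more
#' than 10% of the initial draws are inadmissible the fit is deemed
#' unstable and an error is raised.
#'
#' @param fit an `mmidose_fit`.
#' @param city,sex,a,e scalar covariates.
#' @param D scalar dose in Gy.
#' @param n number of realizations (default 1e4).
#' @param seed integer seed.
#' @return data frame with columns `ERR` and `EAR` (`n` rows); attribute
#'   `n_regenerated` counts replaced realizations.
#' @export
risk_distribution <- function(fit, city, sex, a, e, D, n = 1e4, seed = 1L) {
  model <- fit$model
  evaluate <- function(samples) {
    pars <- .as_parlist(param_values(model))
    if (ncol(samples) > 0L) {
      for (nm in colnames(samples)) pars[[nm]] <- samples[, nm]
    }
    ok <- rep(TRUE, nrow(samples))
    if (model$n_knots > 0L) {
      kn <- sapply(seq_len(model$n_knots),
                   function(j) .pg(pars, paste0("bl.knot", j)) + 0 * ok)
      if (model$n_knots > 1L) {
        ok <- ok & apply(kn, 1L, function(v) !is.unsorted(v, strictly = TRUE))
      }
    }
    h0 <- exp(.log_baseline(model, pars, city, sex, a, e))
    ex <- .excess(model, pars, D)
    eps <- if (model$shape == 11L && !model$modifier_on_categorical) 1
           else .modifier(model, pars, sex, a, e)
    h <- if (model$transfer == "ERR") h0 * (1 + ex * eps) else h0 + ex * eps
    ok <- ok & is.finite(h) & (h > 0)
    data.frame(ERR = h / h0 - 1, EAR = h - h0, ok = ok + 0 * h0)
  }
  if (fit$n_par == 0L) {
    r <- evaluate(matrix(numeric(0), 1L, 0L))
    out <- data.frame(ERR = rep(r$ERR, n), EAR = rep(r$EAR, n))
    attr(out, "n_regenerated") <- 0L
    return(out)
  }
  res <- evaluate(lhs_parameter_samples(fit, n, seed))
  bad <- which(res$ok == 0)
  if (length(bad) > n / 10) {
    stop("more than 10% of realizations are inadmissible: unstable fit",
         call. = FALSE)
  }
  n_regen <- 0L
  round <- 0L
  while (length(bad) > 0L && round < 50L) {
    round <- round + 1L
    repl <- evaluate(lhs_parameter_samples(fit, max(length(bad), 2L),
                                           seed + round))
    good <- which(repl$ok == 1)
    take <- min(length(good), length(bad))
    if (take > 0L) {
      res[bad[seq_len(take)], ] <- repl[good[seq_len(take)], ]
      n_regen <- n_regen + take
      bad <- bad[-seq_len(take)]
    }
  }
  if (length(bad) > 0L) {
    stop("could not regenerate admissible realizations", call. = FALSE)
  }
  out <- res[, c("ERR", "EAR")]
  attr(out, "n_regenerated") <- n_regen
  out
}

#' Largest-remainder allocation of sample counts
#'
#' @param weights non-negative weights summing to 1.
#' @param total total count to allocate.
#' @return integer vector summing exactly to `total`.
#' @export
allocate_samples <- function(weights, total = 1e4) {
  stopifnot(all(weights >= 0), abs(sum(weights) - 1) < 1e-8)
  raw <- weights * total
  base <- floor(raw)
  need <- as.integer(round(total - sum(base)))
  if (need > 0L) {
    add <- order(raw - base, decreasing = TRUE)[seq_len(need)]
    base[add] <- base[add] + 1
  }
  as.integer(base)
}

#' Pool per-model risk distributions by Akaike weight
#'
#' Multi-model inference: each model's risk realizations contribute a
#' weight-proportional share of the pooled sample (largest-remainder
#' rounding so counts sum exactly to `total_n`), and mean, median and
#' percentile bounds are read off the pooled distribution.
#'
#' @param scores a [model_score_table()] (columns `model`, `weight`).
#' @param dists named list of risk-realization data frames (from
#'   [risk_distribution()]), one per score row, each with at least
#'   `total_n` rows, all evaluated at identical covariates and dose.
#' @param total_n pooled sample size (default 1e4).
#' @param level confidence level; the interval is the
#'   `[(1-level)/2, 1-(1-level)/2]` percentile range of the pooled
#'   realizations (type-7 interpolation).
#' @return object of class `mmi_result`: list with `allocations`,
#'   `realizations` (pooled data frame with `model`, `ERR`, `EAR`),
#'   `summary` (rows ERR and EAR: mean, median, lower, upper), `level`.
#' @export
mmi_pool <- function(scores, dists, total_n = 1e4, level = 0.90) {
  stopifnot(is.data.frame(scores), level > 0, level < 1)
  if (!setequal(scores$model, names(dists))) {
    stop("score table and distribution list name different models",
         call. = FALSE)
  }
  alloc <- allocate_samples(scores$weight, total_n)
  pooled <- do.call(rbind, lapply(seq_len(nrow(scores)), function(i) {
    m <- scores$model[i]
    d <- dists[[m]]
    if (nrow(d) < alloc[i]) {
      stop("distribution for '", m, "' has fewer rows than its allocation",
           call. = FALSE)
    }
    if (alloc[i] == 0L) return(NULL)
    cbind(model = m, d[seq_len(alloc[i]), c("ERR", "EAR"), drop = FALSE])
  }))
  probs <- c((1 - level) / 2, 0.5, 1 - (1 - level) / 2)
  summarize <- function(x) {
    q <- stats::quantile(x, probs = probs, type = 7, names = FALSE)
    c(mean = mean(x), median = q[2], lower = q[1], upper = q[3])
  }
  s <- rbind(ERR = summarize(pooled$ERR), EAR = summarize(pooled$EAR))
  structure(list(allocations = stats::setNames(alloc, scores$model),
                 realizations = pooled,
                 summary = data.frame(quantity = rownames(s), s,
                                      row.names = NULL),
                 level = level),
            class = "mmi_result")
}

#' @export
print.mmi_result <- function(x, ...) {
  cat("Multi-model inference over ", length(x$allocations), " model(s), ",
      nrow(x$realizations), " pooled realizations (",
      round(100 * x$level), "% interval)\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Pooled point dose-response across a model set
#'
#' The weight-combined excess `sum_m p_m err_m(D)` of a model set sharing
#' one transfer type; usable as a fixed dose-response (e.g. to score the
#' pooled curve against data through [poisson_deviance()]).
#'
#' @param scores a [model_score_table()].
#' @param models named list of `risk_model` objects (at their estimates)
#'   matching the score rows.
#' @param D dose vector in Gy.
#' @return pooled point excess, same length as `D`.
#' @export
mmi_dose_response <- function(scores, models, D) {
  if (!setequal(scores$model, names(models))) {
    stop("score table and model list name different models", call. = FALSE)
  }
  transfers <- unique(vapply(models, `[[`, character(1), "transfer"))
  if (length(transfers) != 1L) {
    stop("model set mixes ERR and EAR transfers", call. = FALSE)
  }
  out <- numeric(length(D))
  for (i in seq_len(nrow(scores))) {
    out <- out + scores$weight[i] *
      excess_dose_response(models[[scores$model[i]]], D)
  }
  out
}
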