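#' @export
print.dmchain <- function(x, ...) {
  cat("Calibrated aging-chain model (", x$sex, ")\n", sep = "")
  cat("  window: ", x$window[1L], "-", x$window[length(x$window)],
      "; payoff = ", format(x$payoff, digits = 4),
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(signif(coef(x), 4))
  invisible(x)
}

#' @export
coef.dmchain <- function(object, ...) {
  out <- c(object$params$ir_dm, object$params$ir_di)
  if (!is.null(object$drift))
    out <- c(out, g_dm = object$drift$g_dm, g_di = object$drift$g_di)
  out
}

#' @export
summary.dmchain <- function(object, ...) {
  structure(list(fit = object), class = "summary.dmchain")
}

#' @export
print.summary.dmchain <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\n  optimizer: ", length(f$start_payoffs), " start(s), best = #",
      f$best_start, ", ", f$n_evaluations, " payoff evaluations\n",
      sep = "")
  cat("  per-variable fit (RMSE, persons):\n")
  rs <- f$residual_summary
  rs$mean_obs <- signif(rs$mean_obs, 3)
  rs$rmse <- signif(rs$rmse, 3)
  print(rs, row.names = FALSE)
  invisible(x)
}

#' Project a calibrated model forward
#'
#' Simulates the fitted model from the calibration start year to a
#' horizon, optionally under an intervention scenario.  Exogenous series
#' past the data window are held at their final observed value (the entry
#' cohort series is supplied through 2035 and held beyond that).
#'
#' @param object A fitted `dmchain` model.
#' @param horizon Final simulated year (default 2035).
#' @param scenario A scenario name or [make_scenario()] object (default
#'   `"base"`).
#' @param dt Integration step (default: the calibration step).
#' @param drift Optional drift override (default: the fitted drift, if
#'   any); see [run_with_drift()].
#' @param ... Unused.
#' @return A `dmchain_traj`.
#' @export
predict.dmchain <- function(object, horizon = 2035, scenario = "base",
                            dt = NULL, drift = object$drift, ...) {
  if (is.character(scenario)) scenario <- make_scenario(scenario)
  if (scenario$name == "base" && is.null(drift)) scenario_arg <- NULL
  else scenario_arg <- scenario
  if (!is.null(scenario_arg) && scenario_arg$name == "base" &&
      !scenario_arg$dm_ramp && !scenario_arg$di_ramp && is.null(drift))
    scenario_arg <- NULL
  if (is.null(dt)) dt <- object$control$dt
  exog <- extend_exogenous(object$data$exog, horizon)
  simulate_chain(object$params, exog, scenario = scenario_arg,
                 t0 = object$window[1L], t1 = horizon, dt = dt,
                 drift = drift)
}

#' @export
fitted.dmchain <- function(object, ...) {
  tr <- predict(object, horizon = object$window[length(object$window)])
  .model_matrix(tr, object$window)
}

#' @export
residuals.dmchain <- function(object, type = c("raw", "weighted"), ...) {
  type <- match.arg(type)
  obs <- .obs_matrix(object$data, object$window)
  res <- fitted(object) - obs
  if (type == "weighted") {
    v <- names(object$weights)
    res <- sweep(res[, v, drop = FALSE], 2, as.numeric(object$weights), `*`)
  }
  res
}

#' Plot observed against fitted aggregate series
#'
#' @param x A fitted `dmchain` model.
#' @param which Aggregates to draw (default total diabetic population and
#'   dialysis population).
#' @param horizon Final projected year (default 2035).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.dmchain <- function(x, which = c("TotalDM", "DMDiover40"),
                         horizon = 2035, ...) {
  tr <- predict(x, horizon = horizon)
  obs <- .obs_matrix(x$data, x$window)
  obs_ag <- cbind(
    TotalDM = rowSums(obs[, 7:16, drop = FALSE]),
    DMDiover40 = rowSums(obs[, 13:16, drop = FALSE]))
  old <- graphics::par(mfrow = c(1, length(which)))
  on.exit(graphics::par(old))
  for (v in which) {
    graphics::plot(tr$years, tr$aggregates[[v]], type = "l",
                   xlab = "year", ylab = "persons",
                   main = paste0(v, " (", x$sex, ")"), ...)
    graphics::points(x$window, obs_ag[, v], pch = 1)
  }
  invisible(x)
}

#' Simulate synthetic observation data from a fitted model
#'
#' Treats the fitted parameters as ground truth and generates `nsim`
#' observation cross-tables with multiplicative log-normal noise, the
#' same mechanism as [generate_synthetic_country()].
#'
#' @param object A fitted `dmchain` model.
#' @param nsim Number of datasets.
#' @param seed RNG seed (default: the calibration seed).
#' @param cv Observation-noise coefficient of variation (default 0.01).
#' @param ... Unused.
#' @return A list of `nsim` [dmchain_data] objects (single sex).
#' @export
simulate.dmchain <- function(object, nsim = 1, seed = NULL, cv = 0.01,
                             ...) {
  if (is.null(seed)) seed <- object$control$seed
  lapply(seq_len(nsim), function(i) {
    tp <- list(params = object$params, exog = object$data$exog)
    tr <- truth_params(
      male = if (object$sex == "male") tp,
      female = if (object$sex == "female") tp,
      cv = cv, seed = seed + i - 1L)
    generate_synthetic_country(tr, dt = object$control$dt)
  })
}
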