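# shared: turn a fitted model (or explicit params/exog pair) into a
# simulation context
.sens_context <- function(object, horizon, dt = NULL) {
  if (inherits(object, "dmchain")) {
    list(params = object$params,
         exog = extend_exogenous(object$data$exog, horizon),
         dt = if (is.null(dt)) object$control$dt else dt,
         t0 = object$window[1L])
  } else {
    stopifnot(inherits(object$params, "dmchain_params"),
              inherits(object$exog, "dmchain_exog"))
    list(params = object$params,
         exog = extend_exogenous(object$exog, horizon),
         dt = if (is.null(dt)) 1 / 16 else dt,
         t0 = object$params$start_year)
  }
}

#' Sweep one incidence rate over a grid
#'
#' Re-simulates the base run for each grid value of a single calibrated
#' rate (named in the `DM<band>ir` / `DMDi<band>ir` convention), holding
#' everything else fixed — the robustness check used when a calibrated
#' rate lands on an implausible value such as the zero bound.
#'
#' @param object A fitted `dmchain` model, or a list with elements
#'   `params` and `exog`.
#' @param param_name One of [rate_names()], e.g. `"DM3039ir"`.
#' @param grid Strictly increasing rate values within the family bounds.
#' @param horizon Final simulated year (default 2035).
#' @param dt Integration step.
#' @return An object of class `dmchain_sweep`: the grid, one trajectory
#'   per value, and a summary of the 2035-style aggregates per value.
#' @export
sweep_rate <- function(object, param_name, grid, horizon = 2035,
                       dt = NULL) {
  rn <- rate_names()
  if (!param_name %in% c(rn$dm, rn$di))
    stop("unknown parameter \"", param_name, "\"; valid: ",
         paste(c(rn$dm, rn$di), collapse = ", "), call. = FALSE)
  .check_grid(grid)
  fam <- if (param_name %in% rn$dm) "dm" else "di"
  if (any(grid < .RATE_BOUNDS[[fam]][1L]) ||
      any(grid > .RATE_BOUNDS[[fam]][2L]))
    stop("grid outside the ", fam, " rate bounds", call. = FALSE)
  ctx <- .sens_context(object, horizon, dt)
  trajs <- lapply(grid, function(v) {
    p <- ctx$params
    if (fam == "dm") p$ir_dm[param_name] <- v else p$ir_di[param_name] <- v
    simulate_chain(p, ctx$exog, t0 = ctx$t0, t1 = horizon, dt = ctx$dt)
  })
  .sweep_result(param_name, grid, trajs, horizon)
}

#' Sweep the entry diabetes prevalence
#'
#' Base-run trajectories for a grid of diabetes prevalences among
#' 20-year-old entrants (the default assumption is 0.2%).
#'
#' @inheritParams sweep_rate
#' @param grid Strictly increasing fractions in \[0, 1\].
#' @export
sweep_entry_prevalence <- function(object, grid, horizon = 2035,
                                   dt = NULL) {
  .check_grid(grid)
  if (any(grid < 0) || any(grid > 1))
    stop("entry prevalence values must lie in [0, 1]", call. = FALSE)
  ctx <- .sens_context(object, horizon, dt)
  trajs <- lapply(grid, function(v) {
    e <- ctx$exog
    e$entry_dm_prev <- v
    simulate_chain(ctx$params, e, t0 = ctx$t0, t1 = horizon, dt = ctx$dt)
  })
  .sweep_result("entry_dm_prev", grid, trajs, horizon)
}

.check_grid <- function(grid) {
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("grid must be strictly increasing", call. = FALSE)
  invisible(grid)
}

.sweep_result <- function(param, grid, trajs, horizon) {
  summ <- do.call(rbind, lapply(seq_along(grid), function(i) {
    ag <- trajs[[i]]$aggregates
    j <- nrow(ag)
    data.frame(value = grid[i], year = ag$year[j],
               TotalDM = ag$TotalDM[j], DMDiover40 = ag$DMDiover40[j],
               dm_prevalence_pct = ag$dm_prevalence_pct[j])
  }))
  structure(list(param = param, grid = grid, trajectories = trajs,
                 summary = summ, horizon = horizon),
            class = "dmchain_sweep")
}

#' @export
print.dmchain_sweep <- function(x, ...) {
  cat("Sensitivity sweep of ", x$param, " (", length(x$grid),
      " values), aggregates at ", x$horizon, ":\n", sep = "")
  print(cbind(x$summary["value"], round(x$summary[-(1:2)])),
        row.names = FALSE)
  invisible(x)
}

#' Simulate with exponentially drifting rates
#'
#' Relaxes the constant-rate assumption: each rate family is multiplied
#' by `exp(g * (t - ref_year))`, one growth coefficient per family
#' (diabetes incidence, dialysis initiation), `|g| <= 0.05`/yr, reference
#' year 2000 by default.  With `g = 0` the run is identical to the
#' constant-rate base run.  To *estimate* the drift jointly with the
#' rates instead, refit with `dmchain_control(drift = TRUE)`.
#'
#' @inheritParams sweep_rate
#' @param drift List with `g_dm`, `g_di` (1/yr) and optionally
#'   `ref_year` (default 2000).
#' @param scenario Optional scenario applied on top of the drift.
#' @return A `dmchain_traj`.
#' @export
run_with_drift <- function(object, drift, horizon = 2035, dt = NULL,
                           scenario = NULL) {
  ctx <- .sens_context(object, horizon, dt)
  drift <- .check_drift(drift)
  if (is.character(scenario)) scenario <- make_scenario(scenario)
  simulate_chain(ctx$params, ctx$exog, scenario = scenario, t0 = ctx$t0,
                 t1 = horizon, dt = ctx$dt, drift = drift)
}

#' Re-run all four scenarios to an extended horizon
#'
#' @inheritParams sweep_rate
#' @param end_year Final year (default 2055; must be at least the
#'   standard 2035 horizon).
#' @return A named list of four `dmchain_traj` objects (`base`, `DMP`,
#'   `ESRDP`, `DMP+ESRDP`), class `dmchain_runs`.
#' @export
extend_horizon <- function(object, end_year = 2055, dt = NULL) {
  if (end_year < 2035) stop("end_year must be >= 2035", call. = FALSE)
  ctx <- .sens_context(object, end_year, dt)
  names <- c("base", "DMP", "ESRDP", "DMP+ESRDP")
  out <- lapply(names, function(nm) {
    sc <- if (nm == "base") NULL else make_scenario(nm)
    simulate_chain(ctx$params, ctx$exog, scenario = sc, t0 = ctx$t0,
                   t1 = end_year, dt = ctx$dt)
  })
  structure(stats::setNames(out, names), class = "dmchain_runs")
}

#' @export
print.dmchain_runs <- function(x, ...) {
  yr <- x[[1L]]$years[length(x[[1L]]$years)]
  cat("Scenario runs to ", yr, " (", x[[1L]]$sex, "):\n", sep = "")
  for (nm in names(x)) {
    ag <- x[[nm]]$aggregates
    j <- nrow(ag)
    cat(sprintf("  %-10s TotalDM %10.0f  DMDiover40 %8.0f\n", nm,
                ag$TotalDM[j], ag$DMDiover40[j]))
  }
  invisible(x)
}
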