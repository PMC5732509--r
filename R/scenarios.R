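#' Intervention scenarios
#'
#' Hypothetical interventions are expressed as time-varying multipliers on
#' the two rate families. `DMP` (diabetes prevention) ramps every diabetes
#' incidence rate linearly from 1 at `ramp_start` down to `final_level` at
#' `ramp_end` and holds it there; `ESRDP` (end-stage renal disease
#' prevention) applies the same ramp to every dialysis-initiation rate and
#' to the exogenous dialysis inflow at age 40; `DMP+ESRDP` applies both;
#' `base` applies neither.
#'
#' @param name One of `"base"`, `"DMP"`, `"ESRDP"`, `"DMP+ESRDP"`.
#' @param ramp_start Year the decline begins (default 2015).
#' @param ramp_end Year the multiplier reaches `final_level` (default 2025).
#' @param final_level Plateau multiplier (default 0.5, i.e. halving).
#' @return An object of class `dmchain_scenario`.
#' @examples
#' sc <- make_scenario("DMP")
#' ramp_multiplier(c(2014, 2020, 2030), sc, "dm")
#' @export
make_scenario <- function(name = c("base", "DMP", "ESRDP", "DMP+ESRDP"),
                          ramp_start = 2015, ramp_end = 2025,
                          final_level = 0.5) {
  valid <- c("base", "DMP", "ESRDP", "DMP+ESRDP")
  if (!is.character(name) || length(name) != 1L || !name %in% valid)
    stop("unknown scenario; valid names: ", paste(valid, collapse = ", "),
         call. = FALSE)
  stopifnot(ramp_end > ramp_start, final_level > 0, final_level <= 1)
  structure(list(name = name,
                 dm_ramp = name %in% c("DMP", "DMP+ESRDP"),
                 di_ramp = name %in% c("ESRDP", "DMP+ESRDP"),
                 ramp_start = ramp_start, ramp_end = ramp_end,
                 final_level = final_level),
            class = "dmchain_scenario")
}

#' @rdname make_scenario
#' @param t Calendar time(s) at which to evaluate the multiplier.
#' @param spec A `dmchain_scenario`.
#' @param family `"dm"` or `"di"`: which rate family's multiplier.
#' @return `ramp_multiplier()` returns the dimensionless multiplier,
#'   vectorized over `t`: 1 before `ramp_start`, linear down to
#'   `final_level` at `ramp_end`, constant afterwards (identically 1 for a
#'   family the scenario does not ramp).
#' @export
ramp_multiplier <- function(t, spec, family = c("dm", "di")) {
  stopifnot(inherits(spec, "dmchain_scenario"))
  family <- match.arg(family)
  active <- if (family == "dm") spec$dm_ramp else spec$di_ramp
  if (!active) return(rep(1, length(t)))
  frac <- (t - spec$ramp_start) / (spec$ramp_end - spec$ramp_start)
  frac <- pmin(pmax(frac, 0), 1)
  1 + frac * (spec$final_level - 1)
}

#' @export
print.dmchain_scenario <- function(x, ...) {
  cat("Scenario \"", x$name, "\": ", sep = "")
  if (!x$dm_ramp && !x$di_ramp) {
    cat("no intervention (all multipliers 1)\n")
  } else {
    fams <- c(if (x$dm_ramp) "diabetes incidence",
              if (x$di_ramp) "dialysis initiation")
    cat(paste(fams, collapse = " and "), " ramped from 1 (", x$ramp_start,
        ") to ", x$final_level, " (", x$ramp_end, "), then held\n", sep = "")
  }
  invisible(x)
}

#' Compare an intervention run against the base run
#'
#' @param base,scenario Trajectories from [simulate_chain()] /
#'   [predict.dmchain()] on the same sex and horizon.
#' @param report_year Year at which levels and reductions are reported
#'   (default 2035).
#' @return A `data.frame` with one row per aggregate (`TotalDM`,
#'   `DMDiover40`): level in each run at `report_year`, percent reduction
#'   relative to base, and the peak year and value of the aggregate in each
#'   run (ties broken by the earliest year).
#' @export
compare_runs <- function(base, scenario, report_year = 2035) {
  stopifnot(inherits(base, "dmchain_traj"), inherits(scenario, "dmchain_traj"))
  if (!report_year %in% base$years || !report_year %in% scenario$years)
    stop("report year ", report_year, " not covered by both trajectories",
         call. = FALSE)
  vars <- c("TotalDM", "DMDiover40")
  out <- lapply(vars, function(v) {
    b <- base$aggregates[[v]]
    s <- scenario$aggregates[[v]]
    i <- match(report_year, base$years)
    j <- match(report_year, scenario$years)
    data.frame(
      variable = v, year = report_year,
      base_level = b[i], scenario_level = s[j],
      pct_reduction = if (b[i] == s[j]) 0 else (b[i] - s[j]) / b[i] * 100,
      base_peak_year = base$years[which.max(b)],
      base_peak_value = max(b),
      scenario_peak_year = scenario$years[which.max(s)],
      scenario_peak_value = max(s))
  })
  res <- do.call(rbind, out)
  res$sex <- base$sex
  res$scenario <- scenario$scenario
  res
}
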