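#' Instantaneous flows of the stock-and-flow system
#'
#' Evaluates every flow (persons/year) of the aging chain at a point in
#' time: the entry cohort split between the NDM and DM 20-29 stocks by the
#' entry diabetes prevalence, first-order aging out of each closed ten-year
#' band at stock/10 per year, diabetes incidence NDM -> DM, dialysis
#' initiation DM -> DMDi for bands 40-49 and older, the exogenous dialysis
#' inflow at age 40, and deaths from every stock.  DM stocks under 40 have
#' no dialysis-initiation outflow: dialysis patients under 40 sit outside
#' the model, and their arrival at age 40 is the exogenous inflow.
#'
#' @param state Numeric length 16 in [stock_names()] order, all `>= 0`.
#' @param t Calendar time (continuous) within the exogenous domain.
#' @param params A [dmchain_params] object.
#' @param exog A [dmchain_exog] object for the same sex.
#' @param scenario Optional [dmchain_scenario]; `NULL` means base run.
#' @param drift Optional rate drift, see [run_with_drift()].
#' @return A list of class `dmchain_flows`: components `entry` (NDMto20,
#'   DMto20), `aging`, `incidence`, `initiation`, `dialysis_entry40`,
#'   `deaths`, and `dstate`, the 16 net stock derivatives implied by those
#'   flows.
#' @export
chain_flows <- function(state, t, params, exog, scenario = NULL,
                        drift = NULL) {
  stopifnot(inherits(params, "dmchain_params"), inherits(exog, "dmchain_exog"))
  if (length(state) != 16L)
    stop("`state` must have 16 stocks", call. = FALSE)
  if (any(state < 0))
    stop("negative stock in input state", call. = FALSE)
  if (t < exog$years[1L] || t > max(exog$years) + 1)
    stop("time ", t, " outside the exogenous domain [", exog$years[1L], ", ",
         max(exog$years) + 1, "]", call. = FALSE)

  m <- .multipliers(t, scenario, drift)
  yi <- .year_index(t, exog$years)
  e20 <- unname(exog$entry20[as.character(exog$years[yi])])
  e40 <- unname(exog$dial_entry40[yi]) * m$di
  mort <- exog$mort[, yi]
  p0 <- exog$entry_dm_prev

  age <- state * .aging_rates()
  inc <- params$ir_dm * state[.idx_ndm] * m$dm
  ini <- params$ir_di * state[.idx_dm40] * m$di
  dth <- mort * state

  ds <- .assemble_dstate(state, age, inc, ini, dth,
                         e20 * (1 - p0), e20 * p0, e40)

  b <- age_bands()
  aging <- age[-c(6L, 12L, 16L)]
  names(aging) <- paste0(rep(c("NDM", "DM", "DMDi"), c(5, 5, 3)),
                         c(b[1:5], b[1:5], b[3:5]), "aging")
  structure(list(
    entry = c(NDMto20 = e20 * (1 - p0), DMto20 = e20 * p0),
    aging = aging,
    incidence = stats::setNames(inc, paste0("NDM", b, "toDM")),
    initiation = stats::setNames(ini, paste0("DM", b[3:6], "toDMDi")),
    dialysis_entry40 = e40,
    deaths = stats::setNames(dth, paste0(stock_names(), "death")),
    dstate = stats::setNames(ds, stock_names())),
    class = "dmchain_flows")
}

# net derivative from flow components (shared by chain_flows and the
# integrator so the flow-balance identity is exact by construction)
.assemble_dstate <- function(s, age, inc, ini, dth, eN, eD, e40) {
  ds <- -age - dth
  ds[.idx_ndm] <- ds[.idx_ndm] - inc
  ds[.idx_dm]  <- ds[.idx_dm] + inc
  ds[.idx_dm40] <- ds[.idx_dm40] - ini
  ds[.idx_dmdi] <- ds[.idx_dmdi] + ini
  ds[2:6]   <- ds[2:6] + age[1:5]
  ds[8:12]  <- ds[8:12] + age[7:11]
  ds[14:16] <- ds[14:16] + age[13:15]
  ds[1L]  <- ds[1L] + eN
  ds[7L]  <- ds[7L] + eD
  ds[13L] <- ds[13L] + e40
  ds
}

.multipliers <- function(t, scenario, drift) {
  dm <- di <- rep(1, length(t))
  if (!is.null(scenario)) {
    dm <- ramp_multiplier(t, scenario, "dm")
    di <- ramp_multiplier(t, scenario, "di")
  }
  if (!is.null(drift)) {
    dm <- dm * exp(drift$g_dm * (t - drift$ref_year))
    di <- di * exp(drift$g_di * (t - drift$ref_year))
  }
  list(dm = dm, di = di)
}

#' Simulate the aging chain forward in time
#'
#' Explicit fixed-step (Euler) integration of the stock-and-flow system,
#' with annual output sampling.  The step is `1/round(1/dt)` years so an
#' integer number of steps falls in each calendar year; exogenous series
#' are treated as step functions constant within the year.  A step that
#' would drive a stock negative is clipped to zero and counted, and a
#' warning summarising all clipping events is raised at the end.
#'
#' @inheritParams chain_flows
#' @param t0,t1 Start and end calendar years (`t0 < t1`, integers).
#' @param dt Time step in years, `0 < dt <= 1` (default 1/16).
#' @param init Optional replacement initial stock vector (default
#'   `params$init`).
#' @return An object of class `dmchain_traj`: `years`, `stocks` (year x 16
#'   matrix), and `aggregates`, a data frame with NDMover20, DMover20,
#'   DMDiover40, TotalDM (= DMover20 + DMDiover40), popover20 and the
#'   diabetes prevalence in percent.
#' @examples
#' tp <- default_truth()
#' tr <- simulate_chain(tp$male$params, tp$male$exog, t1 = 2015)
#' head(tr$aggregates)
#' @export
simulate_chain <- function(params, exog, scenario = NULL, t0 = NULL,
                           t1 = 2035, dt = 1 / 16, drift = NULL,
                           init = NULL) {
  stopifnot(inherits(params, "dmchain_params"), inherits(exog, "dmchain_exog"))
  if (params$sex != exog$sex)
    stop("`params` and `exog` are for different sexes", call. = FALSE)
  if (is.null(t0)) t0 <- params$start_year
  if (!is.null(scenario) && !inherits(scenario, "dmchain_scenario"))
    stop("`scenario` must come from make_scenario()", call. = FALSE)
  if (dt > 1) stop("`dt` larger than 1 year is not supported", call. = FALSE)
  if (dt <= 0 || t0 >= t1) stop("need t0 < t1 and dt > 0", call. = FALSE)
  if (max(exog$years) < t1 - 1L)
    stop("exogenous series end in ", max(exog$years),
         "; extend_exogenous() to ", t1, " first", call. = FALSE)
  if (is.null(init)) init <- params$init
  if (!is.null(drift)) drift <- .check_drift(drift)

  spy <- max(1L, round(1 / dt))     # steps per year
  dt <- 1 / spy
  years <- seq(as.integer(t0), as.integer(t1))
  nyrs <- length(years) - 1L
  nstep <- nyrs * spy

  # per-step exogenous lookups, precomputed outside the hot loop
  tk <- t0 + (seq_len(nstep) - 1L) * dt
  yi <- .year_index(tk, exog$years)
  e20 <- unname(exog$entry20[as.character(exog$years)[yi]])
  e40 <- unname(exog$dial_entry40[yi])
  mstep <- exog$mort[, yi, drop = FALSE]
  m <- .multipliers(tk, scenario, drift)
  p0 <- exog$entry_dm_prev
  eN <- e20 * (1 - p0)
  eD <- e20 * p0
  e40m <- e40 * m$di

  aging_r <- .aging_rates()
  ir_dm <- unname(params$ir_dm)
  ir_di <- unname(params$ir_di)

  out <- matrix(NA_real_, nrow = length(years), ncol = 16L,
                dimnames = list(years, stock_names()))
  s <- unname(init)
  out[1L, ] <- s
  clipped <- 0L

  for (k in seq_len(nstep)) {
    age <- s * aging_r
    inc <- (ir_dm * m$dm[k]) * s[.idx_ndm]
    ini <- (ir_di * m$di[k]) * s[.idx_dm40]
    dth <- mstep[, k] * s
    ds <- .assemble_dstate(s, age, inc, ini, dth, eN[k], eD[k], e40m[k])
    s <- s + dt * ds
    neg <- s < 0
    if (any(neg)) {
      clipped <- clipped + sum(neg)
      s[neg] <- 0
    }
    if (k %% spy == 0L) {
      if (any(!is.finite(s)))
        stop("non-finite stock value in ",
             paste(stock_names()[!is.finite(s)], collapse = ", "),
             " at t = ", t0 + k * dt, call. = FALSE)
      out[k %/% spy + 1L, ] <- s
    }
  }
  if (clipped > 0L)
    warning("clipped ", clipped, " negative stock value(s) to zero (sex = ",
            params$sex, ", scenario = ",
            if (is.null(scenario)) "base" else scenario$name, ")",
            call. = FALSE)

  traj <- structure(list(
    sex = params$sex, years = years, stocks = out, dt = dt,
    scenario = if (is.null(scenario)) "base" else scenario$name,
    clipped = clipped), class = "dmchain_traj")
  traj$aggregates <- aggregate_series(traj)
  traj
}

#' Aggregate series of a simulated trajectory
#'
#' Sums the stocks of each health state over age bands and derives the
#' total diabetic population and adult diabetes prevalence.
#'
#' @param traj A `dmchain_traj` (its `stocks` matrix is re-summed; the
#'   aggregates stored on the trajectory are produced by this function).
#' @return A data frame with columns year, NDMover20, DMover20,
#'   DMDiover40, TotalDM, popover20, dm_prevalence_pct.
#' @export
aggregate_series <- function(traj) {
  stopifnot(inherits(traj, "dmchain_traj"))
  st <- traj$stocks
  if (is.null(dim(st))) st <- matrix(st, ncol = 16L)
  ndm <- rowSums(st[, .idx_ndm, drop = FALSE])
  dm <- rowSums(st[, .idx_dm, drop = FALSE])
  di <- rowSums(st[, .idx_dmdi, drop = FALSE])
  pop <- ndm + dm + di
  total <- dm + di
  data.frame(year = traj$years, NDMover20 = ndm, DMover20 = dm,
             DMDiover40 = di, TotalDM = total, popover20 = pop,
             dm_prevalence_pct = ifelse(pop > 0, total / pop * 100, NA_real_),
             row.names = NULL)
}

#' @export
print.dmchain_traj <- function(x, ...) {
  cat("Aging-chain trajectory (", x$sex, ", scenario ", x$scenario, "), ",
      x$years[1L], "-", x$years[length(x$years)], ", dt = 1/",
      round(1 / x$dt), " yr\n", sep = "")
  n <- nrow(x$aggregates)
  show <- x$aggregates[unique(c(1L, n)), ]
  print(cbind(show["year"], round(show[-1], 1)), row.names = FALSE)
  invisible(x)
}

#' @describeIn simulate_chain Long-format view: one row per (year, sex,
#'   variable, value) covering the 16 stocks and 6 aggregate series.
#' @param x A `dmchain_traj`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @export
as.data.frame.dmchain_traj <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  stocks <- data.frame(
    year = rep(x$years, times = 16L),
    sex = x$sex,
    variable = rep(stock_names(), each = length(x$years)),
    value = as.vector(x$stocks))
  ag <- x$aggregates
  aggs <- data.frame(
    year = rep(ag$year, times = 6L),
    sex = x$sex,
    variable = rep(names(ag)[-1], each = nrow(ag)),
    value = unlist(ag[-1], use.names = FALSE))
  rbind(stocks, aggs)
}

.check_drift <- function(drift) {
  if (is.null(drift$ref_year)) drift$ref_year <- 2000
  if (is.null(drift$g_dm)) drift$g_dm <- 0
  if (is.null(drift$g_di)) drift$g_di <- 0
  if (abs(drift$g_dm) > 0.05 || abs(drift$g_di) > 0.05)
    stop("|drift growth rate| must be <= 0.05/yr", call. = FALSE)
  drift
}
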