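#' Calibration weights from observed stock averages
#'
#' Each fitted observation series (population, diabetics, dialysis
#' patients; one per age band) receives the inverse of its mean over the
#' calibration window as weight, making the squared residuals scale-free
#' across stocks that differ by orders of magnitude.  A series with zero
#' mean is excluded from the payoff with a warning rather than given an
#' infinite weight — very small stocks would otherwise dominate and
#' destabilise the fit.
#'
#' @param sexdata One sex's component of a [dmchain_data] object.
#' @param years Calibration window (default: all years in the data).
#' @return An object of class `dmchain_weights`: named weights (1/persons)
#'   for the included variables, with excluded variable names in
#'   `attr(, "excluded")`.
#' @export
compute_weights <- function(sexdata, years = NULL) {
  obs <- .obs_matrix(sexdata, years)
  mu <- colMeans(obs)
  excluded <- names(mu)[mu <= 0]
  if (length(excluded))
    warning("variable(s) with zero mean excluded from the payoff: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  w <- 1 / mu[mu > 0]
  structure(w, excluded = excluded, class = "dmchain_weights")
}

# observed variable matrix: years x 16 named columns pop*/DM*/DMDi*
.obs_matrix <- function(sexdata, years = NULL) {
  if (is.null(years)) years <- sexdata$years
  i <- match(years, sexdata$years)
  if (anyNA(i)) stop("data do not cover the calibration window",
                     call. = FALSE)
  b <- age_bands()
  out <- cbind(sexdata$pop[i, , drop = FALSE],
               sexdata$dm[i, , drop = FALSE],
               sexdata$di[i, , drop = FALSE])
  colnames(out) <- .obs_names()
  rownames(out) <- years
  out
}

.obs_names <- function() {
  b <- age_bands()
  c(paste0("pop", b), paste0("DM", b), paste0("DMDi", b[3:6]))
}

# model analogue of the observed variables from a trajectory
.model_matrix <- function(traj, years) {
  i <- match(years, traj$years)
  if (anyNA(i)) stop("trajectory does not cover year(s) ",
                     paste(years[is.na(i)], collapse = ", "), call. = FALSE)
  st <- traj$stocks[i, , drop = FALSE]
  pop <- st[, .idx_ndm, drop = FALSE] + st[, .idx_dm, drop = FALSE]
  pop[, 3:6] <- pop[, 3:6] + st[, .idx_dmdi, drop = FALSE]
  out <- cbind(pop, st[, .idx_dm, drop = FALSE],
               st[, .idx_dmdi, drop = FALSE])
  colnames(out) <- .obs_names()
  out
}

#' Weighted squared-error calibration payoff
#'
#' The quantity minimised by calibration:
#' `sum over variables and years of (w_v * (model - observed))^2`.
#'
#' @param traj A simulated `dmchain_traj` covering the calibration years.
#' @param sexdata One sex's component of a [dmchain_data].
#' @param w Weights from [compute_weights()].
#' @param years Calibration window (default: the data years).
#' @return Non-negative scalar; 0 for a perfect fit.
#' @export
calibration_payoff <- function(traj, sexdata, w, years = NULL) {
  if (is.null(years)) years <- sexdata$years
  obs <- .obs_matrix(sexdata, years)
  mod <- .model_matrix(traj, years)
  miss <- setdiff(names(w), colnames(mod))
  if (length(miss))
    stop("model provides no variable named ", paste(miss, collapse = ", "),
         call. = FALSE)
  v <- names(w)
  sum((sweep(mod[, v, drop = FALSE] - obs[, v, drop = FALSE], 2,
             as.numeric(w), `*`))^2)
}

#' Control options for calibration
#'
#' @param starts Number of optimizer starts (default 8); start points are
#'   deterministic given `seed`.
#' @param seed Integer seed for the multi-start draws.
#' @param dt Integration step used during calibration (default 1/16 yr).
#' @param calibrate_init Also estimate the initial stocks (as multipliers
#'   of the start-year observations, bounded to +/- 20%)? Default `TRUE`.
#' @param drift Also estimate exponential drift coefficients (one per rate
#'   family, bounded to +/- 0.05/yr, reference year = start year)?
#'   Default `FALSE`.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @return A list of class `dmchain_control`.
#' @export
dmchain_control <- function(starts = 8L, seed = 1L, dt = 1 / 16,
                            calibrate_init = TRUE, drift = FALSE,
                            maxiter = 150L) {
  structure(list(starts = as.integer(starts), seed = as.integer(seed),
                 dt = dt, calibrate_init = isTRUE(calibrate_init),
                 drift = isTRUE(drift), maxiter = as.integer(maxiter)),
            class = "dmchain_control")
}

#' Calibrate the aging chain to an observation cross-table
#'
#' Estimates the sex-specific constant diabetes-incidence rates (6), the
#' dialysis-initiation rates (4) and the initial stocks by minimising the
#' weighted squared-error payoff ([calibration_payoff()]) between the
#' simulated and observed stock series over the calibration window.
#' Rates are bounded to \[0, 0.05\]/yr (diabetes incidence) and
#' \[0, 0.02\]/yr (dialysis initiation); initial stocks are searched
#' within 20% of the start-year observations.  The weighted residual
#' vector is minimised by bounded Levenberg-Marquardt with deterministic
#' multi-start; the best payoff wins, ties broken by the first start
#' found.
#'
#' @param data A [dmchain_data] observation cross-table.
#' @param sex `"male"` or `"female"` (calibrations are separate per sex).
#' @param window Calibration years (default: all years in the data).
#' @param control A [dmchain_control] list.
#' @return An object of class `dmchain` with components `params` (the
#'   fitted [dmchain_params]), `payoff`, `converged`, `n_evaluations`,
#'   `weights`, per-start diagnostics and per-variable residual summary.
#'   Supports `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot` and `simulate` methods.
#' @examples
#' \donttest{
#' fix <- build_japan_like_fixture()
#' fit <- dmchain(fix, "male", control = dmchain_control(starts = 2))
#' coef(fit)
#' }
#' @export
dmchain <- function(data, sex, window = NULL,
                    control = dmchain_control()) {
  stopifnot(inherits(data, "dmchain_data"))
  .check_sex(sex)
  if (is.null(data[[sex]])) stop("no ", sex, " data present", call. = FALSE)
  sexdata <- data[[sex]]
  if (is.null(window)) window <- sexdata$years
  w <- compute_weights(sexdata, window)
  obs <- .obs_matrix(sexdata, window)
  vinc <- names(w)
  wv <- as.numeric(w)
  start_year <- window[1L]

  # start-year observations define the initial-stock reference
  b0 <- obs[1L, ]
  init0 <- c(pmax(b0[1:6] - b0[7:12] - c(0, 0, b0[13:16]), 0),
             b0[7:12], b0[13:16])
  names(init0) <- stock_names()

  exog <- sexdata$exog
  nrate <- 10L
  lower <- c(rep(.RATE_BOUNDS$dm[1L], 6), rep(.RATE_BOUNDS$di[1L], 4))
  upper <- c(rep(.RATE_BOUNDS$dm[2L], 6), rep(.RATE_BOUNDS$di[2L], 4))
  if (control$drift) {
    lower <- c(lower, -0.05, -0.05)
    upper <- c(upper, 0.05, 0.05)
  }
  if (control$calibrate_init) {
    lower <- c(lower, rep(.INIT_BOUNDS[1L], 16))
    upper <- c(upper, rep(.INIT_BOUNDS[2L], 16))
  }

  unpack <- function(theta) {
    k <- nrate
    drift <- NULL
    if (control$drift) {
      drift <- list(g_dm = theta[k + 1L], g_di = theta[k + 2L],
                    ref_year = start_year)
      k <- k + 2L
    }
    init <- if (control$calibrate_init)
      init0 * theta[(k + 1L):(k + 16L)] else init0
    list(params = dmchain_params(sex, theta[1:6], theta[7:10], init,
                                 start_year),
         drift = drift)
  }

  nfev <- 0L
  resid_fun <- function(theta) {
    nfev <<- nfev + 1L
    pd <- unpack(theta)
    tr <- suppressWarnings(simulate_chain(
      pd$params, exog, t0 = start_year, t1 = window[length(window)],
      dt = control$dt, drift = pd$drift))
    mod <- .model_matrix(tr, window)
    as.vector(sweep(mod[, vinc, drop = FALSE] -
                      obs[, vinc, drop = FALSE], 2, wv, `*`))
  }

  theta0 <- c(rep(0.004, 6), rep(0.001, 4),
              if (control$drift) c(0, 0),
              if (control$calibrate_init) rep(1, 16))
  starts <- list(theta0)
  if (control$starts > 1L) {
    for (i in 2:control$starts) {
      set.seed(control$seed + i)
      th <- c(stats::runif(6, 0, 0.02), stats::runif(4, 0, 0.005),
              if (control$drift) stats::runif(2, -0.02, 0.02),
              if (control$calibrate_init) stats::runif(16, 0.9, 1.1))
      starts[[i]] <- pmin(pmax(th, lower), upper)
    }
  }

  runs <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    runs[[i]] <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[[i]], lower = lower, upper = upper, fn = resid_fun,
        control = minpack.lm::nls.lm.control(
          maxiter = control$maxiter, nprint = 0)),
      error = function(e) e)
  }
  ok <- !vapply(runs, inherits, logical(1), "error")
  if (!any(ok)) {
    diag <- vapply(seq_along(runs), function(i)
      paste0("start ", i, ": ", conditionMessage(runs[[i]])), character(1))
    stop("optimizer failed on every start:\n  ",
         paste(diag, collapse = "\n  "), call. = FALSE)
  }
  dev <- vapply(runs, function(r) if (inherits(r, "error")) Inf else
    r$deviance, numeric(1))
  best_i <- which.min(dev)          # ties -> first found
  best <- runs[[best_i]]
  pd <- unpack(best$par)

  fitted_traj <- suppressWarnings(simulate_chain(
    pd$params, exog, t0 = start_year, t1 = window[length(window)],
    dt = control$dt, drift = pd$drift))
  mod <- .model_matrix(fitted_traj, window)
  res_raw <- mod - obs
  rsum <- data.frame(
    variable = colnames(obs),
    included = colnames(obs) %in% vinc,
    mean_obs = colMeans(obs),
    rmse = sqrt(colMeans(res_raw^2)),
    row.names = NULL)

  structure(list(
    sex = sex, params = pd$params, drift = pd$drift,
    payoff = best$deviance,
    converged = best$info %in% 1:4,
    n_evaluations = nfev,
    best_start = best_i,
    start_payoffs = dev,
    weights = w, window = window,
    residual_summary = rsum,
    data = sexdata, control = control,
    optimizer_info = best$info, optimizer_message = best$message),
    class = "dmchain")
}
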