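#' Exogenous inputs driving the aging chain
#'
#' Bundles the externally supplied annual series the simulator consumes:
#' the entry cohort reaching age 20 each year, the dialysis-patient inflow
#' reaching age 40 each year, per-stock mortality rates, and the diabetes
#' prevalence assumed among 20-year-old entrants.  All series are step
#' functions, constant within each calendar year.
#'
#' @param sex `"male"` or `"female"`.
#' @param years Integer calendar years the series cover (consecutive).
#' @param entry20 Persons/year entering the 20-29 band; either length
#'   `length(years)` or longer (a named vector extending past the last
#'   `years` entry, e.g. entry cohorts projected through the horizon).
#' @param dial_entry40 Persons/year entering the dialysis stock at age 40.
#' @param mort 16 x `length(years)` matrix of mortality rates (1/yr), rows
#'   in [stock_names()] order, columns the years.
#' @param entry_dm_prev Fraction of 20-year-old entrants who already have
#'   diabetes. Default 0.002 (0.2%).
#' @return An object of class `dmchain_exog`.
#' @seealso [extend_exogenous()]
#' @export
dmchain_exog <- function(sex, years, entry20, dial_entry40, mort,
                         entry_dm_prev = 0.002) {
  .check_sex(sex)
  years <- as.integer(years)
  stopifnot(length(years) >= 1L, all(diff(years) == 1L))
  n <- length(years)

  if (is.null(names(entry20))) {
    stopifnot(length(entry20) >= n)
    names(entry20) <- seq(years[1L], length.out = length(entry20))
  }
  if (is.null(names(dial_entry40))) {
    stopifnot(length(dial_entry40) == n)
    names(dial_entry40) <- years
  }
  mort <- as.matrix(mort)
  if (nrow(mort) != 16L || ncol(mort) != n)
    stop("`mort` must be a 16 x ", n, " matrix (stocks x years)", call. = FALSE)
  rownames(mort) <- stock_names()
  colnames(mort) <- years

  if (any(entry20 < 0) || any(dial_entry40 < 0) || any(mort < 0))
    stop("exogenous series must be non-negative", call. = FALSE)
  if (entry_dm_prev < 0 || entry_dm_prev > 1)
    stop("`entry_dm_prev` must lie in [0, 1]", call. = FALSE)

  structure(
    list(sex = sex, years = years, entry20 = entry20,
         dial_entry40 = dial_entry40, mort = mort,
         entry_dm_prev = entry_dm_prev),
    class = "dmchain_exog")
}

#' Extend exogenous series to a simulation horizon
#'
#' Years past the end of each observed series carry the final observed
#' value forward, the convention used for projection runs.  The entry
#' cohort series is exempt when it already extends past the data window
#' (entry cohorts two decades ahead are known from the current child
#' population, so they are supplied explicitly through the horizon).
#'
#' @param exog A [dmchain_exog] object.
#' @param horizon Final calendar year required.
#' @return A `dmchain_exog` covering `min(years) .. horizon`.
#' @export
extend_exogenous <- function(exog, horizon) {
  stopifnot(inherits(exog, "dmchain_exog"))
  horizon <- as.integer(horizon)
  last <- exog$years[length(exog$years)]
  if (horizon <= last && horizon <= max(as.integer(names(exog$entry20))))
    return(exog)
  if (horizon <= last) return(exog)
  add <- seq(last + 1L, horizon)
  years2 <- c(exog$years, add)

  hold <- function(v, yrs) {
    have <- as.integer(names(v))
    need <- setdiff(yrs, have)
    if (length(need)) {
      ext <- rep(v[[length(v)]], length(need))
      names(ext) <- need
      v <- c(v, ext)
    }
    v[as.character(yrs)]
  }
  entry20 <- {
    have <- as.integer(names(exog$entry20))
    full <- seq(min(have), horizon)
    hold(exog$entry20, full)
  }
  dial40 <- hold(exog$dial_entry40, years2)
  mort <- cbind(exog$mort,
                matrix(exog$mort[, ncol(exog$mort)], nrow = 16L,
                       ncol = length(add),
                       dimnames = list(stock_names(), add)))
  dmchain_exog(exog$sex, years2, entry20, dial40, mort, exog$entry_dm_prev)
}

# column index of year floor(t) in a series covering `years`, clamped
.year_index <- function(t, years) {
  i <- floor(t + 1e-9) - years[1L] + 1L
  pmin(pmax(i, 1L), length(years))
}
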