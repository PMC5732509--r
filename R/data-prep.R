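#' Interpolate diabetes prevalence between anchor years
#'
#' Sex- and band-specific prevalence estimates are available at the anchor
#' years 2000, 2005 and 2010 only; the calibration window needs every year.
#' Values between anchors are linearly interpolated; years beyond the last
#' anchor are linearly extrapolated with the most recent (2005-2010)
#' slope.  Results are clipped to [0, 100].
#'
#' @param anchors Named numeric of length 3: prevalence (%) at years
#'   `"2000"`, `"2005"`, `"2010"`.
#' @param years Years to evaluate (default 2000:2015).
#' @return Named numeric: prevalence (%) per year.
#' @examples
#' interpolate_prevalence(c("2000" = 5, "2005" = 6, "2010" = 6.6))
#' @export
interpolate_prevalence <- function(anchors, years = 2000:2015) {
  ay <- c(2000, 2005, 2010)
  if (length(anchors) != 3L || any(is.na(anchors)))
    stop("need the three anchor values (2000, 2005, 2010)", call. = FALSE)
  if (!is.null(names(anchors))) {
    if (!setequal(names(anchors), as.character(ay)))
      stop("anchor names must be 2000, 2005, 2010", call. = FALSE)
    anchors <- anchors[as.character(ay)]
  }
  slope <- (anchors[[3L]] - anchors[[2L]]) / 5
  out <- ifelse(years <= 2010,
                stats::approx(ay, anchors, xout = pmax(years, 2000),
                              rule = 2)$y,
                anchors[[3L]] + slope * (years - 2010))
  out <- pmin(pmax(out, 0), 100)
  stats::setNames(out, years)
}

#' Counts from prevalence percentages
#'
#' @param pct Named numeric, prevalence (%) per year.
#' @param population Named numeric, persons per year (same years).
#' @return Persons with the condition per year.
#' @export
counts_from_prevalence <- function(pct, population) {
  if (length(pct) != length(population) ||
      (!is.null(names(pct)) && !is.null(names(population)) &&
       !identical(names(pct), names(population))))
    stop("prevalence and population series must cover the same years",
         call. = FALSE)
  pct / 100 * population
}

#' Back-cast age-specific dialysis counts from aggregate totals
#'
#' For early years only all-cause dialysis counts per band and the overall
#' total due to diabetic nephropathy are known.  Each band's all-cause
#' count is multiplied by that band's mean nephropathy share (averaged over
#' the later years where cause-specific counts exist), and the result is
#' rescaled so the bands sum exactly to the known total.
#'
#' @param allcause Persons on dialysis (any cause) per band.
#' @param mean_dn_share Mean fraction due to diabetic nephropathy per band,
#'   each in [0, 1].
#' @param total_dn Total persons on dialysis due to diabetic nephropathy.
#' @return Persons per band, summing exactly to `total_dn`.
#' @examples
#' backcast_dialysis_counts(c(100, 300), c(0.3, 0.4), 100)  # 20, 80
#' @export
backcast_dialysis_counts <- function(allcause, mean_dn_share, total_dn) {
  stopifnot(length(allcause) == length(mean_dn_share), total_dn >= 0,
            all(mean_dn_share >= 0), all(mean_dn_share <= 1))
  raw <- allcause * mean_dn_share
  if (total_dn == 0) return(raw * 0)
  if (sum(raw) == 0)
    stop("all band-level estimates are zero but total_dn > 0", call. = FALSE)
  raw * (total_dn / sum(raw))
}

#' Split all-cause mortality into non-diabetic and diabetic rates
#'
#' Given the all-population mortality rate, the diabetes prevalence and a
#' DM:non-DM mortality hazard ratio (default 2, i.e. a 1:2 non-DM:DM
#' ratio), solves `m_ndm*(1-p) + hr*m_ndm*p = m_all` so that the
#' prevalence-weighted mixture reproduces the observed rate exactly.
#'
#' @param m_all All-cause mortality rate (1/yr).
#' @param dm_prev Diabetes prevalence as a fraction in [0, 1).
#' @param hazard_ratio DM vs non-DM mortality ratio, `>= 1` (default 2).
#' @return Named numeric: `m_ndm` and `m_dm = hazard_ratio * m_ndm`.
#' @examples
#' decompose_mortality(0.011, 0.1)  # m_ndm 0.010, m_dm 0.020
#' @export
decompose_mortality <- function(m_all, dm_prev, hazard_ratio = 2) {
  if (any(m_all < 0)) stop("mortality must be non-negative", call. = FALSE)
  stopifnot(all(dm_prev >= 0), all(dm_prev < 1), hazard_ratio >= 1)
  m_ndm <- m_all / (1 + (hazard_ratio - 1) * dm_prev)
  c(m_ndm = unname(m_ndm), m_dm = unname(hazard_ratio * m_ndm))
}

#' Mortality among diabetics not on dialysis
#'
#' The diabetic mortality rate from [decompose_mortality()] covers all
#' diabetics including those on dialysis, who die much faster.  Removing
#' the dialysis deaths by death-count bookkeeping gives the rate for the
#' DM (not on dialysis) stocks:
#' `(m_dm*n_dm_total - m_di*n_di) / (n_dm_total - n_di)`, floored at 0
#' with a warning if the dialysis deaths exceed the total.
#'
#' @param m_dm Mortality among all diabetics (1/yr).
#' @param n_dm_total All diabetics (persons), `> n_di`.
#' @param m_di Mortality among dialysis patients (1/yr).
#' @param n_di Diabetics on dialysis (persons).
#' @return Mortality rate (1/yr) for diabetics not on dialysis.
#' @export
nondialysis_dm_mortality <- function(m_dm, n_dm_total, m_di, n_di) {
  if (any(n_dm_total <= n_di))
    stop("need n_dm_total > n_di", call. = FALSE)
  out <- (m_dm * n_dm_total - m_di * n_di) / (n_dm_total - n_di)
  if (any(out < 0)) {
    warning("dialysis deaths exceed total diabetic deaths; ",
            "non-dialysis DM mortality floored at 0", call. = FALSE)
    out <- pmax(out, 0)
  }
  out
}

#' Dialysis inflow at age 40
#'
#' The annual number of dialysis patients crossing their 40th birthday is
#' estimated from the prevalent counts in the flanking five-year age
#' groups: the 35-39 and 40-44 counts are averaged and divided by five.
#'
#' @param n_35_39,n_40_44 Persons on dialysis due to diabetic nephropathy
#'   aged 35-39 and 40-44.
#' @return Persons per year.
#' @examples
#' inflow_at_40(600, 400)  # 100 persons/yr
#' @export
inflow_at_40 <- function(n_35_39, n_40_44) {
  stopifnot(all(n_35_39 >= 0), all(n_40_44 >= 0))
  (n_35_39 + n_40_44) / 2 / 5
}

#' Back-extrapolate dialysis mortality from the observed window
#'
#' Cause-specific dialysis mortality is observed for 2012-2015 only; the
#' earlier years are filled by evaluating the ordinary least-squares line
#' through the four observed points backwards, clipping to [0, 1].
#'
#' @param rates Named numeric length 4: observed rates for 2012-2015.
#' @param years Years to back-fill (default 2000:2011).
#' @return Named numeric of extrapolated rates, one per `years`.
#' @export
extrapolate_dialysis_mortality <- function(rates, years = 2000:2011) {
  if (length(rates) != 4L || any(!is.finite(rates)))
    stop("need four finite observed rates (2012-2015)", call. = FALSE)
  obs_years <- if (is.null(names(rates))) 2012:2015 else
    as.integer(names(rates))
  fit <- stats::lm.fit(cbind(1, obs_years), as.numeric(rates))
  out <- fit$coefficients[1L] + fit$coefficients[2L] * years
  if (any(out < 0) || any(out > 1)) {
    warning("extrapolated dialysis mortality clipped to [0, 1] in year(s) ",
            paste(years[out < 0 | out > 1], collapse = ", "), call. = FALSE)
    out <- pmin(pmax(out, 0), 1)
  }
  stats::setNames(out, years)
}
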