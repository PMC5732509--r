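#' Ground-truth settings for synthetic observation data
#'
#' A truth object bundles, per sex, the generating [dmchain_params] and
#' [dmchain_exog], plus the observation-noise level and RNG seed.  Feeding
#' it to [generate_synthetic_country()] yields an observation cross-table
#' with the statistical structure the calibration assumes, with the truth
#' known by construction — the basis of all parameter-recovery tests.
#'
#' @param male,female Per-sex lists with elements `params` and `exog`.
#' @param cv Coefficient of variation of multiplicative observation noise
#'   (`>= 0`; 0 means observations equal model output exactly).
#' @param seed Integer RNG seed for the noise draws.
#' @return An object of class `dmchain_truth`.
#' @export
truth_params <- function(male = NULL, female = NULL, cv = 0, seed = 1L) {
  stopifnot(cv >= 0)
  parts <- Filter(Negate(is.null), list(male = male, female = female))
  if (!length(parts)) stop("supply at least one sex", call. = FALSE)
  for (nm in names(parts)) {
    p <- parts[[nm]]
    stopifnot(inherits(p$params, "dmchain_params"),
              inherits(p$exog, "dmchain_exog"))
    for (fam in c("dm", "di")) {
      r <- if (fam == "dm") p$params$ir_dm else p$params$ir_di
      if (any(r > .RATE_BOUNDS[[fam]][2L]))
        stop("truth ", fam, " rates exceed the calibration bound ",
             .RATE_BOUNDS[[fam]][2L], call. = FALSE)
    }
  }
  structure(c(parts, list(cv = cv, seed = as.integer(seed))),
            class = "dmchain_truth")
}

#' @rdname truth_params
#' @details `default_truth()` supplies a Japan-scale default: entry
#'   cohorts declining 0.8%/yr, age-increasing mortality with a 2:1 DM
#'   vs non-DM hazard ratio, dialysis mortality an order of magnitude
#'   above diabetic mortality, and age-increasing incidence rates.
#' @export
default_truth <- function(cv = 0, seed = 1L) {
  b <- age_bands()
  mk <- function(sex, pop0, prev0, ir_dm, ir_di, m_ndm, m_di, e20_0,
                 di0_total) {
    years <- 2000:2015
    di_shares <- c(0.055, 0.205, 0.37, 0.37)
    di0 <- di0_total * di_shares
    dm0 <- pop0 * prev0
    init <- c(pop0 - dm0, dm0 - c(0, 0, di0), di0)
    init[init < 0] <- 0
    m_dm <- 2 * m_ndm
    mort <- matrix(rep(c(m_ndm, m_dm, m_di), length(years)), nrow = 16L)
    entry20 <- e20_0 * 0.992^(0:35)
    names(entry20) <- 2000:2035
    dial40 <- seq(di0_total * 0.004, di0_total * 0.006, length.out = 16)
    dmchain_truth_sex(sex, ir_dm, ir_di, init, years, entry20, dial40, mort)
  }
  male <- mk("male",
             pop0 = c(9.44, 8.20, 8.03, 9.59, 7.34, 4.71) * 1e6,
             prev0 = c(0.007, 0.020, 0.050, 0.110, 0.190, 0.220),
             ir_dm = c(0.0008, 0.0015, 0.0035, 0.0060, 0.0090, 0.0110),
             ir_di = c(0.0012, 0.0016, 0.0020, 0.0024),
             m_ndm = c(0.0007, 0.0011, 0.0025, 0.0060, 0.0140, 0.0520),
             m_di = c(0.036, 0.056, 0.086, 0.142),
             e20_0 = 790000, di0_total = 34672)
  female <- mk("female",
               pop0 = c(9.07, 8.00, 7.93, 9.86, 7.90, 7.09) * 1e6,
               prev0 = c(0.005, 0.013, 0.032, 0.072, 0.130, 0.160),
               ir_dm = c(0.0006, 0.0011, 0.0024, 0.0042, 0.0063, 0.0078),
               ir_di = c(0.0008, 0.0011, 0.0014, 0.0017),
               m_ndm = c(0.00032, 0.00060, 0.0014, 0.0030, 0.0062, 0.0420),
               m_di = c(0.031, 0.051, 0.081, 0.132),
               e20_0 = 750000, di0_total = 17219)
  truth_params(male, female, cv = cv, seed = seed)
}

# assemble one sex of a truth object
dmchain_truth_sex <- function(sex, ir_dm, ir_di, init, years, entry20,
                              dial40, mort) {
  list(params = dmchain_params(sex, ir_dm, ir_di, init,
                               start_year = years[1L]),
       exog = dmchain_exog(sex, years, entry20, dial40, mort))
}

#' Generate a synthetic observation cross-table from known truth
#'
#' Forward-simulates the true model over the calibration window, samples
#' the stocks annually, and applies independent multiplicative log-normal
#' noise with the stated coefficient of variation (mean-one, so `cv = 0`
#' reproduces the simulated stocks exactly).  Fully reproducible from the
#' truth seed.
#'
#' @param truth A [truth_params] object.
#' @param dt Integration step (default 1/16 yr).
#' @return A [dmchain_data] observation cross-table.
#' @export
generate_synthetic_country <- function(truth, dt = 1 / 16) {
  stopifnot(inherits(truth, "dmchain_truth"))
  set.seed(truth$seed)
  sdlog <- if (truth$cv > 0) sqrt(log(1 + truth$cv^2)) else 0
  noise <- function(n) {
    if (sdlog == 0) rep(1, n) else
      exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
  }
  parts <- lapply(.SEXES[.SEXES %in% names(truth)], function(sex) {
    tp <- truth[[sex]]
    years <- tp$exog$years
    tr <- simulate_chain(tp$params, tp$exog, t0 = years[1L],
                         t1 = years[length(years)], dt = dt)
    st <- tr$stocks
    ndm <- st[, .idx_ndm, drop = FALSE]
    dm <- st[, .idx_dm, drop = FALSE]
    di <- st[, .idx_dmdi, drop = FALSE]
    pop <- ndm + dm
    pop[, 3:6] <- pop[, 3:6] + di
    ny <- nrow(st)
    pop_o <- pop * matrix(noise(ny * 6L), ny)
    dm_o <- dm * matrix(noise(ny * 6L), ny)
    di_o <- di * matrix(noise(ny * 4L), ny)
    # noise must not break the dm + dialysis <= pop invariant
    di6 <- cbind(matrix(0, ny, 2L), di_o)
    pop_o <- pmax(pop_o, dm_o + di6)
    dimnames(pop_o) <- dimnames(dm_o) <- list(years, age_bands())
    dimnames(di_o) <- list(years, age_bands()[3:6])
    list(sex = sex, years = years, pop = pop_o, dm = dm_o, di = di_o,
         exog = tp$exog)
  })
  do.call(dmchain_data, parts)
}

#' Printed anchor values of the Japan-like fixture
#'
#' Published endpoint totals for Japan that the deterministic fixture
#' reproduces exactly: sex-specific diabetic populations (including those
#' on dialysis) and dialysis populations due to diabetic nephropathy in
#' 2000 and 2015, plus the 2015 under-40 dialysis counts that scale the
#' exogenous inflow at age 40.
#'
#' @return A list with elements `dm_total`, `di_total` (2 x 2 matrices,
#'   sex x year) and `under40_2015` (named vector).
#' @export
fixture_anchors <- function() {
  list(
    dm_total = matrix(c(4.19e6, 2.90e6, 5.32e6, 3.39e6), 2,
                      dimnames = list(.SEXES, c("2000", "2015"))),
    di_total = matrix(c(34672, 17219, 83858, 35048), 2,
                      dimnames = list(.SEXES, c("2000", "2015"))),
    under40_2015 = c(male = 947, female = 421))
}

# monotone Hermite interpolation between two endpoint values with end
# slopes tapered relative to the mean slope (growth decelerates)
.taper_interp <- function(y0, y1, years, f0 = 1.3, f1 = 0.7) {
  n <- length(years)
  tau <- (years - years[1L]) / (years[n] - years[1L])
  m0 <- f0 * (y1 - y0)   # slopes in tau units
  m1 <- f1 * (y1 - y0)
  h00 <- 2 * tau^3 - 3 * tau^2 + 1
  h10 <- tau^3 - 2 * tau^2 + tau
  h01 <- -2 * tau^3 + 3 * tau^2
  h11 <- tau^3 - tau^2
  y0 * h00 + m0 * h10 + y1 * h01 + m1 * h11
}

#' Deterministic Japan-like observation fixture
#'
#' Builds an observation cross-table anchored exactly to published
#' endpoint totals for Japan (see [fixture_anchors()]), with monotone
#' cubic interpolation between the anchors (slopes tapering toward 2015,
#' since the observed series decelerate), fixed documented age-allocation
#' shares, and mortality schedules produced by the package's own
#' decomposition at a DM:non-DM hazard ratio of 2.
#'
#' Frozen allocation constants (fractions of the sex total):
#' diabetes by band — males 0.015/0.045/0.105/0.245/0.33/0.26, females
#' 0.012/0.038/0.095/0.225/0.33/0.30; dialysis by band (40+) —
#' 0.055/0.205/0.37/0.37 for both sexes, reflecting the strong old-age
#' skew of the dialysis population.
#'
#' @param hazard_ratio DM:non-DM mortality ratio (default 2).
#' @param entry_dm_prev Diabetes prevalence among 20-year-old entrants
#'   (default 0.002).
#' @return A [dmchain_data] with both sexes, years 2000-2015, entry
#'   cohorts supplied through 2035.
#' @export
build_japan_like_fixture <- function(hazard_ratio = 2,
                                     entry_dm_prev = 0.002) {
  anch <- fixture_anchors()
  years <- 2000:2015
  ny <- length(years)
  b <- age_bands()

  pop_ends <- list(
    male = rbind(c(9.44, 8.20, 8.03, 9.59, 7.34, 4.71),
                 c(6.42, 7.88, 9.32, 7.68, 8.77, 7.39)) * 1e6,
    female = rbind(c(9.07, 8.00, 7.93, 9.86, 7.90, 7.09),
                   c(6.08, 7.61, 9.13, 7.79, 9.27, 11.01)) * 1e6)
  dm_shares <- list(male = c(0.015, 0.045, 0.105, 0.245, 0.33, 0.26),
                    female = c(0.012, 0.038, 0.095, 0.225, 0.33, 0.30))
  di_shares <- c(0.055, 0.205, 0.37, 0.37)
  # all-cause mortality per band at the window endpoints (1/yr)
  mall_ends <- list(
    male = rbind(c(0.00075, 0.0012, 0.0028, 0.0068, 0.016, 0.058),
                 c(0.00060, 0.0009, 0.0022, 0.0052, 0.012, 0.052)),
    female = rbind(c(0.00035, 0.0007, 0.0016, 0.0034, 0.0068, 0.044),
                   c(0.00028, 0.00055, 0.0012, 0.0025, 0.0052, 0.040)))
  # dialysis mortality per 40+ band, observed 2012 and 2015 (1/yr)
  mdi_ends <- list(male = rbind(c(0.037, 0.057, 0.088, 0.145),
                                c(0.035, 0.055, 0.085, 0.140)),
                   female = rbind(c(0.033, 0.053, 0.083, 0.135),
                                  c(0.031, 0.051, 0.080, 0.130)))
  entry20_anchor <- list(male = c(810000, 625000, 520000),
                         female = c(770000, 595000, 495000))

  lin <- function(ends, yrs = years) {
    tau <- (yrs - yrs[1L]) / (yrs[length(yrs)] - yrs[1L])
    outer(1 - tau, ends[1L, ]) + outer(tau, ends[2L, ])
  }

  parts <- lapply(.SEXES, function(sex) {
    pop <- lin(pop_ends[[sex]])
    dm_total <- .taper_interp(anch$dm_total[sex, "2000"],
                              anch$dm_total[sex, "2015"], years)
    di_total <- .taper_interp(anch$di_total[sex, "2000"],
                              anch$di_total[sex, "2015"], years,
                              f0 = 1.5, f1 = 0.5)
    di <- outer(di_total, di_shares)
    dm_all <- outer(dm_total, dm_shares[[sex]])   # includes dialysis
    dm <- dm_all
    dm[, 3:6] <- dm[, 3:6] - di
    dimnames(pop) <- dimnames(dm) <- list(years, b)
    dimnames(di) <- list(years, b[3:6])

    # exogenous mortality: decompose all-cause at the hazard ratio using
    # that year's band prevalence, then strip dialysis deaths out of the
    # diabetic rate for the 40+ bands
    m_all <- lin(mall_ends[[sex]])
    prev <- dm_all / pop
    dec <- decompose_mortality(as.vector(m_all), as.vector(prev),
                               hazard_ratio)
    n6 <- ny * 6L
    m_ndm <- matrix(dec[seq_len(n6)], ny)
    m_dm <- matrix(dec[n6 + seq_len(n6)], ny)
    m_di_obs <- lin(mdi_ends[[sex]], 2012:2015)
    m_di <- matrix(NA_real_, ny, 4L)
    for (j in 1:4) {
      m_di[, j] <- c(extrapolate_dialysis_mortality(
        stats::setNames(m_di_obs[, j], 2012:2015)), m_di_obs[, j])
    }
    m_dm_nd <- m_dm
    m_dm_nd[, 3:6] <- nondialysis_dm_mortality(
      m_dm[, 3:6], dm_all[, 3:6], m_di, di)
    mort <- rbind(t(m_ndm), t(m_dm_nd), t(m_di))

    e_anch <- entry20_anchor[[sex]]
    entry20 <- stats::approx(c(2000, 2015, 2035), e_anch,
                             xout = 2000:2035)$y
    names(entry20) <- 2000:2035

    # dialysis inflow at 40 from the flanking five-year groups, scaled
    # with the dialysis total (under-40 anchor pinned at 2015)
    scale15 <- di_total / di_total[ny]
    n3539 <- 0.7 * anch$under40_2015[[sex]] * scale15
    n4044 <- 0.5 * di[, 1L]
    dial40 <- inflow_at_40(n3539, n4044)

    exog <- dmchain_exog(sex, years, entry20, dial40, mort,
                         entry_dm_prev = entry_dm_prev)
    list(sex = sex, years = years, pop = pop, dm = dm, di = di,
         exog = exog)
  })
  out <- do.call(dmchain_data, parts)
  attr(out, "anchors") <- anch
  out
}
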