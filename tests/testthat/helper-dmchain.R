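# shared fixtures, memoized so expensive calibrations run once per suite

.tt_cache <- new.env(parent = emptyenv())

tt_memo <- function(key, expr) {
  if (!exists(key, .tt_cache)) assign(key, force(expr), .tt_cache)
  get(key, .tt_cache)
}

tt_fixture <- function() tt_memo("fixture", build_japan_like_fixture())

# Japan-like fixture calibration, shared across scenario/sensitivity/
# acceptance tests
tt_fit <- function(sex) {
  tt_memo(paste0("fit_", sex), suppressWarnings(
    dmchain(tt_fixture(), sex,
            control = dmchain_control(starts = 4, seed = 1))))
}

tt_truth <- function() tt_memo("truth", default_truth(cv = 0, seed = 7))

tt_synth <- function() tt_memo("synth",
                               generate_synthetic_country(tt_truth()))

# noise-free recovery fit at the default optimizer settings
tt_recovery_fit <- function(sex) {
  tt_memo(paste0("recovery_", sex),
          dmchain(tt_synth(), sex, control = dmchain_control(starts = 8)))
}

# single-compartment system: one isolated terminal stock (NDMover70) with
# a pure death rate, everything else switched off
tt_single_stock <- function(rate = 0.1, init_value = 1000,
                            years = 2000:2010) {
  init <- rep(0, 16)
  init[6] <- init_value
  mort <- matrix(0, 16, length(years))
  mort[6, ] <- rate
  exog <- dmchain_exog("male", years,
                       entry20 = rep(0, length(years)),
                       dial_entry40 = rep(0, length(years)),
                       mort = mort, entry_dm_prev = 0)
  params <- dmchain_params("male", rep(0, 6), rep(0, 4), init,
                           start_year = years[1])
  list(params = params, exog = exog)
}

# hand-built trajectory whose TotalDM series is exactly `totaldm`
tt_toy_traj <- function(years, totaldm, sex = "male") {
  stocks <- matrix(0, length(years), 16,
                   dimnames = list(years, stock_names()))
  stocks[, 7] <- totaldm      # DM2029 carries the whole aggregate
  stocks[, 1] <- 1e6          # some NDM so prevalence is defined
  tr <- structure(list(sex = sex, years = years, stocks = stocks,
                       dt = 1 / 16, scenario = "base", clipped = 0L),
                  class = "dmchain_traj")
  tr$aggregates <- aggregate_series(tr)
  tr
}
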