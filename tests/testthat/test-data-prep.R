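test_that("prevalence interpolation and extrapolation follow the anchors", {
  a <- c("2000" = 5.0, "2005" = 6.0, "2010" = 6.6)
  out <- interpolate_prevalence(a, 2000:2015)
  expect_equal(unname(out["2003"]), 5.6)
  expect_equal(unname(out["2013"]), 6.96)          # 2005-2010 slope 0.12/yr
  expect_equal(unname(out[c("2000", "2005", "2010")]), unname(a))
  flat <- interpolate_prevalence(c("2000" = 7, "2005" = 7, "2010" = 7))
  expect_true(all(flat == 7))
  # extrapolation is clipped into [0, 100]
  falling <- interpolate_prevalence(c("2000" = 9, "2005" = 5, "2010" = 1),
                                    2000:2015)
  expect_true(all(falling >= 0))
  expect_error(interpolate_prevalence(c("2000" = 5, "2005" = 6)),
               "anchor")
})

test_that("prevalence percentages convert to counts", {
  expect_equal(counts_from_prevalence(6, 1e7), 6e5)
  expect_equal(counts_from_prevalence(0, 123), 0)
  expect_equal(counts_from_prevalence(100, 456), 456)
  expect_error(counts_from_prevalence(c("2000" = 5),
                                      c("2001" = 100)), "same years")
})

test_that("dialysis back-casting rescales to the known total", {
  expect_equal(backcast_dialysis_counts(c(100, 300), c(0.3, 0.4), 100),
               c(20, 80))
  expect_equal(backcast_dialysis_counts(c(100, 300), c(0.3, 0.4), 0),
               c(0, 0))
  # equal shares: output proportional to the all-cause counts
  out <- backcast_dialysis_counts(c(50, 150, 300), rep(0.35, 3), 1000)
  expect_equal(out / sum(out), c(50, 150, 300) / 500)
  # exact-total property over random cases
  set.seed(42)
  for (i in 1:20) {
    ac <- stats::runif(4, 10, 1e4)
    sh <- stats::runif(4, 0.05, 0.9)
    tot <- stats::runif(1, 0, 1e5)
    expect_equal(sum(backcast_dialysis_counts(ac, sh, tot)), tot)
  }
  expect_error(backcast_dialysis_counts(c(0, 0), c(0.3, 0.4), 10),
               "zero")
})

test_that("mortality decomposition solves the mixture exactly", {
  out <- decompose_mortality(0.011, 0.1, 2)
  expect_equal(unname(out), c(0.010, 0.020))
  expect_equal(unname(decompose_mortality(0.02, 0)), c(0.02, 0.04))
  out1 <- decompose_mortality(0.02, 0.3, hazard_ratio = 1)
  expect_equal(unname(out1), c(0.02, 0.02))
  # substituting back reproduces the all-cause rate to machine precision
  set.seed(11)
  for (i in 1:20) {
    m <- stats::runif(1, 0, 0.2)
    p <- stats::runif(1, 0, 0.9)
    hr <- stats::runif(1, 1, 4)
    d <- decompose_mortality(m, p, hr)
    expect_equal(d[["m_ndm"]] * (1 - p) + d[["m_dm"]] * p, m)
    expect_equal(d[["m_dm"]], hr * d[["m_ndm"]])
  }
  expect_error(decompose_mortality(-0.01, 0.1), "non-negative")
})

test_that("non-dialysis diabetic mortality keeps the death bookkeeping", {
  expect_equal(nondialysis_dm_mortality(0.02, 1e6, 0.08, 5e4),
               16000 / 950000)
  expect_equal(nondialysis_dm_mortality(0.02, 1e6, 0.08, 0), 0.02)
  expect_warning(
    out <- nondialysis_dm_mortality(0.001, 1e5, 0.5, 5e4),
    "floored")
  expect_equal(out, 0)
  expect_error(nondialysis_dm_mortality(0.02, 100, 0.08, 100), "n_dm_total")
})

test_that("dialysis inflow at 40 averages the flanking age groups", {
  expect_equal(inflow_at_40(600, 400), 100)
  expect_equal(inflow_at_40(0, 0), 0)
  expect_equal(inflow_at_40(947, 947), 189.4)
})

test_that("dialysis mortality back-extrapolation fits the observed line", {
  r <- c("2012" = 0.080, "2013" = 0.082, "2014" = 0.084, "2015" = 0.086)
  out <- extrapolate_dialysis_mortality(r, 2000:2011)
  expect_equal(unname(out["2011"]), 0.078)
  expect_equal(unname(out["2000"]), 0.056)
  flat <- extrapolate_dialysis_mortality(rep(0.05, 4))
  expect_true(all(abs(flat - 0.05) < 1e-12))
  expect_warning(
    clipped <- extrapolate_dialysis_mortality(
      c("2012" = 0.30, "2013" = 0.20, "2014" = 0.10, "2015" = 0.01)),
    "clipped")
  expect_true(all(clipped >= 0 & clipped <= 1))
  expect_error(extrapolate_dialysis_mortality(c(0.1, NA, 0.1, 0.1)),
               "finite")
})

test_that("exogenous series are held at their final value when extended", {
  tp <- tt_truth()$male
  ex <- tp$exog                      # series through 2015
  ex$entry20 <- ex$entry20[as.character(2000:2015)]
  ext <- extend_exogenous(ex, 2035)
  expect_equal(ext$years, 2000:2035)
  expect_true(all(ext$dial_entry40[as.character(2016:2035)] ==
                    ex$dial_entry40[["2015"]]))
  expect_true(all(ext$mort[, as.character(2016:2035)] ==
                    ex$mort[, "2015"]))
  # horizon inside the data leaves the object unchanged
  expect_identical(extend_exogenous(ex, 2015), ex)
  # longer hold
  ext55 <- extend_exogenous(ex, 2055)
  expect_equal(max(ext55$years), 2055)
  expect_equal(unname(ext55$dial_entry40[["2055"]]),
               unname(ex$dial_entry40[["2015"]]))
  # an entry-cohort series already projected past the data is preserved
  ext2 <- extend_exogenous(tp$exog, 2035)
  expect_equal(ext2$entry20[as.character(2016:2035)],
               tp$exog$entry20[as.character(2016:2035)])
})

test_that("fixture-derived rate series stay within [0, 1]", {
  fix <- tt_fixture()
  for (sex in names(fix)) {
    expect_true(all(fix[[sex]]$exog$mort >= 0 & fix[[sex]]$exog$mort <= 1))
  }
})
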