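test_that("rate sweeps honour their contracts and leave context intact", {
  fit <- tt_fit("female")
  params_before <- fit$params
  expect_error(sweep_rate(fit, "DMfooir", c(0, 0.001)), "unknown parameter")
  expect_error(sweep_rate(fit, "DM3039ir", c(0.001, 0.001)),
               "strictly increasing")
  expect_error(sweep_rate(fit, "DMDi4049ir", c(0, 0.1)), "bounds")

  # single-value grid reproduces a base run with that value substituted
  sw1 <- sweep_rate(fit, "DM3039ir", 0.002, horizon = 2020)
  p <- fit$params
  p$ir_dm["DM3039ir"] <- 0.002
  manual <- simulate_chain(p, extend_exogenous(fit$data$exog, 2020),
                           t1 = 2020, dt = fit$control$dt)
  expect_equal(sw1$trajectories[[1]]$stocks, manual$stocks)
  # the fit's own parameters are untouched by the sweep
  expect_identical(fit$params, params_before)
})

test_that("sweeping DM3039ir over the published range leaves the trends
           intact", {
  fit <- tt_fit("female")
  sw <- sweep_rate(fit, "DM3039ir", c(0, 0.00138225))
  # the added incident cases shift the 2035 levels only modestly ...
  td <- sw$summary$TotalDM
  expect_lt(abs(diff(td)) / td[1], 0.10)
  di <- sw$summary$DMDiover40
  expect_lt(abs(diff(di)) / di[1], 0.05)
  # ... and do not change the shape of the projections: dialysis keeps
  # rising throughout and the two runs track each other closely in
  # every year
  rel_gap <- abs(sw$trajectories[[2]]$aggregates$TotalDM -
                   sw$trajectories[[1]]$aggregates$TotalDM) /
    sw$trajectories[[1]]$aggregates$TotalDM
  expect_true(all(rel_gap < 0.10))
  for (tr in sw$trajectories)
    expect_true(all(diff(tr$aggregates$DMDiover40) > 0))
})

test_that("entry-prevalence sweep is monotone and validated", {
  fit <- tt_fit("male")
  sw <- sweep_entry_prevalence(fit, c(0, 0.002, 0.004))
  expect_true(all(diff(sw$summary$TotalDM) > 0))
  expect_error(sweep_entry_prevalence(fit, c(0.5, 1.5)), "\\[0, 1\\]")
  # the default prevalence reproduces the base run
  sw0 <- sweep_entry_prevalence(fit, 0.002)
  base <- predict(fit)
  expect_equal(sw0$trajectories[[1]]$stocks, base$stocks)
})

test_that("zero drift is bit-identical to the constant-rate run", {
  fit <- tt_fit("male")
  base <- predict(fit)
  drifted <- run_with_drift(fit, list(g_dm = 0, g_di = 0))
  expect_identical(base$stocks, drifted$stocks)
})

test_that("negative drift lowers both 2035 burdens, orderings unchanged", {
  fit <- tt_fit("male")
  base <- predict(fit)
  d <- list(g_dm = -0.01, g_di = -0.01)
  drifted <- run_with_drift(fit, d)
  last <- nrow(base$aggregates)
  expect_lt(drifted$aggregates$TotalDM[last], base$aggregates$TotalDM[last])
  expect_lt(drifted$aggregates$DMDiover40[last],
            base$aggregates$DMDiover40[last])
  expect_error(run_with_drift(fit, list(g_dm = 0.2, g_di = 0)), "0.05")

  # the four scenarios keep their relative order under drift
  runs <- lapply(c("base", "DMP", "ESRDP", "DMP+ESRDP"), function(nm)
    run_with_drift(fit, d, scenario = if (nm == "base") NULL else nm))
  di35 <- sapply(runs, function(tr) tr$aggregates$DMDiover40[last])
  expect_true(di35[4] <= di35[3] && di35[3] <= di35[1] &&
                di35[2] <= di35[1])
})

test_that("extending the horizon reshapes the scenario gaps as expected", {
  fit <- tt_fit("male")
  runs <- extend_horizon(fit, 2055)
  yrs <- runs$base$years
  i35 <- match(2035, yrs)
  i55 <- match(2055, yrs)
  td <- function(nm) runs[[nm]]$aggregates$TotalDM
  di <- function(nm) runs[[nm]]$aggregates$DMDiover40
  # prevention's effect on the diabetic population keeps widening
  expect_gt(abs(td("base")[i55] - td("DMP")[i55]),
            abs(td("base")[i35] - td("DMP")[i35]))
  # the DMP-vs-ESRDP dialysis gap narrows after 2035
  expect_lt(abs(di("DMP")[i55] - di("ESRDP")[i55]),
            abs(di("DMP")[i35] - di("ESRDP")[i35]))
  expect_error(extend_horizon(fit, 2030), ">= 2035")
  # a 2035 horizon reproduces the standard runs
  std <- extend_horizon(fit, 2035)
  expect_equal(std$base$stocks, predict(fit)$stocks)
})
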