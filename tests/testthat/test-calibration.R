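test_that("weights are inverse window means, degenerate series excluded", {
  dat <- tt_synth()$male
  w <- compute_weights(dat)
  obs_mean <- mean(dat$pop[, "2029"])
  expect_equal(unname(w["pop2029"]), 1 / obs_mean)
  # two variables whose means differ 100-fold get weights in ratio 1:100
  expect_equal(unname(w["DM2029"] / w["pop2029"]),
               unname(obs_mean / mean(dat$dm[, "2029"])))
  # an all-zero series is excluded with a warning, not given weight Inf
  dat0 <- dat
  dat0$di[, "4049"] <- 0
  expect_warning(w0 <- compute_weights(dat0), "excluded")
  expect_false("DMDi4049" %in% names(w0))
  expect_true(all(is.finite(w0)))
})

test_that("payoff is zero at a perfect fit and quadratic in the weights", {
  truth <- tt_truth()
  dat <- tt_synth()$male
  w <- compute_weights(dat)
  tr <- simulate_chain(truth$male$params, truth$male$exog, t1 = 2015)
  expect_lt(calibration_payoff(tr, dat, w), 1e-18)

  # any imperfect run: scaling all weights by c scales the payoff by c^2,
  # so the argmin is invariant to a common weight rescaling
  p2 <- truth$male$params
  p2$ir_dm <- p2$ir_dm * 1.5
  tr2 <- simulate_chain(p2, truth$male$exog, t1 = 2015)
  v <- calibration_payoff(tr2, dat, w)
  expect_gt(v, 0)
  w3 <- w
  w3[] <- as.numeric(w) * 3
  expect_equal(calibration_payoff(tr2, dat, w3), 9 * v)

  # and payoff ordering between parameter candidates is preserved
  p3 <- truth$male$params
  p3$ir_di <- p3$ir_di * 0.5
  tr3 <- simulate_chain(p3, truth$male$exog, t1 = 2015)
  v3 <- calibration_payoff(tr3, dat, w)
  expect_equal(calibration_payoff(tr3, dat, w3), 9 * v3)
  expect_equal(v3 < v, 9 * v3 < 9 * v)
})

test_that("noise-free synthetic data returns the generating rates", {
  truth <- tt_truth()
  for (sex in c("male", "female")) {
    fit <- tt_recovery_fit(sex)
    expect_true(fit$converged)
    tru <- c(truth[[sex]]$params$ir_dm, truth[[sex]]$params$ir_di)
    est <- coef(fit)[names(tru)]
    small <- tru < 4e-3
    expect_true(all(abs(est[small] - tru[small]) < 2e-4))
    expect_true(all(abs(est[!small] - tru[!small]) / tru[!small] < 0.05))
    # the payoff at the truth is not beaten by the fit beyond tolerance
    tr_truth <- simulate_chain(truth[[sex]]$params, truth[[sex]]$exog,
                               t1 = 2015)
    pay_truth <- calibration_payoff(tr_truth, tt_synth()[[sex]],
                                    fit$weights)
    expect_lte(fit$payoff, pay_truth + 1e-12)
  }
})

test_that("recovered rates keep the age-increasing pattern of the truth", {
  fit <- tt_recovery_fit("male")
  expect_true(all(diff(fit$params$ir_dm) > 0))
  expect_true(all(diff(fit$params$ir_di) > 0))
})

test_that("a zero generating rate is recovered at the zero bound", {
  truth <- default_truth(cv = 0, seed = 3)
  truth$female$params$ir_dm[2] <- 0          # DM3039ir = 0
  dat <- generate_synthetic_country(truth)
  fit <- dmchain(dat, "female", control = dmchain_control(starts = 4))
  expect_lt(coef(fit)[["DM3039ir"]], 1e-5)
})

test_that("1% observation noise keeps median rate errors within 15%", {
  truth <- tt_truth()
  tru <- c(truth$male$params$ir_dm, truth$male$params$ir_di)
  rel <- sapply(1:10, function(s) {
    t2 <- truth
    t2$cv <- 0.01
    t2$seed <- 100L + s
    dat <- generate_synthetic_country(t2)
    fit <- dmchain(dat, "male", control = dmchain_control(starts = 2))
    abs(coef(fit)[names(tru)] - tru) / tru
  })
  expect_true(all(apply(rel, 1, stats::median) < 0.15))
})

test_that("calibration reports diagnostics and honours the bounds", {
  fit <- tt_fit("male")
  expect_s3_class(fit, "dmchain")
  expect_gte(fit$payoff, 0)
  expect_true(all(fit$params$ir_dm >= 0 & fit$params$ir_dm <= 0.05))
  expect_true(all(fit$params$ir_di >= 0 & fit$params$ir_di <= 0.02))
  expect_equal(length(fit$start_payoffs), 4)
  expect_gt(fit$n_evaluations, 0)
  expect_equal(fit$payoff, min(fit$start_payoffs))
  # residual summary covers all 16 observed variables
  expect_equal(nrow(fit$residual_summary), 16)
  # fitted/residuals are consistent with the observations
  res <- residuals(fit)
  obs <- fitted(fit) - res
  expect_equal(unname(obs[, "DMDi4049"]),
               unname(tt_fixture()$male$di[, "4049"]))
})

test_that("drift estimation on drift-free data returns a near-zero drift", {
  dat <- tt_synth()
  fit <- dmchain(dat, "male",
                 control = dmchain_control(starts = 2, drift = TRUE))
  expect_lt(abs(coef(fit)[["g_dm"]]), 0.005)
  expect_lt(abs(coef(fit)[["g_di"]]), 0.005)
  tru <- c(tt_truth()$male$params$ir_dm)
  expect_true(all(abs(coef(fit)[names(tru)] - tru) / pmax(tru, 4e-3) <
                    0.05))
})
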