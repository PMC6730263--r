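# delta-18O calibration, mass balance, Craig-Gordon model, partitioning.

test_that("standard calibration is the OLS measured-to-true map", {
  std <- data.frame(true = c(-20, -10, 0), measured = c(-20, -10, 0))
  expect_equal(calibrate_delta(c(-15, -5), std), c(-15, -5))

  two <- data.frame(true = c(-22, -2), measured = c(-20, 0))
  expect_equal(calibrate_delta(-10, two), -12)

  # collinear third standard does not change the exact-fit map
  three <- data.frame(true = c(-22, -12, -2), measured = c(-20, -10, 0))
  expect_equal(calibrate_delta(-10, three), calibrate_delta(-10, two))

  degenerate <- data.frame(true = c(-22, -2), measured = c(-5, -5))
  expect_error(calibrate_delta(-10, degenerate), "distinct")
})

test_that("time-linear drift is removed before the standard map", {
  # drift standard measured 0.1 permil/h high and rising; identity map
  times <- as.POSIXct("2017-06-01 00:00:00", tz = "UTC") + (0:10) * 3600
  drift <- data.frame(time = times, measured = -10 + 0.1 * (0:10), true = -10)
  std <- data.frame(true = c(-20, 0), measured = c(-20, 0))
  raw <- c(-15.5 + 0.1 * 2, -15.5 + 0.1 * 8)  # truth -15.5 read at t = 2 h, 8 h
  cal <- calibrate_delta(raw, std, raw_times = times[c(3, 9)], drift = drift)
  expect_equal(cal, c(-15.5, -15.5), tolerance = 1e-9)
})

test_that("delta_ET mass balance mixes the inlet and outlet vapor streams", {
  expect_equal(delta_et_mass_balance(10, 12, -20, -18)$delta_et, -8)
  expect_equal(delta_et_mass_balance(0, 12, -20, -18)$delta_et, -18)  # w_in = 0
  expect_equal(delta_et_mass_balance(10, 12, -15, -15)$delta_et, -15) # degenerate mixing
  expect_warning(out <- delta_et_mass_balance(12, 10, -20, -18), "no net vapor source")
  expect_true(is.na(out$delta_et))
  expect_true(out$flag_no_source)
})

test_that("equilibrium 18O fractionation is >1, ~9.8 permil at 20 degC, decreasing", {
  expect_equal(1000 * log(alpha_equilibrium_18o(20)), 9.75, tolerance = 0.01)
  temps <- seq(-5, 55, by = 5)
  a <- alpha_equilibrium_18o(temps)
  expect_true(all(a > 1))
  expect_true(all(diff(a) < 0))
  expect_error(alpha_equilibrium_18o(80), "range")
})

test_that("Craig-Gordon model obeys its no-fractionation limits", {
  p0 <- craig_gordon_params(20, eps_k = 0, alpha_eq = 1)
  expect_equal(craig_gordon_delta_e(-5, -15, 0, p0)$delta_e, -5)
  h <- 0.6
  expect_equal(craig_gordon_delta_e(-5, -15, h, p0)$delta_e,
               (-5 - h * -15) / (1 - h), tolerance = 1e-12)

  # full evaluation against a spelled-out oracle of the delta-form equation
  pr <- craig_gordon_params(20)
  alpha <- exp(1137 / 293.15^2 - 0.4156 / 293.15 - 0.0020667)
  oracle <- ((1000 - 5) / alpha - 0.6 * (1000 - 15)) /
    ((1 - 0.6) * (1 + 14.25 / 1000)) - 1000
  expect_equal(craig_gordon_delta_e(-5, -15, 0.6, pr)$delta_e, oracle,
               tolerance = 1e-12)
  expect_lt(oracle, -5)  # evaporate is depleted relative to the soil water

  expect_warning(out <- craig_gordon_delta_e(-5, -15, 1, pr), "no net evaporation")
  expect_true(is.na(out$delta_e))
})

test_that("steady-state transpiration carries the source-water signature", {
  expect_identical(delta_t_steady_state(-8), -8)
  expect_identical(delta_t_steady_state(0), 0)
})

test_that("partitioning recovers the endmember mixing fraction", {
  out <- partition_ft(-10, -20, -5, et = 3)
  expect_equal(out$ft, 10 / 15)
  expect_equal(out$t + out$e, 3)
  expect_false(out$clamped)

  # endmember identities
  expect_equal(partition_ft(-5, -20, -5, 2)$ft, 1)
  expect_equal(partition_ft(-5, -20, -5, 2)$e, 0)
  expect_equal(partition_ft(-20, -20, -5, 2)$ft, 0)
  expect_equal(partition_ft(-20, -20, -5, 2)$t, 0)

  # out-of-range raw values are clamped and flagged, conservation kept
  out <- partition_ft(-2, -20, -5, 2)
  expect_true(out$clamped)
  expect_gt(out$ft_raw, 1)
  expect_equal(out$ft, 1)
  expect_equal(out$t + out$e, 2)

  # ill-conditioned separation is rejected
  expect_warning(out <- partition_ft(-10, -10.5, -10, 2), "ill-conditioned")
  expect_false(out$valid)
  expect_true(is.na(out$ft))
})

test_that("ft is invariant under common affine shifts of the deltas", {
  set.seed(42)
  for (i in 1:25) {
    d_e <- runif(1, -30, -15)
    d_t <- runif(1, -10, -2)
    ft <- runif(1)
    d_et <- d_e + ft * (d_t - d_e)
    shift <- runif(1, -20, 20)
    base <- partition_ft(d_et, d_e, d_t, 1)$ft
    shifted <- partition_ft(d_et + shift, d_e + shift, d_t + shift, 1)$ft
    expect_equal(base, ft, tolerance = 1e-12)
    expect_equal(shifted, base, tolerance = 1e-9)
  }
})

test_that("first-order sd propagation responds to each delta's uncertainty", {
  out0 <- partition_ft(-10, -20, -5, 2)
  expect_equal(out0$sd_ft, 0)
  out <- partition_ft(-10, -20, -5, 2, sd_delta_et = 0.3)
  expect_equal(out$sd_ft, 0.3 / 15, tolerance = 1e-12)
  # wider endmember separation -> smaller ft uncertainty
  narrow <- partition_ft(-10, -12, -5, 2, sd_delta_et = 0.3,
                         sd_delta_e = 0.3, sd_delta_t = 0.3)
  wide <- partition_ft(-10, -30, -5, 2, sd_delta_et = 0.3,
                       sd_delta_e = 0.3, sd_delta_t = 0.3)
  expect_lt(wide$sd_ft, narrow$sd_ft)
})
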