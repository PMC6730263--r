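# Chamber / eddy-covariance fusion: correlation gate, offsets,
# nearest-neighbor interpolation, stage and season budgets.

test_that("EC daily sums apply the half-hour Riemann rule", {
  ts <- as.POSIXct("2017-06-07 00:00:00", tz = "UTC") + seq(0, 86400 - 1800, 1800)
  ec <- data.frame(timestamp = ts, nee = -4, et = 1.5)
  out <- ec_daily_sums(ec)
  expect_equal(out$nee_sum, -4 * 86400 * 12e-6)
  expect_equal(out$et_sum, 1.5 * 86400 * 18e-6)
  expect_equal(out$n_halfhours, 48L)
})

test_that("Spearman correlation matches the rank formula and its invariances", {
  ts <- as.POSIXct("2017-06-07 10:00:00", tz = "UTC") + (0:4) * 1800
  ec <- data.frame(timestamp = ts, nee = c(1, 2, 3, 4, 5))
  same <- data.frame(timestamp = ts, nee = c(10, 20, 30, 40, 50))
  expect_equal(campaign_correlation(ec, same)$r, 1)
  rev_ <- data.frame(timestamp = ts, nee = c(50, 40, 30, 20, 10))
  expect_equal(campaign_correlation(ec, rev_)$r, -1)
  # ranks (1,2,3,4,5) vs (2,1,4,3,5): sum d^2 = 4 -> 1 - 6*4/(5*24) = 0.8
  perm <- data.frame(timestamp = ts, nee = c(2, 1, 4, 3, 5))
  expect_equal(campaign_correlation(ec, perm)$r, 1 - 6 * 4 / (5 * 24))
  # monotone transform of either series leaves r unchanged
  expect_equal(campaign_correlation(ec, transform(perm, nee = exp(nee)))$r, 0.8)
  # fewer than 5 matched pairs -> no calibration
  few <- data.frame(timestamp = ts[1:4], nee = 1:4)
  out <- campaign_correlation(ec, few)
  expect_true(is.na(out$r))
  expect_equal(out$n_pairs, 4)
  # matching respects the 15-min window
  shifted <- data.frame(timestamp = ts + 3600, nee = 1:5)
  expect_true(is.na(campaign_correlation(ec, shifted)$r))
})

test_that("campaign offsets are plain daily-sum differences", {
  expect_equal(campaign_offset(c(3, 4), c(3, 4)), 0)
  expect_equal(campaign_offset(c(3, 4), c(5, 6)), 2)
})

test_that("nearest-neighbor offset interpolation honors the tie rule", {
  cal <- data.frame(campaign_date = as.Date(c("2017-05-01", "2017-07-01")),
                    accepted = TRUE, offset = c(1, 5))
  # single accepted campaign: constant series
  one <- cal[1, ]
  expect_equal(interpolate_offsets(one, as.Date("2017-04-01") + 0:60), rep(1, 61))
  # identity on campaign dates
  expect_equal(interpolate_offsets(cal, cal$campaign_date), c(1, 5))
  # exactly midway (2017-05-31 is 30 d from either): earlier campaign wins
  expect_equal(interpolate_offsets(cal, as.Date("2017-05-31")), 1)
  expect_equal(interpolate_offsets(cal, as.Date("2017-06-01")), 5)
  # rejected campaigns are spanned over
  cal$accepted <- c(FALSE, TRUE)
  expect_equal(interpolate_offsets(cal, as.Date("2017-05-01")), 5)
  cal$accepted <- FALSE
  expect_error(interpolate_offsets(cal, as.Date("2017-05-01")), "no accepted")
})

make_budget_inputs <- function(nee_daily = -2, et_daily = 1.2) {
  days <- seq(as.Date("2017-04-01"), as.Date("2017-09-30"), by = "day")
  ec_daily <- data.frame(date = days, nee_sum = nee_daily, et_sum = et_daily)
  cal <- expand.grid(campaign_date = as.Date(c("2017-05-01", "2017-08-01")),
                     treatment = c("CC", "ND"), flux = c("nee", "et"),
                     stringsAsFactors = FALSE)
  cal$accepted <- TRUE
  cal$offset <- 0
  list(ec_daily = ec_daily, cal = cal,
       breaks = as.Date(c("2017-05-31", "2017-07-01", "2017-08-15")))
}

test_that("budget sums are consistent across stages, season and WUE", {
  inp <- make_budget_inputs()
  b <- build_budget(inp$ec_daily, inp$cal, inp$breaks, "2017-04-01", "2017-09-30")
  # identical offsets -> identical treatments -> 0% change
  expect_equal(b$season$pct_nee_vs_cc, c(0, 0))
  # season = sum of stages; wue matches the definition
  for (trt in c("CC", "ND")) {
    ss <- b$stages[b$stages$treatment == trt, ]
    expect_equal(sum(ss$nee_sum), b$season$nee_sum[b$season$treatment == trt])
  }
  expect_equal(b$season$wue_eco,
               -b$season$nee_sum / b$season$et_sum)
  expect_equal(b$season$nee_sum[1], -2 * 183)

  # linearity: scaling the daily series scales every sum
  inp2 <- make_budget_inputs(nee_daily = -4, et_daily = 2.4)
  b2 <- build_budget(inp2$ec_daily, inp2$cal, inp$breaks, "2017-04-01", "2017-09-30")
  expect_equal(b2$season$nee_sum, 2 * b$season$nee_sum)
  expect_equal(b2$stages$et_sum, 2 * b$stages$et_sum)
})

test_that("missing EC days are gap-filled linearly and flagged", {
  inp <- make_budget_inputs()
  drop <- inp$ec_daily$date >= as.Date("2017-06-10") & inp$ec_daily$date <= as.Date("2017-06-12")
  ec <- inp$ec_daily[!drop, ]
  ec$nee_sum <- seq_len(nrow(ec))  # strictly linear -> interpolation is exact
  full_days <- seq(as.Date("2017-04-01"), as.Date("2017-09-30"), by = "day")
  expected <- stats::approx(as.numeric(ec$date), ec$nee_sum,
                            xout = as.numeric(full_days))$y
  b <- build_budget(ec, inp$cal, inp$breaks, "2017-04-01", "2017-09-30")
  cc <- b$daily[b$daily$treatment == "CC", ]
  expect_equal(cc$nee_sum, expected)
  expect_equal(sum(cc$flag_gapfilled_nee), 3)
})

test_that("published season sums yield the published percent contrasts", {
  sums <- example_season_sums()
  cc <- sums[sums$treatment == "CC", ]
  expect_equal(round(percent_vs_cc(sums$nee_sum[sums$treatment == "ND"], cc$nee_sum)), -73)
  expect_equal(round(percent_vs_cc(sums$nee_sum[sums$treatment == "CD"], cc$nee_sum)), -43)
  expect_equal(round(percent_vs_cc(sums$et_sum[sums$treatment == "ND"], cc$et_sum)), -40)
})
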