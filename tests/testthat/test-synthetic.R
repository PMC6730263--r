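# The synthetic grassland-season generator: determinism, night rules,
# shelter arithmetic, and exact zero-noise inversion of the samplers.

test_that("configuration validation rejects inconsistent seasons", {
  expect_error(truth_config(stage_breaks = c("2017-07-01", "2017-05-31", "2017-08-15")),
               "increasing")
  expect_error(truth_config(season_start = "2017-04-01", season_end = "2017-04-10",
                            stage_breaks = c("2017-04-03", "2017-04-05", "2017-04-07")),
               "30 days")
  expect_error(truth_config(precip_exclusion_frac = 1.2), "0, 1")
  expect_error(truth_config(campaign_dates = "2018-01-01"), "within the season")
})

test_that("identical seeds give identical generated tables", {
  cfg <- truth_config(seed = 3, season_start = "2017-06-01",
                      season_end = "2017-07-15",
                      stage_breaks = c("2017-06-10", "2017-06-20", "2017-07-01"),
                      campaign_dates = c("2017-06-07", "2017-07-05"))
  s1 <- generate_season(cfg)
  s2 <- generate_season(cfg)
  expect_identical(s1$meteo, s2$meteo)
  expect_identical(s1$truth_halfhourly, s2$truth_halfhourly)
  c1 <- sample_chamber_campaigns(s1)
  c2 <- sample_chamber_campaigns(s2)
  expect_identical(c1$chamber, c2$chamber)
  expect_identical(c1$isotopes, c2$isotopes)
  expect_identical(sample_ec_series(s1), sample_ec_series(s2))
  # ... and the RNG state of the caller is untouched
  set.seed(99); before <- .Random.seed
  invisible(generate_season(cfg))
  expect_identical(.Random.seed, before)
})

test_that("GPP and T are exactly zero whenever PPFD is zero", {
  season <- test_season_short()
  m <- season$meteo
  dark_ts <- m$timestamp[m$ppfd == 0]
  for (trt in c("CC", "ND")) {
    tr <- season$truth_halfhourly[season$truth_halfhourly$treatment == trt, ]
    night <- tr[tr$timestamp %in% dark_ts, ]
    expect_true(all(night$gpp == 0))
    expect_true(all(night$t == 0))
    expect_true(all(night$ft == 0))
    # Reco and E stay nonzero at night
    expect_true(all(night$reco > 0))
    expect_true(all(night$e > 0))
  }
})

test_that("truth ft lies in [0, 1] and its daytime level rises through the season", {
  season <- test_season(7)
  tr <- season$truth_halfhourly[season$truth_halfhourly$treatment == "CC", ]
  expect_true(all(tr$ft >= 0 & tr$ft <= 1))
  day <- tr[tr$t > 0, ]
  mon <- format(day$timestamp, "%m")
  expect_lt(mean(day$ft[mon == "04"]), mean(day$ft[mon == "09"]))
})

test_that("sheltered precipitation is exactly the configured exclusion of ambient", {
  season <- test_season(7)
  m <- season$meteo
  expect_equal(m$precip_sheltered, m$precip * (1 - 0.367))
  expect_equal(sum(m$precip_sheltered) / sum(m$precip), 0.633)
  expect_gt(sum(m$precip), 200)  # a plausible temperate growing season
  expect_lt(sum(m$precip), 700)
})

test_that("zero-noise sampling inverts exactly through chamber_flux", {
  season <- test_season(7)
  camp <- sample_chamber_campaigns(season, campaign_dates = "2017-06-07",
                                   zero_noise = TRUE)
  fl <- chamber_flux(camp$chamber)
  light <- fl[!fl$dark, ]
  tr <- truth_for(season, light)
  mi <- match(paste(light$treatment, format(light$timestamp)),
              paste(tr$treatment, format(tr$timestamp)))
  expect_equal(light$nee, tr$nee[mi], tolerance = 1e-9)
  expect_equal(light$et, tr$et[mi], tolerance = 1e-9)
  dark <- fl[fl$dark, ]
  tr_d <- truth_fluxes(season, dark$timestamp[dark$treatment == "CC"], "CC")
  expect_equal(dark$nee[dark$treatment == "CC"], tr_d$reco, tolerance = 1e-9)
})

test_that("zero delta noise makes the isotope partition return truth ft exactly", {
  season <- test_season(7)
  camp <- sample_chamber_campaigns(season, campaign_dates = "2017-07-12",
                                   zero_noise = TRUE)
  fl <- chamber_flux(camp$chamber)
  part <- partition_campaign(fl[!fl$dark, ], camp$isotopes)
  key <- paste(part$treatment, format(part$timestamp))
  tr <- truth_for(season, part)
  truth_ft <- tr$ft[match(key, paste(tr$treatment, format(tr$timestamp)))]
  expect_true(all(part$valid))
  expect_equal(part$ft, truth_ft, tolerance = 1e-9)
  expect_true(all(abs(part$delta_t - part$delta_e) >= 5))
})

test_that("sample SD of recovered chamber fluxes matches the configured noise", {
  season <- test_season(7)
  camp <- suppressWarnings(
    sample_chamber_campaigns(season, campaign_dates = "2017-07-12", seed = 123))
  fl <- suppressWarnings(chamber_flux(camp$chamber))
  light <- fl[!fl$dark, ]
  key <- paste(light$treatment, format(light$timestamp))
  tr <- truth_for(season, light)
  mi <- match(key, paste(tr$treatment, format(tr$timestamp)))
  resid_nee <- light$nee - tr$nee[mi]
  resid_et <- light$et - tr$et[mi]
  expect_gt(length(resid_nee), 200)
  expect_lt(abs(sd(resid_nee) - 0.5) / 0.5, 0.15)
  expect_lt(abs(sd(resid_et) - 0.08) / 0.08, 0.15)
})

test_that("the EC series is a biased, rank-preserving transform of CC truth", {
  season <- test_season_short()
  ec0 <- sample_ec_series(season, zero_noise = TRUE)
  cc <- season$truth_halfhourly[season$truth_halfhourly$treatment == "CC", ]
  # bias-free check: remove the configured offsets and compare daily sums
  cfg <- season$config
  ec0$nee <- ec0$nee - cfg$ec_offset_nee / (12e-6 * 86400)
  ec0$et <- ec0$et - cfg$ec_offset_et / (18e-6 * 86400)
  ecd <- ec_daily_sums(ec0)
  # same half-hour Riemann convention applied to the truth series: exact
  ecd_truth <- ec_daily_sums(cc[, c("timestamp", "nee", "et")])
  expect_equal(ecd$nee_sum, ecd_truth$nee_sum, tolerance = 1e-9)
  expect_equal(ecd$et_sum, ecd_truth$et_sum, tolerance = 1e-9)
  # and the fine-grid truth integrals agree to quadrature error
  td <- season$truth_daily[season$truth_daily$treatment == "CC", ]
  m <- merge(ecd, td, by = "date")
  expect_equal(m$nee_sum.x, m$nee_sum.y, tolerance = 5e-3)
  expect_equal(m$et_sum.x, m$et_sum.y, tolerance = 5e-3)
  # noise-free series: Spearman r with truth is 1, also after monotone transform
  expect_equal(cor(ec0$nee, cc$nee, method = "spearman"), 1)
  expect_equal(cor(exp(ec0$et / 2), cc$et, method = "spearman"), 1)
})

test_that("written CSV tables round-trip and are byte-stable under the seed", {
  season <- test_season_short()
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_season_csv(season, dir1)
  write_season_csv(season, dir2)
  for (f in c("meteo.csv", "chamber.csv", "isotopes.csv", "ec.csv")) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)))
  }
  chamber <- read_flux_csv(file.path(dir1, "chamber.csv"))
  expect_s3_class(chamber$timestamp, "POSIXct")
  expect_true(all(c("co2_in", "co2_out", "h2o_in", "h2o_out", "dark") %in% names(chamber)))
})
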