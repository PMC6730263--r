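# Synthetic grassland growing season with known ground truth: half-hourly
# meteorology, noise-free flux truth per treatment, chamber campaign
# sampling (flux + isotope tables constructed to invert exactly under zero
# noise), and a biased, noisy eddy-covariance series for the ambient
# control.

#' Configuration of the synthetic grassland season (the ground truth)
#'
#' Bundles every knob of the generator: season span and growth-stage
#' breaks, per-treatment multiplicative effects on GPP, Reco and ET,
#' canopy/soil flux amplitudes, the seasonal transpiration-fraction ramp,
#' noise standard deviations, the eddy-covariance daily-sum bias, and the
#' rain-out shelter exclusion fraction. Defaults emulate a temperate
#' grassland growing season (April-September) under a crossed nitrogen x
#' drought manipulation with four treatments (CC, CD, NC, ND), ten chamber
#' campaigns and three plots per treatment.
#'
#' @param seed Integer RNG seed; identical seeds give identical tables.
#' @param season_start,season_end Season span (Date or coercible),
#'   >= 30 days.
#' @param stage_breaks Three dates inside the span splitting it into the
#'   four growth stages (spring start, summer peak, summer dieback, autumn
#'   peak).
#' @param treatment_effects data.frame with columns `treatment`, `gpp`,
#'   `reco`, `et`: dimensionless multiplicative scalars. Defaults follow
#'   reported treatment responses (drought lowers GPP and ET, fertilization
#'   plus drought raises Reco).
#' @param ft_day_start,ft_day_end Daytime transpiration share of ET at
#'   season start/end; ramps linearly (truth ft increases with time).
#' @param gpp_amp Midday GPP amplitude at full canopy, umol CO2 m-2 s-1.
#' @param reco_base Ecosystem respiration at 15 degC and full canopy,
#'   umol CO2 m-2 s-1; responds to daily mean temperature with `q10`.
#' @param q10 Temperature sensitivity of Reco (default 2).
#' @param t_amp Midday transpiration amplitude at full canopy,
#'   mmol H2O m-2 s-1.
#' @param e_min Soil evaporation floor, mmol H2O m-2 s-1.
#' @param noise_sd_nee,noise_sd_et Additive Gaussian SD of chamber fluxes
#'   (umol CO2 m-2 s-1 / mmol H2O m-2 s-1).
#' @param noise_sd_delta Additive Gaussian SD of each measured delta-18O
#'   (permil).
#' @param ec_offset_nee,ec_offset_et Additive daily-sum bias of the EC
#'   series (g C m-2 d-1 / kg H2O m-2 d-1), distributed uniformly over the
#'   day.
#' @param ec_noise_nee,ec_noise_et Additive Gaussian SD per EC half-hour
#'   (flux units).
#' @param precip_exclusion_frac Fraction of ambient precipitation excluded
#'   by the rain-out shelters (default 0.367).
#' @param campaign_dates Chamber campaign dates; default ten campaigns,
#'   roughly monthly with weekly intensification in July.
#' @param n_plots Plots per treatment (default 3).
#' @param sample_interval_min Chamber sampling interval within a campaign
#'   day, minutes (default 30).
#' @param dark_offset_min Lag of the paired dark reading after each light
#'   reading, minutes (default 10).
#' @param delta_source,delta_soil,delta_atm delta-18O of xylem/source
#'   water, evaporating-depth soil water, and atmospheric vapor (permil).
#' @param co2_ambient Inlet CO2 mixing ratio, umol mol-1.
#' @param flow Chamber flow, L min-1.
#' @param pressure Air pressure, kPa.
#' @param base_area Chamber base area, cm2.
#' @return An object of class `truth_config` (a validated list).
#' @export
truth_config <- function(seed = 1L,
                         season_start = "2017-04-01",
                         season_end = "2017-09-30",
                         stage_breaks = c("2017-05-31", "2017-07-01", "2017-08-15"),
                         treatment_effects = data.frame(
                           treatment = c("CC", "CD", "NC", "ND"),
                           gpp = c(1.00, 0.80, 0.75, 0.62),
                           reco = c(1.00, 1.07, 1.00, 1.36),
                           et = c(1.00, 0.75, 0.87, 0.60)),
                         ft_day_start = 0.60, ft_day_end = 0.90,
                         gpp_amp = 16, reco_base = 1.1, q10 = 2,
                         t_amp = 4.5, e_min = 0.10,
                         noise_sd_nee = 0.5, noise_sd_et = 0.08,
                         noise_sd_delta = 0.3,
                         ec_offset_nee = 0.8, ec_offset_et = -0.15,
                         ec_noise_nee = 1.0, ec_noise_et = 0.15,
                         precip_exclusion_frac = 0.367,
                         campaign_dates = c("2017-04-12", "2017-05-10",
                                            "2017-06-07", "2017-07-05",
                                            "2017-07-12", "2017-07-19",
                                            "2017-07-26", "2017-08-16",
                                            "2017-09-06", "2017-09-27"),
                         n_plots = 3, sample_interval_min = 30,
                         dark_offset_min = 10,
                         delta_source = -8, delta_soil = -5, delta_atm = -18,
                         co2_ambient = 412, flow = 30, pressure = 101.3,
                         base_area = 962) {
  cfg <- list(seed = as.integer(seed),
              season_start = as.Date(season_start),
              season_end = as.Date(season_end),
              stage_breaks = as.Date(stage_breaks),
              treatment_effects = treatment_effects,
              ft_day_start = ft_day_start, ft_day_end = ft_day_end,
              gpp_amp = gpp_amp, reco_base = reco_base, q10 = q10,
              t_amp = t_amp, e_min = e_min,
              noise_sd_nee = noise_sd_nee, noise_sd_et = noise_sd_et,
              noise_sd_delta = noise_sd_delta,
              ec_offset_nee = ec_offset_nee, ec_offset_et = ec_offset_et,
              ec_noise_nee = ec_noise_nee, ec_noise_et = ec_noise_et,
              precip_exclusion_frac = precip_exclusion_frac,
              campaign_dates = as.Date(campaign_dates),
              n_plots = as.integer(n_plots),
              sample_interval_min = sample_interval_min,
              dark_offset_min = dark_offset_min,
              delta_source = delta_source, delta_soil = delta_soil,
              delta_atm = delta_atm,
              co2_ambient = co2_ambient, flow = flow, pressure = pressure,
              base_area = base_area)
  validate_truth_config(cfg)
  structure(cfg, class = "truth_config")
}

#' @noRd
validate_truth_config <- function(cfg) {
  span <- as.numeric(cfg$season_end - cfg$season_start)
  if (span < 30) stop("season span must cover at least 30 days")
  if (length(cfg$stage_breaks) != 3 || is.unsorted(cfg$stage_breaks, strictly = TRUE)) {
    stop("`stage_breaks` must be 3 strictly increasing dates")
  }
  if (any(cfg$stage_breaks <= cfg$season_start) || any(cfg$stage_breaks >= cfg$season_end)) {
    stop("`stage_breaks` must lie strictly inside the season span")
  }
  if (cfg$precip_exclusion_frac < 0 || cfg$precip_exclusion_frac > 1) {
    stop("`precip_exclusion_frac` must lie in [0, 1]")
  }
  te <- cfg$treatment_effects
  if (!all(c("treatment", "gpp", "reco", "et") %in% names(te))) {
    stop("`treatment_effects` needs columns treatment, gpp, reco, et")
  }
  if (any(cfg$ft_day_start < 0, cfg$ft_day_start > 1,
          cfg$ft_day_end < 0, cfg$ft_day_end > 1)) {
    stop("ft_day bounds must lie in [0, 1]")
  }
  if (any(cfg$campaign_dates < cfg$season_start | cfg$campaign_dates > cfg$season_end)) {
    stop("campaign dates must lie within the season")
  }
  if (cfg$n_plots < 1) stop("need at least one plot per treatment")
  invisible(cfg)
}

#' @export
print.truth_config <- function(x, ...) {
  cat("Synthetic grassland season configuration\n")
  cat("  season:", format(x$season_start), "to", format(x$season_end),
      "| stages broken at", paste(format(x$stage_breaks), collapse = ", "), "\n")
  cat("  treatments:", paste(x$treatment_effects$treatment, collapse = ", "),
      "|", x$n_plots, "plots each |", length(x$campaign_dates), "campaigns\n")
  cat("  shelter exclusion:", x$precip_exclusion_frac,
      "| seed:", x$seed, "\n")
  invisible(x)
}

# ---- day-level drivers ------------------------------------------------------

#' @noRd
.round_half_hour <- function(h) round(h * 2) / 2

#' @noRd
season_drivers <- function(cfg) {
  dates <- seq(cfg$season_start, cfg$season_end, by = "day")
  doy <- as.integer(format(dates, "%j"))
  frac <- as.numeric(dates - cfg$season_start) /
    max(1, as.numeric(cfg$season_end - cfg$season_start))

  daylen <- .round_half_hour(12 + 4.2 * sin(2 * pi * (doy - 80) / 365))
  sunrise_h <- .round_half_hour(13 - daylen / 2)
  sunset_h <- sunrise_h + daylen
  # photic window: photoperiod trimmed by one half-hour at each end
  # (light-compensation lag); GPP and T are zero outside it
  sr_p <- sunrise_h + 0.5
  ss_p <- sunset_h - 0.5

  t_daily <- 12.5 + 7 * sin(2 * pi * (doy - 110) / 365)
  ppfd_max <- 1500 + 450 * sin(2 * pi * (doy - 100) / 365)
  s <- 0.18 + 0.80 * exp(-0.5 * ((doy - 160) / 26)^2) +
    0.50 * exp(-0.5 * ((doy - 247) / 15)^2) -
    0.28 * exp(-0.5 * ((doy - 203) / 13)^2)
  s <- pmin(pmax(s, 0.05), 1.2)
  ft_day <- cfg$ft_day_start + (cfg$ft_day_end - cfg$ft_day_start) * frac

  data.frame(date = dates, doy = doy, daylen = daylen,
             sunrise_h = sunrise_h, sunset_h = sunset_h,
             sr_p = sr_p, ss_p = ss_p,
             t_daily = t_daily, ppfd_max = ppfd_max,
             season_shape = s, ft_day = ft_day)
}

# ---- continuous truth -------------------------------------------------------

#' Noise-free truth fluxes of the synthetic season at arbitrary times
#'
#' Diel shapes: GPP and transpiration follow a half-sine over the photic
#' window (exactly zero when PPFD is zero); ecosystem respiration responds
#' to the daily mean temperature (Q10) and soil evaporation holds a
#' day-level value, both therefore constant within a day and nonzero at
#' night. Treatment effects scale GPP, Reco and ET multiplicatively.
#'
#' @param season A [generate_season()] object (or a `truth_config`).
#' @param times POSIXct vector (UTC).
#' @param treatment One of the configured treatments.
#' @return data.frame with `timestamp`, `treatment`, `gpp`, `reco`, `nee`
#'   (umol CO2 m-2 s-1), `t`, `e`, `et` (mmol H2O m-2 s-1), `ft`.
#' @export
truth_fluxes <- function(season, times, treatment) {
  cfg <- if (inherits(season, "truth_config")) season else season$config
  drv <- if (inherits(season, "truth_config")) season_drivers(cfg) else season$drivers
  te <- cfg$treatment_effects
  i <- match(treatment, te$treatment)
  if (is.na(i)) stop("unknown treatment: ", treatment)

  times <- as_utc_posix(times)
  d <- as.Date(times, tz = "UTC")
  j <- match(d, drv$date)
  if (anyNA(j)) stop("times outside the configured season")
  h <- (as.numeric(times) - as.numeric(as.POSIXct(paste(d, "00:00:00"), tz = "UTC"))) / 3600

  lp <- drv$ss_p[j] - drv$sr_p[j]
  photic <- h > drv$sr_p[j] & h < drv$ss_p[j]
  shape <- ifelse(photic, sin(pi * (h - drv$sr_p[j]) / lp), 0)

  s <- drv$season_shape[j]
  q10f <- cfg$q10^((drv$t_daily[j] - 15) / 10)

  gpp <- -cfg$gpp_amp * te$gpp[i] * s * shape
  reco <- cfg$reco_base * te$reco[i] * q10f * (0.5 + 0.5 * s)
  t_flux <- cfg$t_amp * te$et[i] * s * shape
  # day-level soil evaporation set by the target daytime T/(T+E) split
  t_day_mean <- cfg$t_amp * te$et[i] * s * (2 / pi)
  e_flux <- te$et[i] * cfg$e_min +
    (1 - drv$ft_day[j]) / drv$ft_day[j] * t_day_mean
  et <- t_flux + e_flux

  data.frame(timestamp = times, treatment = treatment,
             gpp = gpp, reco = reco, nee = gpp + reco,
             t = t_flux, e = e_flux, et = et,
             ft = ifelse(et > 0, t_flux / et, 0))
}

# ---- meteorology ------------------------------------------------------------

#' @noRd
meteo_at <- function(cfg, drv, times) {
  times <- as_utc_posix(times)
  d <- as.Date(times, tz = "UTC")
  j <- match(d, drv$date)
  h <- (as.numeric(times) - as.numeric(as.POSIXct(paste(d, "00:00:00"), tz = "UTC"))) / 3600
  air_temp <- drv$t_daily[j] + 5.5 * cos(2 * pi * (h - 14.5) / 24)
  rh <- pmin(pmax(97 - 4.6 * (air_temp - (drv$t_daily[j] - 5.5)), 35), 100)
  lit <- h >= drv$sunrise_h[j] & h <= drv$sunset_h[j]
  ppfd <- ifelse(lit, drv$ppfd_max[j] *
                   sin(pi * (h - drv$sunrise_h[j]) / drv$daylen[j]), 0)
  ppfd <- pmax(ppfd, 0)
  data.frame(timestamp = times, air_temp = air_temp, rh = rh, ppfd = ppfd,
             pressure = cfg$pressure)
}

#' Generate the synthetic season: meteorology, truth tables, daily truth
#'
#' Builds the 30-min meteorology (air temperature, relative humidity, PPFD,
#' precipitation under ambient and sheltered conditions, pressure), the
#' half-hourly noise-free truth fluxes for every treatment, and daily/
#' seasonal truth sums integrated on a fine (2-min) grid. Identical
#' configurations and seeds give identical tables; the caller's RNG state
#' is untouched.
#'
#' @param cfg A [truth_config()].
#' @return List of class `grassflux_season` with elements `config`,
#'   `drivers`, `meteo`, `truth_halfhourly`, `truth_daily`, `truth_season`.
#' @export
generate_season <- function(cfg) {
  stopifnot(inherits(cfg, "truth_config"))
  validate_truth_config(cfg)
  drv <- season_drivers(cfg)

  grid <- seq(as.POSIXct(paste(cfg$season_start, "00:00:00"), tz = "UTC"),
              as.POSIXct(paste(cfg$season_end, "23:30:00"), tz = "UTC"),
              by = 1800)
  meteo <- meteo_at(cfg, drv, grid)

  # precipitation: seeded wet-day process, spread over six half-hour slots
  precip <- numeric(length(grid))
  meteo_day <- as.Date(grid, tz = "UTC")
  with_seed(cfg$seed, {
    for (k in seq_len(nrow(drv))) {
      if (stats::runif(1) < 0.45) {
        amount <- stats::rgamma(1, shape = 0.9, scale = 5.4)
        start <- sample.int(43, 1)
        idx <- which(meteo_day == drv$date[k])[start:(start + 5)]
        precip[idx] <- precip[idx] + amount / 6
      }
    }
  })
  meteo$precip <- precip
  meteo$precip_sheltered <- precip * (1 - cfg$precip_exclusion_frac)

  treatments <- cfg$treatment_effects$treatment
  lite <- list(config = cfg, drivers = drv)  # avoid re-deriving drivers
  truth_hh <- do.call(rbind, lapply(treatments, function(trt) {
    truth_fluxes(lite, grid, trt)
  }))

  # daily truth sums on a 2-min grid (trapezoid)
  fine_h <- seq(0, 24, by = 1 / 30)
  w <- c(diff(fine_h) / 2, 0) + c(0, diff(fine_h) / 2)  # hours
  truth_daily <- do.call(rbind, lapply(treatments, function(trt) {
    do.call(rbind, lapply(seq_len(nrow(drv)), function(k) {
      tt <- as.POSIXct(paste(drv$date[k], "00:00:00"), tz = "UTC") +
        pmin(fine_h, 24 - 1e-9) * 3600
      tr <- truth_fluxes(lite, tt, trt)
      data.frame(date = drv$date[k], treatment = trt,
                 nee_sum = sum(w * tr$nee) * 3600 * .G_C_PER_UMOL,
                 gpp_sum = sum(w * tr$gpp) * 3600 * .G_C_PER_UMOL,
                 reco_sum = sum(w * tr$reco) * 3600 * .G_C_PER_UMOL,
                 et_sum = sum(w * tr$et) * 3600 * .KG_H2O_PER_MMOL,
                 t_sum = sum(w * tr$t) * 3600 * .KG_H2O_PER_MMOL,
                 e_sum = sum(w * tr$e) * 3600 * .KG_H2O_PER_MMOL)
    }))
  }))
  rownames(truth_daily) <- NULL

  truth_season <- do.call(rbind, lapply(split(truth_daily, truth_daily$treatment),
                                        function(df) {
    data.frame(treatment = df$treatment[1],
               nee_sum = sum(df$nee_sum), gpp_sum = sum(df$gpp_sum),
               reco_sum = sum(df$reco_sum), et_sum = sum(df$et_sum),
               t_sum = sum(df$t_sum), e_sum = sum(df$e_sum))
  }))
  rownames(truth_season) <- NULL

  structure(list(config = cfg, drivers = drv, meteo = meteo,
                 truth_halfhourly = truth_hh, truth_daily = truth_daily,
                 truth_season = truth_season),
            class = "grassflux_season")
}

#' @export
print.grassflux_season <- function(x, ...) {
  cat("Synthetic grassland season:",
      format(x$config$season_start), "to", format(x$config$season_end), "\n")
  cat("  meteo rows:", nrow(x$meteo),
      "| truth rows:", nrow(x$truth_halfhourly), "\n")
  cat("  ambient precip:", round(sum(x$meteo$precip), 1),
      "mm | sheltered:", round(sum(x$meteo$precip_sheltered), 1), "mm\n")
  print(x$truth_season, digits = 4)
  invisible(x)
}

# ---- campaign sampling ------------------------------------------------------

#' @noRd
invert_chamber_h2o <- function(et, w_in, n, area_m2) {
  # solve et = n * (w_out - w_in) / (area * (1 - w_out/1000)) for w_out
  (n * w_in + et * area_m2) / (n + et * area_m2 / 1000)
}

#' Sample chamber campaigns (flux and isotope tables) from the truth
#'
#' For each campaign date, treatment and plot, light-chamber observations
#' are taken every `sample_interval_min` minutes across the photic window.
#' Mixing-ratio differences are back-computed from the (noise-added) truth
#' fluxes through the same open-chamber balance that [chamber_flux()]
#' applies, so the zero-noise composition `chamber_flux(sample(truth))` is
#' the identity. Each light reading gets a paired dark reading
#' `dark_offset_min` later whose NEE is the truth Reco. Isotope records are
#' constructed so that the mass-balance / Craig-Gordon / steady-state
#' partitioning inverts to the truth transpired fraction exactly before
#' delta noise is added.
#'
#' @param season A [generate_season()] object.
#' @param campaign_dates,n_plots Overrides of the configured campaign
#'   design.
#' @param zero_noise Force all noise SDs to zero (default `FALSE`).
#' @param seed RNG seed for the sampling noise (default: the configured
#'   seed plus one).
#' @return list with `chamber` (light + dark observation rows) and
#'   `isotopes` (one row per light observation).
#' @export
sample_chamber_campaigns <- function(season, campaign_dates = NULL,
                                     n_plots = NULL, zero_noise = FALSE,
                                     seed = NULL) {
  stopifnot(inherits(season, "grassflux_season"))
  cfg <- season$config
  drv <- season$drivers
  if (is.null(campaign_dates)) campaign_dates <- cfg$campaign_dates
  campaign_dates <- as.Date(campaign_dates)
  if (any(campaign_dates < cfg$season_start | campaign_dates > cfg$season_end)) {
    stop("campaign dates must lie within the season")
  }
  if (is.null(n_plots)) n_plots <- cfg$n_plots
  stopifnot(n_plots >= 1)
  sd_nee <- if (zero_noise) 0 else cfg$noise_sd_nee
  sd_et <- if (zero_noise) 0 else cfg$noise_sd_et
  sd_delta <- if (zero_noise) 0 else cfg$noise_sd_delta

  treatments <- cfg$treatment_effects$treatment
  area_m2 <- cfg$base_area * 1e-4

  if (is.null(seed)) seed <- cfg$seed + 1L
  chamber <- list(); isotopes <- list()
  with_seed(seed, {
    for (d in as.list(campaign_dates)) {
      k <- match(d, drv$date)
      hours <- seq(drv$sr_p[k], drv$ss_p[k], by = cfg$sample_interval_min / 60)
      tt <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC") + hours * 3600
      met <- meteo_at(cfg, drv, tt)
      n_mol <- molar_flow(cfg$flow, met$air_temp, cfg$pressure)
      w_in <- met$rh / 100 * saturation_vapor_pressure(met$air_temp) /
        cfg$pressure * 1000
      for (trt in treatments) {
        tr <- truth_fluxes(cfg, tt, trt)
        for (p in seq_len(n_plots)) {
          plot_id <- paste0(trt, "-", p)
          nee_obs <- tr$nee + stats::rnorm(length(tt), 0, sd_nee)
          et_obs <- tr$et + stats::rnorm(length(tt), 0, sd_et)
          reco_obs <- tr$reco + stats::rnorm(length(tt), 0, sd_nee)
          e_obs <- tr$e + stats::rnorm(length(tt), 0, sd_et)

          w_out <- invert_chamber_h2o(et_obs, w_in, n_mol, area_m2)
          light <- data.frame(
            timestamp = tt, plot_id = plot_id, treatment = trt,
            co2_in = cfg$co2_ambient,
            co2_out = cfg$co2_ambient + nee_obs * area_m2 / n_mol,
            h2o_in = w_in, h2o_out = w_out,
            flow = cfg$flow, base_area = cfg$base_area,
            air_temp = met$air_temp, pressure = cfg$pressure, dark = FALSE)
          w_out_d <- invert_chamber_h2o(e_obs, w_in, n_mol, area_m2)
          dark <- data.frame(
            timestamp = tt + cfg$dark_offset_min * 60, plot_id = plot_id,
            treatment = trt, co2_in = cfg$co2_ambient,
            co2_out = cfg$co2_ambient + reco_obs * area_m2 / n_mol,
            h2o_in = w_in, h2o_out = w_out_d,
            flow = cfg$flow, base_area = cfg$base_area,
            air_temp = met$air_temp, pressure = cfg$pressure, dark = TRUE)
          chamber[[length(chamber) + 1L]] <- rbind(light, dark)

          # isotope construction: delta_ET mixes the Craig-Gordon delta_E
          # and steady-state delta_T endmembers at the truth ft, then the
          # outlet vapor delta is chosen so the mass balance returns it
          t_soil <- drv$t_daily[k]
          h_norm <- pmin(met$rh / 100 * saturation_vapor_pressure(met$air_temp) /
                           saturation_vapor_pressure(t_soil), 0.95)
          delta_source_p <- cfg$delta_source + (p - (n_plots + 1) / 2) * 0.25
          cg <- craig_gordon_params(t_soil)
          d_e <- craig_gordon_delta_e(cfg$delta_soil, cfg$delta_atm, h_norm, cg)$delta_e
          d_t <- delta_t_steady_state(delta_source_p)
          d_et <- d_e + tr$ft * (d_t - d_e)
          d_out <- (d_et * (w_out - w_in) + w_in * cfg$delta_atm) / w_out
          isotopes[[length(isotopes) + 1L]] <- data.frame(
            timestamp = tt, plot_id = plot_id, treatment = trt,
            delta_v_in = cfg$delta_atm + stats::rnorm(length(tt), 0, sd_delta),
            delta_v_out = d_out + stats::rnorm(length(tt), 0, sd_delta),
            w_in = w_in, w_out = w_out,
            delta_soil = cfg$delta_soil + stats::rnorm(length(tt), 0, sd_delta),
            delta_source = delta_source_p + stats::rnorm(length(tt), 0, sd_delta),
            t_soil = t_soil, h_norm = h_norm)
        }
      }
    }
  })
  list(chamber = do.call(rbind, chamber), isotopes = do.call(rbind, isotopes))
}

#' Sample the half-hourly eddy-covariance series for the ambient control
#'
#' The EC series is the CC truth flux plus the configured daily-sum bias
#' distributed uniformly over the day, plus additive Gaussian noise per
#' half-hour. With zero bias and zero noise its daily sums equal the truth
#' daily sums (Riemann, half-hour means).
#'
#' @param season A [generate_season()] object.
#' @param zero_noise Force EC noise to zero (default `FALSE`).
#' @param seed RNG seed for the EC noise (default: the configured seed
#'   plus two).
#' @return data.frame with `timestamp`, `nee` (umol CO2 m-2 s-1), `et`
#'   (mmol H2O m-2 s-1).
#' @export
sample_ec_series <- function(season, zero_noise = FALSE, seed = NULL) {
  stopifnot(inherits(season, "grassflux_season"))
  cfg <- season$config
  tr <- season$truth_halfhourly
  cc <- tr[tr$treatment == "CC", , drop = FALSE]
  bias_nee <- cfg$ec_offset_nee / (.G_C_PER_UMOL * .SECONDS_PER_DAY)
  bias_et <- cfg$ec_offset_et / (.KG_H2O_PER_MMOL * .SECONDS_PER_DAY)
  sd_nee <- if (zero_noise) 0 else cfg$ec_noise_nee
  sd_et <- if (zero_noise) 0 else cfg$ec_noise_et
  if (is.null(seed)) seed <- cfg$seed + 2L
  with_seed(seed, {
    data.frame(timestamp = cc$timestamp,
               nee = cc$nee + bias_nee + stats::rnorm(nrow(cc), 0, sd_nee),
               et = cc$et + bias_et + stats::rnorm(nrow(cc), 0, sd_et))
  })
}
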