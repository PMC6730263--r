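# End-to-end convenience wrappers: chamber tables -> partitioned fluxes ->
# daily sums -> treatment means, and the full season budget.

#' Process chamber campaigns through flux computation, NEE and ET
#' partitioning, and daily integration
#'
#' @param chamber Chamber observation table (light + dark rows).
#' @param isotopes Isotope observation table.
#' @param meteo Meteorology table.
#' @param dilution_correction,eps_k,sd_delta,threshold,smooth,span Passed
#'   to the respective stages.
#' @return list with `fluxes` (all records with NEE/ET), `partitioned`
#'   (light records with Reco/GPP and isotope-partitioned T/E), `daily`
#'   (per plot-day sums) and `daily_treatment` (treatment means of the
#'   plot-day sums, with between-plot SDs).
#' @export
process_campaigns <- function(chamber, isotopes, meteo,
                              dilution_correction = TRUE, eps_k = 28.5 * 0.5,
                              sd_delta = 0, threshold = 1,
                              smooth = FALSE, span = 0.75) {
  fluxes <- chamber_flux(chamber, dilution_correction = dilution_correction)
  light <- partition_nee(fluxes)
  part <- partition_campaign(light, isotopes, eps_k = eps_k,
                             sd_delta = sd_delta, threshold = threshold)
  daily <- daily_sums(part, meteo, smooth = smooth, span = span)

  daily$.key <- paste(daily$treatment, daily$date)
  agg <- function(col, f) as.numeric(tapply(daily[[col]], daily$.key, f))
  keys <- sort(unique(daily$.key))
  km <- do.call(rbind, strsplit(keys, " "))
  dt <- data.frame(treatment = km[, 1], date = as.Date(km[, 2]))
  ord <- order(keys)
  for (col in c("nee_sum", "gpp_sum", "reco_sum", "et_sum", "t_sum", "e_sum")) {
    dt[[col]] <- as.numeric(tapply(daily[[col]], daily$.key, mean)[keys])
    dt[[paste0("sd_", sub("_sum", "", col))]] <-
      as.numeric(tapply(daily[[col]], daily$.key, stats::sd)[keys])
  }
  daily$.key <- NULL
  list(fluxes = fluxes, partitioned = part, daily = daily,
       daily_treatment = dt[order(dt$date, dt$treatment), ])
}

#' Run the complete synthetic-world pipeline to a season budget
#'
#' Generates (or accepts) campaign and EC samples from a synthetic season,
#' processes the chamber data, calibrates against the EC series and builds
#' the stage/season budget.
#'
#' @param season A [generate_season()] object.
#' @param campaigns,ec Optional pre-sampled tables (default: sampled from
#'   the season's configuration).
#' @param zero_noise Sample with all noise SDs forced to zero.
#' @param r_threshold Spearman acceptance gate (default 0.75).
#' @param smooth,span Passed to [process_campaigns()].
#' @return list with the [process_campaigns()] elements plus
#'   `calibrations` and `budget`.
#' @export
run_season_pipeline <- function(season, campaigns = NULL, ec = NULL,
                                zero_noise = FALSE, r_threshold = 0.75,
                                smooth = FALSE, span = 0.75) {
  stopifnot(inherits(season, "grassflux_season"))
  if (is.null(campaigns)) {
    campaigns <- sample_chamber_campaigns(season, zero_noise = zero_noise)
  }
  if (is.null(ec)) ec <- sample_ec_series(season, zero_noise = zero_noise)
  proc <- process_campaigns(campaigns$chamber, campaigns$isotopes,
                            season$meteo, smooth = smooth, span = span)
  light <- proc$fluxes[!proc$fluxes$dark, , drop = FALSE]
  calib <- campaign_calibrations(ec, light, proc$daily_treatment,
                                 r_threshold = r_threshold)
  budget <- build_budget(ec_daily_sums(ec), calib,
                         season$config$stage_breaks,
                         season$config$season_start, season$config$season_end)
  c(proc, list(ec = ec, calibrations = calib, budget = budget))
}
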