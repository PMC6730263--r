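# Open dynamic chamber flux computation: NEE, ET from inlet/outlet mixing
# ratios; dark-chamber partitioning into Reco and GPP; water use efficiencies.

#' Molar air flow through an open chamber
#'
#' Converts a volumetric flow at chamber conditions to a molar flow with the
#' ideal gas law, `n = P * Vdot / (R * T)`.
#'
#' @param flow Volumetric flow in L min-1 (must be > 0).
#' @param air_temp Air temperature in degrees Celsius.
#' @param pressure Air pressure in kPa.
#' @return Molar flow in mol s-1.
#' @examples
#' molar_flow(22.414, 0, 101.325) * 60  # one mole per minute at STP
#' @export
molar_flow <- function(flow, air_temp, pressure) {
  if (any(flow <= 0, na.rm = TRUE)) stop("`flow` must be positive (L min-1)")
  if (any(pressure <= 0, na.rm = TRUE)) stop("`pressure` must be positive (kPa)")
  if (any(air_temp <= -100, na.rm = TRUE)) stop("`air_temp` out of physical range")
  (pressure * 1000) * (flow * 1e-3 / 60) / (.R_GAS * (air_temp + 273.15))
}

#' Compute NEE and ET from open-chamber observations
#'
#' Open-system mass balance: the flux through the chamber base area is the
#' molar air flow times the inlet-to-outlet mixing ratio difference,
#' `F = n * (chi_out - chi_in) / A`. CO2 depletion in the outlet air during
#' net uptake yields NEE < 0 (carbon sink); water vapor enrichment yields
#' ET > 0 (loss to the atmosphere). For ET a dilution correction is applied
#' by default: the dry-air molar flow is obtained by dividing by
#' `(1 - w_out)` with `w_out` as a mole fraction.
#'
#' @param obs A data.frame of chamber observations with columns `timestamp`,
#'   `plot_id`, `treatment`, `co2_in`, `co2_out` (umol mol-1), `h2o_in`,
#'   `h2o_out` (mmol mol-1), `flow` (L min-1), `base_area` (cm2, default 962
#'   filled in when absent), `air_temp` (degC), `pressure` (kPa), `dark`
#'   (logical).
#' @param dilution_correction Apply the water-dilution correction to ET
#'   (default `TRUE`). NEE is never dilution-corrected.
#' @return The input with columns `nee` (umol CO2 m-2 s-1), `et`
#'   (mmol H2O m-2 s-1) and `flag_condensation` (TRUE where
#'   `h2o_out < h2o_in`, i.e. apparent negative ET) appended.
#' @export
chamber_flux <- function(obs, dilution_correction = TRUE) {
  required <- c("timestamp", "plot_id", "co2_in", "co2_out", "h2o_in",
                "h2o_out", "flow", "air_temp", "pressure")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols)) {
    stop("`obs` lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(obs$base_area)) obs$base_area <- 962
  if (is.null(obs$dark)) obs$dark <- FALSE
  stopifnot(all(obs$base_area > 0), all(obs$flow > 0))
  if (any(c(obs$co2_in, obs$co2_out, obs$h2o_in, obs$h2o_out) < 0, na.rm = TRUE)) {
    stop("mixing ratios must be non-negative")
  }

  n <- molar_flow(obs$flow, obs$air_temp, obs$pressure)
  area_m2 <- obs$base_area * 1e-4

  obs$nee <- n * (obs$co2_out - obs$co2_in) / area_m2
  et_n <- if (dilution_correction) n / (1 - obs$h2o_out / 1000) else n
  obs$et <- et_n * (obs$h2o_out - obs$h2o_in) / area_m2

  obs$flag_condensation <- obs$h2o_out < obs$h2o_in
  if (any(obs$flag_condensation, na.rm = TRUE)) {
    warning(sum(obs$flag_condensation, na.rm = TRUE),
            " observation(s) with h2o_out < h2o_in (condensation?); ",
            "negative ET retained and flagged")
  }
  obs
}

#' Partition chamber NEE into Reco and GPP with paired dark readings
#'
#' Each light (transparent-chamber) flux is paired with the nearest
#' dark-chamber flux on the same plot within a time window; the dark NEE is
#' ecosystem respiration (stored positive as release) and
#' `GPP = NEE - Reco` (negative = uptake), so `NEE = GPP + Reco` holds
#' exactly for every partitioned record.
#'
#' @param fluxes Output of [chamber_flux()] containing both light and dark
#'   records (`dark` logical column).
#' @param window_min Maximum light-to-dark pairing distance in minutes
#'   (default 30). Ties go to the earlier dark record.
#' @return The light records with `reco`, `gpp` and `flag_unpaired`
#'   appended; unpaired records keep `NA` for `reco`/`gpp`.
#' @export
partition_nee <- function(fluxes, window_min = 30) {
  stopifnot(is.logical(fluxes$dark))
  light <- fluxes[!fluxes$dark, , drop = FALSE]
  dark <- fluxes[fluxes$dark, , drop = FALSE]
  light$reco <- NA_real_
  light$gpp <- NA_real_
  light$flag_unpaired <- TRUE
  if (nrow(dark) && nrow(light)) {
    lt <- as.numeric(as_utc_posix(light$timestamp))
    dt <- as.numeric(as_utc_posix(dark$timestamp))
    for (i in seq_len(nrow(light))) {
      cand <- which(dark$plot_id == light$plot_id[i])
      if (!length(cand)) next
      d <- abs(dt[cand] - lt[i])
      j <- cand[order(d, dt[cand])[1L]]  # nearest; tie -> earlier dark record
      if (min(d) <= window_min * 60) {
        light$reco[i] <- dark$nee[j]
        light$gpp[i] <- light$nee[i] - dark$nee[j]
        light$flag_unpaired[i] <- FALSE
      }
    }
  }
  if (any(light$flag_unpaired)) {
    warning(sum(light$flag_unpaired), " light record(s) without a dark record within ",
            window_min, " min left unpartitioned")
  }
  light
}

#' Canopy water use efficiency, GPP / T
#'
#' @param gpp_daily Daily GPP sum in g C m-2 d-1 (sign-insensitive; the
#'   magnitude is used).
#' @param t_daily Daily transpiration sum in kg H2O m-2 d-1 (must be > 0).
#' @param sd_gpp,sd_t Standard deviations of the inputs for first-order
#'   error propagation (default 0).
#' @return data.frame with `wue_can` (g C kg-1 H2O), `sd` and `flag_undefined`.
#' @export
wue_can <- function(gpp_daily, t_daily, sd_gpp = 0, sd_t = 0) {
  undef <- !is.na(t_daily) & t_daily <= 0
  if (any(undef)) warning("WUE_can undefined where T <= 0; flagged")
  val <- ifelse(undef, NA_real_, abs(gpp_daily) / t_daily)
  sd <- propagate_sd_ratio(abs(gpp_daily), t_daily,
                           rep_len(sd_gpp, length(val)), rep_len(sd_t, length(val)))
  sd[undef] <- NA_real_
  data.frame(wue_can = val, sd = sd, flag_undefined = undef)
}

#' Ecosystem water use efficiency, NEE / ET
#'
#' NEE is sign-flipped so that carbon assimilation gives positive WUE_eco;
#' negative values are allowed (ecosystem acting as a carbon source).
#'
#' @param nee_daily Daily NEE sum in g C m-2 d-1 (negative = sink).
#' @param et_daily Daily ET sum in kg H2O m-2 d-1 (must be > 0).
#' @param sd_nee,sd_et Standard deviations for error propagation (default 0).
#' @return data.frame with `wue_eco` (g C kg-1 H2O), `sd` and
#'   `flag_undefined`.
#' @examples
#' wue_eco(-389.6, 306.0)$wue_eco  # 1.27 after rounding to 2 decimals
#' @export
wue_eco <- function(nee_daily, et_daily, sd_nee = 0, sd_et = 0) {
  undef <- !is.na(et_daily) & et_daily <= 0
  if (any(undef)) warning("WUE_eco undefined where ET <= 0; flagged")
  val <- ifelse(undef, NA_real_, -nee_daily / et_daily)
  sd <- propagate_sd_ratio(-nee_daily, et_daily,
                           rep_len(sd_nee, length(val)), rep_len(sd_et, length(val)))
  sd[undef] <- NA_real_
  data.frame(wue_eco = val, sd = sd, flag_undefined = undef)
}
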