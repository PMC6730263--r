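# delta-18O calibration, flux mass balance for delta_ET, Craig-Gordon
# modelling of delta_E, steady-state delta_T, and the two-endmember
# partitioning of ET into transpiration and soil evaporation.

#' Calibrate raw delta values against laboratory standards
#'
#' Fits an ordinary least-squares linear map from measured to true standard
#' values and applies it to raw observations. When repeated measurements of
#' a drift standard are supplied, a time-linear instrument drift is removed
#' first (residual of the drift standard regressed on time, evaluated at
#' each raw observation's time).
#'
#' @param raw Numeric vector of raw delta values (permil).
#' @param standards data.frame with columns `true` and `measured` (>= 2
#'   distinct measured values).
#' @param raw_times,drift Optional drift correction: `drift` is a data.frame
#'   with columns `time`, `measured` and `true` for one standard sampled
#'   repeatedly; `raw_times` gives the measurement time of each raw value.
#' @return Calibrated delta values (permil).
#' @examples
#' std <- data.frame(true = c(-22, -2), measured = c(-20, 0))
#' calibrate_delta(-10, std)  # -12
#' @export
calibrate_delta <- function(raw, standards, raw_times = NULL, drift = NULL) {
  stopifnot(is.data.frame(standards), all(c("true", "measured") %in% names(standards)))
  if (nrow(standards) < 2 || length(unique(standards$measured)) < 2) {
    stop("need >= 2 standards with distinct measured values")
  }
  if (!is.null(drift)) {
    stopifnot(!is.null(raw_times), all(c("time", "measured", "true") %in% names(drift)))
    tt <- as.numeric(as_utc_posix(drift$time))
    fit_d <- stats::lm(I(measured - true) ~ tt, data = cbind(drift, tt = tt))
    resid_at <- stats::predict(fit_d,
                               newdata = data.frame(tt = as.numeric(as_utc_posix(raw_times))))
    raw <- raw - resid_at
  }
  fit <- stats::lm(true ~ measured, data = standards)
  unname(stats::predict(fit, newdata = data.frame(measured = raw)))
}

#' Isotopic signature of evapotranspiration by flux mass balance
#'
#' Two-endmember mixing of the chamber inlet and outlet vapor streams:
#' `delta_ET = (w_out * d_out - w_in * d_in) / (w_out - w_in)`. Requires a
#' net vapor source inside the chamber (`w_out > w_in`); records violating
#' this are returned as `NA` and flagged.
#'
#' @param w_in,w_out Inlet/outlet water vapor mixing ratios (mmol mol-1).
#' @param delta_in,delta_out Inlet/outlet vapor delta-18O (permil).
#' @return data.frame with `delta_et` (permil) and `flag_no_source`.
#' @examples
#' delta_et_mass_balance(10, 12, -20, -18)$delta_et  # -8
#' @export
delta_et_mass_balance <- function(w_in, w_out, delta_in, delta_out) {
  stopifnot(all(w_in >= 0, na.rm = TRUE), all(w_out >= 0, na.rm = TRUE))
  bad <- !is.na(w_in) & !is.na(w_out) & w_out <= w_in
  val <- (w_out * delta_out - w_in * delta_in) / (w_out - w_in)
  val[bad] <- NA_real_
  if (any(bad)) warning(sum(bad), " record(s) with w_out <= w_in: no net vapor source")
  data.frame(delta_et = val, flag_no_source = bad)
}

#' Equilibrium liquid-vapor fractionation factor for 18O
#'
#' Temperature-dependent equilibrium fractionation,
#' `ln(alpha) = 1137/T^2 - 0.4156/T - 0.0020667` with T in kelvin
#' (Majoube 1971 coefficients). Monotone decreasing and > 1 over the valid
#' range.
#'
#' @param temp Temperature in degrees Celsius, within \[-10, 60\].
#' @return Dimensionless fractionation factor alpha (> 1).
#' @examples
#' 1000 * log(alpha_equilibrium_18o(20))  # ~9.8 permil
#' @export
alpha_equilibrium_18o <- function(temp) {
  if (any(temp < -10 | temp > 60, na.rm = TRUE)) {
    stop("`temp` outside the supported range [-10, 60] degC")
  }
  tk <- temp + 273.15
  exp(1137 / tk^2 - 0.4156 / tk - 0.0020667)
}

#' Craig-Gordon parameter set
#'
#' Bundles the equilibrium fractionation at the evaporating-surface
#' temperature with a kinetic fractionation constant. The kinetic term
#' defaults to the common fully-diffusive 18O value 28.5 permil scaled by an
#' aerodynamic weight of 0.5 (turbulent transport fractionates less); both
#' are configurable.
#'
#' @param temp Evaporating-surface (soil) temperature, degC.
#' @param eps_k Kinetic fractionation in permil (default `28.5 * 0.5`).
#' @param alpha_eq Override for the equilibrium factor (default from
#'   [alpha_equilibrium_18o()]).
#' @return list with `alpha_eq`, `eps_eq` (permil), `eps_k` (permil), and a
#'   `formulation` tag.
#' @export
craig_gordon_params <- function(temp, eps_k = 28.5 * 0.5, alpha_eq = NULL) {
  if (is.null(alpha_eq)) alpha_eq <- alpha_equilibrium_18o(temp)
  list(alpha_eq = alpha_eq, eps_eq = (alpha_eq - 1) * 1000, eps_k = eps_k,
       formulation = "craig-gordon / majoube1971")
}

#' Craig-Gordon isotopic composition of soil evaporation
#'
#' Delta-notation Craig-Gordon model:
#' `delta_E = [ (1000 + delta_soil)/alpha_eq - h * (1000 + delta_atm) ] /
#' [ (1 - h) * (1 + eps_k/1000) ] - 1000`,
#' with `h` the atmospheric humidity normalized to the evaporating-surface
#' temperature. Requires `h < 1` (net evaporation); violations yield `NA`
#' with a flag.
#'
#' @param delta_soil delta-18O of liquid soil water at the evaporating depth
#'   (permil).
#' @param delta_v_atm delta-18O of atmospheric vapor (permil).
#' @param h_norm Normalized humidity, fraction in \[0, 1).
#' @param params A [craig_gordon_params()] list (vectorized over
#'   `alpha_eq`).
#' @return data.frame with `delta_e` (permil) and `flag_saturated`.
#' @export
craig_gordon_delta_e <- function(delta_soil, delta_v_atm, h_norm, params) {
  stopifnot(all(h_norm >= 0, na.rm = TRUE))
  bad <- !is.na(h_norm) & h_norm >= 1
  val <- ((1000 + delta_soil) / params$alpha_eq - h_norm * (1000 + delta_v_atm)) /
    ((1 - h_norm) * (1 + params$eps_k / 1000)) - 1000
  val[bad] <- NA_real_
  if (any(bad)) warning(sum(bad), " record(s) with h_norm >= 1: no net evaporation")
  data.frame(delta_e = val, flag_saturated = bad)
}

#' Isotopic composition of transpiration under isotopic steady state
#'
#' At isotopic steady state the transpired vapor carries the isotopic
#' signature of the plant's source (xylem) water unaltered. A
#' non-steady-state leaf-water model is a documented extension point and is
#' not implemented.
#'
#' @param delta_source delta-18O of xylem/source water (permil).
#' @return delta-18O of transpired vapor (permil), equal to `delta_source`.
#' @export
delta_t_steady_state <- function(delta_source) {
  delta_source
}

#' Partition ET into transpiration and evaporation from isotopic endmembers
#'
#' The transpired fraction is the two-endmember mixing ratio
#' `ft = (delta_ET - delta_E) / (delta_T - delta_E)`; `T = ft * ET` and
#' `E = ET - T`, so `E + T = ET` exactly. `ft` is clamped to \[0, 1\] with
#' the raw value and a `clamped` flag retained. Records where the endmember
#' separation `|delta_T - delta_E|` falls below `threshold` are
#' ill-conditioned and marked invalid. Standard deviations are propagated to
#' first order.
#'
#' @param delta_et,delta_e,delta_t The three isotopic signatures (permil).
#' @param et Evapotranspiration flux (any unit; `t`/`e` inherit it).
#' @param sd_delta_et,sd_delta_e,sd_delta_t,sd_et Optional standard
#'   deviations (default 0).
#' @param threshold Minimum endmember separation in permil (default 1).
#' @return data.frame with `ft_raw`, `ft`, `clamped`, `valid`, `t`, `e`,
#'   `sd_ft`, `sd_t`, `sd_e`.
#' @examples
#' partition_ft(-10, -20, -5, 1)$ft  # 2/3
#' @export
partition_ft <- function(delta_et, delta_e, delta_t, et,
                         sd_delta_et = 0, sd_delta_e = 0, sd_delta_t = 0,
                         sd_et = 0, threshold = 1) {
  n <- max(length(delta_et), length(delta_e), length(delta_t), length(et))
  delta_et <- rep_len(delta_et, n); delta_e <- rep_len(delta_e, n)
  delta_t <- rep_len(delta_t, n); et <- rep_len(et, n)
  sd_delta_et <- rep_len(sd_delta_et, n); sd_delta_e <- rep_len(sd_delta_e, n)
  sd_delta_t <- rep_len(sd_delta_t, n); sd_et <- rep_len(sd_et, n)

  sep <- delta_t - delta_e
  valid <- !is.na(sep) & abs(sep) >= threshold & !is.na(delta_et)
  if (any(!valid)) {
    warning(sum(!valid), " record(s) ill-conditioned (|delta_T - delta_E| < ",
            threshold, " permil) or missing; marked invalid")
  }

  ft_raw <- (delta_et - delta_e) / sep
  ft_raw[!valid] <- NA_real_
  clamped <- !is.na(ft_raw) & (ft_raw < 0 | ft_raw > 1)
  ft <- pmin(pmax(ft_raw, 0), 1)

  # first-order propagation of the ratio (a - b) / (c - b),
  # a = delta_ET, b = delta_E, c = delta_T
  d_a <- 1 / sep
  d_c <- -(delta_et - delta_e) / sep^2
  d_b <- (delta_et - delta_t) / sep^2
  sd_ft <- sqrt((d_a * sd_delta_et)^2 + (d_b * sd_delta_e)^2 + (d_c * sd_delta_t)^2)
  sd_ft[!valid] <- NA_real_

  t_flux <- ft * et
  e_flux <- et - t_flux
  sd_t <- sqrt((et * sd_ft)^2 + (ft * sd_et)^2)
  sd_e <- sqrt((et * sd_ft)^2 + ((1 - ft) * sd_et)^2)

  data.frame(delta_et = delta_et, delta_e = delta_e, delta_t = delta_t,
             ft_raw = ft_raw, ft = ft, clamped = clamped, valid = valid,
             et = et, t = t_flux, e = e_flux,
             sd_ft = sd_ft, sd_t = sd_t, sd_e = sd_e)
}

#' Partition a campaign's chamber ET fluxes with matched isotope records
#'
#' Joins light-chamber flux records to isotope observations by plot and
#' timestamp, derives `delta_ET` by mass balance from the inlet/outlet
#' vapor, models `delta_E` with Craig-Gordon at the soil temperature and
#' `delta_T` at isotopic steady state, and applies [partition_ft()].
#'
#' @param fluxes Light chamber fluxes (from [chamber_flux()], optionally
#'   already through [partition_nee()]).
#' @param isotopes Isotope observation table with columns `timestamp`,
#'   `plot_id`, `delta_v_in`, `delta_v_out`, `w_in`, `w_out`, `delta_soil`,
#'   `delta_source`, `t_soil`, `h_norm`.
#' @param eps_k Kinetic fractionation (permil) passed to
#'   [craig_gordon_params()].
#' @param sd_delta Measurement standard deviation assumed for each delta
#'   observation (permil, default 0) for error propagation.
#' @param threshold Conditioning threshold on `|delta_T - delta_E|`.
#' @return The joined rows with partition columns from [partition_ft()]
#'   appended.
#' @export
partition_campaign <- function(fluxes, isotopes, eps_k = 28.5 * 0.5,
                               sd_delta = 0, threshold = 1) {
  key_f <- paste(fluxes$plot_id, format(as_utc_posix(fluxes$timestamp), "%Y-%m-%d %H:%M:%S"))
  key_i <- paste(isotopes$plot_id, format(as_utc_posix(isotopes$timestamp), "%Y-%m-%d %H:%M:%S"))
  idx <- match(key_f, key_i)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no flux records could be matched to isotope records")
  fl <- fluxes[keep, , drop = FALSE]
  iso <- isotopes[idx[keep], , drop = FALSE]

  det <- delta_et_mass_balance(iso$w_in, iso$w_out, iso$delta_v_in, iso$delta_v_out)
  cg <- craig_gordon_params(iso$t_soil, eps_k = eps_k)
  de <- craig_gordon_delta_e(iso$delta_soil, iso$delta_v_in, iso$h_norm, cg)
  dt <- delta_t_steady_state(iso$delta_source)

  # mass-balance propagation of per-delta noise onto delta_ET
  dw <- iso$w_out - iso$w_in
  sd_det <- sqrt((iso$w_out / dw)^2 + (iso$w_in / dw)^2) * sd_delta
  # Craig-Gordon sensitivities to delta_soil and delta_v_atm
  denom <- (1 - iso$h_norm) * (1 + cg$eps_k / 1000)
  sd_de <- sd_delta * sqrt((1 / (cg$alpha_eq * denom))^2 + (iso$h_norm / denom)^2)

  part <- partition_ft(det$delta_et, de$delta_e, dt, fl$et,
                       sd_delta_et = sd_det, sd_delta_e = sd_de,
                       sd_delta_t = sd_delta, threshold = threshold)
  out <- cbind(fl, part[, setdiff(names(part), "et")])
  out$flag_no_source <- det$flag_no_source
  out
}
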