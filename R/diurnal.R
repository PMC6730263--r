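# Campaign-day smoothing and integration to daily sums: loess with a 68%
# confidence band, PPFD-based photoperiod bounds, trapezoidal integration
# with sunrise/sunset anchoring of GPP and T, and night extrapolation of E
# and Reco from the first/last measured hour.

#' Loess smoothing with a 68% confidence band
#'
#' Local linear regression with tricube weights; the band is the point
#' estimate plus/minus one standard error of the local fit (a 68% interval
#' under normality). With fewer than 4 points the smoother falls back to
#' linear interpolation and flags the result.
#'
#' @param times Numeric or POSIXct abscissae.
#' @param values Numeric ordinates.
#' @param span Loess span (default 0.75).
#' @param degree Local polynomial degree (default 1).
#' @param at Optional abscissae at which to evaluate (defaults to `times`).
#' @return data.frame with `time`, `fit`, `se`, `lwr`, `upr`,
#'   `flag_fallback`.
#' @export
loess_smooth <- function(times, values, span = 0.75, degree = 1, at = NULL) {
  x <- if (inherits(times, "POSIXct")) as.numeric(times) else as.numeric(times)
  x0 <- if (is.null(at)) x else if (inherits(at, "POSIXct")) as.numeric(at) else as.numeric(at)
  out_time <- if (is.null(at)) times else at
  ok <- !is.na(x) & !is.na(values)
  if (sum(ok) < 4) {
    fit <- stats::approx(x[ok], values[ok], xout = x0, rule = 2)$y
    return(data.frame(time = out_time, fit = fit, se = NA_real_,
                      lwr = NA_real_, upr = NA_real_, flag_fallback = TRUE))
  }
  mod <- stats::loess(values ~ x, data = data.frame(x = x[ok], values = values[ok]),
                      span = span, degree = degree,
                      control = stats::loess.control(surface = "direct"))
  pr <- stats::predict(mod, newdata = data.frame(x = x0), se = TRUE)
  data.frame(time = out_time, fit = pr$fit, se = pr$se.fit,
             lwr = pr$fit - pr$se.fit, upr = pr$fit + pr$se.fit,
             flag_fallback = FALSE)
}

#' Photoperiod bounds of a day from PPFD
#'
#' Sunrise is the first 30-min timestamp of the day with PPFD above a
#' threshold, sunset the last. On an all-dark day both are `NA`; daytime
#' fluxes (GPP, T) then integrate to zero.
#'
#' @param meteo Meteorology table with `timestamp` and `ppfd`.
#' @param date A `Date` (or coercible).
#' @param ppfd_threshold Threshold in umol m-2 s-1 (default 5).
#' @return list with POSIXct `sunrise` and `sunset` (NA if all dark).
#' @export
day_bounds <- function(meteo, date, ppfd_threshold = 5) {
  ts <- as_utc_posix(meteo$timestamp)
  date <- as.Date(date)
  sel <- as.Date(ts, tz = "UTC") == date
  if (!any(sel)) stop("meteorology does not cover ", format(date))
  lit <- sel & !is.na(meteo$ppfd) & meteo$ppfd > ppfd_threshold
  if (!any(lit)) {
    return(list(sunrise = as.POSIXct(NA, tz = "UTC"),
                sunset = as.POSIXct(NA, tz = "UTC")))
  }
  list(sunrise = min(ts[lit]), sunset = max(ts[lit]))
}

#' @noRd
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

#' Integrate one campaign day of (partitioned) fluxes to daily sums
#'
#' Daytime fluxes are integrated trapezoidally on a regular grid spanning
#' midnight to midnight. GPP and T are anchored to zero at sunrise and
#' sunset and are zero at night. E and Reco are extended over the
#' pre-measurement night with the mean of the first measured hour and over
#' the post-measurement night with the mean of the last measured hour; at
#' night NEE equals Reco and ET equals E. NEE and ET are rebuilt as
#' GPP + Reco and T + E on the grid so the flux identities carry over to the
#' daily sums exactly. Component standard deviations, when present, are
#' propagated through the trapezoid weights assuming independent records.
#'
#' @param day_fluxes One plot-day of flux records with columns `timestamp`,
#'   `reco`, `gpp` (umol CO2 m-2 s-1), `t`, `e` (mmol H2O m-2 s-1), and
#'   optionally `sd_reco`, `sd_gpp`, `sd_t`, `sd_e`.
#' @param sunrise,sunset POSIXct photoperiod bounds (see [day_bounds()]);
#'   both `NA` for an all-dark day.
#' @param grid_min Integration grid step in minutes (default 30).
#' @return One-row data.frame: `date`, `nee_sum`, `gpp_sum`, `reco_sum`
#'   (g C m-2 d-1), `et_sum`, `t_sum`, `e_sum` (kg H2O m-2 d-1), matching
#'   `sd_*` columns, `sunrise`, `sunset`, `flag_low_confidence` (measured
#'   window < 2 h).
#' @export
integrate_daily <- function(day_fluxes, sunrise, sunset, grid_min = 30) {
  ts <- as_utc_posix(day_fluxes$timestamp)
  o <- order(ts)
  day_fluxes <- day_fluxes[o, , drop = FALSE]
  ts <- ts[o]
  date <- as.Date(ts[1], tz = "UTC")
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  tsec <- as.numeric(ts) - as.numeric(midnight)
  t0 <- min(tsec); tn <- max(tsec)
  low_conf <- (tn - t0) < 2 * 3600
  sr <- if (is.na(sunrise)) NA_real_ else as.numeric(sunrise) - as.numeric(midnight)
  ss <- if (is.na(sunset)) NA_real_ else as.numeric(sunset) - as.numeric(midnight)

  grid <- seq(0, .SECONDS_PER_DAY, by = grid_min * 60)

  first_hour <- tsec <= t0 + 3600
  last_hour <- tsec >= tn - 3600

  comp <- function(col) {
    v <- day_fluxes[[col]]
    if (is.null(v)) return(NULL)
    if (col %in% c("gpp", "t", "sd_gpp", "sd_t")) {
      if (is.na(sr)) return(rep(0, length(grid)))
      anchor <- !(col %in% c("sd_gpp", "sd_t"))  # sd anchors carry no value
      inside <- tsec > sr & tsec < ss
      xx <- c(sr, tsec[inside], ss)
      yy <- c(if (anchor) 0 else 0, v[inside], if (anchor) 0 else 0)
      y <- rep(0, length(grid))
      day <- grid >= sr & grid <= ss
      y[day] <- stats::approx(xx, yy, xout = grid[day], rule = 2, ties = "ordered")$y
      y
    } else {
      start_mean <- mean(v[first_hour], na.rm = TRUE)
      end_mean <- mean(v[last_hour], na.rm = TRUE)
      # all-NA edge hours (e.g. every record flagged invalid): fall back to
      # the nearest valid record
      if (!is.finite(start_mean)) start_mean <- v[which(!is.na(v))[1]]
      if (!is.finite(end_mean)) end_mean <- v[rev(which(!is.na(v)))[1]]
      y <- stats::approx(tsec, v, xout = grid, rule = 2, ties = "ordered")$y
      y[grid < t0] <- start_mean
      y[grid > tn] <- end_mean
      y
    }
  }

  gpp <- comp("gpp"); t_ <- comp("t"); reco <- comp("reco"); e_ <- comp("e")
  if (is.null(gpp) || is.null(reco) || is.null(t_) || is.null(e_)) {
    stop("`day_fluxes` must carry partitioned components gpp, reco, t, e")
  }
  nee <- gpp + reco
  et <- t_ + e_

  sums_c <- vapply(list(nee = nee, gpp = gpp, reco = reco),
                   function(y) .trapz(grid, y) * .G_C_PER_UMOL, numeric(1))
  sums_w <- vapply(list(et = et, t = t_, e = e_),
                   function(y) .trapz(grid, y) * .KG_H2O_PER_MMOL, numeric(1))

  # sd of the trapezoid sum: quadrature over grid nodes with trapezoid weights
  grid_sd <- function(col, fac) {
    y <- comp(col)
    if (is.null(y)) return(0)
    w <- c(diff(grid) / 2, 0) + c(0, diff(grid) / 2)
    sqrt(sum((w * y)^2)) * fac
  }
  sd_gpp <- grid_sd("sd_gpp", .G_C_PER_UMOL)
  sd_reco <- grid_sd("sd_reco", .G_C_PER_UMOL)
  sd_t <- grid_sd("sd_t", .KG_H2O_PER_MMOL)
  sd_e <- grid_sd("sd_e", .KG_H2O_PER_MMOL)

  out <- data.frame(
    date = date,
    nee_sum = sums_c[["nee"]], gpp_sum = sums_c[["gpp"]], reco_sum = sums_c[["reco"]],
    et_sum = sums_w[["et"]], t_sum = sums_w[["t"]], e_sum = sums_w[["e"]],
    sd_nee = propagate_sd_sum(sd_gpp, sd_reco), sd_gpp = sd_gpp, sd_reco = sd_reco,
    sd_et = propagate_sd_sum(sd_t, sd_e), sd_t = sd_t, sd_e = sd_e,
    sunrise = if (is.na(sr)) as.POSIXct(NA, tz = "UTC") else midnight + sr,
    sunset = if (is.na(ss)) as.POSIXct(NA, tz = "UTC") else midnight + ss,
    flag_low_confidence = low_conf
  )
  for (extra in c("plot_id", "treatment")) {
    if (!is.null(day_fluxes[[extra]])) out[[extra]] <- day_fluxes[[extra]][1]
  }
  out
}

#' Daily sums for all plot-days of a partitioned campaign table
#'
#' Convenience wrapper: splits a partitioned flux table by plot and calendar
#' day, optionally loess-smooths each component series, derives photoperiod
#' bounds from the meteorology, and integrates each day with
#' [integrate_daily()].
#'
#' @param partitioned Table with `timestamp`, `plot_id`, `treatment`,
#'   `gpp`, `reco` (umol m-2 s-1), `t`, `e` (mmol m-2 s-1).
#' @param meteo Meteorology table (for [day_bounds()]).
#' @param smooth Apply [loess_smooth()] to each component before
#'   integration (default `FALSE`; with smoothing on, the loess standard
#'   errors feed the daily-sum error propagation).
#' @param span,ppfd_threshold,grid_min Passed through to the smoothing /
#'   bounds / integration steps.
#' @return data.frame of daily sums, one row per plot-day.
#' @export
daily_sums <- function(partitioned, meteo, smooth = FALSE, span = 0.75,
                       ppfd_threshold = 5, grid_min = 30) {
  ts <- as_utc_posix(partitioned$timestamp)
  partitioned$.date <- as.Date(ts, tz = "UTC")
  pieces <- split(partitioned, list(partitioned$plot_id, partitioned$.date), drop = TRUE)
  rows <- lapply(pieces, function(df) {
    df <- df[order(as_utc_posix(df$timestamp)), , drop = FALSE]
    if (smooth && nrow(df) >= 4) {
      for (col in c("gpp", "reco", "t", "e")) {
        sm <- loess_smooth(as_utc_posix(df$timestamp), df[[col]], span = span)
        df[[col]] <- sm$fit
        df[[paste0("sd_", col)]] <- sm$se
      }
    }
    b <- day_bounds(meteo, df$.date[1], ppfd_threshold = ppfd_threshold)
    integrate_daily(df, b$sunrise, b$sunset, grid_min = grid_min)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$date, out$plot_id), , drop = FALSE]
}
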