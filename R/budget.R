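# Chamber / eddy-covariance fusion: correlation-gated additive offset
# calibration per campaign, nearest-neighbor interpolation of offsets, and
# stage/season budgets with ecosystem water use efficiency.

#' Daily sums of a half-hourly eddy-covariance series
#'
#' Riemann sums of the half-hour means: NEE in umol CO2 m-2 s-1 integrates
#' to g C m-2 d-1, ET in mmol H2O m-2 s-1 to kg H2O m-2 d-1.
#'
#' @param ec Table with `timestamp`, `nee`, `et` at 30-min resolution.
#' @return data.frame with `date`, `nee_sum`, `et_sum`, `n_halfhours`.
#' @export
ec_daily_sums <- function(ec) {
  ts <- as_utc_posix(ec$timestamp)
  d <- as.Date(ts, tz = "UTC")
  agg <- function(v) tapply(v, d, sum, na.rm = TRUE)
  n <- tapply(!is.na(ec$nee), d, sum)
  out <- data.frame(
    date = as.Date(names(agg(ec$nee))),
    nee_sum = as.numeric(agg(ec$nee)) * 1800 * .G_C_PER_UMOL,
    et_sum = as.numeric(agg(ec$et)) * 1800 * .KG_H2O_PER_MMOL,
    n_halfhours = as.integer(n)
  )
  rownames(out) <- NULL
  out
}

#' Spearman rank correlation between eddy-covariance and chamber fluxes
#'
#' Each chamber observation is matched to the nearest half-hourly
#' eddy-covariance record within a window; the rank correlation (invariant
#' under monotone transforms, appropriate for non-normal flux data) is
#' returned. Fewer than `min_pairs` matches yields `NA` with zero pairs
#' usable for calibration.
#'
#' @param ec Half-hourly EC table (`timestamp`, plus the column named in
#'   `flux`).
#' @param chamber Chamber flux records (`timestamp`, plus `flux` column).
#' @param flux Column name to correlate (e.g. `"nee"` or `"et"`).
#' @param window_min Maximum matching distance in minutes (default 15).
#' @param min_pairs Minimum usable pairs (default 5).
#' @return list with `r` (Spearman) and `n_pairs`.
#' @export
campaign_correlation <- function(ec, chamber, flux = "nee", window_min = 15,
                                 min_pairs = 5) {
  et_ <- as.numeric(as_utc_posix(ec$timestamp))
  ct_ <- as.numeric(as_utc_posix(chamber$timestamp))
  idx <- vapply(ct_, function(t) {
    j <- which.min(abs(et_ - t))
    if (abs(et_[j] - t) <= window_min * 60) j else NA_integer_
  }, integer(1))
  ok <- !is.na(idx) & !is.na(chamber[[flux]])
  x <- chamber[[flux]][ok]
  y <- ec[[flux]][idx[ok]]
  ok2 <- !is.na(y)
  if (sum(ok2) < min_pairs) return(list(r = NA_real_, n_pairs = sum(ok2)))
  list(r = stats::cor(x[ok2], y[ok2], method = "spearman"), n_pairs = sum(ok2))
}

#' Average daily-sum offset between chamber and eddy-covariance fluxes
#'
#' Additive calibration offset for one campaign: the mean over campaign
#' days of (chamber daily sum - EC daily sum).
#'
#' @param ec_daily_sum,chamber_daily_sum Daily sums on matching days (same
#'   length).
#' @return Mean offset (chamber minus EC).
#' @export
campaign_offset <- function(ec_daily_sum, chamber_daily_sum) {
  stopifnot(length(ec_daily_sum) == length(chamber_daily_sum))
  mean(chamber_daily_sum - ec_daily_sum, na.rm = TRUE)
}

#' Per-campaign correlation gating and offset calibration
#'
#' For each campaign date and treatment: computes the Spearman correlation
#' between that treatment's half-hourly chamber fluxes and the (single,
#' ambient) EC series, accepts the campaign when `r > r_threshold`, and for
#' accepted campaigns computes the additive daily-sum offset per flux.
#'
#' @param ec Half-hourly EC table (`timestamp`, `nee`, `et`).
#' @param fluxes Chamber flux records across campaigns (`timestamp`,
#'   `treatment`, `nee`, `et`; light records).
#' @param chamber_daily Chamber daily sums per treatment and date
#'   (`date`, `treatment`, `nee_sum`, `et_sum`), e.g. treatment means of
#'   [daily_sums()] output.
#' @param r_threshold Acceptance gate on Spearman r (default 0.75,
#'   strictly greater).
#' @param window_min Matching window for [campaign_correlation()].
#' @return data.frame with one row per campaign date x treatment x flux:
#'   `campaign_date`, `treatment`, `flux`, `spearman_r`, `n_pairs`,
#'   `accepted`, `offset` (NA unless accepted).
#' @export
campaign_calibrations <- function(ec, fluxes, chamber_daily,
                                  r_threshold = 0.75, window_min = 15) {
  ecd <- ec_daily_sums(ec)
  dates <- sort(unique(as.Date(as_utc_posix(fluxes$timestamp), tz = "UTC")))
  rows <- list()
  for (d in as.list(dates)) {
    for (trt in unique(fluxes$treatment)) {
      ch <- fluxes[fluxes$treatment == trt &
                     as.Date(as_utc_posix(fluxes$timestamp), tz = "UTC") == d, , drop = FALSE]
      if (!nrow(ch)) next
      for (fx in c("nee", "et")) {
        cc <- campaign_correlation(ec, ch, flux = fx, window_min = window_min)
        accepted <- !is.na(cc$r) && cc$r > r_threshold
        off <- NA_real_
        if (accepted) {
          sum_col <- paste0(fx, "_sum")
          chs <- chamber_daily[chamber_daily$treatment == trt & chamber_daily$date == d, sum_col]
          ecs <- ecd[ecd$date == d, sum_col]
          # plot-level daily tables are averaged to the treatment mean
          if (length(chs)) chs <- mean(chs, na.rm = TRUE)
          if (length(chs) && length(ecs)) off <- campaign_offset(ecs, chs)
          else accepted <- FALSE
        }
        rows[[length(rows) + 1L]] <- data.frame(
          campaign_date = d, treatment = trt, flux = fx,
          spearman_r = cc$r, n_pairs = cc$n_pairs,
          accepted = accepted, offset = off)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Nearest-neighbor interpolation of campaign offsets over the season
#'
#' Every season day receives the offset of the temporally nearest accepted
#' campaign (ties go to the earlier campaign); the mapping is the identity
#' on campaign dates. Rejected campaigns contribute nothing and are spanned
#' over.
#'
#' @param calibrations Output of [campaign_calibrations()] (or any frame
#'   with `campaign_date`, `accepted`, `offset`), already filtered to one
#'   treatment and one flux.
#' @param dates Vector of `Date`s to cover.
#' @return Numeric vector of offsets along `dates`.
#' @export
interpolate_offsets <- function(calibrations, dates) {
  acc <- calibrations[calibrations$accepted, , drop = FALSE]
  if (!nrow(acc)) stop("no accepted calibration campaign; budget cannot be produced")
  cd <- as.numeric(as.Date(acc$campaign_date))
  o <- order(cd)
  cd <- cd[o]; off <- acc$offset[o]
  vapply(as.numeric(as.Date(dates)), function(d) {
    dist <- abs(cd - d)
    off[order(dist, cd)[1L]]  # nearest; tie -> earlier campaign
  }, numeric(1))
}

#' Stage and season budgets from offset-calibrated eddy-covariance sums
#'
#' The calibrated daily series is the EC daily sum plus the interpolated
#' treatment offset; days missing from the EC record are gap-filled by
#' linear interpolation of the calibrated series and flagged. Daily sums
#' are accumulated per growth stage (four stages delimited by three break
#' dates) and over the season; ecosystem water use efficiency is the
#' season-level `-NEE / ET`, and percent changes versus the CC control are
#' computed on unrounded sums.
#'
#' @param ec_daily EC daily sums ([ec_daily_sums()] output).
#' @param calibrations [campaign_calibrations()] output for all treatments.
#' @param stage_breaks Three `Date`s splitting the season into 4 stages.
#' @param season_start,season_end Season span (`Date`).
#' @return list with `daily` (calibrated daily series per treatment,
#'   `flag_gapfilled` marking filled days), `stages` (per treatment x stage
#'   sums) and `season` (per treatment: `nee_sum`, `et_sum`, `wue_eco`,
#'   `pct_nee_vs_cc`, `pct_et_vs_cc`, `pct_wue_vs_cc`).
#' @export
build_budget <- function(ec_daily, calibrations, stage_breaks,
                         season_start, season_end) {
  stage_breaks <- as.Date(stage_breaks)
  stopifnot(length(stage_breaks) == 3, !is.unsorted(stage_breaks))
  days <- seq(as.Date(season_start), as.Date(season_end), by = "day")
  stage_of <- findInterval(as.numeric(days), as.numeric(stage_breaks)) + 1L

  treatments <- unique(calibrations$treatment)
  daily_list <- list()
  for (trt in treatments) {
    row <- data.frame(treatment = trt, date = days, stage = stage_of)
    for (fx in c("nee", "et")) {
      cal <- calibrations[calibrations$treatment == trt & calibrations$flux == fx, , drop = FALSE]
      offs <- interpolate_offsets(cal, days)
      ec_v <- ec_daily[[paste0(fx, "_sum")]][match(days, ec_daily$date)]
      filled <- is.na(ec_v)
      if (any(filled)) {
        ec_v <- stats::approx(as.numeric(days[!filled]), ec_v[!filled],
                              xout = as.numeric(days), rule = 2)$y
      }
      row[[paste0(fx, "_sum")]] <- ec_v + offs
      row[[paste0("flag_gapfilled_", fx)]] <- filled
    }
    daily_list[[trt]] <- row
  }
  daily <- do.call(rbind, daily_list)
  rownames(daily) <- NULL

  stages <- do.call(rbind, lapply(treatments, function(trt) {
    dd <- daily[daily$treatment == trt, , drop = FALSE]
    data.frame(treatment = trt, stage = 1:4,
               nee_sum = as.numeric(tapply(dd$nee_sum, dd$stage, sum)[as.character(1:4)]),
               et_sum = as.numeric(tapply(dd$et_sum, dd$stage, sum)[as.character(1:4)]))
  }))
  rownames(stages) <- NULL

  season <- do.call(rbind, lapply(treatments, function(trt) {
    ss <- stages[stages$treatment == trt, , drop = FALSE]
    data.frame(treatment = trt, nee_sum = sum(ss$nee_sum), et_sum = sum(ss$et_sum))
  }))
  season$wue_eco <- wue_eco(season$nee_sum, season$et_sum)$wue_eco
  cc <- season[season$treatment == "CC", , drop = FALSE]
  if (nrow(cc) == 1) {
    season$pct_nee_vs_cc <- percent_vs_cc(season$nee_sum, cc$nee_sum)
    season$pct_et_vs_cc <- percent_vs_cc(season$et_sum, cc$et_sum)
    season$pct_wue_vs_cc <- percent_vs_cc(season$wue_eco, cc$wue_eco)
  }
  rownames(season) <- NULL
  list(daily = daily, stages = stages, season = season)
}
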