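# Meteorological derivations and soil-moisture series utilities.

#' Vapor pressure deficit from the August-Roche-Magnus equation
#'
#' Saturation vapor pressure
#' `e_s = 0.61094 * exp(17.625 * T / (T + 243.04))` kPa and
#' `VPD = e_s * (1 - rh/100)`.
#'
#' @param air_temp Air temperature in degrees Celsius.
#' @param rh Relative humidity in percent, within \[0, 100\].
#' @return VPD in kPa (>= 0).
#' @examples
#' vpd_magnus(20, 50)  # ~1.17 kPa
#' @export
vpd_magnus <- function(air_temp, rh) {
  if (any(rh < 0 | rh > 100, na.rm = TRUE)) stop("`rh` must lie in [0, 100]")
  saturation_vapor_pressure(air_temp) * (1 - rh / 100)
}

#' Gap-fill a daily soil volumetric water content series
#'
#' Gaps of at most `max_gap_days` days are filled by linear interpolation.
#' Longer gaps are reconstructed from replicate sensors: the offset between
#' the broken sensor (mean of its last 10 pre-gap values) and the replicate
#' mean at those same times is added to the replicate mean over the gap.
#' Long gaps without replicate coverage are left missing.
#'
#' @param series data.frame with `timestamp` (daily cadence) and `vwc`
#'   (m3 m-3; `NA` marks gaps).
#' @param replicates Optional numeric matrix/data.frame of replicate-sensor
#'   VWC aligned row-by-row with `series` (one column per replicate).
#' @param max_gap_days Threshold between interpolation and the offset
#'   method (default 10).
#' @param n_reference Number of pre-gap points used for the offset
#'   (default 10).
#' @return `series` with `vwc` filled where possible and a `quality` flag
#'   column: `"measured"`, `"interpolated"`, `"offset_modeled"` or
#'   `"missing"`.
#' @export
gap_fill_vwc <- function(series, replicates = NULL, max_gap_days = 10,
                         n_reference = 10) {
  stopifnot(all(c("timestamp", "vwc") %in% names(series)))
  v <- series$vwc
  quality <- ifelse(is.na(v), "missing", "measured")
  if (!is.null(replicates)) {
    replicates <- as.matrix(replicates)
    stopifnot(nrow(replicates) == nrow(series))
  }
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tnum <- as.numeric(as.Date(series$timestamp))
  for (k in seq_along(r$lengths)) {
    if (!r$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    gap_days <- tnum[i1] - tnum[i0] + 1
    if (gap_days <= max_gap_days && i0 > 1 && i1 < length(v)) {
      fill <- stats::approx(tnum[c(i0 - 1L, i1 + 1L)], v[c(i0 - 1L, i1 + 1L)],
                            xout = tnum[i0:i1])$y
      v[i0:i1] <- fill
      quality[i0:i1] <- "interpolated"
    } else if (!is.null(replicates)) {
      pre <- which(!is.na(series$vwc[seq_len(i0 - 1L)]))
      pre <- utils::tail(pre, n_reference)
      rep_mean <- rowMeans(replicates, na.rm = TRUE)
      if (length(pre) && all(is.finite(rep_mean[c(pre, i0:i1)]))) {
        offset <- mean(series$vwc[pre]) - mean(rep_mean[pre])
        v[i0:i1] <- rep_mean[i0:i1] + offset
        quality[i0:i1] <- "offset_modeled"
      }
    }
  }
  series$vwc <- v
  series$quality <- quality
  series
}

#' Percent VWC differences versus the CC control by stage
#'
#' For daily-averaged VWC series per treatment, computes
#' `100 * (mean_trt - mean_CC) / mean_CC` within each stage window, with a
#' first-order propagated standard deviation from the standard errors of
#' the two stage means.
#'
#' @param vwc_daily data.frame with `date`, `treatment`, `vwc` (daily
#'   means; optionally `depth`, in which case results are per depth).
#' @param stage_breaks Three `Date`s splitting the season into 4 stages.
#' @return data.frame with `treatment`, `stage` (and `depth` if supplied),
#'   `pct_diff`, `sd`.
#' @export
treatment_vwc_difference <- function(vwc_daily, stage_breaks) {
  stage_breaks <- as.Date(stage_breaks)
  stopifnot(length(stage_breaks) == 3)
  vwc_daily$stage <- findInterval(as.numeric(as.Date(vwc_daily$date)),
                                  as.numeric(stage_breaks)) + 1L
  has_depth <- !is.null(vwc_daily$depth)
  keys <- if (has_depth) list(vwc_daily$stage, vwc_daily$depth) else list(vwc_daily$stage)
  pieces <- split(vwc_daily, keys, drop = TRUE)
  rows <- lapply(pieces, function(df) {
    cc <- df$vwc[df$treatment == "CC"]
    if (!length(cc)) return(NULL)
    m_cc <- mean(cc, na.rm = TRUE)
    se_cc <- stats::sd(cc, na.rm = TRUE) / sqrt(sum(!is.na(cc)))
    trts <- setdiff(unique(df$treatment), "CC")
    do.call(rbind, lapply(trts, function(trt) {
      x <- df$vwc[df$treatment == trt]
      m <- mean(x, na.rm = TRUE)
      se <- stats::sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x)))
      diff_sd <- propagate_sd_sum(se, se_cc)
      out <- data.frame(treatment = trt, stage = df$stage[1],
                        pct_diff = 100 * (m - m_cc) / m_cc,
                        sd = 100 * propagate_sd_ratio(m - m_cc, m_cc, diff_sd, se_cc))
      if (!is.null(df$depth)) out$depth <- df$depth[1]
      out
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
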