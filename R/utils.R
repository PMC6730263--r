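# Internal constants and small shared helpers.

# Universal gas constant [J mol-1 K-1]
.R_GAS <- 8.314462618

# Unit conversion factors used throughout the daily/seasonal accounting:
# a CO2 flux in umol m-2 s-1 integrates to grams of carbon with 12e-6 g per
# umol; a water flux in mmol m-2 s-1 integrates to kg with 18e-6 kg per mmol.
.G_C_PER_UMOL <- 12e-6
.KG_H2O_PER_MMOL <- 18e-6

.SECONDS_PER_DAY <- 86400

.TREATMENTS <- c("CC", "CD", "NC", "ND")

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @noRd
as_utc_posix <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  as.POSIXct(x, tz = "UTC")
}

#' Saturated vapor pressure, August-Roche-Magnus form
#'
#' @param air_temp Air temperature in degrees Celsius.
#' @return Saturation vapor pressure in kPa.
#' @seealso [vpd_magnus()]
#' @export
saturation_vapor_pressure <- function(air_temp) {
  0.61094 * exp(17.625 * air_temp / (air_temp + 243.04))
}

#' Standard-error propagation for sums and ratios
#'
#' `propagate_sd_sum()` combines independent standard deviations of added
#' quantities in quadrature. `propagate_sd_ratio()` applies first-order error
#' propagation to a ratio `a / b` (relative variances add).
#'
#' @param ... For `propagate_sd_sum()`, numeric vectors of standard
#'   deviations (recycled to common length and combined elementwise).
#' @return Standard deviation of the sum (same units as inputs).
#' @examples
#' propagate_sd_sum(3, 4)            # 5
#' propagate_sd_ratio(10, 5, 1, 0.5) # ~0.283 (14.1% relative)
#' @export
propagate_sd_sum <- function(...) {
  sds <- list(...)
  if (length(sds) == 1L && is.list(sds[[1L]])) sds <- sds[[1L]]
  stopifnot(all(vapply(sds, function(s) all(s >= 0 | is.na(s)), logical(1))))
  sqrt(Reduce(`+`, lapply(sds, function(s) s^2)))
}

#' @rdname propagate_sd_sum
#' @param a,b Numerator and denominator of the ratio.
#' @param sd_a,sd_b Their standard deviations.
#' @export
propagate_sd_ratio <- function(a, b, sd_a, sd_b) {
  stopifnot(all(sd_a >= 0 | is.na(sd_a)), all(sd_b >= 0 | is.na(sd_b)))
  n <- max(length(a), length(b), length(sd_a), length(sd_b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  sd_a <- rep_len(sd_a, n); sd_b <- rep_len(sd_b, n)
  out <- abs(a / b) * sqrt((sd_a / a)^2 + (sd_b / b)^2)
  # a == 0 with sd_a given: ratio sd reduces to sd_a / |b|
  zero_a <- !is.na(a) & a == 0
  out[zero_a] <- sd_a[zero_a] / abs(b[zero_a])
  out
}

#' Percent change of a treatment quantity relative to the control
#'
#' Computed on magnitudes, `100 * (|x| / |x_cc| - 1)`, so a treatment that
#' halves the size of a carbon sink reports -50 regardless of the sign
#' convention of the flux.
#'
#' @param x Treatment value(s).
#' @param x_cc Control (CC) value.
#' @return Signed percent change (negative = reduction in magnitude).
#' @export
percent_vs_cc <- function(x, x_cc) {
  100 * (abs(x) / abs(x_cc) - 1)
}
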