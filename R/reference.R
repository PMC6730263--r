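# Published reference values used in the worked example and for desk
# checks of the water-use-efficiency and percent-change arithmetic.

#' Published growing-season sums for a temperate grassland nitrogen x
#' drought experiment
#'
#' Seasonal (April-September) sums of net ecosystem exchange and
#' evapotranspiration reported for a seminatural temperate grassland under
#' the four treatments of a crossed nitrogen-addition x rain-out-shelter
#' manipulation: CC (control), CD (precipitation reduction), NC (nitrogen
#' addition), ND (both). NEE is negative for a carbon sink. These values
#' serve as reference inputs for [wue_eco()] and [percent_vs_cc()]
#' examples and checks; they are not produced by the generator.
#'
#' @return data.frame with `treatment`, `nee_sum` (g C m-2) and `et_sum`
#'   (kg H2O m-2).
#' @examples
#' sums <- example_season_sums()
#' round(wue_eco(sums$nee_sum, sums$et_sum)$wue_eco, 2)
#' @export
example_season_sums <- function() {
  data.frame(treatment = c("CC", "CD", "NC", "ND"),
             nee_sum = c(-389.6, -222.9, -157.3, -106.5),
             et_sum = c(306.0, 229.9, 267.2, 184.8))
}
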