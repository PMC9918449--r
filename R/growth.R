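#' CO2 fertilisation factor
#'
#' Saturating rectangular-hyperbola response of C3 photosynthesis to
#' atmospheric CO2, normalised to 1 at the reference concentration (default
#' 350 ppm), giving about 1.2 at 700 ppm with the default half-saturation
#' constant of 175 ppm.
#'
#' @param co2_ppm Atmospheric CO2, ppm.
#' @param constants Model constants (`fco2_half_sat`, `fco2_ref_ppm`).
#' @return Dimensionless fertilisation factor.
#' @examples
#' f_co2(c(350, 700))
#' @export
f_co2 <- function(co2_ppm, constants = wl_constants()) {
  stopifnot(all(co2_ppm > 0))
  k <- constants$fco2_half_sat
  ref <- constants$fco2_ref_ppm
  (co2_ppm / (co2_ppm + k)) / (ref / (ref + k))
}

#' Daily biomass increment
#'
#' Radiation-use-efficiency biomass model: intercepted radiation
#' (radiation x fractional canopy cover) times RUE, scaled by the CO2
#' fertilisation factor and the effective photosynthesis multiplier from the
#' waterlogging response.
#'
#' @param radn Solar radiation, MJ/m2/day.
#' @param cover Fractional canopy cover, 0 to 1.
#' @param rue Radiation use efficiency, g/MJ.
#' @param co2_ppm Atmospheric CO2, ppm.
#' @param eff_photo_multiplier Effective photosynthesis multiplier
#'   (from [three_stage_response()]), 0 to 1.
#' @param constants Model constants.
#' @return Biomass increment, g/m2.
#' @examples
#' daily_growth(20, 0.5, 1.2, 350, 1)  # 12 g/m2
#' @export
daily_growth <- function(radn, cover, rue, co2_ppm, eff_photo_multiplier,
                         constants = wl_constants()) {
  stopifnot(radn >= 0, cover >= 0, cover <= 1, rue >= 0,
            eff_photo_multiplier >= 0, eff_photo_multiplier <= 1)
  radn * cover * rue * f_co2(co2_ppm, constants) * eff_photo_multiplier
}

# Stage-driven fractional canopy cover: zero until emergence, expanding
# through the vegetative phases to a plateau of 0.85 at flag leaf, then
# senescing through grain fill.
canopy_cover <- function(stage) {
  x <- c(1, 3, 4, 5, 7, 8, 9, 11)
  y <- c(0, 0.05, 0.45, 0.85, 0.85, 0.60, 0.20, 0.10)
  if (length(stage) == 1) {
    lin_interp(x, y, stage)
  } else {
    stats::approx(x, y, xout = stage, rule = 2)$y
  }
}
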