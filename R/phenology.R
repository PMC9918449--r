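#' Daily thermal time
#'
#' Piecewise-linear three-point thermal-time response evaluated on the daily
#' mean temperature: zero at or below the base and at or above the maximum
#' cardinal temperature, peaking at the optimum (where one degree-day is
#' accrued per degree above base).
#'
#' @param maxt,mint Daily maximum and minimum temperature, deg C
#'   (`maxt >= mint`). Vectorised.
#' @param cardinals Numeric length-3 vector `(base, optimum, maximum)` deg C.
#' @return Degree-days (>= 0).
#' @examples
#' thermal_time(34, 26, c(0, 26, 34))  # mean 30 -> 13
#' @export
thermal_time <- function(maxt, mint, cardinals = c(0, 26, 34)) {
  if (any(maxt < mint)) stop("maxt must be >= mint")
  stopifnot(length(cardinals) == 3, cardinals[1] < cardinals[2],
            cardinals[2] < cardinals[3])
  tmean <- (maxt + mint) / 2
  b <- cardinals[1]; o <- cardinals[2]; m <- cardinals[3]
  peak <- o - b
  ifelse(tmean <= b | tmean >= m, 0,
         ifelse(tmean <= o,
                peak * (tmean - b) / (o - b),
                peak * (m - tmean) / (m - o)))
}

#' Vernalisation factor
#'
#' Multiplier in \[0, 1\] on pre-floral thermal-time accumulation expressing
#' the unmet cold requirement of a genotype. Daily vernalisation units accrue
#' at cool mean temperatures (full effectiveness near 0-12 deg C, tapering to
#' none at 18 deg C); the factor follows the APSIM linear form
#' `1 - 0.0054545 * vern_sens * (50 - V)` clamped to \[0, 1\], where `V` is
#' the accumulated vernalisation (capped at 50 effective days).
#' `vern_sens = 0` or a saturated requirement give a factor of 1.
#'
#' @param cum_vern_days Accumulated vernalisation units (effective days).
#' @param vern_sens Vernalisation sensitivity, 0 to 5.
#' @return Factor in \[0, 1\].
#' @export
vernalisation_factor <- function(cum_vern_days, vern_sens) {
  stopifnot(vern_sens >= 0, vern_sens <= 5)
  v <- pmin(cum_vern_days, 50)
  pmin(1, pmax(0, 1 - 0.0054545 * vern_sens * (50 - v)))
}

#' Daily vernalisation units
#'
#' Effectiveness (0 to 1) of one day towards the vernalisation requirement,
#' as a function of daily mean temperature: 1 between 0 and 12 deg C,
#' linearly tapering to 0 at -4 and at 18 deg C.
#'
#' @param maxt,mint Daily temperature extremes, deg C.
#' @return Vernalisation units for the day, in \[0, 1\].
#' @export
vernalisation_units <- function(maxt, mint) {
  tmean <- (maxt + mint) / 2
  ifelse(tmean <= -4 | tmean >= 18, 0,
         ifelse(tmean < 0, (tmean + 4) / 4,
                ifelse(tmean <= 12, 1, (18 - tmean) / 6)))
}

#' Photoperiod factor
#'
#' Multiplier in \[0, 1\] on pre-floral thermal-time accumulation for a
#' long-day response: development slows under short days in proportion to
#' `photop_sens`. Follows the APSIM quadratic form
#' `1 - 0.002 * photop_sens * (20 - DL)^2` clamped to \[0, 1\], where `DL` is
#' the civil day length (hours) from latitude and day of year.
#' `photop_sens = 0` gives a factor of 1 for any day length.
#'
#' @param latitude Latitude, degrees (negative = southern hemisphere).
#' @param doy Day of year.
#' @param photop_sens Day-length sensitivity, 0 to 5.
#' @return Factor in \[0, 1\].
#' @export
photoperiod_factor <- function(latitude, doy, photop_sens) {
  stopifnot(photop_sens >= 0, photop_sens <= 5)
  dl <- day_length(latitude, doy)
  pmin(1, pmax(0, 1 - 0.002 * photop_sens * (20 - dl)^2))
}

#' Civil day length
#'
#' Day length in hours from latitude and day of year (hemisphere from the
#' latitude sign), including civil twilight as used for crop photoperiod
#' responses.
#'
#' @inheritParams photoperiod_factor
#' @return Hours of daylight.
#' @export
day_length <- function(latitude, doy) {
  # geosphere::daylength handles polar edge cases; add ~40 min of twilight
  pmin(24, geosphere::daylength(latitude, doy) + 0.7)
}

# Thermal-time targets (degree-days) for each phase between consecutive
# stage codes 1..11. Phase i spans stage i -> i+1. Pre-floral phases
# (emergence -> floral initiation, codes 3-5) are additionally modulated by
# vernalisation/photoperiod factors during simulation.
phase_tt_targets <- function(genotype, sowing_depth = 20) {
  c(
    sow_germ = 15,                                    # 1 -> 2
    germ_emerg = 40 + 1.5 * sowing_depth,             # 2 -> 3
    juvenile = genotype$tt_end_of_juvenile,           # 3 -> 4
    floral_init = 350,                                # 4 -> 5
    flag_flower = 180,                                # 5 -> 6
    flower_sgf = 120,                                 # 6 -> 7
    grain_fill = 330,                                 # 7 -> 8
    egf_maturity = 40,                                # 8 -> 9
    mat_ripe = 1,                                     # 9 -> 10
    ripe_end = 1                                      # 10 -> 11
  )
}

# Continuous stage code from cumulative thermal time within the current
# phase: code = phase index + fractional progress.
stage_from_tt <- function(cum_phase_tt, targets) {
  stage <- 1
  for (i in seq_along(targets)) {
    if (cum_phase_tt[i] >= targets[i] - 1e-9) {
      stage <- i + 1
    } else {
      stage <- i + cum_phase_tt[i] / targets[i]
      break
    }
  }
  min(stage, 11)
}

#' Map APSIM-style stage codes to a Zadoks-like growth-stage scale
#'
#' Piecewise-linear mapping from the continuous 1-11 stage code to the
#' 0-100 growth-stage scale used by the six phase bins of the stress
#' typology. Anchors: emergence (3) -> 10, end of juvenile (4) -> 21,
#' floral initiation (5) -> 32, flowering (6) -> 65, start of grain fill
#' (7) -> 71, end of grain fill (8) -> 87, maturity (9) -> 92. The exact
#' correspondence is a package convention (the two scales have no printed
#' one-to-one mapping).
#'
#' @param stage Continuous stage code(s) in \[1, 11\].
#' @return Growth stage on the 0-100 scale.
#' @export
stage_to_zadoks <- function(stage) {
  x <- c(1, 3, 4, 5, 6, 7, 8, 9, 11)
  y <- c(0, 10, 21, 32, 65, 71, 87, 92, 100)
  stats::approx(x, y, xout = stage, rule = 2)$y
}
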