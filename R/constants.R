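#' Model constants and tunable overrides
#'
#' Central registry of the numerical constants of the waterlogging stress
#' model. Every value can be overridden, but overrides are validated against
#' their documented range so configuration files cannot silently push the
#' model outside its calibrated domain.
#'
#' @details
#' The constants are:
#' \describe{
#'   \item{rtfr_threshold}{Fraction of roots waterlogged at and below which no
#'     stress is invoked (default 0.8). Both stress indices equal 1 up to this
#'     value and decrease linearly beyond it.}
#'   \item{oxdef_pheno_floor}{Value of the phenology stress index at full
#'     saturation (default 0.8).}
#'   \item{saturation_fraction}{A soil layer counts as waterlogged when its
#'     water content reaches DUL + saturation_fraction * (SAT - DUL)
#'     (default 0.97; avoids floating-point knife-edges at exactly SAT).}
#'   \item{capillary_fringe_fraction}{A layer resting on a saturated layer
#'     is also flagged waterlogged while its content exceeds
#'     DUL + capillary_fringe_fraction * (SAT - DUL) (default 0.5),
#'     representing the tension-saturated capillary fringe above a perched
#'     water table; 0 disables the rule.}
#'   \item{stage_mod_anchors}{Stage (x) and modifier (y) anchor points of the
#'     stage-dependent phenology modifier. Defaults: 0.65 flat below stage 4,
#'     0.65 to 0.95 between stages 4 and 5.5, 0.95 to 1.0 up to stage 6,
#'     1.0 to 1.5 between stages 6 and 10, 1.5 flat above 10.}
#'   \item{lag_days}{Duration (days) of response stage one, during which
#'     growth is unaffected by saturation (default 3).}
#'   \item{adapt_days}{Days from the end of the lag to the fully adapted
#'     response (default 10).}
#'   \item{fco2_half_sat}{Half-saturation constant (ppm) of the rectangular
#'     hyperbola CO2 fertilisation response (default 175, giving a response
#'     normalised to 1 at 350 ppm and about 1.2 at 700 ppm).}
#'   \item{fco2_ref_ppm}{CO2 concentration (ppm) at which the fertilisation
#'     factor is 1 (default 350).}
#' }
#'
#' @param ... Named overrides of the defaults listed above.
#' @return A named list of constants with class `wl_constants`.
#' @examples
#' wl_constants()
#' wl_constants(lag_days = 5)
#' @export
wl_constants <- function(...) {
  defaults <- list(
    rtfr_threshold = 0.8,
    oxdef_pheno_floor = 0.8,
    saturation_fraction = 0.97,
    capillary_fringe_fraction = 0.5,
    stage_mod_anchors = list(
      x = c(1, 4, 5.5, 6, 10, 11),
      y = c(0.65, 0.65, 0.95, 1.0, 1.5, 1.5)
    ),
    lag_days = 3,
    adapt_days = 10,
    fco2_half_sat = 175,
    fco2_ref_ppm = 350
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad) || is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("unknown model constant(s): ", paste(bad, collapse = ", "))
    }
    defaults[names(overrides)] <- overrides
  }
  validate_wl_constants(defaults)
  structure(defaults, class = "wl_constants")
}

validate_wl_constants <- function(x) {
  stopifnot(
    is.numeric(x$rtfr_threshold), x$rtfr_threshold > 0, x$rtfr_threshold < 1,
    is.numeric(x$oxdef_pheno_floor), x$oxdef_pheno_floor >= 0,
    x$oxdef_pheno_floor <= 1,
    is.numeric(x$saturation_fraction), x$saturation_fraction > 0,
    x$saturation_fraction <= 1,
    is.numeric(x$capillary_fringe_fraction),
    x$capillary_fringe_fraction >= 0,
    x$capillary_fringe_fraction <= 1,
    is.numeric(x$lag_days), x$lag_days >= 0,
    is.numeric(x$adapt_days), x$adapt_days >= 0,
    is.numeric(x$fco2_half_sat), x$fco2_half_sat > 0,
    is.numeric(x$fco2_ref_ppm), x$fco2_ref_ppm > 0
  )
  a <- x$stage_mod_anchors
  stopifnot(length(a$x) == length(a$y), !is.unsorted(a$x), all(a$y > 0))
  invisible(x)
}
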