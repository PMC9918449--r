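#' Photosynthesis waterlogging stress index
#'
#' Dimensionless multiplier (`oxdef_photo`) applied to daily photosynthesis as
#' a function of the fraction of roots waterlogged (`rtfr`). Below the stress
#' threshold (default 0.8) no stress is invoked and the index equals 1; from
#' the threshold it decreases linearly, reaching 0 when the whole root zone is
#' saturated.
#'
#' @param rtfr Fraction of roots in saturated soil layers, in \[0, 1\].
#'   Vectorised.
#' @param constants Model constants, see [wl_constants()].
#' @return Numeric vector of multipliers in \[0, 1\]; 1 means no stress,
#'   0 full stress.
#' @examples
#' oxdef_photo_factor(c(0, 0.5, 0.8, 0.9, 1))
#' @seealso [oxdef_pheno_factor()], [three_stage_response()]
#' @export
oxdef_photo_factor <- function(rtfr, constants = wl_constants()) {
  check_rtfr(rtfr)
  thr <- constants$rtfr_threshold
  ifelse(rtfr < thr, 1, 1 - (rtfr - thr) / (1 - thr))
}

#' Phenology waterlogging stress index
#'
#' Dimensionless index (`oxdef_pheno`) modifying developmental rate under
#' waterlogging. Equals 1 below the stress threshold (default 0.8) and
#' decreases linearly to 0.8 when the soil profile is fully saturated.
#'
#' @inheritParams oxdef_photo_factor
#' @return Numeric vector in \[0.8, 1\] (for the default floor).
#' @examples
#' oxdef_pheno_factor(c(0.7, 0.9, 1))
#' @export
oxdef_pheno_factor <- function(rtfr, constants = wl_constants()) {
  check_rtfr(rtfr)
  thr <- constants$rtfr_threshold
  floor_ <- constants$oxdef_pheno_floor
  ifelse(rtfr < thr, 1, 1 - (1 - floor_) * (rtfr - thr) / (1 - thr))
}

check_rtfr <- function(rtfr) {
  if (!is.numeric(rtfr) || anyNA(rtfr) || any(rtfr < 0 | rtfr > 1)) {
    stop("rtfr must be numeric in [0, 1]")
  }
  invisible(rtfr)
}

#' Stage-dependent phenology stress modifier
#'
#' The modifier (`y_oxdef_lim_pheno`) giving the magnitude and direction of
#' the phenology response to waterlogging as a function of the continuous
#' crop stage code (1 sowing to 11 end of crop; flowering at 6). Values below
#' 1 (pre-flowering) delay development; values above 1 (post-flowering)
#' truncate grain filling. The default anchors are 0.65 at stage 4.0 rising
#' to 0.95 at stage 5.5, closing to 1.0 at flowering, then 1.0 rising to 1.5
#' between stages 6 and 10. Below stage 4 the value 0.65 is extended flat;
#' above stage 10 the value 1.5 is held.
#'
#' The modifier acts only on days with active waterlogging stress; it is the
#' multiplier realised at full saturation, interpolated towards 1 at milder
#' stress (see [simulate_season()]).
#'
#' @param stage Continuous APSIM-style stage code in \[1, 11\]. Vectorised.
#' @inheritParams oxdef_photo_factor
#' @return Numeric vector of modifiers (default range \[0.65, 1.5\]).
#' @examples
#' stage_modifier_pheno(c(4, 5.5, 6, 8, 10))
#' @export
stage_modifier_pheno <- function(stage, constants = wl_constants()) {
  if (!is.numeric(stage) || anyNA(stage) || any(stage < 1 | stage > 11)) {
    stop("stage must be numeric in [1, 11]")
  }
  a <- constants$stage_mod_anchors
  stats::approx(a$x, a$y, xout = stage, rule = 2)$y
}

#' Three-stage waterlogging response and adaptation
#'
#' Effective photosynthesis multiplier for a genotype given the age of the
#' current continuous waterlogging spell. The plant response is conceptualised
#' in three stages: (1) an initial lag in which water supply is unimpeded and
#' growth is unaffected; (2) a full-stress stage in which oxygen-dependent
#' processes are limited and the raw stress index applies; and (3) an adapted
#' stage in which morphological adaptation (e.g. aerenchyma formation) lifts
#' the multiplier to a genotype-specific floor. Fully tolerant genotypes
#' (floor = 1) recover pre-waterlogging photosynthetic rates after adaptation.
#'
#' @param wl_spell_age Days of continuous root-zone saturation (0 on the first
#'   saturated day); resets when `rtfr` drops below the stress threshold.
#' @param raw_stress Raw stress index from [oxdef_photo_factor()].
#' @param genotype A [genotype()] object (uses `y_oxdef_lim_photo_floor`,
#'   `lag_days`, `adapt_days`).
#' @param constants Model constants supplying default lag/adaptation durations
#'   when the genotype does not override them.
#' @return Effective photosynthesis multiplier in \[0, 1\].
#' @examples
#' g <- genotype_preset("spring_susceptible")
#' three_stage_response(0, 0, g)    # lag stage: no stress
#' three_stage_response(7, 0, g)    # full stress
#' three_stage_response(30, 0, g)   # adapted floor
#' @export
three_stage_response <- function(wl_spell_age, raw_stress, genotype,
                                 constants = wl_constants()) {
  stopifnot(is.numeric(wl_spell_age), wl_spell_age >= 0,
            is.numeric(raw_stress), raw_stress >= 0, raw_stress <= 1)
  lag <- genotype$lag_days %||% constants$lag_days
  adapt <- genotype$adapt_days %||% constants$adapt_days
  floor_ <- genotype$y_oxdef_lim_photo_floor
  ifelse(wl_spell_age <= lag, 1,
         ifelse(wl_spell_age <= lag + adapt, raw_stress,
                pmax(raw_stress, floor_)))
}

#' Adaptation relief for the phenology response
#'
#' Scaling in \[0, 1\] applied to the phenology stress severity, mirroring the
#' three response stages: 0 during the lag (no developmental stress), 1 during
#' full stress, and `1 - floor` once adapted, so that a fully tolerant
#' genotype carries no residual developmental stress after adaptation.
#'
#' @inheritParams three_stage_response
#' @return Severity scaling in \[0, 1\].
#' @keywords internal
pheno_stress_gate <- function(wl_spell_age, genotype,
                              constants = wl_constants()) {
  lag <- genotype$lag_days %||% constants$lag_days
  adapt <- genotype$adapt_days %||% constants$adapt_days
  floor_ <- genotype$y_oxdef_lim_photo_floor
  ifelse(wl_spell_age <= lag, 0,
         ifelse(wl_spell_age <= lag + adapt, 1, 1 - floor_))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
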