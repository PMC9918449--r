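#' Simulate one barley season
#'
#' Daily loop from sowing to maturity coupling phenology (thermal time with
#' vernalisation/photoperiod modulation and waterlogging-induced
#' delay/truncation), the layered bucket water balance, the fraction-of-roots
#' -waterlogged stress driver, the three-stage waterlogging response, and
#' radiation-use-efficiency growth with CO2 fertilisation. Yield is formed
#' from maturity biomass through a potential harvest index penalised by mean
#' photosynthetic stress over the reproductive window (stages 5 to 7),
#' reflecting the tight coupling of cereal yield with kernel number set
#' around flowering.
#'
#' Phenology stress mechanics: on days with an active waterlogging spell
#' older than the response lag, the daily thermal-time increment is
#' multiplied by `1 + (stage_modifier - 1) * severity` where
#' `severity = (1 - oxdef_pheno_factor(rtfr)) / (1 - pheno floor)`, scaled by
#' the adaptation gate of the three-stage response. The stage modifier is
#' below 1 before flowering (delaying flowering) and above 1 afterwards
#' (truncating grain fill), so the printed anchors (0.65 at stage 4, 1.5 at
#' stage 10) are the multipliers realised at full saturation.
#'
#' @param weather A [weather_series()] covering sowing through at least
#'   ~330 days after sowing.
#' @param soil A [soil_profile()].
#' @param genotype A [genotype()].
#' @param mgmt A [management()].
#' @param sowing_year Calendar year of sowing (defaults to the first year of
#'   the series).
#' @param mode `"waterlogging"` (full stress physiology) or `"default"`
#'   (both stress indices pinned to 1, emulating a model without
#'   waterlogging physics).
#' @param constants Model constants, see [wl_constants()].
#' @param max_days Safety cap on season length, days.
#' @return A `season_result` list: `yield` (kg/ha), `flowering_doy`,
#'   `maturity_doy` (day of year; `NA` if never reached), `flowering_das`,
#'   `maturity_das` (days after sowing), `waterlogged_days` (days with
#'   effective photosynthesis multiplier < 1), `growing_season_rain` (mm),
#'   `complete` (logical), and `daily` (data.frame trajectory: date, stage,
#'   zadoks, cum_tt, rtfr, wl_spell_age, oxdef_photo, oxdef_pheno, biomass,
#'   root_depth, soil_water, drainage, runoff).
#' @examples
#' w <- generate_weather(weather_gen_params(seed = 7), 2, 1990)
#' s <- generate_soil("freely_drained", seed = 1)
#' res <- simulate_season(w, s, genotype_preset("spring_susceptible"),
#'                        management(sowing_doy = 90))
#' res$yield
#' @export
simulate_season <- function(weather, soil, genotype, mgmt,
                            sowing_year = NULL,
                            mode = c("waterlogging", "default"),
                            constants = wl_constants(),
                            max_days = 360) {
  mode <- match.arg(mode)
  stopifnot(inherits(weather, "weather_series"),
            inherits(soil, "soil_profile"),
            inherits(genotype, "genotype"),
            inherits(mgmt, "management"))
  rec <- weather$records
  if (is.null(sowing_year)) sowing_year <- rec$year[1]
  start <- which(rec$year == sowing_year & rec$doy == mgmt$sowing_doy)
  if (length(start) != 1) {
    stop("sowing date ", sowing_year, "-", mgmt$sowing_doy,
         " not found in weather series")
  }
  n_avail <- nrow(rec) - start + 1
  n_days <- min(max_days, n_avail)

  ly <- soil$layers
  n_layers <- nrow(ly)
  cap_ll <- ly$ll * ly$thickness
  cap_dul <- ly$dul * ly$thickness
  # annual reset: profile at lower limit plus the initial plant-available
  # water distributed top-down (water-table layers are pinned at saturation
  # inside the water balance)
  layer_water <- cap_ll
  paw <- mgmt$initial_plant_available_water
  for (i in seq_len(n_layers)) {
    add <- min(paw, cap_dul[i] - cap_ll[i])
    layer_water[i] <- layer_water[i] + add
    paw <- paw - add
    if (paw <= 0) break
  }

  targets <- phase_tt_targets(genotype, mgmt$sowing_depth)
  phase_tt <- numeric(length(targets))
  cardinals <- c(genotype$temp_base, genotype$temp_opt, genotype$temp_max)
  co2_map <- weather$co2_ppm_by_year
  profile_depth <- sum(ly$thickness)
  root_rate <- 15  # mm/day descent while unimpeded
  ctx <- wb_context(soil, constants)
  layer_bottom <- ctx$bottom
  layer_top <- ctx$top
  # photoperiod factor per calendar day (constant within a latitude/genotype)
  pp_by_doy <- photoperiod_factor(weather$latitude, 1:366,
                                  genotype$photop_sens)
  sm_anchors <- constants$stage_mod_anchors
  fco2_by_year <- lapply(co2_map, f_co2, constants = constants)

  stage <- 1
  cum_tt <- 0
  cum_vern <- 0
  root_depth <- 0
  biomass <- 0
  spell_age <- -1  # -1 = no active spell; first saturated day has age 0
  flowering_das <- NA_integer_
  maturity_das <- NA_integer_

  day_idx <- integer(n_days)
  out <- data.frame(
    year = integer(n_days), doy = integer(n_days), stage = numeric(n_days),
    zadoks = numeric(n_days), cum_tt = numeric(n_days),
    rtfr = numeric(n_days), wl_spell_age = integer(n_days),
    oxdef_photo = numeric(n_days), oxdef_pheno = numeric(n_days),
    biomass = numeric(n_days), root_depth = numeric(n_days),
    soil_water = numeric(n_days), drainage = numeric(n_days),
    runoff = numeric(n_days)
  )

  thr <- constants$rtfr_threshold
  lag <- genotype$lag_days
  adapt <- genotype$adapt_days
  floor_photo <- genotype$y_oxdef_lim_photo_floor
  pheno_span <- 1 - constants$oxdef_pheno_floor
  d <- 0
  for (d in seq_len(n_days)) {
    i <- start + d - 1
    radn <- rec$radn[i]; maxt <- rec$maxt[i]; mint <- rec$mint[i]
    rain <- rec$rain[i]
    tmean <- (maxt + mint) / 2

    # water balance (crop + soil evaporative demand scaled by cover)
    cover <- canopy_cover(stage)
    pet <- potential_et(radn, maxt, mint)
    demand <- pet * max(0.3, cover)  # bare-soil evaporation keeps a floor
    wb <- wb_step(ctx, layer_water, rain, demand,
                  et_depth = max(150, root_depth))
    layer_water <- wb$layer_water
    sat <- wb$saturated

    # root front: linear descent, halted while the root zone is waterlogged
    # or the layer at the front is saturated (roots cannot respire into,
    # and so cannot penetrate, saturated soil), bounded by the profile depth
    rtfr <- rtfr_fast(root_depth, sat, layer_top, layer_bottom)
    emerged <- stage >= 3
    if (emerged && root_depth == 0) root_depth <- mgmt$sowing_depth
    if (emerged && rtfr < thr && stage < 9) {
      front_sat <- sat[min(which(root_depth <= layer_bottom + 1e-9),
                           ctx$n)]
      if (!front_sat) {
        root_depth <- min(profile_depth, root_depth + root_rate)
        rtfr <- rtfr_fast(root_depth, sat, layer_top, layer_bottom)
      }
    }

    # waterlogging spell bookkeeping (first saturated day = age 0)
    spell_age <- if (rtfr >= thr) {
      if (spell_age < 0) 0 else spell_age + 1
    } else {
      -1
    }

    if (mode == "default" || spell_age < 0) {
      eff_photo <- 1
      tt_mult <- 1
    } else {
      # three-stage response: lag, full stress, adapted floor; the same
      # gating scales the developmental severity
      stress_frac <- (rtfr - thr) / (1 - thr)       # 0..1 beyond threshold
      raw <- 1 - stress_frac                        # oxdef_photo
      if (spell_age <= lag) {
        eff_photo <- 1
        gate <- 0
      } else if (spell_age <= lag + adapt) {
        eff_photo <- raw
        gate <- 1
      } else {
        eff_photo <- max(raw, floor_photo)
        gate <- 1 - floor_photo
      }
      sev <- stress_frac * gate                     # (1 - oxdef_pheno)/span
      tt_mult <- 1 + (lin_interp(sm_anchors$x, sm_anchors$y, stage) - 1) *
        sev
    }

    # thermal time, modulated pre-florally by vernalisation/photoperiod
    dtt <- thermal_time_scalar(tmean, cardinals)
    if (stage >= 3 && stage < 5) {
      cum_vern <- cum_vern + vernalisation_units(maxt, mint)
      fv <- vernalisation_factor(cum_vern, genotype$vern_sens)
      dtt <- dtt * min(fv, pp_by_doy[rec$doy[i]])
    }
    dtt <- dtt * tt_mult
    cum_tt <- cum_tt + dtt

    # advance phases
    phase <- max(1, min(length(targets), floor(stage)))
    left <- dtt
    while (left > 0 && phase <= length(targets)) {
      room <- targets[phase] - phase_tt[phase]
      used <- min(left, room)
      phase_tt[phase] <- phase_tt[phase] + used
      left <- left - used
      # epsilon guards against an asymptotic floating-point stall where
      # phase_tt + (target - phase_tt) lands a ULP short of the target
      if (phase_tt[phase] >= targets[phase] - 1e-9) {
        phase_tt[phase] <- targets[phase]
        phase <- phase + 1
      } else {
        break
      }
    }
    new_stage <- stage_from_tt(phase_tt, targets)
    if (is.na(flowering_das) && new_stage >= 6) flowering_das <- d
    if (is.na(maturity_das) && new_stage >= 9) maturity_das <- d
    stage <- new_stage

    # growth up to maturity
    if (stage < 9) {
      biomass <- biomass + radn * canopy_cover(stage) * genotype$rue *
        fco2_by_year[[as.character(rec$year[i])]] * eff_photo
    }

    out$year[d] <- rec$year[i]; out$doy[d] <- rec$doy[i]
    out$stage[d] <- stage
    out$cum_tt[d] <- cum_tt; out$rtfr[d] <- rtfr
    out$wl_spell_age[d] <- max(0L, spell_age)
    out$oxdef_photo[d] <- eff_photo; out$oxdef_pheno[d] <- tt_mult
    out$biomass[d] <- biomass; out$root_depth[d] <- root_depth
    out$soil_water[d] <- sum(layer_water)
    out$drainage[d] <- wb$drainage; out$runoff[d] <- wb$runoff
    day_idx[d] <- i

    if (!is.na(maturity_das)) break
  }

  complete <- !is.na(maturity_das)
  out <- out[seq_len(d), , drop = FALSE]
  out$zadoks <- stage_to_zadoks(out$stage)

  # yield: harvest index penalised by mean reproductive-window stress
  repro <- out$stage >= 5 & out$stage <= 7
  repro_stress <- if (any(repro)) mean(out$oxdef_photo[repro]) else 1
  yield_kg_ha <- if (complete) {
    biomass * genotype$harvest_index_potential * repro_stress * 10
  } else {
    0
  }

  gs_days <- seq_len(if (complete) maturity_das else d)
  structure(list(
    yield = yield_kg_ha,
    flowering_das = flowering_das,
    maturity_das = maturity_das,
    flowering_doy = if (!is.na(flowering_das)) out$doy[flowering_das] else NA_integer_,
    maturity_doy = if (complete) out$doy[maturity_das] else NA_integer_,
    waterlogged_days = sum(out$oxdef_photo < 1),
    growing_season_rain = sum(rec$rain[day_idx[gs_days]]),
    complete = complete,
    mode = mode,
    genotype = genotype$name,
    maturity_class = genotype$maturity_class,
    sowing = c(year = sowing_year, doy = mgmt$sowing_doy),
    scenario = weather$scenario_tag,
    daily = out
  ), class = "season_result")
}

# scalar fast paths for the daily loop -------------------------------------

# linear interpolation with flat extrapolation (scalar x)
lin_interp <- function(xs, ys, x) {
  if (x <= xs[1]) return(ys[1])
  n <- length(xs)
  if (x >= xs[n]) return(ys[n])
  j <- findInterval(x, xs)
  ys[j] + (ys[j + 1] - ys[j]) * (x - xs[j]) / (xs[j + 1] - xs[j])
}

thermal_time_scalar <- function(tmean, cardinals) {
  b <- cardinals[1]; o <- cardinals[2]; m <- cardinals[3]
  if (tmean <= b || tmean >= m) return(0)
  if (tmean <= o) (o - b) * (tmean - b) / (o - b) else (o - b) * (m - tmean) / (m - o)
}

rtfr_fast <- function(root_depth, saturated, layer_top, layer_bottom) {
  if (root_depth <= 0) return(0)
  if (!any(saturated)) return(0)
  in_root <- pmax(0, pmin(layer_bottom, root_depth) - layer_top)
  sum(in_root[saturated]) / root_depth
}

#' @export
print.season_result <- function(x, ...) {
  cat("<season_result> ", x$genotype, ", sown ", x$sowing["year"], "-",
      x$sowing["doy"], " (", x$scenario, ", ", x$mode, " mode)\n", sep = "")
  if (x$complete) {
    cat("  yield ", round(x$yield), " kg/ha; flowering ", x$flowering_das,
        " das, maturity ", x$maturity_das, " das; ", x$waterlogged_days,
        " waterlogged day(s)\n", sep = "")
  } else {
    cat("  incomplete season (maturity not reached in the weather slice)\n")
  }
  invisible(x)
}
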