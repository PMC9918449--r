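#' One day of the layered bucket water balance
#'
#' Cascading-bucket substitute for a Richards-equation solver: rain is added
#' to the top layer; water above each layer's drained upper limit drains to
#' the layer below at a rate limited by the layer's saturated conductivity
#' and by the room available below (so a slowly conducting subsoil backs
#' water up and perches saturation above it); water above saturation is
#' pushed back up and leaves the top of the profile as runoff; evaporative
#' demand is extracted top-down from plant-available water. Layers at or
#' below the water table are held at saturation and take no part in storage
#' change: drainage reaching them passes through and leaves the profile.
#'
#' Mass balance closes exactly:
#' `rain = change in storage + drainage + runoff + actual_et`.
#'
#' @param profile A [soil_profile()].
#' @param layer_water Current water content per layer, mm (within
#'   \[0, SAT * thickness\]).
#' @param rain Rainfall, mm (>= 0).
#' @param potential_et Evaporative demand, mm (>= 0).
#' @param et_depth Depth (mm) over which demand can be extracted (e.g. root
#'   depth plus a surface-evaporation layer).
#' @param constants Model constants (saturation flag fraction).
#' @return List with `layer_water` (updated, mm), `drainage`, `runoff`,
#'   `actual_et` (mm), and logical `saturated` flags per layer.
#' @examples
#' sp <- generate_soil("duplex_waterlogging_prone", seed = 2)
#' w0 <- with(sp$layers, dul * thickness)
#' water_balance_step(sp, w0, rain = 40, potential_et = 2)
#' @export
water_balance_step <- function(profile, layer_water, rain, potential_et,
                               et_depth = NULL, constants = wl_constants()) {
  if (rain < 0 || potential_et < 0) stop("rain and ET must be >= 0")
  stopifnot(length(layer_water) == nrow(profile$layers))
  ctx <- wb_context(profile, constants)
  wb_step(ctx, layer_water, rain, potential_et, et_depth)
}

# Precomputed per-profile quantities for the daily step (built once per
# season rather than once per day).
wb_context <- function(profile, constants = wl_constants()) {
  ly <- profile$layers
  bottom <- cumsum(ly$thickness)
  cap_sat <- ly$sat * ly$thickness
  cap_dul <- ly$dul * ly$thickness
  list(
    n = nrow(ly),
    thickness = ly$thickness,
    k_sat = ly$k_sat,
    cap_sat = cap_sat, cap_dul = cap_dul, cap_ll = ly$ll * ly$thickness,
    bottom = bottom, top = bottom - ly$thickness,
    pinned = pinned_layers(profile),
    sat_thr = cap_dul + constants$saturation_fraction * (cap_sat - cap_dul),
    fringe_thr = cap_dul +
      constants$capillary_fringe_fraction * (cap_sat - cap_dul)
  )
}

wb_step <- function(ctx, layer_water, rain, potential_et, et_depth = NULL) {
  n <- ctx$n
  cap_sat <- ctx$cap_sat
  cap_dul <- ctx$cap_dul
  cap_ll <- ctx$cap_ll
  bottom <- ctx$bottom
  top <- ctx$top
  pinned <- ctx$pinned
  ly <- list(k_sat = ctx$k_sat, thickness = ctx$thickness)

  w <- layer_water
  w[pinned] <- cap_sat[pinned]
  w0 <- w
  drainage <- 0
  runoff <- 0

  # infiltration into the top layer (sheds as runoff if the water table
  # reaches the surface)
  if (!pinned[1]) {
    w[1] <- w[1] + rain
  } else {
    runoff <- runoff + rain
  }

  # downward saturated flow: DUL-excess moves down, limited by k_sat and by
  # room (to SAT) in the receiving layer; the water table accepts nothing,
  # so percolate perches above pinned layers; only the profile bottom drains
  for (i in seq_len(n)) {
    if (pinned[i]) next
    excess <- max(0, w[i] - cap_dul[i])
    flux <- min(excess, ly$k_sat[i])
    if (i < n) {
      room <- if (pinned[i + 1]) 0 else max(0, cap_sat[i + 1] - w[i + 1])
      flux <- min(flux, room)
      w[i] <- w[i] - flux
      w[i + 1] <- w[i + 1] + flux
    } else {
      w[i] <- w[i] - flux
      drainage <- drainage + flux
    }
  }

  # back-up: water above saturation rises; excess at the surface runs off
  for (i in rev(seq_len(n))) {
    if (pinned[i]) next
    over <- max(0, w[i] - cap_sat[i])
    if (over > 0) {
      w[i] <- cap_sat[i]
      j <- i - 1
      while (over > 0 && j >= 1) {
        if (!pinned[j]) {
          take <- min(over, cap_sat[j] - w[j])
          w[j] <- w[j] + take
          over <- over - take
        }
        j <- j - 1
      }
      runoff <- runoff + over
    }
  }

  # evaporative extraction, top-down, limited by plant-available water;
  # saturated layers below the surface are skipped (roots cannot extract
  # water under anoxia - uptake failure under waterlogging is part of the
  # stress being modelled), but the top layer always evaporates: a wet or
  # ponded surface keeps losing water to the atmosphere
  sat_thr <- ctx$sat_thr
  sat_now <- pinned | (w >= sat_thr - 1e-9)
  actual_et <- 0
  demand <- potential_et
  max_depth <- if (is.null(et_depth)) bottom[n] else et_depth
  for (i in seq_len(n)) {
    if (demand <= 0 || top[i] >= max_depth) break
    if (pinned[i] || (i > 1 && sat_now[i])) next
    avail <- max(0, w[i] - cap_ll[i])
    frac <- min(1, max(0, (max_depth - top[i]) / ly$thickness[i]))
    take <- min(demand, avail * frac)
    w[i] <- w[i] - take
    actual_et <- actual_et + take
    demand <- demand - take
  }

  saturated <- pinned | (w >= sat_thr - 1e-9)
  # capillary fringe: a layer resting on a saturated layer is itself held
  # near saturation by capillarity; flag it anoxic while it remains in the
  # upper part of the DUL-SAT range (keeps a perched table from flickering
  # in and out of the flag on single dry days)
  if (any(saturated) && ctx$fringe_thr[1] > 0) {
    for (i in rev(seq_len(n - 1))) {
      if (saturated[i + 1] && !saturated[i] && w[i] >= ctx$fringe_thr[i]) {
        saturated[i] <- TRUE
      }
    }
  }

  list(layer_water = w, drainage = drainage, runoff = runoff,
       actual_et = actual_et, saturated = saturated,
       storage_change = sum(w - w0))
}

# Index of the layer containing a given depth (mm below surface).
layer_at_depth <- function(profile, depth) {
  bottom <- cumsum(profile$layers$thickness)
  min(which(depth <= bottom + 1e-9), nrow(profile$layers))
}

# Layers whose bottom lies below the water table depth are permanently
# saturated (a layer straddling the table counts once its bottom passes it).
pinned_layers <- function(profile) {
  if (is.na(profile$water_table_depth)) {
    return(rep(FALSE, nrow(profile$layers)))
  }
  cumsum(profile$layers$thickness) > profile$water_table_depth + 1e-9
}

#' Fraction of roots waterlogged
#'
#' Proportion of the root zone lying within saturated soil layers, with
#' partial-layer proration at both the saturated-layer and root-front
#' boundaries. Pre-emergence (`root_depth = 0`) is defined as 0.
#'
#' @param root_depth Root front depth, mm below the surface.
#' @param saturated Logical saturation flag per layer (from
#'   [water_balance_step()]).
#' @param profile A [soil_profile()].
#' @return `rtfr` in \[0, 1\].
#' @examples
#' sp <- generate_soil("freely_drained", seed = 1)
#' fraction_roots_waterlogged(600, rep(TRUE, nrow(sp$layers)), sp)
#' @export
fraction_roots_waterlogged <- function(root_depth, saturated, profile) {
  if (root_depth < 0) stop("root_depth must be >= 0")
  if (root_depth == 0) return(0)
  ly <- profile$layers
  bottom <- cumsum(ly$thickness)
  top <- bottom - ly$thickness
  in_root <- pmax(0, pmin(bottom, root_depth) - top)
  sum(in_root[saturated]) / root_depth
}

#' Priestley-Taylor-style potential evapotranspiration
#'
#' Radiation-driven daily potential ET (mm) from solar radiation and mean
#' temperature: net radiation approximated as a fixed fraction of incoming
#' shortwave, the slope of the saturation vapour pressure curve from the
#' Tetens equation, and the Priestley-Taylor coefficient 1.26.
#'
#' @param radn Solar radiation, MJ/m2/day.
#' @param maxt,mint Daily temperature extremes, deg C.
#' @return Potential ET, mm/day (>= 0).
#' @export
potential_et <- function(radn, maxt, mint) {
  tmean <- (maxt + mint) / 2
  es <- 0.6108 * exp(17.27 * tmean / (tmean + 237.3))       # kPa
  delta <- 4098 * es / (tmean + 237.3)^2                    # kPa/degC
  gamma <- 0.066                                            # kPa/degC
  rn <- 0.75 * radn                                         # MJ/m2/day
  pmax(0, 1.26 * delta / (delta + gamma) * rn / 2.45)
}
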