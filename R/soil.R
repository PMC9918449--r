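#' Layered soil profile
#'
#' A soil profile as an ordered set of layers with volumetric water limits
#' (lower limit LL, drained upper limit DUL, saturation SAT, all mm/mm) and
#' saturated hydraulic conductivity (mm/day), plus an optional static water
#' table depth (mm below the surface). Layers at or below the water table are
#' held permanently saturated.
#'
#' @param layers A data.frame with columns `thickness` (mm), `ll`, `dul`,
#'   `sat` (mm/mm), `k_sat` (mm/day).
#' @param water_table_depth Water table depth in mm below the surface, or
#'   `NA` for none.
#' @param runoff_curve Dimensionless runoff parameter (retained for
#'   configuration compatibility; the bucket model only generates runoff when
#'   the whole profile is saturated).
#' @param archetype Optional archetype tag (metadata).
#' @return A list with class `soil_profile`.
#' @examples
#' generate_soil("duplex_waterlogging_prone", seed = 1)
#' @export
soil_profile <- function(layers, water_table_depth = NA_real_,
                         runoff_curve = 73, archetype = NA_character_) {
  stopifnot(is.data.frame(layers),
            all(c("thickness", "ll", "dul", "sat", "k_sat") %in% names(layers)))
  with(layers, stopifnot(
    all(thickness > 0), all(k_sat >= 0),
    all(ll > 0), all(ll < dul), all(dul < sat), all(sat < 1)
  ))
  structure(list(
    layers = layers,
    water_table_depth = water_table_depth,
    runoff_curve = runoff_curve,
    archetype = archetype
  ), class = "soil_profile")
}

#' @export
print.soil_profile <- function(x, ...) {
  cat("<soil_profile>", if (!is.na(x$archetype)) x$archetype else "", "\n")
  cat("  ", nrow(x$layers), " layers, total depth ",
      sum(x$layers$thickness), " mm", sep = "")
  if (!is.na(x$water_table_depth)) {
    cat(", water table at ", x$water_table_depth, " mm", sep = "")
  }
  cat("\n")
  print(x$layers, row.names = FALSE)
  invisible(x)
}

soil_archetypes <- c("freely_drained", "duplex_waterlogging_prone",
                     "shallow_water_table")

#' Generate a synthetic soil profile
#'
#' Seeded generator of 4-8 layer profiles (total depth 1.0-1.8 m) for three
#' archetypes: `freely_drained` (conductive subsoil, no water table),
#' `duplex_waterlogging_prone` (texture-contrast profile with a nearly
#' slowly permeable clay subsoil under a permeable topsoil, so that rain
#' perches above the clay), and `shallow_water_table` (water table within the
#' profile). Per-layer limits always satisfy LL < DUL < SAT.
#'
#' @param archetype One of `"freely_drained"`, `"duplex_waterlogging_prone"`,
#'   `"shallow_water_table"`.
#' @param seed Integer seed; the same seed returns an identical profile.
#' @return A [soil_profile()].
#' @export
generate_soil <- function(archetype, seed = 1L) {
  if (!archetype %in% soil_archetypes) {
    stop("unknown soil archetype '", archetype, "'; available: ",
         paste(soil_archetypes, collapse = ", "))
  }
  with_seed(seed, {
    n_layers <- sample(5:7, 1)
    total_depth <- stats::runif(1, 1200, 1600)
    # thicker layers at depth
    w <- seq(0.6, 1.6, length.out = n_layers)
    thickness <- round(total_depth * w / sum(w), 0)
    # textural trend: loam topsoil to clay-ish subsoil
    frac <- seq(0, 1, length.out = n_layers)
    ll <- round(0.10 + 0.08 * frac + stats::runif(n_layers, -0.01, 0.01), 3)
    dul <- round(ll + 0.12 + 0.04 * frac + stats::runif(n_layers, -0.01, 0.01), 3)
    sat <- round(dul + 0.10 - 0.03 * frac + stats::runif(n_layers, -0.005, 0.005), 3)
    k_sat <- switch(archetype,
      freely_drained = round(exp(stats::runif(n_layers, log(80), log(250))), 1),
      duplex_waterlogging_prone = {
        k <- round(exp(stats::runif(n_layers, log(60), log(150))), 1)
        clay_from <- ceiling(n_layers / 2)
        # slowly permeable clay B horizon (a fraction of a mm to ~1.5 mm/day):
        # perched saturation builds over wet winter spells and drains again
        # once rainfall eases, so waterlogging is seasonal, not permanent
        k[clay_from:n_layers] <-
          round(stats::runif(n_layers - clay_from + 1, 0.2, 1.5), 2)
        k
      },
      shallow_water_table = round(exp(stats::runif(n_layers, log(20), log(120))), 1)
    )
    wt <- if (archetype == "shallow_water_table") {
      round(stats::runif(1, 0.35, 0.6) * sum(thickness))
    } else {
      NA_real_
    }
    soil_profile(
      data.frame(thickness = thickness, ll = ll, dul = dul, sat = sat,
                 k_sat = k_sat),
      water_table_depth = wt,
      archetype = archetype
    )
  })
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}
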