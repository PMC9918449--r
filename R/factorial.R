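#' Factorial simulation design
#'
#' Specification of a genotype x environment x management x climate factorial:
#' sites (soil archetype, weather-generator parameters, latitude and
#' early/late sowing dates), genotypes, climate scenarios (tag, monthly
#' deltas, CO2 source) and the number of stochastic weather realisations per
#' scenario (the desk-scale stand-in for an ensemble of climate projections;
#' default 27). Realisation seeds are derived deterministically from the
#' master seed.
#'
#' @param sites Named list; each site a list with `soil_archetype`,
#'   `weather_params` ([weather_gen_params()]), `latitude`, `sowing_doys`
#'   (named vector `c(ES = ..., LS = ...)`).
#' @param genotypes List of [genotype()] objects.
#' @param scenarios Named list; each a list with `deltas`
#'   ([climate_deltas()]) and optional `co2_source` (defaults to keeping the
#'   baseline CO2 map). Include an identity-delta entry for the baseline.
#' @param n_realisations Weather realisations per cell.
#' @param n_years Simulated seasons per realisation.
#' @param start_year First sowing year.
#' @param master_seed Master integer seed.
#' @return A list with class `factorial_design`.
#' @export
factorial_design <- function(sites, genotypes, scenarios,
                             n_realisations = 27, n_years = 10,
                             start_year = 1985, master_seed = 1L) {
  stopifnot(length(sites) >= 1, length(genotypes) >= 1,
            length(scenarios) >= 1, n_realisations >= 1, n_years >= 1)
  if (is.null(names(sites)) || is.null(names(scenarios))) {
    stop("sites and scenarios must be named lists")
  }
  for (s in sites) {
    stopifnot(inherits(s$weather_params, "weather_gen_params"),
              s$soil_archetype %in% soil_archetypes,
              all(c("ES", "LS") %in% names(s$sowing_doys)))
  }
  for (g in genotypes) stopifnot(inherits(g, "genotype"))
  for (sc in scenarios) stopifnot(inherits(sc$deltas, "climate_deltas"))
  structure(list(
    sites = sites, genotypes = genotypes, scenarios = scenarios,
    n_realisations = n_realisations, n_years = n_years,
    start_year = start_year, master_seed = as.integer(master_seed)
  ), class = "factorial_design")
}

# Deterministic per-(site, realisation) seed derived from the master seed;
# kept well below 2^31.
derive_seed <- function(master_seed, site_idx, realisation) {
  (as.integer(master_seed) * 7919L + site_idx * 653L + realisation * 31L) %%
    2000000011L
}

#' Run a factorial waterlogging simulation
#'
#' Simulates every (site, genotype, sowing window, scenario, realisation,
#' year) cell twice under identical weather - once with the waterlogging
#' physics enabled and once with both stress indices pinned to 1 - yielding
#' paired `yield_wl` / `yield_default` per season for the yield-penalty
#' metric. Optionally each cell is also run on the freely drained soil
#' archetype as the simulation analogue of a drained control treatment
#' (`yield_ck`, for the yield-loss metric). Fully reproducible from the
#' master seed.
#'
#' @param design A [factorial_design()].
#' @param include_control Also simulate the drained-control run
#'   (`yield_ck`)? Default `TRUE`.
#' @param constants Model constants.
#' @param progress Print one line per site/scenario/realisation block?
#' @return A `results_table` data.frame, one row per season: site, genotype,
#'   maturity_class, sowing_window, scenario, realisation, sowing_year,
#'   yield_default, yield_wl, yield_ck, waterlogged_days,
#'   growing_season_rain, flowering_das, maturity_das, complete, plus the
#'   six phase-mean stress values (`stress_JV1` .. `stress_GF2`).
#' @export
run_factorial <- function(design, include_control = TRUE,
                          constants = wl_constants(), progress = FALSE) {
  stopifnot(inherits(design, "factorial_design"))
  bins <- phase_bins()
  rows <- list()
  for (si in seq_along(design$sites)) {
    site_name <- names(design$sites)[si]
    site <- design$sites[[si]]
    soil <- generate_soil(site$soil_archetype,
                          seed = derive_seed(design$master_seed, si, 0L))
    ctrl_soil <- if (include_control) {
      generate_soil("freely_drained",
                    seed = derive_seed(design$master_seed, si, 0L))
    }
    for (ri in seq_len(design$n_realisations)) {
      wseed <- derive_seed(design$master_seed, si, ri)
      wp <- site$weather_params
      wp$seed <- wseed
      # one extra year so late-sown seasons can run past the final new year
      baseline <- generate_weather(wp, design$n_years + 1,
                                   design$start_year,
                                   site_id = site_name,
                                   latitude = site$latitude)
      for (sci in seq_along(design$scenarios)) {
        sc_name <- names(design$scenarios)[sci]
        sc <- design$scenarios[[sci]]
        co2_src <- sc$co2_source
        if (!is.null(sc$co2_horizon)) {
          # delta-perturbed scenarios reuse baseline weather years; carry
          # the horizon-mean CO2 on every simulated year
          yrs <- unique(baseline$records$year)
          co2_src <- stats::setNames(rep(sc$co2_horizon, length(yrs)),
                                     as.character(yrs))
        }
        wx <- apply_climate_deltas(baseline, sc$deltas, sc_name,
                                   co2_source = co2_src)
        if (progress) {
          message(site_name, " / ", sc_name, " / realisation ", ri)
        }
        for (g in design$genotypes) {
          for (sw in c("ES", "LS")) {
            mgmt <- management(site$sowing_doys[[sw]], sw)
            for (yr in seq_len(design$n_years)) {
              sow_year <- design$start_year + yr - 1
              wl <- simulate_season(wx, soil, g, mgmt, sow_year,
                                    mode = "waterlogging",
                                    constants = constants)
              dflt <- simulate_season(wx, soil, g, mgmt, sow_year,
                                      mode = "default",
                                      constants = constants)
              ck <- if (include_control) {
                simulate_season(wx, ctrl_soil, g, mgmt, sow_year,
                                mode = "waterlogging",
                                constants = constants)
              }
              psv <- phase_stress_vector(wl, bins)
              rows[[length(rows) + 1L]] <- data.frame(
                site = site_name, genotype = g$name,
                maturity_class = g$maturity_class, sowing_window = sw,
                scenario = sc_name, realisation = ri,
                sowing_year = sow_year,
                yield_default = dflt$yield, yield_wl = wl$yield,
                yield_ck = if (include_control) ck$yield else NA_real_,
                waterlogged_days = wl$waterlogged_days,
                growing_season_rain = dflt$growing_season_rain,
                flowering_das = wl$flowering_das,
                maturity_das = wl$maturity_das,
                complete = wl$complete & dflt$complete,
                t(psv$stress) |> as.data.frame() |>
                  stats::setNames(paste0("stress_", bins$bin))
              )
            }
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("results_table", "data.frame")
  out
}

#' Fit and label typologies per maturity class from a results table
#'
#' Pools the waterlogging-mode stress vectors of a [run_factorial()] results
#' table and fits one typology per maturity class (spring -> SW labels,
#' winter -> WW labels), attaching a `pattern` column to the table.
#'
#' @param results A `results_table`.
#' @param k Clusters per typology.
#' @param seed Seed for the k-means restarts.
#' @return List with `results` (the table with a `pattern` column) and
#'   `typologies` (named list per maturity class).
#' @export
classify_results <- function(results, k = 4, seed = 1L) {
  stress_cols <- paste0("stress_", phase_bins()$bin)
  results$pattern <- NA_character_
  typologies <- list()
  for (mc in unique(results$maturity_class)) {
    ix <- which(results$maturity_class == mc)
    x <- as.matrix(results[ix, stress_cols])
    ty <- fit_typology(x, k = k, seed = seed)
    ty <- label_clusters(ty, mc)
    typologies[[mc]] <- ty
    results$pattern[ix] <- typology_assignments(ty)
  }
  list(results = results, typologies = typologies)
}

#' ANOVA + LSD test of pattern-frequency shifts across climate periods
#'
#' For each stress pattern, tests whether its recurrence frequency differs
#' between climate periods by one-way analysis of variance with realisations
#' as replicates, followed by least-significant-difference (LSD) pairwise
#' comparisons at `alpha`, summarised as grouping letters assigned by the
#' standard descending-mean procedure (periods sharing a letter do not
#' differ).
#'
#' @param freqs data.frame with columns `period`, `realisation`, `pattern`,
#'   `pct` (one frequency per realisation per period per pattern), e.g.
#'   built with [realisation_frequencies()].
#' @param alpha Significance level for the LSD comparisons.
#' @return data.frame, one row per (pattern, period): mean frequency, and
#'   per pattern the ANOVA `F`, `p`, and LSD `letter` (`NA` with
#'   `skipped = TRUE` when all groups have zero variance).
#' @export
frequency_shift_test <- function(freqs, alpha = 0.05) {
  stopifnot(all(c("period", "realisation", "pattern", "pct") %in%
                  names(freqs)))
  if (length(unique(freqs$period)) < 2) stop("need >= 2 periods")
  out <- list()
  for (p in unique(freqs$pattern)) {
    d <- freqs[freqs$pattern == p, ]
    d$period <- factor(d$period)
    if (any(table(d$period) < 2)) stop("need >= 2 realisations per period")
    means <- tapply(d$pct, d$period, mean)
    if (stats::var(d$pct) < 1e-12) {
      out[[p]] <- data.frame(pattern = p, period = names(means),
                             mean_pct = as.numeric(means),
                             F = NA_real_, p_value = NA_real_,
                             letter = NA_character_, skipped = TRUE)
      next
    }
    fit <- stats::aov(pct ~ period, data = d)
    an <- summary(fit)[[1]]
    letters <- lsd_letters(d$pct, d$period, alpha = alpha)
    out[[p]] <- data.frame(pattern = p, period = names(means),
                           mean_pct = as.numeric(means),
                           F = an$`F value`[1], p_value = an$`Pr(>F)`[1],
                           letter = letters[names(means)], skipped = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# LSD grouping letters: pooled-MSE pairwise t tests; letters assigned by the
# usual descending-mean insertion procedure.
lsd_letters <- function(y, group, alpha = 0.05) {
  group <- factor(group)
  means <- sort(tapply(y, group, mean), decreasing = TRUE)
  ns <- tapply(y, group, length)[names(means)]
  fit <- stats::aov(y ~ group)
  mse <- summary(fit)[[1]]$`Mean Sq`[2]
  dfe <- fit$df.residual
  tcrit <- stats::qt(1 - alpha / 2, dfe)
  differ <- function(a, b) {
    lsd <- tcrit * sqrt(mse * (1 / ns[a] + 1 / ns[b]))
    abs(means[a] - means[b]) > lsd
  }
  k <- length(means)
  # membership matrix: rows = groups (desc mean), cols = letters
  cols <- list()
  for (i in seq_len(k)) {
    placed <- FALSE
    for (ci in seq_along(cols)) {
      if (all(!vapply(cols[[ci]], function(j) differ(i, j), logical(1)))) {
        cols[[ci]] <- c(cols[[ci]], i)
        placed <- TRUE
      }
    }
    if (!placed) {
      # new letter containing this group and every earlier group it does
      # not differ from
      members <- i
      for (j in rev(seq_len(i - 1))) {
        if (!differ(i, j)) members <- c(j, members)
      }
      cols[[length(cols) + 1]] <- members
    }
  }
  lab <- vapply(seq_len(k), function(i) {
    paste(letters[which(vapply(cols, function(m) i %in% m, logical(1)))],
          collapse = "")
  }, character(1))
  stats::setNames(lab, names(means))
}

#' Per-realisation pattern frequencies
#'
#' Frequencies (% of seasons) of each stress pattern within every
#' (period, realisation) block of a classified results table, the input
#' expected by [frequency_shift_test()].
#'
#' @param results Classified results (with a `pattern` column).
#' @param period_col Column defining the climate period (default
#'   `"scenario"`).
#' @return data.frame with columns `period`, `realisation`, `pattern`, `pct`.
#' @export
realisation_frequencies <- function(results, period_col = "scenario") {
  keep <- !is.na(results$pattern)
  r <- results[keep, ]
  patterns <- sort(unique(r$pattern))
  blocks <- split(r, list(r[[period_col]], r$realisation), drop = TRUE)
  out <- do.call(rbind, lapply(blocks, function(b) {
    data.frame(period = b[[period_col]][1], realisation = b$realisation[1],
               pattern = patterns,
               pct = 100 * vapply(patterns,
                                  function(p) mean(b$pattern == p),
                                  numeric(1)))
  }))
  rownames(out) <- NULL
  out
}

#' Yield benefit of waterlogging tolerance in wet years
#'
#' Pairs a tolerant and a susceptible genotype differing only in their
#' waterlogging tolerance parameters and computes, per site, the mean (and
#' SEM) yield benefit (tolerant minus susceptible, kg/ha and %) over
#' season-years whose growing-season rainfall exceeds the given percentile
#' within each (site, sowing, scenario) cell. Also reports the benefit over
#' all years and over the complementary dry years (to verify tolerance
#' carries no dry-year cost).
#'
#' @param results A `results_table`.
#' @param tolerant,susceptible Genotype names forming the pair.
#' @param rainfall_percentile Wet-year threshold percentile (default 90).
#' @return data.frame per (site, subset in wet/dry/all): `n`,
#'   `mean_benefit_kg_ha`, `sem_benefit_kg_ha`, `mean_benefit_pct`.
#' @export
tolerance_benefit <- function(results, tolerant, susceptible,
                              rainfall_percentile = 90) {
  tol <- results[results$genotype == tolerant, ]
  sus <- results[results$genotype == susceptible, ]
  if (!nrow(tol) || !nrow(sus)) {
    stop("tolerant/susceptible pair not found in results")
  }
  key <- function(d) {
    interaction(d$site, d$sowing_window, d$scenario, d$realisation,
                d$sowing_year, drop = FALSE)
  }
  m <- match(key(sus), key(tol))
  if (anyNA(m)) stop("tolerant and susceptible rows do not pair one-to-one")
  paired <- data.frame(
    site = sus$site, sowing_window = sus$sowing_window,
    scenario = sus$scenario, realisation = sus$realisation,
    sowing_year = sus$sowing_year,
    rain = sus$growing_season_rain,
    benefit = tol$yield_wl[m] - sus$yield_wl,
    benefit_pct = ifelse(sus$yield_wl > 0,
                         100 * (tol$yield_wl[m] - sus$yield_wl) /
                           sus$yield_wl, NA_real_)
  )
  cell <- interaction(paired$site, paired$sowing_window, paired$scenario,
                      drop = TRUE)
  thr <- stats::ave(paired$rain, cell, FUN = function(r) {
    stats::quantile(r, rainfall_percentile / 100, names = FALSE)
  })
  paired$wet <- paired$rain > thr
  if (!any(paired$wet)) {
    warning("empty wet-year selection at percentile ", rainfall_percentile)
  }
  summarise <- function(d, subset_name) {
    if (!nrow(d)) {
      return(data.frame(site = character(), subset = character(),
                        n = integer(), mean_benefit_kg_ha = numeric(),
                        sem_benefit_kg_ha = numeric(),
                        mean_benefit_pct = numeric()))
    }
    do.call(rbind, lapply(split(d, d$site), function(s) {
      data.frame(site = s$site[1], subset = subset_name, n = nrow(s),
                 mean_benefit_kg_ha = mean(s$benefit),
                 sem_benefit_kg_ha = stats::sd(s$benefit) /
                   sqrt(nrow(s)),
                 mean_benefit_pct = mean(s$benefit_pct, na.rm = TRUE))
    }))
  }
  out <- rbind(summarise(paired[paired$wet, ], "wet"),
               summarise(paired[!paired$wet, ], "dry"),
               summarise(paired, "all"))
  rownames(out) <- NULL
  out
}
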