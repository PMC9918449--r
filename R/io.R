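#' Read a daily weather file
#'
#' Reads the package's columnar weather format: comment/header lines
#' starting with `!` or `#` carrying `site_id = ...`, `latitude = ...`,
#' `scenario_tag = ...`, an optional units line, then whitespace- or
#' comma-delimited columns `year day radn maxt mint rain`. Both delimiters
#' parse to identical series. Validation failures (maxt < mint, negative
#' rain, non-numeric or NaN fields, gaps in the (year, doy) sequence) are
#' reported with the offending line or gap.
#'
#' @param path File path.
#' @param co2_source CO2 map builder: the function [co2_for_year()]
#'   (default) or a named year -> ppm table.
#' @return A [weather_series()].
#' @export
read_weather <- function(path, co2_source = co2_for_year) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  meta <- list(site_id = "unknown", latitude = NA_real_,
               scenario_tag = "baseline")
  is_meta <- grepl("^\\s*[!#]", lines)
  for (l in lines[is_meta]) {
    m <- regmatches(l, regexec(
      "(site_id|latitude|scenario_tag)\\s*=\\s*([^ !#]+)", l))[[1]]
    if (length(m) == 3) {
      meta[[m[2]]] <- if (m[2] == "latitude") as.numeric(m[3]) else m[3]
    }
  }
  body <- lines[!is_meta & nzchar(trimws(lines))]
  body_no <- which(!is_meta & nzchar(trimws(lines)))
  # skip a column-name header and a units line if present
  drop <- grepl("^\\s*(year)\\b", body, ignore.case = TRUE) |
    grepl("\\(|mm|MJ", body) & !grepl("^\\s*[0-9]", body)
  body_no <- body_no[!drop]; body <- body[!drop]
  if (!length(body)) stop("no data rows in ", path)
  fields <- strsplit(trimws(gsub(",", " ", body)), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 6)) {
    stop("malformed row (expected 6 fields) at line ",
         body_no[which(nf != 6)[1]], " of ", path)
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 6, byrow = TRUE)
  bad <- which(apply(m, 1, function(r) anyNA(r) | any(is.nan(r))))
  if (length(bad)) {
    stop("non-numeric or NaN field at line ", body_no[bad[1]], " of ", path)
  }
  records <- stats::setNames(as.data.frame(m),
                             c("year", "doy", "radn", "maxt", "mint", "rain"))
  bad_t <- which(records$maxt < records$mint)
  if (length(bad_t)) {
    stop("maxt < mint at line ", body_no[bad_t[1]], " of ", path)
  }
  # name the first gap explicitly before full validation
  if (nrow(records) > 1) {
    nxt <- ifelse(records$doy[-nrow(records)] <
                    days_in_year(records$year[-nrow(records)]),
                  records$doy[-nrow(records)] + 1, 1)
    nxt_yr <- ifelse(nxt == 1, records$year[-nrow(records)] + 1,
                     records$year[-nrow(records)])
    gap <- which(records$doy[-1] != nxt | records$year[-1] != nxt_yr)
    if (length(gap)) {
      stop("gap in (year, doy) sequence after ", records$year[gap[1]], "-",
           records$doy[gap[1]], " at line ", body_no[gap[1] + 1],
           " of ", path)
    }
  }
  weather_series(meta$site_id, meta$latitude, records,
                 if (is.function(co2_source)) {
                   yrs <- unique(records$year)
                   stats::setNames(vapply(yrs, co2_source, numeric(1)),
                                   as.character(yrs))
                 } else co2_source,
                 meta$scenario_tag)
}

#' Write a daily weather file
#'
#' Emits the CSV dialect of the weather format: `!` metadata lines, a column
#' header, a units comment line, then comma-separated rows. C-locale decimal
#' points and `\n` newlines regardless of platform.
#'
#' @param series A [weather_series()].
#' @param path Target path.
#' @return `path`, invisibly.
#' @export
write_weather <- function(series, path) {
  stopifnot(inherits(series, "weather_series"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  wl <- function(...) writeLines(..., con = con, sep = "\n")
  wl(paste0("! site_id = ", series$site_id))
  wl(paste0("! latitude = ", format(series$latitude, decimal.mark = ".")))
  wl(paste0("! scenario_tag = ", series$scenario_tag))
  wl("year,day,radn,maxt,mint,rain")
  wl("! (),(),(MJ/m2),(C),(C),(mm)")
  r <- series$records
  wl(sprintf("%d,%d,%s,%s,%s,%s", r$year, r$doy,
             fmt_num(r$radn), fmt_num(r$maxt), fmt_num(r$mint),
             fmt_num(r$rain)))
  invisible(path)
}

fmt_num <- function(x) formatC(x, format = "fg", flag = "#", digits = 8)

#' Read/write CO2 tables
#'
#' Two-column CSV `year,co2_ppm` mapping calendar years to atmospheric CO2.
#'
#' @param path File path.
#' @return `read_co2_table`: a named numeric vector (names = years).
#' @export
read_co2_table <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("year", "co2_ppm") %in% names(d)))
  if (anyNA(d$co2_ppm) || any(is.nan(d$co2_ppm))) {
    stop("NaN/NA co2_ppm values in ", path)
  }
  stats::setNames(d$co2_ppm, as.character(d$year))
}

#' @param co2 Named numeric vector year -> ppm.
#' @rdname read_co2_table
#' @export
write_co2_table <- function(co2, path) {
  utils::write.csv(data.frame(year = as.integer(names(co2)),
                              co2_ppm = as.numeric(co2)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write soil, genotype and management parameter files
#'
#' YAML key-value serialisation of the package's parameter objects.
#'
#' @param path File path.
#' @return The corresponding object.
#' @export
read_soil <- function(path) {
  y <- yaml::yaml.load_file(path)
  soil_profile(as.data.frame(y$layers),
               water_table_depth = y$water_table_depth %||% NA_real_,
               runoff_curve = y$runoff_curve %||% 73,
               archetype = y$archetype %||% NA_character_)
}

#' @param soil A [soil_profile()].
#' @rdname read_soil
#' @export
write_soil <- function(soil, path) {
  yaml::write_yaml(list(
    archetype = soil$archetype, water_table_depth = soil$water_table_depth,
    runoff_curve = soil$runoff_curve,
    layers = as.list(soil$layers)
  ), path)
  invisible(path)
}

#' @rdname read_soil
#' @export
read_genotype <- function(path) {
  y <- yaml::yaml.load_file(path)
  do.call(genotype, y)
}

#' @param g A [genotype()].
#' @rdname read_soil
#' @export
write_genotype <- function(g, path) {
  yaml::write_yaml(unclass(g), path)
  invisible(path)
}

#' @rdname read_soil
#' @export
read_management <- function(path) {
  do.call(management, yaml::yaml.load_file(path))
}

#' @param mgmt A [management()].
#' @rdname read_soil
#' @export
write_management <- function(mgmt, path) {
  yaml::write_yaml(unclass(mgmt), path)
  invisible(path)
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration with optional sections `seeds` (named
#' integers), `paths` (named file paths) and `constants` (model-constant
#' overrides, validated against their documented ranges via
#' [wl_constants()]). Unknown top-level sections and unknown constant names
#' are rejected.
#'
#' @param path YAML file path.
#' @return A list with class `run_config`: `seeds`, `paths`, `constants`
#'   (a [wl_constants()] object).
#' @export
read_run_config <- function(path) {
  y <- yaml::yaml.load_file(path)
  known <- c("seeds", "paths", "constants")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stop("unknown run-config section(s): ", paste(bad, collapse = ", "))
  }
  seeds <- y$seeds %||% list()
  if (length(seeds) && (is.null(names(seeds)) ||
                        !all(vapply(seeds, is.numeric, logical(1))))) {
    stop("seeds must be named integers")
  }
  constants <- do.call(wl_constants, y$constants %||% list())
  structure(list(seeds = lapply(seeds, as.integer),
                 paths = y$paths %||% list(),
                 constants = constants),
            class = "run_config")
}

#' Generate a runnable miniature fixture study
#'
#' Writes a complete small factorial study (2 sites x 2 genotypes x 2
#' sowing windows x 2 scenarios x `n_realisations` realisations x `n_years`
#' seasons) to a directory: weather files per site/realisation, soil and
#' genotype YAML files, a CO2 table and a study manifest. The two sites pair
#' a freely drained, drier profile with a waterlogging-prone duplex profile
#' under winter-dominant rainfall; the genotypes pair a susceptible with a
#' fully tolerant line. Deterministic under the master seed: two calls with
#' the same seed produce identical trees.
#'
#' @param out_dir Output directory (created if needed).
#' @param master_seed Integer master seed.
#' @param n_realisations,n_years Study size (defaults 3 and 5).
#' @return The [factorial_design()] for the study, invisibly; files under
#'   `out_dir`.
#' @export
make_fixture_study <- function(out_dir, master_seed = 1L,
                               n_realisations = 3, n_years = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  design <- fixture_design(master_seed, n_realisations, n_years)
  for (si in seq_along(design$sites)) {
    site_name <- names(design$sites)[si]
    site <- design$sites[[si]]
    soil <- generate_soil(site$soil_archetype,
                          seed = derive_seed(master_seed, si, 0L))
    write_soil(soil, file.path(out_dir, paste0("soil_", site_name, ".yaml")))
    for (ri in seq_len(n_realisations)) {
      wp <- site$weather_params
      wp$seed <- derive_seed(master_seed, si, ri)
      w <- generate_weather(wp, n_years + 1, design$start_year,
                            site_id = site_name, latitude = site$latitude)
      write_weather(w, file.path(out_dir, sprintf("weather_%s_r%02d.csv",
                                                  site_name, ri)))
    }
  }
  for (g in design$genotypes) {
    write_genotype(g, file.path(out_dir, paste0("genotype_", g$name,
                                                ".yaml")))
  }
  yrs <- seq(design$start_year, design$start_year + n_years)
  write_co2_table(stats::setNames(co2_for_year(yrs), yrs),
                  file.path(out_dir, "co2_ssp585.csv"))
  manifest <- list(
    package = "barleywl",
    version = as.character(utils::packageVersion("barleywl")),
    master_seed = as.integer(master_seed),
    n_realisations = n_realisations, n_years = n_years,
    sites = names(design$sites), scenarios = names(design$scenarios),
    genotypes = vapply(design$genotypes, `[[`, character(1), "name")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(design)
}

#' Design of the miniature fixture study
#'
#' The in-memory [factorial_design()] used by [make_fixture_study()]: a dry,
#' freely drained site and a wet, waterlogging-prone duplex site (both at
#' 51 N with winter-peaking rainfall), susceptible and tolerant winter
#' genotypes, and baseline vs 2080-style scenarios (the latter with +2 to
#' +3 deg C monthly offsets and wetter autumn-to-spring months).
#'
#' @inheritParams make_fixture_study
#' @return A [factorial_design()].
#' @export
fixture_design <- function(master_seed = 1L, n_realisations = 3,
                           n_years = 5) {
  sites <- list(
    dry_drained = list(
      soil_archetype = "freely_drained",
      weather_params = weather_gen_params(
        mean_annual_rain = 450, p_wet_wet = 0.45, p_dry_wet = 0.18,
        temp_mean = 11, seed = 1L),
      latitude = 51,
      sowing_doys = c(ES = 274, LS = 305)
    ),
    wet_duplex = list(
      soil_archetype = "duplex_waterlogging_prone",
      weather_params = weather_gen_params(
        mean_annual_rain = 850, p_wet_wet = 0.65, p_dry_wet = 0.28,
        rain_peak_doy = 15, rain_seasonality = 0.5, temp_mean = 10,
        seed = 1L),
      latitude = 51,
      sowing_doys = c(ES = 274, LS = 305)
    )
  )
  genotypes <- list(
    genotype_preset("winter_susceptible"),
    genotype_preset("winter_tolerant")
  )
  deltas_2080 <- climate_deltas(
    monthly_temp_offset = c(3, 3, 2.5, 2, 2, 2, 2.5, 2.5, 2, 2, 2.5, 3),
    monthly_rain_factor = c(1.25, 1.25, 1.2, 1.1, 1, 0.9, 0.9, 0.9, 1,
                            1.1, 1.2, 1.25),
    monthly_radn_factor = rep(1, 12)
  )
  scenarios <- list(
    baseline = list(deltas = climate_deltas(), co2_source = NULL),
    # delta-perturbed weather keeps baseline years; the horizon-mean CO2 of
    # 2070-2099 is carried on every simulated year
    "2080" = list(deltas = deltas_2080,
                  co2_horizon = mean(co2_for_year(2070:2099)))
  )
  factorial_design(sites, genotypes, scenarios,
                   n_realisations = n_realisations, n_years = n_years,
                   start_year = 1995, master_seed = master_seed)
}
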