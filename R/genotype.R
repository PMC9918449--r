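#' Barley genotype parameter set
#'
#' Phenology and waterlogging-tolerance parameters of a simulated barley
#' genotype. Vernalisation and photoperiod sensitivities follow the APSIM
#' convention (range 0 to 5, higher = more sensitive); spring types use
#' `vern_sens = 1`, `photop_sens = 1`, `tt_end_of_juvenile = 400`, winter
#' types `vern_sens` of 2.5 or 4, `photop_sens` 2.5 to 4, and
#' `tt_end_of_juvenile` 400 to 750.
#'
#' @param name Genotype name.
#' @param maturity_class `"spring"` or `"winter"`.
#' @param vern_sens Vernalisation sensitivity, 0 to 5.
#' @param photop_sens Photoperiod (day-length) sensitivity, 0 to 5.
#' @param tt_end_of_juvenile Thermal time (degree-days) from emergence to end
#'   of the juvenile phase.
#' @param y_oxdef_lim_photo_floor Post-adaptation photosynthesis multiplier
#'   under sustained waterlogging, in \[0, 1\]; 1 = fully tolerant,
#'   0 = fully susceptible.
#' @param lag_days Duration of response stage one (no stress), days.
#' @param adapt_days Days from end of lag to the adapted floor.
#' @param rue Radiation use efficiency, g biomass per MJ intercepted.
#' @param harvest_index_potential Potential harvest index (0 to 1).
#' @param temp_base,temp_opt,temp_max Cardinal temperatures (deg C) of the
#'   thermal-time response.
#' @return A list with class `genotype`.
#' @examples
#' genotype_preset("winter_tolerant")
#' @export
genotype <- function(name, maturity_class = c("spring", "winter"),
                     vern_sens = 1, photop_sens = 1,
                     tt_end_of_juvenile = 400,
                     y_oxdef_lim_photo_floor = 0.5,
                     lag_days = 3, adapt_days = 10,
                     rue = 1.25, harvest_index_potential = 0.48,
                     temp_base = 0, temp_opt = 26, temp_max = 34) {
  maturity_class <- match.arg(maturity_class)
  stopifnot(
    vern_sens >= 0, vern_sens <= 5,
    photop_sens >= 0, photop_sens <= 5,
    tt_end_of_juvenile > 0,
    y_oxdef_lim_photo_floor >= 0, y_oxdef_lim_photo_floor <= 1,
    lag_days >= 0, adapt_days >= 0, rue > 0,
    harvest_index_potential > 0, harvest_index_potential <= 1,
    temp_base < temp_opt, temp_opt < temp_max
  )
  structure(list(
    name = name, maturity_class = maturity_class,
    vern_sens = vern_sens, photop_sens = photop_sens,
    tt_end_of_juvenile = tt_end_of_juvenile,
    y_oxdef_lim_photo_floor = y_oxdef_lim_photo_floor,
    lag_days = lag_days, adapt_days = adapt_days,
    rue = rue, harvest_index_potential = harvest_index_potential,
    temp_base = temp_base, temp_opt = temp_opt, temp_max = temp_max
  ), class = "genotype")
}

#' Shipped genotype presets
#'
#' Spring and winter parameter sets (vernalisation sensitivity 1 for spring,
#' 2.5/4 for winter; juvenile thermal time 400 to 750 degree-days) in
#' waterlogging-susceptible and waterlogging-tolerant variants. The tolerant
#' variants differ only in the post-adaptation photosynthesis floor.
#'
#' @param name One of `"spring_susceptible"`, `"spring_tolerant"`,
#'   `"winter_susceptible"`, `"winter_tolerant"`, `"winter_early"`.
#' @return A [genotype()] object.
#' @export
genotype_preset <- function(name) {
  presets <- list(
    spring_susceptible = genotype(
      "spring_susceptible", "spring", vern_sens = 1, photop_sens = 1,
      tt_end_of_juvenile = 400, y_oxdef_lim_photo_floor = 0.3),
    spring_tolerant = genotype(
      "spring_tolerant", "spring", vern_sens = 1, photop_sens = 1,
      tt_end_of_juvenile = 400, y_oxdef_lim_photo_floor = 1),
    winter_susceptible = genotype(
      "winter_susceptible", "winter", vern_sens = 4, photop_sens = 3,
      tt_end_of_juvenile = 750, y_oxdef_lim_photo_floor = 0.3),
    winter_tolerant = genotype(
      "winter_tolerant", "winter", vern_sens = 4, photop_sens = 3,
      tt_end_of_juvenile = 750, y_oxdef_lim_photo_floor = 1),
    winter_early = genotype(
      "winter_early", "winter", vern_sens = 2.5, photop_sens = 2.5,
      tt_end_of_juvenile = 400, y_oxdef_lim_photo_floor = 0.3)
  )
  if (!name %in% names(presets)) {
    stop("unknown genotype preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  presets[[name]]
}

#' @export
print.genotype <- function(x, ...) {
  cat("<genotype> ", x$name, " (", x$maturity_class, ")\n", sep = "")
  cat("  vern_sens ", x$vern_sens, ", photop_sens ", x$photop_sens,
      ", tt_end_of_juvenile ", x$tt_end_of_juvenile, " Cd\n", sep = "")
  cat("  waterlogging floor ", x$y_oxdef_lim_photo_floor,
      " (lag ", x$lag_days, " d, adapt ", x$adapt_days, " d)\n", sep = "")
  invisible(x)
}

#' Crop management settings
#'
#' Sowing and stand configuration for a simulated season. Defaults follow the
#' factorial protocol: 180 plants per square metre, 20 mm sowing depth,
#' 200 mm row spacing, 15 mm initial plant-available water, and no nitrogen
#' limitation.
#'
#' @param sowing_doy Sowing day of year (1 to 366).
#' @param sowing_window_tag `"ES"` (early) or `"LS"` (late); metadata only.
#' @param sowing_density Plants per square metre.
#' @param sowing_depth Sowing depth, mm.
#' @param row_spacing Row spacing, mm.
#' @param initial_plant_available_water Plant-available water at sowing, mm,
#'   distributed top-down through the profile.
#' @param nitrogen_limiting Must be `FALSE`; nitrogen dynamics are not
#'   modelled (simulations are run without nitrogen stress).
#' @return A list with class `management`.
#' @export
management <- function(sowing_doy, sowing_window_tag = "ES",
                       sowing_density = 180, sowing_depth = 20,
                       row_spacing = 200,
                       initial_plant_available_water = 15,
                       nitrogen_limiting = FALSE) {
  stopifnot(sowing_doy >= 1, sowing_doy <= 366,
            sowing_window_tag %in% c("ES", "LS"),
            sowing_density > 0, sowing_depth > 0, row_spacing > 0,
            initial_plant_available_water >= 0)
  if (isTRUE(nitrogen_limiting)) {
    stop("nitrogen dynamics are not modelled; nitrogen_limiting must be FALSE")
  }
  structure(list(
    sowing_doy = sowing_doy, sowing_window_tag = sowing_window_tag,
    sowing_density = sowing_density, sowing_depth = sowing_depth,
    row_spacing = row_spacing,
    initial_plant_available_water = initial_plant_available_water,
    nitrogen_limiting = FALSE
  ), class = "management")
}
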