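#' Synthetic species trait table
#'
#' Six invented species mirroring the functional roles found along a
#' temperate mountain elevation gradient: two warm-preferring
#' shade-tolerant broadleaf/conifer species of the submontane-montane zone
#' (`beech_syn`, `fir_syn`), two cold-preferring subalpine conifers
#' (`spruce_syn`, `stonepine_syn`) and two temperature-indifferent species
#' (`maple_syn`, `larch_syn`). The `_syn` suffix marks them as synthetic
#' stand-ins: parameter values are plausible but invented, not reproductions
#' of any calibrated species parameterization.
#'
#' @return Data frame with columns `species`, `shade_tolerance` (1-5),
#'   `lai_max`, `role`.
#' @export
default_species_traits <- function() {
  data.frame(
    species = c("beech_syn", "fir_syn", "spruce_syn", "stonepine_syn",
                "maple_syn", "larch_syn"),
    shade_tolerance = c(5, 5, 3, 3, 4, 1),
    lai_max = c(7, 7, 6.5, 5, 6, 5.5),
    role = c("warm", "warm", "cold", "cold", "indifferent", "indifferent"),
    stringsAsFactors = FALSE
  )
}

#' Synthetic species establishment parameter set
#'
#' Establishment filters for the six synthetic species of
#' [default_species_traits()]. GDD windows are positioned along the
#' default synthetic landscape's elevation-GDD gradient (roughly 1430 C d
#' at 700 m down to 700 C d at 1300 m with a 0.65 C / 100 m lapse rate) so
#' that warm-preferring species are GDD-limited at their upper range edge
#' and cold-preferring species are excluded from the warmest sites by
#' their GDD maximum.
#'
#' @return Named list of [species_establishment_params()].
#' @export
default_establishment_params <- function() {
  spp <- list(
    species_establishment_params("beech_syn", min_winter_tmin = -25,
      chill_days_required = 40, gdd_min = 1200, gdd_max = 3200,
      budburst_gdd = 200, frost_resistance = 0.6, p_max = 0.6,
      elev_low = 600, elev_high = 1100),
    species_establishment_params("fir_syn", min_winter_tmin = -28,
      chill_days_required = 35, gdd_min = 1100, gdd_max = 3000,
      budburst_gdd = 220, frost_resistance = 0.7, p_max = 0.5,
      elev_low = 600, elev_high = 1150),
    species_establishment_params("spruce_syn", min_winter_tmin = -35,
      chill_days_required = 30, gdd_min = 500, gdd_max = 1150,
      budburst_gdd = 180, frost_resistance = 0.85, p_max = 0.6,
      elev_low = 800, elev_high = 1600),
    species_establishment_params("stonepine_syn", min_winter_tmin = -40,
      chill_days_required = 25, gdd_min = 300, gdd_max = 850,
      budburst_gdd = 150, frost_resistance = 0.9, p_max = 0.4,
      elev_low = 1100, elev_high = 2000),
    species_establishment_params("maple_syn", min_winter_tmin = -30,
      chill_days_required = 30, gdd_min = 650, gdd_max = 3200,
      budburst_gdd = 200, frost_resistance = 0.75, p_max = 0.5,
      elev_low = 600, elev_high = 1300),
    species_establishment_params("larch_syn", min_winter_tmin = -40,
      chill_days_required = 25, gdd_min = 400, gdd_max = 3200,
      budburst_gdd = 160, frost_resistance = 0.9, p_max = 0.5,
      elev_low = 800, elev_high = 2000)
  )
  stats::setNames(spp, vapply(spp, function(s) s$name, character(1)))
}
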