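#' Paired simulation experiment configuration
#'
#' Collects every tunable of the paired macroclimate-versus-microclimate
#' experiment in named sections. All randomness in a run derives from
#' `seed`; paired modes within a replicate share the climate-year and
#' wind-event sequences and all process-level random draws, so that with
#' zeroed offset coefficients both modes produce bit-identical
#' trajectories.
#'
#' @param years Simulated years per run.
#' @param replicates Paired replicates.
#' @param seed Root RNG seed (integer).
#' @param weather_pool_years Size of the climate-year pool that replicate
#'   sequences are drawn from.
#' @param null_offsets If `TRUE`, both offset models are zeroed (micro
#'   equals macro; used for the pairing contract).
#' @param offset_model List: `bounds` (arguments to [truncation_bounds()])
#'   and optional `min` / `max` coefficient overrides (arguments to
#'   [offset_coefficients()]).
#' @param decomposition Arguments to [decomposition_params()].
#' @param beetle Arguments to [beetle_params()].
#' @param establishment List: `stems_per_attempt` (stems ha^-1 per
#'   successful trial) and `cohort_attrition` (annual fractional loss of
#'   the regeneration cohort).
#' @param experiment List of engine constants: wind regime
#'   (`wind_lambda` patches yr^-1, `wind_radius_mean` in 10 m cells,
#'   `wind_severity` fraction of LAI and live carbon removed), beetle
#'   mortality coupling (`beetle_x0`, `beetle_steepness`,
#'   `beetle_max_kill`, `beetle_kill_severity`), canopy regrowth rate
#'   (`regrowth_rate`, logistic), productivity (`npp_max` Mg C ha^-1
#'   yr^-1, `npp_k` per LAI unit saturation), live-carbon ceiling
#'   (`live_max` Mg C ha^-1), initial live carbon per LAI
#'   (`live_init_per_lai`), litterfall split to the litter pool
#'   (`litter_split`, remainder to downed wood), the dense-stand LAI
#'   threshold (`dense_lai_threshold`) and annual potential
#'   evapotranspiration (`pet`, mm).
#' @param fixtures A [fixture_spec()] for the synthetic landscape.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(years = 30, replicates = 5, seed = 1L,
                              weather_pool_years = 30,
                              null_offsets = FALSE,
                              offset_model = list(),
                              decomposition = list(),
                              beetle = list(),
                              establishment = list(),
                              experiment = list(),
                              fixtures = fixture_spec()) {
  stopifnot(years >= 1, replicates >= 1)
  est_default <- list(stems_per_attempt = 500, cohort_attrition = 0.1)
  exp_default <- list(wind_lambda = 0.6, wind_radius_mean = 4,
                      wind_severity = 0.8,
                      beetle_x0 = 1.2, beetle_steepness = 0.3,
                      beetle_max_kill = 0.35, beetle_kill_severity = 0.8,
                      regrowth_rate = 0.3, npp_max = 8, npp_k = 0.3,
                      live_max = 120, live_init_per_lai = 20,
                      litter_split = 0.7, dense_lai_threshold = 4,
                      pet = 600)
  establishment <- utils::modifyList(est_default, establishment)
  experiment <- utils::modifyList(exp_default, experiment)
  if (!inherits(fixtures, "fixture_spec")) {
    fixtures <- do.call(fixture_spec, as.list(fixtures))
  }
  structure(list(years = as.integer(years),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed),
                 weather_pool_years = as.integer(weather_pool_years),
                 null_offsets = isTRUE(null_offsets),
                 offset_model = offset_model,
                 decomposition = decomposition,
                 beetle = beetle,
                 establishment = establishment,
                 experiment = experiment,
                 fixtures = fixtures),
            class = "simulation_config")
}

# Materialize parameter objects from a config.
config_offset_coefs <- function(config) {
  if (config$null_offsets) {
    return(list(min = null_offset_coefficients("min"),
                max = null_offset_coefficients("max")))
  }
  om <- config$offset_model
  list(min = do.call(offset_coefficients, c(list(kind = "min"), om$min)),
       max = do.call(offset_coefficients, c(list(kind = "max"), om$max)))
}

config_bounds <- function(config) {
  b <- config$offset_model$bounds
  if (is.null(b)) truncation_bounds() else do.call(truncation_bounds, b)
}

config_decomp_params <- function(config) {
  dp <- config$decomposition
  if (length(dp)) {
    if (!is.null(dp$k_ref)) dp$k_ref <- unlist(dp$k_ref)
    if (!is.null(dp$humification)) dp$humification <- unlist(dp$humification)
  }
  do.call(decomposition_params, dp)
}

config_beetle_params <- function(config) {
  do.call(beetle_params, config$beetle)
}
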