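#' Bark beetle development parameters
#'
#' Degree-day phenology constants for Ips typographus. The defaults follow
#' the PHENIPS family of thermal-sum models: development accumulates
#' between a lower threshold of 8.3 C and an upper cap of 38.9 C in bark
#' temperature, one generation requires 557 degree-days, spring swarming
#' starts once daily maximum air temperature reaches 16.5 C, and
#' development stops at the diapause date in late summer. Overwintering
#' fails when minimum winter temperature drops below a lethal threshold.
#' All constants are configurable.
#'
#' @param bark_alpha0,bark_alpha1 Linear map from daily maximum air
#'   temperature to effective bark temperature (`bark = a0 + a1 * tmax`).
#'   Defaults (0, 1) pass air temperature through; sun-exposed bark can be
#'   modeled with a1 > 1 or a0 > 0.
#' @param dd_base Lower development threshold, degrees C.
#' @param dd_upper Upper development cap, degrees C.
#' @param dd_per_generation Thermal sum per completed generation, C d.
#' @param swarming_tmax_threshold Daily maximum air temperature that
#'   triggers spring swarming, degrees C.
#' @param season_start_doy First day of year on which swarming can occur.
#' @param diapause_doy Last day of year with development (photoperiod-
#'   driven diapause approximated by a fixed date).
#' @param winter_lethal_tmin Minimum winter temperature below which the
#'   overwintering brood dies, degrees C.
#' @return A `beetle_params` list.
#' @export
beetle_params <- function(bark_alpha0 = 0, bark_alpha1 = 1,
                          dd_base = 8.3, dd_upper = 38.9,
                          dd_per_generation = 557,
                          swarming_tmax_threshold = 16.5,
                          season_start_doy = 91L, diapause_doy = 258L,
                          winter_lethal_tmin = -22) {
  if (dd_base >= dd_upper) stop("dd_base must be below dd_upper", call. = FALSE)
  if (dd_per_generation <= 0) stop("dd_per_generation must be > 0", call. = FALSE)
  if (season_start_doy >= diapause_doy) {
    stop("season_start_doy must precede diapause_doy", call. = FALSE)
  }
  structure(list(bark_alpha0 = bark_alpha0, bark_alpha1 = bark_alpha1,
                 dd_base = dd_base, dd_upper = dd_upper,
                 dd_per_generation = dd_per_generation,
                 swarming_tmax_threshold = swarming_tmax_threshold,
                 season_start_doy = as.integer(season_start_doy),
                 diapause_doy = as.integer(diapause_doy),
                 winter_lethal_tmin = winter_lethal_tmin),
            class = "beetle_params")
}

#' Bark temperature from daily maximum air temperature
#'
#' Linear map `a0 + a1 * tmax`; the microclimate coupling feeds this the
#' maximum *microclimate* instead of macroclimate air temperature.
#'
#' @param tmax_air Daily maximum air temperature, degrees C (vectorized).
#' @param params [beetle_params()].
#' @return Bark temperature, degrees C.
#' @export
bark_temperature <- function(tmax_air, params = beetle_params()) {
  params$bark_alpha0 + params$bark_alpha1 * tmax_air
}

#' Daily degree-day increment
#'
#' `max(0, min(t_bark, dd_upper) - dd_base)`: no development below the base
#' threshold, capped accumulation above the upper threshold.
#'
#' @param t_bark Bark temperature, degrees C (vectorized).
#' @param params [beetle_params()].
#' @return Degree-day increment, C d.
#' @export
daily_development <- function(t_bark, params = beetle_params()) {
  pmax(0, pmin(t_bark, params$dd_upper) - params$dd_base)
}

#' Fractional completed generations in one year
#'
#' Swarming onset is the first day at or after `season_start_doy` whose
#' maximum air temperature reaches the swarming threshold. From onset
#' through the diapause date, daily development (computed on bark
#' temperature) is accumulated; the thermal sum divided by
#' `dd_per_generation` gives fractional completed generations. Years
#' without onset yield zero generations.
#'
#' @param tmax Daily maximum air temperature for one calendar year
#'   (vector of length >= 365, day 1 = Jan 1), degrees C.
#' @param params [beetle_params()].
#' @return List `generations`, `swarming_onset_doy` (`NA` if none),
#'   `dd_accumulated`.
#' @export
completed_generations <- function(tmax, params = beetle_params()) {
  if (length(tmax) < 365) {
    stop("need a full calendar year of daily maxima (>= 365 days)", call. = FALSE)
  }
  if (!all(is.finite(tmax))) stop("non-finite tmax in series", call. = FALSE)
  doy <- seq_along(tmax)
  candidates <- which(doy >= params$season_start_doy &
                        tmax >= params$swarming_tmax_threshold)
  if (!length(candidates) || candidates[1] > params$diapause_doy) {
    return(list(generations = 0, swarming_onset_doy = NA_integer_,
                dd_accumulated = 0))
  }
  onset <- candidates[1]
  window <- onset:params$diapause_doy
  dd <- sum(daily_development(bark_temperature(tmax[window], params), params))
  list(generations = dd / params$dd_per_generation,
       swarming_onset_doy = as.integer(onset), dd_accumulated = dd)
}

#' Overwintering survival from minimum winter temperature
#'
#' Binary rule: the brood survives (1) unless any day of the winter window
#' falls strictly below the lethal minimum temperature (0). The
#' microclimate coupling uses minimum *microclimate* temperature, so
#' canopy warming of cold nights can rescue broods that would die in the
#' open.
#'
#' @param tmin_winter Daily minimum temperatures of the winter window
#'   (typically Dec-Feb), degrees C.
#' @param params [beetle_params()].
#' @return 0 or 1.
#' @export
overwinter_survival <- function(tmin_winter, params = beetle_params()) {
  if (!length(tmin_winter)) stop("empty winter window", call. = FALSE)
  if (!all(is.finite(tmin_winter))) stop("non-finite tmin in window", call. = FALSE)
  as.numeric(min(tmin_winter) >= params$winter_lethal_tmin)
}
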