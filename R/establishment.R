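#' Species establishment parameters
#'
#' Abiotic regeneration filters per species: lethal minimum winter
#' temperature, a chilling-day requirement inside a dormant-season
#' temperature band, a growing-degree-day (GDD) window, and a frost
#' sensitivity applied after budburst. The filters act as hard thresholds
#' (establishment probability 0 when any fails); when all pass the
#' probability is `p_max * frost_resistance^frost_days`.
#'
#' @param name Species id.
#' @param min_winter_tmin Lethal threshold: establishment fails if the
#'   annual minimum daily tmin is below this, degrees C.
#' @param chill_days_required Dormant-season days required inside the
#'   chilling band.
#' @param chill_band Length-2 `c(low, high)`, degrees C, inclusive.
#' @param gdd_base Base temperature for degree-day accumulation, degrees C.
#' @param gdd_min,gdd_max Annual GDD window allowing establishment, C d.
#' @param budburst_gdd Cumulative GDD at which budburst occurs, C d.
#' @param frost_resistance In \[0, 1\]; per-frost-day survival multiplier
#'   after budburst (1 = frost-insensitive).
#' @param p_max Establishment probability when all filters pass and no
#'   frost occurs.
#' @param elev_low,elev_high Elevation range, m (reporting only).
#' @return A `species_establishment_params` list.
#' @export
species_establishment_params <- function(name, min_winter_tmin = -30,
                                         chill_days_required = 30,
                                         chill_band = c(-5, 5),
                                         gdd_base = 5,
                                         gdd_min = 300, gdd_max = 3000,
                                         budburst_gdd = 150,
                                         frost_resistance = 0.8,
                                         p_max = 0.5,
                                         elev_low = NA_real_,
                                         elev_high = NA_real_) {
  if (gdd_min > gdd_max) stop("gdd_min must be <= gdd_max", call. = FALSE)
  if (frost_resistance < 0 || frost_resistance > 1) {
    stop("frost_resistance must lie in [0, 1]", call. = FALSE)
  }
  if (p_max < 0 || p_max > 1) stop("p_max must lie in [0, 1]", call. = FALSE)
  if (chill_band[1] >= chill_band[2]) {
    stop("chill_band must satisfy low < high", call. = FALSE)
  }
  structure(list(name = name, min_winter_tmin = min_winter_tmin,
                 chill_days_required = chill_days_required,
                 chill_band = chill_band, gdd_base = gdd_base,
                 gdd_min = gdd_min, gdd_max = gdd_max,
                 budburst_gdd = budburst_gdd,
                 frost_resistance = frost_resistance, p_max = p_max,
                 elev_low = elev_low, elev_high = elev_high),
            class = "species_establishment_params")
}

#' Count chilling days
#'
#' Dormant-season days whose mean temperature lies inside the chilling
#' band, bounds inclusive.
#'
#' @param tmean Daily mean temperatures of the dormant window, degrees C.
#' @param band Length-2 `c(low, high)`, degrees C.
#' @return Integer count.
#' @export
count_chilling_days <- function(tmean, band = c(-5, 5)) {
  if (!length(tmean)) stop("empty dormant window", call. = FALSE)
  sum(tmean >= band[1] & tmean <= band[2])
}

#' Annual growing degree days
#'
#' `sum(max(0, tmean - base))` over the year.
#'
#' @param tmean Daily mean temperatures, degrees C.
#' @param base Base temperature, degrees C.
#' @return GDD, C d.
#' @export
growing_degree_days <- function(tmean, base = 5) {
  sum(pmax(0, tmean - base))
}

#' Growing-season frost days after budburst
#'
#' Budburst is the first day on which cumulative GDD reaches
#' `budburst_gdd`; the count is the number of growing-season days after
#' budburst (through `season_end_doy`) with minimum temperature below
#' 0 C. Zero if budburst never occurs. Restricting the window to the
#' growing season keeps ordinary late-autumn frosts, which dormant
#' seedlings tolerate, from being counted as damaging events.
#'
#' @param tmin,tmean Daily minimum and mean temperatures for one year.
#' @param budburst_gdd Budburst threshold, C d.
#' @param gdd_base GDD base temperature, degrees C.
#' @param season_end_doy Last day of year counted as growing season
#'   (default 273, Sep 30).
#' @return Integer count of post-budburst growing-season frost days.
#' @export
frost_days_after_budburst <- function(tmin, tmean, budburst_gdd = 150,
                                      gdd_base = 5, season_end_doy = 273L) {
  stopifnot(length(tmin) == length(tmean))
  cum <- cumsum(pmax(0, tmean - gdd_base))
  bb <- which(cum >= budburst_gdd)[1]
  last <- min(season_end_doy, length(tmin))
  if (is.na(bb) || bb >= last) return(0L)
  sum(tmin[(bb + 1L):last] < 0)
}

#' Establishment probability for one species-year
#'
#' Applies the three threshold filters (minimum winter temperature,
#' chilling, GDD window) and, when all pass, discounts `p_max` by
#' `frost_resistance` per post-budburst frost day.
#'
#' @param tmin,tmean Daily minimum and mean temperature for one calendar
#'   year (day 1 = Jan 1, length >= 365), degrees C. With microclimate
#'   coupling these are below-canopy series.
#' @param params [species_establishment_params()].
#' @param dormant_doy Integer days-of-year forming the dormant window for
#'   chilling (default Nov 1 - Mar 31 within the same calendar year).
#' @return List with the filter booleans `passed_winter_min`,
#'   `passed_chilling`, `passed_gdd`, plus `gdd`, `chill_days`,
#'   `frost_days` and `probability`.
#' @export
establishment_probability <- function(tmin, tmean, params,
                                      dormant_doy = c(1:90, 305:365)) {
  stopifnot(inherits(params, "species_establishment_params"),
            length(tmin) >= 365, length(tmin) == length(tmean))
  dormant_doy <- dormant_doy[dormant_doy <= length(tmean)]
  passed_winter_min <- min(tmin) >= params$min_winter_tmin
  chill_days <- count_chilling_days(tmean[dormant_doy], params$chill_band)
  passed_chilling <- chill_days >= params$chill_days_required
  gdd <- growing_degree_days(tmean, params$gdd_base)
  passed_gdd <- gdd >= params$gdd_min && gdd <= params$gdd_max
  frost_days <- frost_days_after_budburst(tmin, tmean, params$budburst_gdd,
                                          params$gdd_base)
  probability <- if (passed_winter_min && passed_chilling && passed_gdd) {
    params$p_max * params$frost_resistance^frost_days
  } else 0
  list(passed_winter_min = passed_winter_min,
       passed_chilling = passed_chilling, passed_gdd = passed_gdd,
       gdd = gdd, chill_days = chill_days, frost_days = frost_days,
       probability = probability)
}

#' Stochastic establishment draws
#'
#' One Bernoulli trial per probability; a success adds `stems_per_attempt`
#' stems per hectare to the regeneration cohort. When `u` (pre-drawn
#' uniforms) is supplied the draws are a deterministic function of `u`,
#' which lets paired simulations share randomness across modes.
#'
#' @param probabilities Numeric vector in \[0, 1\].
#' @param stems_per_attempt Stems ha^-1 added per successful trial.
#' @param u Optional uniforms of the same length (default: drawn from the
#'   current RNG state).
#' @return Numeric vector of established stems ha^-1.
#' @export
establish <- function(probabilities, stems_per_attempt = 500, u = NULL) {
  if (any(probabilities < 0 | probabilities > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(u)) u <- stats::runif(length(probabilities))
  stopifnot(length(u) == length(probabilities))
  as.numeric(u < probabilities) * stems_per_attempt
}

#' Read species establishment parameters from CSV
#'
#' One row per species with the columns of
#' [species_establishment_params()] (`chill_band` split into
#' `chill_low`/`chill_high`).
#'
#' @param path CSV path.
#' @return List of `species_establishment_params`, named by species.
#' @export
read_species_params_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    species_establishment_params(
      name = r$name, min_winter_tmin = r$min_winter_tmin,
      chill_days_required = r$chill_days_required,
      chill_band = c(r$chill_low, r$chill_high), gdd_base = r$gdd_base,
      gdd_min = r$gdd_min, gdd_max = r$gdd_max,
      budburst_gdd = r$budburst_gdd, frost_resistance = r$frost_resistance,
      p_max = r$p_max, elev_low = r$elev_low, elev_high = r$elev_high)
  })
  stats::setNames(out, df$name)
}
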