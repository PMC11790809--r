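#' Synthetic landscape fixture specification
#'
#' Parameters of the synthetic terrain, weather and stand generators. The
#' defaults emulate a temperate mountain forest landscape: a 50 x 50 grid
#' of 10 m cells spanning roughly 700-1300 m elevation, mean annual
#' temperature about 7 C at the valley bottom falling with a moist-
#' adiabatic lapse rate of 0.65 C per 100 m, a 9 C seasonal half-
#' amplitude, an 8 C mean diurnal range, red-noise daily anomalies, and
#' elevation-zoned stands (shade-tolerant broadleaf-conifer mixtures low,
#' spruce-dominated mid, open larch-stone pine stands near the treeline).
#'
#' @param nrow,ncol Grid size in 10 m cells (multiples of 10).
#' @param cell_size Cell edge, m.
#' @param base_elevation Valley-bottom elevation, m.
#' @param relief_amplitude Total elevation range, m.
#' @param correlation_length Terrain autocorrelation length, m.
#' @param mat Mean annual temperature at `base_elevation`, degrees C.
#' @param seasonal_amplitude Half-amplitude of the seasonal temperature
#'   cycle, degrees C (peak around July 20).
#' @param diurnal_range Mean daily tmax - tmin, degrees C.
#' @param ar1,innovation_sd AR(1) coefficient (|ar1| < 1) and innovation
#'   standard deviation of daily temperature anomalies, degrees C.
#' @param lapse Temperature lapse rate, degrees C per 100 m.
#' @param daily_precip_mean Mean daily precipitation, mm (gamma-distributed
#'   draws; about 1500 mm per year at the default).
#' @param treeline Elevation above which cells are unstockable, m.
#' @param rock_fraction Fraction of below-treeline cells that are
#'   unstockable rock.
#' @param seed RNG seed for all fixture randomness.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(nrow = 50, ncol = 50, cell_size = 10,
                         base_elevation = 700, relief_amplitude = 600,
                         correlation_length = 150,
                         mat = 7, seasonal_amplitude = 9,
                         diurnal_range = 8, ar1 = 0.7, innovation_sd = 2,
                         lapse = 0.65, daily_precip_mean = 4,
                         treeline = 1250, rock_fraction = 0.05,
                         seed = 42L) {
  stopifnot(nrow >= 1, ncol >= 1, relief_amplitude >= 0,
            seasonal_amplitude >= 0, diurnal_range >= 0, abs(ar1) < 1,
            innovation_sd >= 0)
  structure(as.list(environment()), class = "fixture_spec")
}

# Circular (periodic) Gaussian smoothing of a matrix via FFT.
gaussian_field <- function(nr, nc, sigma_cells) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma_cells <= 0) return(z)
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  kern <- exp(-outer(di^2, dj^2, "+") / (2 * sigma_cells^2))
  kern <- kern / sum(kern)
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(kern), inverse = TRUE)) / (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Generate synthetic terrain
#'
#' A smoothed Gaussian random field plus a linear cross-valley gradient is
#' scaled to the requested relief; aspect and northness follow from the
#' elevation gradients, TPI from the 500 m neighborhood mean, and the
#' stockable mask excludes cells above the treeline and a random rock
#' fraction.
#'
#' @param spec A [fixture_spec()].
#' @return A [terrain_grid()].
#' @export
generate_terrain <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  nr <- spec$nrow; nc <- spec$ncol
  if (spec$relief_amplitude == 0) {
    dem <- matrix(spec$base_elevation, nr, nc)
  } else {
    field <- gaussian_field(nr, nc, spec$correlation_length / spec$cell_size)
    ramp <- matrix((col(field) - 1) / max(1, nc - 1), nr, nc)
    shape <- 0.6 * ramp + 0.4 * (field - min(field)) / diff(range(field))
    shape <- (shape - min(shape)) / diff(range(shape))
    dem <- spec$base_elevation + spec$relief_amplitude * shape
  }
  rock <- matrix(stats::runif(nr * nc) < spec$rock_fraction, nr, nc)
  stockable <- dem <= spec$treeline & !rock
  terrain_grid(dem, stockable = stockable, cell_size = spec$cell_size)
}

#' Generate synthetic daily weather
#'
#' Daily mean temperature is a seasonal cosine (peak July 20) around the
#' mean annual temperature, lapse-shifted for `elev_offset`, plus an AR(1)
#' anomaly; minima and maxima sit half a diurnal range below/above the
#' mean, so `tmin <= tmean <= tmax` holds by construction. Precipitation
#' is gamma-distributed daily rainfall.
#'
#' @param spec A [fixture_spec()].
#' @param years Number of calendar years (starting 2001).
#' @param elev_offset Elevation above `base_elevation`, m; temperatures
#'   are shifted by `-lapse * elev_offset / 100`.
#' @param seed RNG seed (default `spec$seed + 1`).
#' @return Daily weather data frame (see [validate_weather()]).
#' @export
generate_weather <- function(spec, years = 1, elev_offset = 0,
                             seed = spec$seed + 1L) {
  stopifnot(inherits(spec, "fixture_spec"), years >= 1)
  set.seed(seed)
  dates <- seq(as.Date("2001-01-01"), as.Date(sprintf("%d-12-31", 2000 + years)),
               by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  anom <- as.numeric(stats::arima.sim(list(ar = spec$ar1), n,
                                      sd = spec$innovation_sd))
  base <- spec$mat - spec$lapse * elev_offset / 100
  tmean <- base + spec$seasonal_amplitude * cos(2 * pi * (doy - 201) / 365.25) +
    anom
  precip <- stats::rgamma(n, shape = 0.6,
                          scale = spec$daily_precip_mean / 0.6)
  validate_weather(data.frame(
    date = dates,
    tmin = tmean - spec$diurnal_range / 2,
    tmax = tmean + spec$diurnal_range / 2,
    tmean = tmean,
    precip = precip))
}

#' Default elevation-band stand rules
#'
#' Zonation used by [generate_stands()]: dense shade-tolerant mixtures in
#' the submontane band, spruce-dominated montane stands, and sparser
#' spruce-stone pine-larch stands in the subalpine band below the
#' treeline.
#'
#' @return Data frame of band rules with nested share lists.
#' @export
default_stand_rules <- function() {
  list(
    list(name = "submontane_mixed", elev_max = 950, lai_mean = 5.5, lai_sd = 1,
         shares = c(beech_syn = 0.5, fir_syn = 0.3, maple_syn = 0.2)),
    list(name = "montane_spruce", elev_max = 1100, lai_mean = 5, lai_sd = 1,
         shares = c(spruce_syn = 0.7, fir_syn = 0.1, larch_syn = 0.2)),
    list(name = "subalpine", elev_max = Inf, lai_mean = 3.5, lai_sd = 1,
         shares = c(spruce_syn = 0.4, stonepine_syn = 0.3, larch_syn = 0.3))
  )
}

#' Generate synthetic stands
#'
#' Assigns each 100 m cell a forest type from its mean elevation, draws
#' 10 m LAI around the type mean (clamped to \[0, 8\], zero on unstockable
#' cells) and sets the stand shade tolerance from the type's basal-area
#' shares. Every band below the treeline contains dense (LAI > 4) cells
#' so that local-scale, dense-stand analyses are non-empty.
#'
#' @param terrain A [terrain_grid()].
#' @param spec A [fixture_spec()].
#' @param rules Band rules, see [default_stand_rules()].
#' @param traits Species trait table, see [default_species_traits()].
#' @param seed RNG seed (default `spec$seed + 2`).
#' @return List `canopy` ([canopy_grid()]), `composition` (100 m cells x
#'   species share matrix, rows in column-major cell order), `band`
#'   (band name per 100 m cell), `lai_max10` (per-10 m-cell LAI ceiling).
#' @export
generate_stands <- function(terrain, spec, rules = default_stand_rules(),
                            traits = default_species_traits(),
                            seed = spec$seed + 2L) {
  stopifnot(inherits(terrain, "terrain_grid"))
  set.seed(seed)
  nr <- nrow(terrain$dem); nc <- ncol(terrain$dem)
  f <- 10L
  elev100 <- block_mean(terrain$dem, f)
  n100 <- length(elev100)
  band_idx <- vapply(as.vector(elev100), function(e) {
    which(vapply(rules, function(r) e <= r$elev_max, logical(1)))[1]
  }, integer(1))
  comp <- matrix(0, n100, nrow(traits),
                 dimnames = list(NULL, traits$species))
  for (k in seq_len(n100)) {
    sh <- rules[[band_idx[k]]]$shares
    comp[k, names(sh)] <- sh
  }
  # per-10m-cell band index (each 10m cell inherits its 100m cell's band)
  bi100 <- matrix(band_idx, nr %/% f, nc %/% f)
  band10 <- bi100[(seq_len(nr) - 1L) %/% f + 1L,
                  (seq_len(nc) - 1L) %/% f + 1L, drop = FALSE]
  lai_mean10 <- matrix(vapply(rules, `[[`, numeric(1), "lai_mean")[band10], nr, nc)
  lai_sd10 <- matrix(vapply(rules, `[[`, numeric(1), "lai_sd")[band10], nr, nc)
  lai <- pmin(pmax(lai_mean10 + stats::rnorm(nr * nc) * lai_sd10, 0), 8)
  lai[!terrain$stockable] <- 0
  stol_band <- vapply(rules, function(r) {
    compute_weighted_stol(r$shares, traits)
  }, numeric(1))
  stol <- matrix(stol_band[band10], nr, nc)
  lai_max10 <- pmin(lai_mean10 + 1.5, 8)
  list(canopy = canopy_grid(lai, stol),
       composition = comp,
       band = vapply(rules, `[[`, character(1), "name")[band_idx],
       lai_max10 = lai_max10)
}
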