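# Shared builders for small in-code fixtures.

# One non-leap calendar year of constant weather, optionally overridden on
# selected days of year.
constant_weather_year <- function(tmean = 10, diurnal = 8,
                                  tmean_override = NULL, doy = NULL) {
  dates <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  tm <- rep(tmean, length(dates))
  if (!is.null(tmean_override)) tm[doy] <- tmean_override
  data.frame(date = dates, tmin = tm - diurnal / 2, tmax = tm + diurnal / 2,
             tmean = tm, precip = 3)
}

# A seasonal (sinusoidal) noise-free year: warmest around July 20.
sinusoidal_weather_year <- function(mat = 7, amplitude = 9, diurnal = 8) {
  dates <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  doy <- as.integer(format(dates, "%j"))
  tm <- mat + amplitude * cos(2 * pi * (doy - 201) / 365.25)
  data.frame(date = dates, tmin = tm - diurnal / 2, tmax = tm + diurnal / 2,
             tmean = tm, precip = 3)
}

# Tiny flat terrain whose 10 m grid divides into 100 m cells.
flat_terrain <- function(nr = 10, nc = 10, elev = 800, stockable = NULL) {
  dem <- matrix(elev, nr, nc)
  if (is.null(stockable)) stockable <- matrix(TRUE, nr, nc)
  terrain_grid(dem, stockable = stockable)
}

# Uniform canopy over a grid.
uniform_canopy <- function(nr = 10, nc = 10, lai = 5, stol = 4) {
  canopy_grid(matrix(lai, nr, nc), matrix(stol, nr, nc))
}

# Small experiment configuration used by several engine tests.
small_config <- function(...) {
  args <- utils::modifyList(
    list(years = 5, replicates = 1, seed = 11, weather_pool_years = 5,
         fixtures = fixture_spec(nrow = 20, ncol = 20, seed = 5)),
    list(...))
  do.call(simulation_config, args)
}
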