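test_that("monthly macro averages follow the calendar", {
  w <- constant_weather_year(tmean = 6, diurnal = 8)  # tmin 2, tmax 10
  avg <- monthly_macro_average(w, 2001, 3)
  expect_equal(avg$avg_tmin, 2)
  expect_equal(avg$avg_tmax, 10)

  w2 <- constant_weather_year(tmean = 1)
  w2$tmin <- rep(c(0, 2), length.out = nrow(w2))
  w2$tmean <- pmax(w2$tmin, w2$tmean)
  sel <- as.integer(format(w2$date, "%m")) == 4   # April: 30 days
  expect_equal(monthly_macro_average(w2, 2001, 4)$avg_tmin,
               mean(w2$tmin[sel]))

  jan <- as.integer(format(w$date, "%m")) == 1
  expect_equal(monthly_macro_average(w, 2001, 1)$avg_tmax,
               sum(w$tmax[jan]) / 31)
  expect_error(monthly_macro_average(w, 1999, 1), "no weather days")
})

test_that("apply_offsets adds per-month constants and round-trips", {
  w <- sinusoidal_weather_year()
  set.seed(21)
  off <- data.frame(year = 2001, month = 1:12,
                    offset_min = round(runif(12, 0, 1.5), 3),
                    offset_max = round(runif(12, -3, 0), 3))
  off$offset_mean <- (off$offset_min + off$offset_max) / 2
  micro <- apply_offsets(w, off)
  mo <- as.integer(format(w$date, "%m"))
  expect_equal(attr(micro, "repaired"), 0)
  # recovered offsets equal the monthly field (machine noise only)
  expect_equal(micro$tmin - w$tmin, off$offset_min[mo], tolerance = 1e-12)
  expect_equal(micro$tmax - w$tmax, off$offset_max[mo], tolerance = 1e-12)
  expect_equal(micro$tmean - w$tmean, off$offset_mean[mo], tolerance = 1e-12)
  # within a month the micro-macro difference is constant per component
  for (m in 1:12) {
    expect_equal(length(unique(round(micro$tmin[mo == m] - w$tmin[mo == m],
                                     9))), 1)
  }
})

test_that("zero offsets are the identity and missing months are rejected", {
  w <- sinusoidal_weather_year()
  off0 <- data.frame(year = 2001, month = 1:12, offset_min = 0,
                     offset_max = 0, offset_mean = 0)
  micro <- apply_offsets(w, off0)
  expect_identical(micro$tmin, w$tmin)
  expect_identical(micro$tmax, w$tmax)
  expect_identical(micro$tmean, w$tmean)

  off_feb <- data.frame(year = 2001, month = c(1, 3:12), offset_min = -2.2,
                        offset_max = -2.2, offset_mean = -2.2)
  expect_error(apply_offsets(w, off_feb), "2001 2")

  off <- off0
  off$offset_max <- -2.2
  off$offset_mean <- -1.1
  micro2 <- apply_offsets(w, off)
  expect_equal(micro2$tmax, w$tmax - 2.2)
})

test_that("extreme offsets trigger midpoint ordering repair", {
  w <- constant_weather_year(tmean = 10, diurnal = 2)  # tmin 9, tmax 11
  off <- data.frame(year = 2001, month = 1:12, offset_min = 2,
                    offset_max = -2, offset_mean = 0)
  micro <- apply_offsets(w, off)
  expect_equal(attr(micro, "repaired"), 365)
  expect_true(all(micro$tmax >= micro$tmin))
  expect_equal(micro$tmin, micro$tmax)
  expect_equal(micro$tmin[1], 10)  # midpoint of (11, 9)
})

test_that("monthly offsets on a homogeneous landscape equal the point prediction", {
  terr <- flat_terrain(10, 10)
  can <- uniform_canopy(10, 10, lai = 6, stol = 4)
  w <- constant_weather_year(tmean = 21, diurnal = 8)  # tmax 25
  om <- compute_monthly_offsets(terr, can, w, 2001, 7)
  # flat terrain: northness 0, tpi 0; max offset is the worked example
  expect_equal(dim(om$max), c(1, 1))
  expect_equal(om$max[1, 1], -4.4545, tolerance = 1e-10)
  expect_equal(om$mean[1, 1], (om$min[1, 1] + om$max[1, 1]) / 2)

  # zero-coefficient model: all offsets zero, micro == macro downstream
  cfg0min <- null_offset_coefficients("min")
  cfg0max <- null_offset_coefficients("max")
  om0 <- compute_monthly_offsets(terr, can, w, 2001, 7,
                                 coefs_min = cfg0min, coefs_max = cfg0max)
  expect_equal(om0$min[1, 1], 0)
  expect_equal(om0$max[1, 1], 0)
})

test_that("summer max offsets are more negative than winter under fixed dense canopy", {
  terr <- flat_terrain(10, 10)
  can <- uniform_canopy(10, 10, lai = 5, stol = 4)
  w <- sinusoidal_weather_year(mat = 7, amplitude = 9)
  om_jan <- compute_monthly_offsets(terr, can, w, 2001, 1)
  om_jul <- compute_monthly_offsets(terr, can, w, 2001, 7)
  expect_lt(om_jul$max[1, 1], om_jan$max[1, 1])
  expect_lt(om_jul$max[1, 1], 0)
})

test_that("weather CSV round trip preserves the series", {
  w <- sinusoidal_weather_year()
  path <- tempfile(fileext = ".csv")
  write_weather_csv(w, path)
  w2 <- read_weather_csv(path)
  expect_equal(w2$tmin, w$tmin)
  expect_equal(w2$date, w$date)
  unlink(path)
})

test_that("weather validation rejects inverted days", {
  w <- constant_weather_year()
  w$tmin[5] <- 99
  expect_error(validate_weather(w), "tmin <= tmean <= tmax")
})
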