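test_that("chilling days count dormant-season days inside the band, inclusive", {
  expect_equal(count_chilling_days(rep(20, 60), c(-5, 5)), 0)
  expect_equal(count_chilling_days(rep(0, 30), c(-5, 5)), 30)
  expect_equal(count_chilling_days(c(5, -5, 5.0001, -5.0001), c(-5, 5)), 2)
  expect_error(count_chilling_days(numeric(0)), "empty")
})

test_that("growing degree days accumulate excess over base", {
  expect_equal(growing_degree_days(rep(2, 365), base = 5), 0)
  tm <- rep(0, 365)
  tm[100:199] <- 10  # 100 days at base + 5
  expect_equal(growing_degree_days(tm, base = 5), 500)
  set.seed(8)
  for (i in 1:10) {
    tm <- rnorm(365, 8, 6)
    extra <- c(tm, 20)  # adding a warm day never decreases GDD
    expect_gte(growing_degree_days(extra), growing_degree_days(tm))
  }
})

test_that("frost days are counted only between budburst and season end", {
  tmean <- rep(10, 365)
  tmin <- rep(5, 365)
  # budburst at cumulative GDD 150 with base 5: day 30 (30 * 5)
  tmin[c(40, 60)] <- -1
  expect_equal(frost_days_after_budburst(tmin, tmean, 150, 5), 2)
  # frost before budburst is not counted
  tmin2 <- rep(5, 365)
  tmin2[10] <- -5
  expect_equal(frost_days_after_budburst(tmin2, tmean, 150, 5), 0)
  # frost after the growing season is not counted
  tmin3 <- rep(5, 365)
  tmin3[300] <- -5
  expect_equal(frost_days_after_budburst(tmin3, tmean, 150, 5), 0)
  # no budburst -> zero
  expect_equal(frost_days_after_budburst(rep(-2, 365), rep(0, 365), 150, 5), 0)
})

test_that("threshold filters gate the probability; frost discounts it", {
  sp <- species_establishment_params("test", min_winter_tmin = -20,
                                     chill_days_required = 20,
                                     gdd_min = 500, gdd_max = 2000,
                                     budburst_gdd = 150, gdd_base = 5,
                                     frost_resistance = 0.5, p_max = 0.8)
  base_tmean <- c(rep(0, 90), rep(12, 183), rep(0, 92))   # GDD = 183*7 = 1281
  base_tmin <- base_tmean - 5

  ok <- establishment_probability(base_tmin, base_tmean, sp)
  expect_true(ok$passed_winter_min && ok$passed_chilling && ok$passed_gdd)
  expect_equal(ok$frost_days, 0)
  expect_equal(ok$probability, 0.8)

  # two post-budburst frosts: 0.8 * 0.5^2 = 0.2
  tmin_frost <- base_tmin
  tmin_frost[150:151] <- -1
  fr <- establishment_probability(tmin_frost, base_tmean, sp)
  expect_equal(fr$frost_days, 2)
  expect_equal(fr$probability, 0.2)

  # GDD below the window -> hard zero
  cold <- establishment_probability(base_tmin - 6, base_tmean - 6, sp)
  expect_false(cold$passed_gdd)
  expect_equal(cold$probability, 0)

  # lethal winter minimum -> hard zero even though GDD passes
  killed_tmin <- base_tmin
  killed_tmin[20] <- -25
  kd <- establishment_probability(killed_tmin, base_tmean, sp)
  expect_false(kd$passed_winter_min)
  expect_equal(kd$probability, 0)
})

test_that("warmer minima can only help; cooler means can only reduce GDD", {
  sp_warm <- species_establishment_params("warmpref", gdd_min = 1200,
                                          gdd_max = 3000)
  sp_cold <- species_establishment_params("coldpref", gdd_min = 300,
                                          gdd_max = 1150)
  set.seed(31)
  for (i in 1:10) {
    tmean <- 7 + 9 * cos(2 * pi * (1:365 - 201) / 365) + rnorm(365, sd = 2)
    tmin <- tmean - 4
    r0w <- establishment_probability(tmin, tmean, sp_warm)
    r0c <- establishment_probability(tmin, tmean, sp_cold)
    # positive min offsets: winter filter can only flip fail -> pass,
    # frost days can only drop
    r1w <- establishment_probability(tmin + 1, tmean, sp_warm)
    expect_gte(r1w$passed_winter_min, r0w$passed_winter_min)
    expect_lte(r1w$frost_days, r0w$frost_days)
    # negative mean offsets: GDD drops; warm-limited species move toward
    # failing gdd_min, cold-limited toward passing gdd_max
    r2w <- establishment_probability(tmin, tmean - 1, sp_warm)
    r2c <- establishment_probability(tmin, tmean - 1, sp_cold)
    expect_lte(r2w$gdd, r0w$gdd)
    expect_lte(r2w$passed_gdd, r0w$passed_gdd)
    expect_gte(r2c$passed_gdd, r0c$passed_gdd)
  }
})

test_that("establish is an exact Bernoulli at the given probability", {
  expect_equal(establish(rep(0, 50), 500), rep(0, 50))
  expect_equal(establish(rep(1, 50), 500), rep(500, 50))
  set.seed(99)
  draws <- establish(rep(0.3, 10000), stems_per_attempt = 1)
  freq <- mean(draws)
  se <- sqrt(0.3 * 0.7 / 10000)
  expect_lt(abs(freq - 0.3), 3 * se)
  # shared uniforms make draws deterministic and monotone in p
  u <- runif(100)
  lo <- establish(rep(0.2, 100), 1, u = u)
  hi <- establish(rep(0.6, 100), 1, u = u)
  expect_true(all(hi >= lo))
  expect_error(establish(c(0.5, 1.2)), "probabilities")
})

test_that("species parameter CSV round trip", {
  params <- default_establishment_params()
  df <- do.call(rbind, lapply(params, function(p) {
    data.frame(name = p$name, min_winter_tmin = p$min_winter_tmin,
               chill_days_required = p$chill_days_required,
               chill_low = p$chill_band[1], chill_high = p$chill_band[2],
               gdd_base = p$gdd_base, gdd_min = p$gdd_min,
               gdd_max = p$gdd_max, budburst_gdd = p$budburst_gdd,
               frost_resistance = p$frost_resistance, p_max = p$p_max,
               elev_low = p$elev_low, elev_high = p$elev_high)
  }))
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  back <- read_species_params_csv(path)
  expect_equal(names(back), names(params))
  expect_equal(back$spruce_syn$gdd_max, params$spruce_syn$gdd_max)
  expect_equal(back$beech_syn$chill_band, params$beech_syn$chill_band)
  unlink(path)
})

test_that("invalid species parameters are rejected at construction", {
  expect_error(species_establishment_params("x", gdd_min = 10, gdd_max = 5),
               "gdd_min")
  expect_error(species_establishment_params("x", frost_resistance = 1.2),
               "frost_resistance")
  expect_error(species_establishment_params("x", chill_band = c(5, -5)),
               "chill_band")
})
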