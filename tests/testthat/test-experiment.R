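test_that("experiment shape: one replicate, one year, both modes", {
  cfg <- simulation_config(years = 1, replicates = 1, seed = 2,
                           weather_pool_years = 2,
                           fixtures = fixture_spec(nrow = 20, ncol = 20,
                                                   seed = 5))
  x <- run_experiment(cfg)
  expect_s3_class(x$indicators, "data.frame")
  expect_equal(nrow(x$indicators), 2)
  expect_setequal(x$indicators$mode, c("macro", "micro"))
  expect_equal(nrow(x$cells), 2 * 4)  # 2 modes x 4 climate cells
  expect_true(all(c("rh", "nep", "total_c", "mean_generations",
                    "regen_density", "share_spruce_syn")
                  %in% names(x$indicators)))
  # species shares sum to 1 where forest exists
  shares <- rowSums(x$indicators[, grep("^share_", names(x$indicators))])
  expect_equal(shares, rep(1, 2), tolerance = 1e-9)
})

test_that("same seed gives bit-identical indicator tables (determinism)", {
  cfg <- small_config(years = 3)
  x1 <- run_experiment(cfg)
  x2 <- run_experiment(cfg)
  expect_identical(x1$indicators, x2$indicators)
  expect_identical(x1$cells, x2$cells)
  expect_identical(x1$disturbances, x2$disturbances)
})

test_that("paired modes share the wind-event sequence within a replicate", {
  cfg <- simulation_config(years = 8, replicates = 2, seed = 6,
                           weather_pool_years = 5,
                           experiment = list(wind_lambda = 2),
                           fixtures = fixture_spec(nrow = 20, ncol = 20,
                                                   seed = 5))
  x <- run_experiment(cfg)
  d <- x$disturbances[x$disturbances$agent == "wind", ]
  for (r in unique(d$replicate)) {
    dm <- d[d$replicate == r & d$mode == "macro", c("cell", "year")]
    di <- d[d$replicate == r & d$mode == "micro", c("cell", "year")]
    expect_equal(dm[order(dm$year, dm$cell), ],
                 di[order(di$year, di$cell), ], ignore_attr = TRUE)
  }
})

test_that("zero-coefficient offsets make paired trajectories identical", {
  cfg <- small_config(null_offsets = TRUE)
  x <- run_experiment(cfg)
  a <- x$indicators[x$indicators$mode == "macro", ]
  b <- x$indicators[x$indicators$mode == "micro", ]
  a$mode <- b$mode <- NULL
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
  ca <- x$cells[x$cells$mode == "macro", ]
  cb <- x$cells[x$cells$mode == "micro", ]
  ca$mode <- cb$mode <- NULL
  rownames(ca) <- rownames(cb) <- NULL
  expect_identical(ca, cb)
})

test_that("carbon ledger closes over the whole run", {
  # run_year() itself asserts the annual ledger at 1e-6 relative tolerance;
  # a run completing without error certifies closure every year.
  cfg <- small_config(years = 6)
  expect_no_error(run_experiment(cfg, modes = "micro"))
})

test_that("dense-stand means select the dense subset only", {
  cfg <- small_config(years = 2)
  x <- run_experiment(cfg)
  li <- local_indicators(x, lai_threshold = 4)
  expect_true(nrow(li) >= 2)
  dense <- x$cells[x$cells$forest & x$cells$lai > 4 &
                     x$cells$mode == "micro" & x$cells$replicate == 1, ]
  expect_equal(li$rh[li$mode == "micro" & li$replicate == 1],
               mean(dense$rh))
  # threshold above all LAI -> empty with warning
  expect_warning(empty <- local_indicators(x, lai_threshold = 99),
                 "no dense")
  expect_equal(nrow(empty), 0)
  # threshold below all LAI -> equals the forest-wide mean
  all_cells <- x$cells[x$cells$forest & x$cells$mode == "micro" &
                         x$cells$replicate == 1, ]
  li0 <- local_indicators(x, lai_threshold = -1)
  expect_equal(li0$generations[li0$mode == "micro" & li0$replicate == 1],
               mean(all_cells$generations))
})

test_that("patch deltas recover a synthetic indicator step", {
  # hand-built history: one cell disturbed in year 12 of 30, indicator
  # steps from 1 to 3 at the disturbance -> delta +2
  years <- 30
  cells <- data.frame(year = rep(1:years, 2), mode = "micro",
                      cell = 1L, row = 1L, col = 1L, elev = 800,
                      forest = TRUE, lai = 5,
                      rh = rep(c(rep(1, 11), rep(3, years - 11)), 2),
                      generations = 0, survival = 1,
                      regen_added = 0, regen_density = 0,
                      replicate = rep(1:2, each = years))
  x <- structure(list(
    cells = cells,
    disturbances = data.frame(cell = 1L, agent = "wind", year = 12L,
                              mode = "micro", replicate = 1:2),
    n100r = 2L, n100c = 2L, elev100 = rep(800, 4),
    regen = NULL, indicators = NULL), class = "fm_experiment")
  d <- disturbance_patch_deltas(x, indicators = "rh")
  expect_equal(nrow(d), 2)
  expect_equal(d$delta_rh, c(2, 2))
  expect_equal(d$n_cells, c(1, 1))
  # a constant indicator gives delta 0
  x$cells$rh <- 5
  d0 <- disturbance_patch_deltas(x, indicators = "rh")
  expect_equal(d0$delta_rh, c(0, 0))
  # no disturbances -> empty table
  x$disturbances <- x$disturbances[0, ]
  expect_equal(nrow(disturbance_patch_deltas(x)), 0)
})

test_that("patches truncated by the simulation bounds are dropped", {
  cells <- data.frame(year = rep(1:10, 1), mode = "micro", cell = 1L,
                      row = 1L, col = 1L, elev = 800, forest = TRUE,
                      lai = 5, rh = 1, generations = 0, survival = 1,
                      regen_added = 0, regen_density = 0, replicate = 1L)
  x <- structure(list(
    cells = cells,
    disturbances = data.frame(cell = 1L, agent = "wind", year = 5L,
                              mode = "micro", replicate = 1L),
    n100r = 2L, n100c = 2L, elev100 = rep(800, 4),
    regen = NULL, indicators = NULL), class = "fm_experiment")
  d <- disturbance_patch_deltas(x, indicators = "rh")
  expect_equal(nrow(d), 0)
  expect_equal(attr(d, "dropped"), 1L)
})

test_that("elevation band summary: identical densities give zero difference", {
  regen <- expand.grid(replicate = 1:2, mode = c("macro", "micro"),
                       cell = 1:9, species = "spruce_syn",
                       stringsAsFactors = FALSE)
  regen$elev <- rep(seq(800, 1200, by = 50), each = 4)
  regen$stems <- 100
  regen$forest <- TRUE
  x <- structure(list(regen = regen, elev100 = seq(800, 1200, by = 50),
                      n100r = 3L, n100c = 3L), class = "fm_experiment")
  s <- elevation_band_summary(x)
  expect_equal(nrow(s), 3)
  expect_equal(s$rel_diff, rep(0, 3))
  expect_false(any(s$excluded))
  # micro 110 vs macro 100 -> +0.10
  x$regen$stems[x$regen$mode == "micro"] <- 110
  s2 <- elevation_band_summary(x)
  expect_equal(s2$rel_diff, rep(0.10, 3))
  # zero macro density in every band -> species skipped entirely
  x$regen$stems[x$regen$mode == "macro"] <- 0
  expect_equal(nrow(elevation_band_summary(x)), 0)
})

test_that("configuration JSON round trip preserves the sections", {
  cfg <- simulation_config(years = 7, replicates = 2, seed = 123,
                           experiment = list(wind_lambda = 1.5),
                           fixtures = fixture_spec(nrow = 20, ncol = 20,
                                                   mat = 6, seed = 99))
  path <- tempfile(fileext = ".json")
  write_config_json(cfg, path)
  back <- read_config_json(path)
  expect_equal(back$years, 7)
  expect_equal(back$experiment$wind_lambda, 1.5)
  expect_equal(back$experiment$npp_max, cfg$experiment$npp_max)
  expect_equal(back$fixtures$mat, 6)
  expect_s3_class(back, "simulation_config")
  unlink(path)
})
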