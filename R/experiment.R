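#' Initialize a synthetic landscape state
#'
#' Builds the full simulation state from the fixture section of a
#' configuration: terrain, stands, per-100 m-cell species composition,
#' carbon pools, live carbon, regeneration cohort ledger and
#' time-since-disturbance. Climate cells are 1 ha (100 m); the grids are
#' 10 m.
#'
#' @param config A [simulation_config()].
#' @return A `landscape_state` list.
#' @export
init_landscape <- function(config) {
  spec <- config$fixtures
  terrain <- generate_terrain(spec)
  stands <- generate_stands(terrain, spec)
  traits <- default_species_traits()
  f <- 10L
  elev100 <- as.vector(block_mean(terrain$dem, f))
  n_stock <- as.vector(block_mean(terrain$stockable * 1, f)) * f^2
  forest <- n_stock > 0
  lai100 <- as.vector(block_mean(stands$canopy$lai, f))
  ex <- config$experiment
  live_c <- ex$live_init_per_lai * lai100
  frac <- n_stock / f^2
  pools <- cbind(standing_deadwood = 5 * frac, downed_wood = 10 * frac,
                 litter = 8 * frac, soil_organic_matter = 80 * frac)
  n100 <- length(elev100)
  structure(list(
    terrain = terrain, canopy = stands$canopy,
    composition = stands$composition, traits = traits,
    estab_params = default_establishment_params(),
    lai_max10 = stands$lai_max10, band = stands$band,
    elev100 = elev100, n_stockable = n_stock, forest = forest,
    live_c = live_c, pools = pools,
    cohorts = matrix(0, n100, nrow(traits),
                     dimnames = list(NULL, traits$species)),
    tsd = rep(NA_real_, n100),
    t_adjust10 = -spec$lapse * (terrain$dem - spec$base_elevation) / 100,
    year = 0L), class = "landscape_state")
}

# Deterministic stream seed below 2^31, derived from the root seed.
stream_seed <- function(root, rep, id) {
  as.integer((abs(as.numeric(root)) %% 10000) * 131071 +
               rep * 1009 + id) %% .Machine$integer.max
}

# Draw the wind-event sequence for one replicate: a list (one element per
# year) of events with center (10 m row/col) and radius (10 m cells).
draw_wind_sequence <- function(config, seed) {
  set.seed(seed)
  ex <- config$experiment
  spec <- config$fixtures
  lapply(seq_len(config$years), function(y) {
    k <- stats::rpois(1, ex$wind_lambda)
    if (k == 0) return(list())
    lapply(seq_len(k), function(i) {
      list(ci = sample.int(spec$nrow, 1), cj = sample.int(spec$ncol, 1),
           radius = max(1, stats::rpois(1, ex$wind_radius_mean)))
    })
  })
}

# 10 m circular patch mask around (ci, cj).
patch_mask <- function(nr, nc, ci, cj, radius) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (rr - ci)^2 + (cc - cj)^2 <= radius^2
}

#' Simulate one year of landscape dynamics
#'
#' Order of operations: (1) monthly temperature offsets from the current
#' canopy and terrain; (2) daily microclimate series per climate cell;
#' (3) decomposition with the climate modifier from mean microclimate or
#' macroclimate temperature; (4) bark beetle phenology from maximum and
#' overwintering from minimum micro-/macroclimate temperature;
#' (5) establishment filters from minimum/mean micro-/macroclimate
#' temperature; (6) wind patches (LAI removal, live carbon to deadwood);
#' (7) beetle-caused mortality with probability increasing in completed
#' generations x overwintering survival x spruce share; (8) logistic
#' canopy regrowth and the annual LAI/shade-tolerance refresh.
#'
#' The annual carbon ledger closes exactly: change in total carbon equals
#' NPP input minus heterotrophic respiration.
#'
#' @param state A `landscape_state` from [init_landscape()].
#' @param w Daily weather for one calendar year (365 days, dated 2001) at
#'   the fixture's base elevation.
#' @param config A [simulation_config()].
#' @param mode `"macro"` or `"micro"`: which temperature series drives
#'   decomposition, beetle development and establishment.
#' @param year_index Simulation year (1-based), used for RNG streams.
#' @param streams Named list of integer stream seeds (`estab`, `beetle`).
#' @param wind_events List of wind events for this year (see
#'   [draw_wind_sequence()]).
#' @return List `state` (updated), `indicators` (one-row data frame),
#'   `cells` (per-climate-cell data frame), `regen_added` (cells x
#'   species matrix, stems ha^-1), `disturbed` (data frame of cell, agent).
#' @export
run_year <- function(state, w, config, mode = c("macro", "micro"),
                     year_index = 1L, streams = list(estab = 1L, beetle = 2L),
                     wind_events = list()) {
  mode <- match.arg(mode)
  ex <- config$experiment
  spec <- config$fixtures
  terrain <- state$terrain
  f <- 10L
  n100 <- length(state$elev100)
  nsp <- nrow(state$traits)
  coefs <- config_offset_coefs(config)
  bounds <- config_bounds(config)
  dp <- config_decomp_params(config)
  bp <- config_beetle_params(config)

  total_before <- sum(state$live_c) + sum(state$pools)

  # (1) monthly offsets from the current canopy
  off_min <- off_max <- off_mean <- matrix(0, n100, 12)
  for (m in 1:12) {
    om <- compute_monthly_offsets(terrain, state$canopy, w, 2001, m,
                                  coefs_min = coefs$min, coefs_max = coefs$max,
                                  bounds = bounds,
                                  t_adjust = state$t_adjust10, factor = f)
    off_min[, m] <- as.vector(om$min)
    off_max[, m] <- as.vector(om$max)
    off_mean[, m] <- as.vector(om$mean)
  }

  # (2) daily series per climate cell: macro is the base series lapse-
  # shifted to cell elevation; micro adds the month's offsets with the
  # same additive rule and midpoint ordering repair as apply_offsets()
  mo <- as.integer(format(w$date, "%m"))
  t_adj100 <- as.vector(block_mean(state$t_adjust10, f))
  lai100 <- as.vector(block_mean(state$canopy$lai, f))
  ndays <- length(mo)
  macro_tmin <- outer(rep(1, n100), w$tmin) + t_adj100
  macro_tmax <- outer(rep(1, n100), w$tmax) + t_adj100
  macro_tmean <- outer(rep(1, n100), w$tmean) + t_adj100
  if (mode == "micro") {
    use_tmin <- macro_tmin + off_min[, mo]
    use_tmax <- macro_tmax + off_max[, mo]
    use_tmean <- macro_tmean + off_mean[, mo]
    inv <- use_tmax < use_tmin
    if (any(inv)) {
      mid <- (use_tmin[inv] + use_tmax[inv]) / 2
      use_tmin[inv] <- mid
      use_tmax[inv] <- mid
    }
  } else {
    use_tmin <- macro_tmin
    use_tmax <- macro_tmax
    use_tmean <- macro_tmean
  }

  forest <- state$forest
  rh <- npp <- gens <- surv <- rep(0, n100)

  # (3) decomposition + productivity
  moist <- moisture_modifier(sum(w$precip), ex$pet, dp)
  for (k in which(forest)) {
    modifier <- temperature_modifier(use_tmean[k, ], dp) * moist
    npp[k] <- ex$npp_max * (1 - exp(-ex$npp_k * lai100[k]))
    litterfall <- npp[k] * min(1, state$live_c[k] / ex$live_max)
    state$live_c[k] <- state$live_c[k] + npp[k] - litterfall
    res <- step_pools(do.call(carbon_pools, as.list(state$pools[k, ])), dp,
                      climate_modifier = modifier,
                      inputs = c(litter = ex$litter_split * litterfall,
                                 downed_wood = (1 - ex$litter_split) * litterfall))
    state$pools[k, ] <- unclass(res$pools)
    rh[k] <- res$rh
  }

  # (4) bark beetle phenology
  winter_doy <- c(1:59, 335:ndays)
  for (k in which(forest)) {
    gens[k] <- completed_generations(use_tmax[k, ], bp)$generations
    surv[k] <- overwinter_survival(use_tmin[k, winter_doy], bp)
  }

  # (5) establishment (shared uniforms across modes via the stream seed)
  set.seed(streams$estab + year_index)
  u_est <- matrix(stats::runif(n100 * nsp), n100, nsp)
  est <- config$establishment
  state$cohorts <- state$cohorts * (1 - est$cohort_attrition)
  added <- matrix(0, n100, nsp, dimnames = dimnames(state$cohorts))
  for (k in which(forest)) {
    probs <- vapply(state$estab_params, function(sp) {
      establishment_probability(use_tmin[k, ], use_tmean[k, ], sp)$probability
    }, numeric(1))
    added[k, ] <- establish(probs, est$stems_per_attempt, u = u_est[k, ])
  }
  state$cohorts <- state$cohorts + added

  # (6) wind disturbance (sequence shared across modes)
  nr <- nrow(terrain$dem); nc <- ncol(terrain$dem)
  disturbed <- data.frame(cell = integer(0), agent = character(0))
  for (ev in wind_events) {
    mask <- patch_mask(nr, nc, ev$ci, ev$cj, ev$radius) & terrain$stockable
    if (!any(mask)) next
    state$canopy$lai[mask] <- state$canopy$lai[mask] * (1 - ex$wind_severity)
    fh <- as.vector(block_mean(mask * 1, f))
    loss <- state$live_c * fh * ex$wind_severity
    state$live_c <- state$live_c - loss
    state$pools[, "standing_deadwood"] <- state$pools[, "standing_deadwood"] + 0.5 * loss
    state$pools[, "downed_wood"] <- state$pools[, "downed_wood"] + 0.5 * loss
    hit <- which(fh > 0.2)
    state$tsd[hit] <- 0
    if (length(hit)) {
      disturbed <- rbind(disturbed, data.frame(cell = hit, agent = "wind"))
    }
  }

  # (7) beetle-caused mortality (pressure = generations x survival x
  # spruce share; uniforms shared across modes)
  spruce <- state$composition[, "spruce_syn"]
  pressure <- gens * surv * spruce
  p_kill <- ex$beetle_max_kill *
    stats::plogis((pressure - ex$beetle_x0) / ex$beetle_steepness)
  p_kill[pressure <= 0] <- 0
  set.seed(streams$beetle + year_index)
  u_b <- stats::runif(n100)
  outbreak <- which(u_b < p_kill & forest)
  for (k in outbreak) {
    kf <- spruce[k] * ex$beetle_kill_severity
    loss <- state$live_c[k] * kf
    state$live_c[k] <- state$live_c[k] - loss
    state$pools[k, "standing_deadwood"] <- state$pools[k, "standing_deadwood"] + loss
    bi <- (k - 1) %% (nr %/% f) + 1; bj <- (k - 1) %/% (nr %/% f) + 1
    ri <- ((bi - 1) * f + 1):(bi * f); rj <- ((bj - 1) * f + 1):(bj * f)
    state$canopy$lai[ri, rj] <- state$canopy$lai[ri, rj] * (1 - kf)
    state$composition[k, "spruce_syn"] <-
      state$composition[k, "spruce_syn"] * (1 - ex$beetle_kill_severity)
    tot <- sum(state$composition[k, ])
    if (tot > 0) state$composition[k, ] <- state$composition[k, ] / tot
    state$tsd[k] <- 0
  }
  if (length(outbreak)) {
    disturbed <- rbind(disturbed, data.frame(cell = outbreak, agent = "beetle"))
  }

  # (8) logistic canopy regrowth and annual canopy refresh
  lai <- state$canopy$lai
  grow <- ex$regrowth_rate * pmax(lai, 0.5) * (1 - lai / state$lai_max10)
  lai <- pmin(pmax(lai + grow, 0), state$lai_max10)
  lai[!terrain$stockable] <- 0
  stol100 <- vapply(seq_len(n100), function(k) {
    compute_weighted_stol(state$composition[k, ], state$traits)
  }, numeric(1))
  stol10 <- matrix(0, nr, nc)
  for (k in seq_len(n100)) {
    bi <- (k - 1) %% (nr %/% f) + 1; bj <- (k - 1) %/% (nr %/% f) + 1
    stol10[((bi - 1) * f + 1):(bi * f), ((bj - 1) * f + 1):(bj * f)] <- stol100[k]
  }
  state$canopy <- canopy_grid(lai, stol10, year_index)
  state$tsd <- state$tsd + 1
  state$year <- year_index

  if (any(!is.finite(state$live_c)) || any(!is.finite(state$pools))) {
    stop(sprintf("non-finite landscape state in year %d", year_index),
         call. = FALSE)
  }
  total_after <- sum(state$live_c) + sum(state$pools)
  balance <- (total_before + sum(npp) - sum(rh)) - total_after
  if (abs(balance) > 1e-6 * max(1, total_after)) {
    stop(sprintf("carbon ledger violation in year %d: %.3g", year_index,
                 balance), call. = FALSE)
  }

  fc <- which(forest)
  live_tot <- sum(state$live_c[fc])
  shares <- if (live_tot > 0) {
    colSums(state$composition[fc, , drop = FALSE] * state$live_c[fc]) / live_tot
  } else colMeans(state$composition[fc, , drop = FALSE])
  n100r <- nr %/% f
  indicators <- data.frame(
    year = year_index, mode = mode,
    rh = mean(rh[fc]), npp = mean(npp[fc]), nep = mean(npp[fc] - rh[fc]),
    total_c = mean(state$live_c[fc] + rowSums(state$pools[fc, , drop = FALSE])),
    mean_generations = mean(gens[fc]),
    regen_density = mean(rowSums(state$cohorts[fc, , drop = FALSE])),
    area_wind = sum(disturbed$agent == "wind"),
    area_beetle = sum(disturbed$agent == "beetle"))
  for (s in state$traits$species) indicators[[paste0("share_", s)]] <- shares[[s]]
  cells <- data.frame(
    year = year_index, mode = mode, cell = seq_len(n100),
    row = (seq_len(n100) - 1) %% n100r + 1,
    col = (seq_len(n100) - 1) %/% n100r + 1,
    elev = state$elev100, forest = forest, lai = lai100,
    rh = rh, generations = gens, survival = surv,
    regen_added = rowSums(added), regen_density = rowSums(state$cohorts))
  list(state = state, indicators = indicators, cells = cells,
       regen_added = added, disturbed = disturbed)
}

#' Run the paired macroclimate-versus-microclimate experiment
#'
#' For every replicate, one climate-year sequence and one wind-event
#' sequence are drawn once and reused for both modes; the modes differ
#' only in the temperature series fed to decomposition, beetle phenology
#' and establishment. Establishment and beetle-mortality uniforms are also
#' shared across modes, so with zeroed offset coefficients the paired
#' trajectories are bit-identical.
#'
#' @param config A [simulation_config()].
#' @param modes Character vector of modes to run (default both).
#' @return An `fm_experiment` list: `indicators` (replicate x mode x year
#'   landscape indicators), `cells` (per-climate-cell annual values),
#'   `regen` (stems established per replicate, mode, cell and species),
#'   `disturbances` (annual disturbance log), `elev100`, `config`.
#' @export
run_experiment <- function(config, modes = c("macro", "micro")) {
  stopifnot(inherits(config, "simulation_config"))
  spec <- config$fixtures
  pool <- lapply(seq_len(config$weather_pool_years), function(i) {
    generate_weather(spec, years = 1, elev_offset = 0,
                     seed = stream_seed(config$seed, 0, 5000 + i))
  })
  template <- init_landscape(config)
  ind_l <- cell_l <- dist_l <- regen_l <- list()
  for (rep_i in seq_len(config$replicates)) {
    set.seed(stream_seed(config$seed, rep_i, 1))
    climate_idx <- sample.int(config$weather_pool_years, config$years,
                              replace = TRUE)
    wind_seq <- draw_wind_sequence(config, stream_seed(config$seed, rep_i, 2))
    streams <- list(estab = stream_seed(config$seed, rep_i, 3),
                    beetle = stream_seed(config$seed, rep_i, 4))
    for (mode in modes) {
      state <- template
      regen_tot <- matrix(0, length(template$elev100), nrow(template$traits),
                          dimnames = dimnames(template$cohorts))
      for (y in seq_len(config$years)) {
        out <- run_year(state, pool[[climate_idx[y]]], config, mode = mode,
                        year_index = y, streams = streams,
                        wind_events = wind_seq[[y]])
        state <- out$state
        out$indicators$replicate <- rep_i
        out$cells$replicate <- rep_i
        ind_l[[length(ind_l) + 1L]] <- out$indicators
        cell_l[[length(cell_l) + 1L]] <- out$cells
        regen_tot <- regen_tot + out$regen_added
        if (nrow(out$disturbed)) {
          d <- out$disturbed
          d$year <- y; d$mode <- mode; d$replicate <- rep_i
          dist_l[[length(dist_l) + 1L]] <- d
        }
      }
      regen_l[[length(regen_l) + 1L]] <- data.frame(
        replicate = rep_i, mode = mode,
        cell = rep(seq_len(nrow(regen_tot)), ncol(regen_tot)),
        species = rep(colnames(regen_tot), each = nrow(regen_tot)),
        stems = as.vector(regen_tot),
        elev = rep(template$elev100, ncol(regen_tot)),
        forest = rep(template$forest, ncol(regen_tot)))
    }
  }
  structure(list(
    indicators = do.call(rbind, ind_l),
    cells = do.call(rbind, cell_l),
    regen = do.call(rbind, regen_l),
    disturbances = if (length(dist_l)) do.call(rbind, dist_l) else
      data.frame(cell = integer(0), agent = character(0),
                 year = integer(0), mode = character(0),
                 replicate = integer(0)),
    elev100 = template$elev100,
    n100r = nrow(template$terrain$dem) %/% 10L,
    n100c = ncol(template$terrain$dem) %/% 10L,
    config = config), class = "fm_experiment")
}

#' Dense-stand (local-scale) indicator means
#'
#' Annual means of heterotrophic respiration, completed beetle generations
#' and regeneration density over dense forested climate cells (LAI above
#' the threshold), per replicate and mode.
#'
#' @param x An `fm_experiment`.
#' @param lai_threshold Dense-stand LAI threshold (default 4).
#' @return Data frame with one row per (replicate, mode); empty (with a
#'   warning) when no cell-year exceeds the threshold.
#' @export
local_indicators <- function(x, lai_threshold = 4) {
  stopifnot(inherits(x, "fm_experiment"))
  dense <- x$cells[x$cells$forest & x$cells$lai > lai_threshold, ]
  if (!nrow(dense)) {
    warning("no dense cell-years (LAI > ", lai_threshold, ")")
    return(data.frame(replicate = integer(0), mode = character(0),
                      rh = numeric(0), generations = numeric(0),
                      regen_density = numeric(0)))
  }
  agg <- stats::aggregate(dense[, c("rh", "generations", "regen_density")],
                          by = list(replicate = dense$replicate,
                                    mode = dense$mode), FUN = mean)
  agg[order(agg$replicate, agg$mode), ]
}

# 8-neighbor connected components over a set of climate-cell indices.
connected_patches <- function(cells, n100r, n100c) {
  if (!length(cells)) return(integer(0))
  rows <- (cells - 1) %% n100r + 1
  cols <- (cells - 1) %/% n100r + 1
  lab <- rep(0L, length(cells))
  cur <- 0L
  key <- paste(rows, cols)
  for (i in seq_along(cells)) {
    if (lab[i] > 0) next
    cur <- cur + 1L
    queue <- i
    lab[i] <- cur
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      nb <- which(lab == 0 & abs(rows - rows[j]) <= 1 & abs(cols - cols[j]) <= 1)
      lab[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  lab
}

#' Post- minus pre-disturbance indicator changes in disturbance patches
#'
#' Disturbed climate cells are accumulated over consecutive
#' `accumulation_window`-year blocks, grouped into contiguous patches
#' (8-neighbor connectivity), and each patch's indicators are compared
#' between a post-disturbance window (`post_lag` to `post_end` years after
#' the patch's mean disturbance year) and an equal-length pre-disturbance
#' window. Patches whose windows are truncated by the simulation bounds
#' are dropped; their count is reported in the `dropped` attribute.
#'
#' @param x An `fm_experiment`.
#' @param indicators Cell-table columns to difference.
#' @param accumulation_window Years of cumulative disturbance forming one
#'   patch generation (default 10).
#' @param post_lag,post_end Post-disturbance window bounds, years since
#'   disturbance (default 5-15).
#' @return Data frame with one row per (replicate, mode, patch) and one
#'   `delta_*` column per indicator.
#' @export
disturbance_patch_deltas <- function(x, indicators = c("rh", "generations",
                                                       "regen_added"),
                                     accumulation_window = 10,
                                     post_lag = 5, post_end = 15) {
  stopifnot(inherits(x, "fm_experiment"))
  d <- x$disturbances
  out <- list()
  dropped <- 0L
  if (nrow(d)) {
    d$block <- (d$year - 1) %/% accumulation_window
    groups <- unique(d[, c("replicate", "mode", "block")])
    years_max <- max(x$cells$year)
    win_len <- post_end - post_lag + 1
    for (g in seq_len(nrow(groups))) {
      sel <- d$replicate == groups$replicate[g] & d$mode == groups$mode[g] &
        d$block == groups$block[g]
      cells <- sort(unique(d$cell[sel]))
      lab <- connected_patches(cells, x$n100r, x$n100c)
      for (p in unique(lab)) {
        pc <- cells[lab == p]
        t_dist <- round(mean(d$year[sel & d$cell %in% pc]))
        post <- (t_dist + post_lag):(t_dist + post_end)
        pre <- (t_dist - win_len):(t_dist - 1)
        if (min(pre) < 1 || max(post) > years_max) {
          dropped <- dropped + 1L
          next
        }
        ct <- x$cells[x$cells$replicate == groups$replicate[g] &
                        x$cells$mode == groups$mode[g] &
                        x$cells$cell %in% pc, ]
        row <- data.frame(replicate = groups$replicate[g],
                          mode = groups$mode[g], patch = p,
                          n_cells = length(pc), year_disturbed = t_dist)
        for (ind in indicators) {
          row[[paste0("delta_", ind)]] <-
            mean(ct[[ind]][ct$year %in% post]) -
            mean(ct[[ind]][ct$year %in% pre])
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(replicate = integer(0), mode = character(0),
               patch = integer(0), n_cells = integer(0),
               year_disturbed = numeric(0))
  attr(res, "dropped") <- dropped
  res
}

# Weighted quantile (type-4-style, monotone interpolation of the ECDF).
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

#' Species regeneration differences along elevation bands
#'
#' For each species, three elevation bands (width `band_width`) are
#' centered on the lower bound, median and upper bound of its macroclimate
#' regeneration elevation distribution (stems-weighted 5th, 50th and 95th
#' percentiles). Within each band the relative micro-versus-macro
#' difference in mean regeneration density is reported; bands whose center
#' falls below the landscape's minimum elevation are flagged excluded, and
#' bands with zero macroclimate density get `NA`.
#'
#' @param x An `fm_experiment`.
#' @param band_width Band width, m (default 100).
#' @return Data frame: species, band, center elevation, macro and micro
#'   mean densities, `rel_diff`, `excluded`.
#' @export
elevation_band_summary <- function(x, band_width = 100) {
  stopifnot(inherits(x, "fm_experiment"))
  r <- x$regen[x$regen$forest, ]
  out <- list()
  for (sp in unique(r$species)) {
    rs <- r[r$species == sp, ]
    macro <- rs[rs$mode == "macro", ]
    if (sum(macro$stems) == 0) next
    centers <- weighted_quantile(macro$elev, macro$stems, c(0.05, 0.5, 0.95))
    names(centers) <- c("lower", "median", "upper")
    for (b in names(centers)) {
      lo <- centers[[b]] - band_width / 2
      hi <- centers[[b]] + band_width / 2
      in_band <- rs$elev >= lo & rs$elev <= hi
      dm <- mean(rs$stems[in_band & rs$mode == "macro"])
      dmi <- mean(rs$stems[in_band & rs$mode == "micro"])
      out[[length(out) + 1L]] <- data.frame(
        species = sp, band = b, center_elev = unname(centers[[b]]),
        macro = dm, micro = dmi,
        rel_diff = if (is.finite(dm) && dm > 0) (dmi - dm) / dm else NA_real_,
        excluded = centers[[b]] < min(x$elev100))
    }
  }
  if (!length(out)) {
    return(data.frame(species = character(0), band = character(0),
                      center_elev = numeric(0), macro = numeric(0),
                      micro = numeric(0), rel_diff = numeric(0),
                      excluded = logical(0)))
  }
  do.call(rbind, out)
}
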