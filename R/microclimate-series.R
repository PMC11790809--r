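#' Validate a daily weather table
#'
#' A daily weather series is a data frame with columns `date` (Date),
#' `tmin`, `tmax`, `tmean` (degrees C) and optionally `precip` (mm).
#' `tmin <= tmean <= tmax` must hold on every day.
#'
#' @param w Data frame.
#' @return `w`, with `date` coerced to `Date`, invisibly checked.
#' @export
validate_weather <- function(w) {
  needed <- c("date", "tmin", "tmax", "tmean")
  missing_cols <- setdiff(needed, names(w))
  if (length(missing_cols)) {
    stop(sprintf("weather table lacks columns: %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  w$date <- as.Date(w$date)
  bad <- which(w$tmin > w$tmax | w$tmean < w$tmin | w$tmean > w$tmax)
  if (length(bad)) {
    stop(sprintf("tmin <= tmean <= tmax violated on %d day(s), first %s",
                 length(bad), w$date[bad[1]]), call. = FALSE)
  }
  w
}

#' Read / write daily weather CSV
#'
#' Columns `date,tmin,tmax,tmean,precip` with ISO dates, degrees C and mm.
#'
#' @param path File path.
#' @return `read_weather_csv()` returns the validated data frame.
#' @export
read_weather_csv <- function(path) {
  validate_weather(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @param w Weather data frame.
#' @rdname read_weather_csv
#' @export
write_weather_csv <- function(w, path) {
  utils::write.csv(validate_weather(w), path, row.names = FALSE)
  invisible(path)
}

#' Monthly averages of daily minimum and maximum temperature
#'
#' The offset models use "average daily" predictors: the monthly mean of
#' daily minima and maxima.
#'
#' @param w Daily weather data frame (see [validate_weather()]).
#' @param year,month Calendar year and month to average over.
#' @return Named list `avg_tmin`, `avg_tmax` (degrees C).
#' @export
monthly_macro_average <- function(w, year, month) {
  w <- validate_weather(w)
  sel <- as.integer(format(w$date, "%Y")) == year &
    as.integer(format(w$date, "%m")) == month
  if (!any(sel)) {
    stop(sprintf("no weather days in %d-%02d", year, month), call. = FALSE)
  }
  list(avg_tmin = mean(w$tmin[sel]), avg_tmax = mean(w$tmax[sel]))
}

#' Monthly offset field from terrain, canopy and macroclimate
#'
#' For every stockable 10 m cell, builds the minimum- and maximum-offset
#' predictor vectors from the month's macroclimate averages and the current
#' canopy/terrain state, truncates them, predicts both offsets, derives the
#' mean offset, and aggregates all three components to 100 m climate cells
#' over stockable cells only.
#'
#' @param terrain A [terrain_grid()].
#' @param canopy A [canopy_grid()].
#' @param w Daily weather data frame for (at least) the requested month.
#' @param year,month Calendar month to compute offsets for.
#' @param coefs_min,coefs_max [offset_coefficients()] of kind min / max.
#' @param bounds [truncation_bounds()].
#' @param t_adjust Optional matrix (10 m grid) of additive adjustments to
#'   the macroclimate monthly averages, e.g. an elevation lapse relative to
#'   the weather reference point; default 0.
#' @param factor Aggregation factor to climate cells (default 10).
#' @return List with 100 m matrices `min`, `max`, `mean`, `n_stockable`,
#'   plus `cell10` (the unaggregated 10 m `min`/`max`/`mean` grids) and
#'   `year`, `month`.
#' @export
compute_monthly_offsets <- function(terrain, canopy, w, year, month,
                                    coefs_min = offset_coefficients("min"),
                                    coefs_max = offset_coefficients("max"),
                                    bounds = truncation_bounds(),
                                    t_adjust = 0, factor = 10L) {
  stopifnot(inherits(terrain, "terrain_grid"), inherits(canopy, "canopy_grid"))
  avg <- monthly_macro_average(w, year, month)
  dm <- dim(terrain$dem)
  adj <- if (is.matrix(t_adjust)) t_adjust else matrix(t_adjust, dm[1], dm[2])
  grids <- list()
  for (kind in c("min", "max")) {
    tm <- (if (kind == "min") avg$avg_tmin else avg$avg_tmax) + adj
    p <- predictor_vector(t_macro = as.vector(tm),
                          lai = as.vector(canopy$lai),
                          northness = as.vector(terrain$northness),
                          stol = as.vector(canopy$stol),
                          tpi = as.vector(terrain$tpi), kind = kind)
    p <- truncate_predictors(p, bounds)
    co <- if (kind == "min") coefs_min else coefs_max
    grids[[kind]] <- matrix(predict_offset(p, co), dm[1], dm[2])
  }
  grids$mean <- derive_mean_offset(grids$min, grids$max)
  agg <- aggregate_offsets(grids, terrain$stockable, factor = factor)
  agg$cell10 <- grids
  agg$year <- year
  agg$month <- month
  agg
}

#' Apply monthly offsets to a daily macroclimate series
#'
#' Adds the month's offset triple to every day of that month:
#' `micro_tmin = tmin + offset_min`, `micro_tmax = tmax + offset_max`,
#' `micro_tmean = tmean + offset_mean`. Because the minimum offset is
#' typically positive (canopies warm cold nights) and the maximum offset
#' negative (canopies cool hot days), extreme offsets can invert the daily
#' range; such days are repaired by collapsing min and max to their
#' midpoint and counted in the `repaired` attribute.
#'
#' @param w Daily weather data frame.
#' @param offsets Data frame with columns `year`, `month`, `offset_min`,
#'   `offset_max`, `offset_mean` covering every month of `w`.
#' @return Data frame `date`, `tmin`, `tmax`, `tmean` (microclimate,
#'   degrees C) with attribute `repaired` (number of order-repaired days).
#' @export
apply_offsets <- function(w, offsets) {
  w <- validate_weather(w)
  yr <- as.integer(format(w$date, "%Y"))
  mo <- as.integer(format(w$date, "%m"))
  key <- paste(yr, mo)
  okey <- paste(offsets$year, offsets$month)
  if (anyDuplicated(okey)) stop("duplicate (year, month) in offset field", call. = FALSE)
  hit <- match(key, okey)
  if (anyNA(hit)) {
    miss <- key[which(is.na(hit))[1]]
    stop(sprintf("offset field misses month %s of the weather series", miss),
         call. = FALSE)
  }
  if (!all(is.finite(offsets$offset_min)) || !all(is.finite(offsets$offset_max)) ||
      !all(is.finite(offsets$offset_mean))) {
    stop("offsets must be finite", call. = FALSE)
  }
  tmin <- w$tmin + offsets$offset_min[hit]
  tmax <- w$tmax + offsets$offset_max[hit]
  tmean <- w$tmean + offsets$offset_mean[hit]
  inverted <- tmax < tmin
  if (any(inverted)) {
    mid <- (tmin[inverted] + tmax[inverted]) / 2
    tmin[inverted] <- mid
    tmax[inverted] <- mid
  }
  out <- data.frame(date = w$date, tmin = tmin, tmax = tmax, tmean = tmean)
  if (!is.null(w$precip)) out$precip <- w$precip
  attr(out, "repaired") <- sum(inverted)
  out
}
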