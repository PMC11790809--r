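#' Terrain grid container
#'
#' Bundles the 10 m terrain rasters used by the offset model: elevation,
#' aspect, northness, topographic position index (TPI) and the stockable
#' mask (cells able to carry forest; rock/water/alpine cells are
#' unstockable). All grids are plain R matrices, row-major with the origin
#' in the upper-left corner and cell registration at the center, in one
#' projected CRS with square pixels.
#'
#' @param dem Elevation matrix, m.
#' @param aspect Aspect matrix, degrees clockwise from north; `NA` on flat
#'   cells.
#' @param stockable Logical matrix; `TRUE` where forest can grow.
#' @param cell_size Pixel edge length, m (default 10).
#' @param tpi_radius Radius of the TPI neighborhood, m (default 500).
#' @return A `terrain_grid` list with elements `dem`, `aspect`, `northness`,
#'   `tpi`, `stockable`, `cell_size`.
#' @export
terrain_grid <- function(dem, aspect = NULL, stockable = NULL,
                         cell_size = 10, tpi_radius = 500) {
  stopifnot(is.matrix(dem), all(is.finite(dem)))
  if (is.null(aspect)) aspect <- aspect_from_dem(dem, cell_size)
  if (is.null(stockable)) stockable <- matrix(TRUE, nrow(dem), ncol(dem))
  stopifnot(identical(dim(dem), dim(aspect)), identical(dim(dem), dim(stockable)))
  structure(list(dem = dem, aspect = aspect,
                 northness = compute_northness(aspect),
                 tpi = compute_tpi(dem, radius = tpi_radius, cell_size = cell_size),
                 stockable = stockable, cell_size = cell_size),
            class = "terrain_grid")
}

#' Northness from aspect
#'
#' Cosine of topographic aspect: 1 on north-facing slopes, -1 on
#' south-facing slopes, 0 on east/west slopes. Flat cells (undefined
#' aspect, `NA`) get the neutral value 0.
#'
#' @param aspect Aspect in degrees clockwise from north, in \[0, 360);
#'   `NA` for flat cells. Vector or matrix.
#' @return Northness in \[-1, 1\], same shape as `aspect`.
#' @export
compute_northness <- function(aspect) {
  if (any(!is.na(aspect) & (aspect < 0 | aspect >= 360))) {
    stop("aspect must be in [0, 360) degrees (NA for flat cells)", call. = FALSE)
  }
  out <- cos(aspect * pi / 180)
  out[is.na(aspect)] <- 0
  out
}

#' Downslope aspect from a DEM
#'
#' Central-difference gradients (one-sided at the grid edge) give the
#' steepest-descent direction; its compass bearing is the aspect. Cells
#' with (near-)zero gradient are flat and get `NA`.
#'
#' @param dem Elevation matrix, m; rows run north to south.
#' @param cell_size Pixel edge, m.
#' @param flat_tol Gradient magnitude (m per m) below which a cell counts
#'   as flat.
#' @return Aspect matrix in degrees clockwise from north, `NA` on flat cells.
#' @export
aspect_from_dem <- function(dem, cell_size = 10, flat_tol = 1e-8) {
  nr <- nrow(dem); nc <- ncol(dem)
  # d/dx: east positive (columns); d/dy: north positive (rows decrease north)
  ix_hi <- pmin(seq_len(nc) + 1L, nc); ix_lo <- pmax(seq_len(nc) - 1L, 1L)
  iy_hi <- pmin(seq_len(nr) + 1L, nr); iy_lo <- pmax(seq_len(nr) - 1L, 1L)
  dx <- (dem[, ix_hi, drop = FALSE] - dem[, ix_lo, drop = FALSE]) /
    ((ix_hi - ix_lo)[col(dem)] * cell_size)
  dy <- (dem[iy_lo, , drop = FALSE] - dem[iy_hi, , drop = FALSE]) /
    ((iy_hi - iy_lo)[row(dem)] * cell_size)
  east <- -dx; north <- -dy  # steepest-descent components
  asp <- (atan2(east, north) * 180 / pi) %% 360
  asp[sqrt(dx^2 + dy^2) < flat_tol] <- NA_real_
  asp
}

# Mean of `x` over the disk of radius `radius` (in m) around each cell,
# neighborhood clipped at the grid boundary. O(cells x kernel offsets).
focal_disk_mean <- function(x, radius, cell_size) {
  nr <- nrow(x); nc <- ncol(x)
  r_cells <- floor(radius / cell_size)
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  for (di in -r_cells:r_cells) {
    ilo <- max(1, 1 - di); ihi <- min(nr, nr - di)
    if (ilo > ihi) next
    span <- floor(sqrt((radius / cell_size)^2 - di^2))
    for (dj in -span:span) {
      jlo <- max(1, 1 - dj); jhi <- min(nc, nc - dj)
      if (jlo > jhi) next
      src_i <- ilo:ihi; src_j <- jlo:jhi
      dst_i <- src_i + di; dst_j <- src_j + dj
      acc[dst_i, dst_j] <- acc[dst_i, dst_j] + x[src_i, src_j]
      cnt[dst_i, dst_j] <- cnt[dst_i, dst_j] + 1
    }
  }
  acc / cnt
}

#' Topographic position index
#'
#' Cell elevation minus the mean elevation of all cells whose centers lie
#' within `radius` of the cell center (the cell itself included); the
#' neighborhood is clipped at the grid boundary, no padding. Positive TPI
#' marks ridges, negative valleys.
#'
#' @param dem Elevation matrix, m.
#' @param radius Neighborhood radius, m (default 500).
#' @param cell_size Pixel edge, m.
#' @return TPI matrix, m.
#' @export
compute_tpi <- function(dem, radius = 500, cell_size = 10) {
  stopifnot(is.matrix(dem))
  if (nrow(dem) < 1 || ncol(dem) < 1) stop("empty DEM", call. = FALSE)
  if (radius <= cell_size) stop("TPI radius must exceed the cell size", call. = FALSE)
  dem - focal_disk_mean(dem, radius, cell_size)
}

#' Basal-area-weighted mean shade tolerance
#'
#' Weighted mean of per-species shade-tolerance classes (1 = very
#' light-demanding, 5 = very shade tolerant), weighted by relative basal
#' area. Canopy-free cells (zero basal area) take a configurable neutral
#' default.
#'
#' @param shares Named numeric vector of basal-area shares (>= 0); names
#'   are species ids.
#' @param traits Data frame with columns `species` and `shade_tolerance`
#'   (classes in \[1, 5\]), e.g. from [default_species_params()].
#' @param no_canopy_default Value returned when all shares are zero
#'   (default 3, the scale midpoint).
#' @return Scalar in \[1, 5\].
#' @export
compute_weighted_stol <- function(shares, traits, no_canopy_default = 3) {
  stopifnot(is.numeric(shares), !is.null(names(shares)))
  if (any(shares < 0)) stop("basal-area shares must be >= 0", call. = FALSE)
  unknown <- setdiff(names(shares), traits$species)
  if (length(unknown)) {
    stop(sprintf("unknown species: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  if (sum(shares) == 0) return(no_canopy_default)
  classes <- traits$shade_tolerance[match(names(shares), traits$species)]
  sum(shares * classes) / sum(shares)
}

#' Canopy grid container
#'
#' Per-10 m-cell leaf area index and stand shade tolerance, refreshed
#' annually by the simulation engine.
#'
#' @param lai LAI matrix, m^2 m^-2, >= 0.
#' @param stol Shade-tolerance matrix, values in \[1, 5\].
#' @param last_update_year Simulation year of the last refresh.
#' @return A `canopy_grid` list.
#' @export
canopy_grid <- function(lai, stol, last_update_year = 0L) {
  stopifnot(is.matrix(lai), is.matrix(stol), identical(dim(lai), dim(stol)))
  if (any(lai < 0)) stop("LAI must be >= 0", call. = FALSE)
  if (any(stol < 1 | stol > 5)) stop("shade tolerance must lie in [1, 5]", call. = FALSE)
  structure(list(lai = lai, stol = stol,
                 last_update_year = as.integer(last_update_year)),
            class = "canopy_grid")
}

# Block-mean helper: mean over factor x factor blocks, optionally restricted
# to a mask; blocks without masked cells yield `empty`.
block_mean <- function(x, factor, mask = NULL, empty = NA_real_) {
  nr <- nrow(x); nc <- ncol(x)
  bi <- (row(x) - 1L) %/% factor; bj <- (col(x) - 1L) %/% factor
  idx <- as.vector(bi + bj * (nr %/% factor) + 1L)
  nb <- (nr %/% factor) * (nc %/% factor)
  m <- if (is.null(mask)) rep(1, nr * nc) else as.vector(mask) * 1
  sums <- rowsum(as.vector(x) * m, idx)
  cnts <- rowsum(m, idx)
  out <- rep(empty, nb)
  grp <- as.integer(rownames(sums))
  nonzero <- cnts[, 1] > 0
  out[grp[nonzero]] <- sums[nonzero, 1] / cnts[nonzero, 1]
  matrix(out, nr %/% factor, nc %/% factor)
}

#' Aggregate 10 m offsets to 100 m climate cells
#'
#' Averages each offset component (min, max, mean) over the stockable 10 m
#' cells of every 100 m cell. Cells without any stockable 10 m cell get
#' offsets (0, 0, 0): outside forest the open-air macroclimate applies
#' unmodified.
#'
#' @param offsets A list with matrices `min`, `max`, `mean` at 10 m
#'   resolution (as produced by the offset model applied per cell).
#' @param stockable Logical matrix, same shape.
#' @param factor Aggregation factor (default 10, i.e. 10 m to 100 m).
#' @return A list of matrices `min`, `max`, `mean` at the coarse
#'   resolution, plus `n_stockable` (count per coarse cell).
#' @export
aggregate_offsets <- function(offsets, stockable, factor = 10L) {
  stopifnot(is.list(offsets), all(c("min", "max", "mean") %in% names(offsets)))
  dm <- dim(offsets$min)
  if (!identical(dm, dim(offsets$max)) || !identical(dm, dim(offsets$mean)) ||
      !identical(dm, dim(stockable))) {
    stop("offset grids and stockable mask must share dimensions", call. = FALSE)
  }
  if (dm[1] %% factor != 0 || dm[2] %% factor != 0) {
    stop("grid dimensions must be multiples of the aggregation factor", call. = FALSE)
  }
  res <- lapply(offsets[c("min", "max", "mean")], block_mean,
                factor = factor, mask = stockable, empty = 0)
  res$n_stockable <- block_mean(stockable * 1, factor) * factor^2
  res
}
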