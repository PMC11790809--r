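#' Read / write grids as ESRI ASCII rasters
#'
#' Plain-text single-band raster exchange (.asc): a six-line header
#' (ncols, nrows, xllcorner, yllcorner, cellsize, NODATA_value) followed by
#' rows from north to south. Values equal to the nodata marker become `NA`
#' on read; `NA` is written as the nodata marker.
#'
#' @param path File path.
#' @return `read_ascii_grid()` returns a matrix with attributes
#'   `xllcorner`, `yllcorner`, `cellsize`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  for (i in 1:6) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
  }
  vals <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  attr(m, "xllcorner") <- hdr$xllcorner
  attr(m, "yllcorner") <- hdr$yllcorner
  attr(m, "cellsize") <- hdr$cellsize
  m
}

#' @param m Numeric matrix (rows north to south).
#' @param cellsize Cell edge, m.
#' @param xllcorner,yllcorner Lower-left corner coordinates.
#' @param nodata Nodata marker.
#' @rdname read_ascii_grid
#' @export
write_ascii_grid <- function(m, path, cellsize = 10, xllcorner = 0,
                             yllcorner = 0, nodata = -9999) {
  m2 <- m
  m2[is.na(m2)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(m)),
               sprintf("nrows %d", nrow(m)),
               sprintf("xllcorner %g", xllcorner),
               sprintf("yllcorner %g", yllcorner),
               sprintf("cellsize %g", cellsize),
               sprintf("NODATA_value %g", nodata)), con)
  utils::write.table(format(m2, trim = TRUE, scientific = FALSE), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Save / load a simulation configuration as JSON
#'
#' Serializes a [simulation_config()] to JSON and restores it, preserving
#' section structure (`offset_model`, `decomposition`, `beetle`,
#' `establishment`, `experiment`, `fixtures`).
#'
#' @param config A [simulation_config()].
#' @param path JSON file path.
#' @return `read_config_json()` returns a `simulation_config`.
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "simulation_config"))
  plain <- unclass(config)
  plain$fixtures <- unclass(plain$fixtures)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$fixtures <- do.call(fixture_spec, raw$fixtures)
  do.call(simulation_config, raw)
}
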