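# Plain-text raster and table I/O. Rasters travel as ESRI ASCII grids
# (.asc): a six-line header (ncols, nrows, xllcorner, yllcorner, cellsize,
# NODATA_value) followed by rows of values, north row first.

writeAsciiGrid <- function(values, path, cellSize, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", ncol(values)),
    paste("nrows", nrow(values)),
    "xllcorner 0", "yllcorner 0",
    paste("cellsize", format(cellSize, digits = 15)),
    paste("NODATA_value", nodata)), con)
  v <- values
  v[!is.finite(v)] <- nodata
  writeLines(apply(v, 1L, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = " ")), con)
  invisible(path)
}

readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  keys <- vapply(hdr, `[[`, "", 1L)
  vals <- as.numeric(vapply(hdr, `[[`, "", 2L))
  names(vals) <- keys
  nr <- as.integer(vals[["nrows"]]); nc <- as.integer(vals[["ncols"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  if (length(body) != nr * nc)
    stop("grid body has ", length(body), " values, expected ", nr * nc)
  values <- matrix(body, nr, nc, byrow = TRUE)
  values[values == vals[["nodata_value"]]] <- NA_real_
  list(values = values, cellSize = vals[["cellsize"]],
       nodata = vals[["nodata_value"]])
}

#' Write / read a land-use map as an ESRI ASCII grid
#'
#' Class codes round-trip exactly; the package's nodata code 0 is written as
#' the grid's NODATA value.
#'
#' @param map a [LandUseMap-class].
#' @param path file path (`.asc`).
#' @return `writeLandUse` returns the path invisibly; `readLandUse` returns
#'   a [LandUseMap-class].
#' @export
writeLandUse <- function(map, path) {
  stopifnot(is(map, "LandUseMap"))
  v <- map@grid
  v[v == NODATA] <- NA
  writeAsciiGrid(v, path, map@cellSize, nodata = -9999)
}

#' @rdname writeLandUse
#' @export
readLandUse <- function(path) {
  g <- readAsciiGrid(path)
  v <- g$values
  v[is.na(v)] <- NODATA
  landUseMap(matrix(as.integer(v), nrow(v), ncol(v)), g$cellSize)
}

#' Write / read a driver stack as one ASCII grid per layer
#'
#' Layers are written as `<prefix>_<layer>.asc` plus a `<prefix>_layers.csv`
#' manifest holding layer order and normalisation bounds.
#'
#' @param drivers a [DriverStack-class].
#' @param prefix path prefix for the layer files.
#' @param cellSize cell size recorded in the headers (default 30).
#' @return `writeDrivers` returns the manifest path invisibly;
#'   `readDrivers` returns a [DriverStack-class].
#' @export
writeDrivers <- function(drivers, prefix, cellSize = 30) {
  stopifnot(is(drivers, "DriverStack"))
  nm <- driverNames(drivers)
  for (i in seq_along(nm)) {
    writeAsciiGrid(drivers@values[, , i], paste0(prefix, "_", nm[i], ".asc"),
                   cellSize)
  }
  manifest <- data.frame(layer = nm, min = drivers@bounds[, 1L],
                         max = drivers@bounds[, 2L])
  write.csv(manifest, paste0(prefix, "_layers.csv"), row.names = FALSE)
  invisible(paste0(prefix, "_layers.csv"))
}

#' @rdname writeDrivers
#' @export
readDrivers <- function(prefix) {
  manifest <- read.csv(paste0(prefix, "_layers.csv"))
  grids <- lapply(manifest$layer, function(nm)
    readAsciiGrid(paste0(prefix, "_", nm, ".asc"))$values)
  shapes <- unique(lapply(grids, dim))
  if (length(shapes) != 1L) stop("driver layers do not share one shape")
  naPat <- lapply(grids, function(g) which(is.na(g)))
  if (length(unique(naPat)) != 1L)
    stop("nodata cells do not coincide across layers")
  values <- array(unlist(grids), dim = c(shapes[[1L]], length(grids)),
                  dimnames = list(NULL, NULL, manifest$layer))
  bounds <- as.matrix(manifest[, c("min", "max")])
  rownames(bounds) <- manifest$layer
  new("DriverStack", values = values, bounds = bounds)
}
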