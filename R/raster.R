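#' Create a RasterGrid
#'
#' @param values numeric matrix (row 1 = top of the map); `NA` marks nodata.
#' @param cellSize cell edge length in metres.
#' @param origin map coordinates of the top-left corner of cell `(1, 1)`.
#' @param crs text identifier of the projected CRS.
#' @return A [RasterGrid-class] object.
#' @examples
#' r <- RasterGrid(matrix(1:12, 3, 4), cellSize = 10)
#' dim(r)
#' @export
RasterGrid <- function(values, cellSize = 1, origin = c(0, 0), crs = "local") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("RasterGrid", values = values, cellSize = cellSize,
      origin = as.numeric(origin), crs = crs)
}

#' @describeIn RasterGrid the value matrix.
#' @param x,object a `RasterGrid`.
#' @export
rasterValues <- function(x) x@values

#' @describeIn RasterGrid cell size in metres.
#' @export
cellSize <- function(x) x@cellSize

#' @describeIn RasterGrid top-left corner coordinates.
#' @export
rasterOrigin <- function(x) x@origin

#' @export
setMethod("dim", "RasterGrid", function(x) dim(x@values))

setMethod("show", "RasterGrid", function(object) {
  v <- object@values
  cat("RasterGrid:", nrow(v), "x", ncol(v), "cells @", object@cellSize,
      "m | crs:", object@crs, "\n")
  cat("  origin (top-left):", object@origin[1], ",", object@origin[2], "\n")
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  values: [%.3g, %.3g], %d NA\n", min(fin), max(fin),
                sum(is.na(v))))
  else cat("  values: all NA\n")
})

## row/col of the cell containing each point; NA row for off-raster points
.cellIndex <- function(raster, xy) {
  xy <- matrix(xy, ncol = 2)
  s <- raster@cellSize
  col <- floor((xy[, 1] - raster@origin[1]) / s) + 1
  row <- floor((raster@origin[2] - xy[, 2]) / s) + 1
  ## top edge (y == y0) belongs to row 1 under the half-open convention
  row[xy[, 2] == raster@origin[2]] <- 1
  bad <- row < 1 | row > nrow(raster@values) | col < 1 | col > ncol(raster@values)
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

## map centre coordinates of cells given (row, col)
.cellCenter <- function(raster, rowcol) {
  rowcol <- matrix(rowcol, ncol = 2)
  s <- raster@cellSize
  cbind(x = raster@origin[1] + (rowcol[, 2] - 0.5) * s,
        y = raster@origin[2] - (rowcol[, 1] - 0.5) * s)
}

#' Extract raster values at point coordinates
#'
#' Returns the value of the cell containing each point (no interpolation).
#' Points outside the raster yield `NA`.
#'
#' @param raster a [RasterGrid-class].
#' @param xy two-column matrix of map coordinates.
#' @return numeric vector of cell values.
#' @export
extractAt <- function(raster, xy) {
  idx <- .cellIndex(raster, xy)
  out <- rep(NA_real_, nrow(idx))
  ok <- !is.na(idx[, 1])
  out[ok] <- raster@values[cbind(idx[ok, 1], idx[ok, 2])]
  out
}

#' Aggregate a raster to a coarser resolution by block mean
#'
#' Nodata cells never enter the mean; a block that is entirely nodata stays
#' nodata. The target cell size must be an integer multiple of the source.
#'
#' @param raster source [RasterGrid-class].
#' @param targetCell target cell size in metres.
#' @return a coarser [RasterGrid-class] with the same origin and CRS.
#' @export
aggregateRaster <- function(raster, targetCell) {
  f <- targetCell / raster@cellSize
  if (abs(f - round(f)) > 1e-9)
    stop("targetCell must be an integer multiple of the source cell size")
  f <- as.integer(round(f))
  if (f == 1L) return(raster)
  v <- raster@values
  nr <- floor(nrow(v) / f); nc <- floor(ncol(v) / f)
  if (nr < 1 || nc < 1) stop("raster smaller than one target cell")
  v <- v[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  grp_r <- rep(seq_len(nr), each = f)
  grp_c <- rep(seq_len(nc), each = f)
  sums <- rowsum(v, grp_r, na.rm = TRUE)
  cnts <- rowsum((!is.na(v)) + 0, grp_r)
  sums <- t(rowsum(t(sums), grp_c, na.rm = TRUE))
  cnts <- t(rowsum(t(cnts), grp_c))
  out <- sums / cnts
  out[cnts == 0] <- NA_real_
  dimnames(out) <- NULL
  RasterGrid(out, cellSize = targetCell, origin = raster@origin,
             crs = raster@crs)
}

#' Read and write rasters as Esri ASCII grids
#'
#' Plain-text raster exchange format carrying grid registration (corner,
#' cell size, nodata sentinel). Values are written row-major from the top of
#' the map, matching the internal orientation.
#'
#' @param path file path.
#' @param crs CRS identifier to attach on read (the format itself carries
#'   none).
#' @return `readAsciiGrid` returns a [RasterGrid-class];
#'   `writeAsciiGrid` invisibly returns `path`.
#' @export
readAsciiGrid <- function(path, crs = "local") {
  head <- readLines(path, n = 6L)
  kv <- strsplit(trimws(head), "\\s+")
  keys <- tolower(vapply(kv, `[`, "", 1L))
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  names(vals) <- keys
  nc <- as.integer(vals[["ncols"]]); nr <- as.integer(vals[["nrows"]])
  s <- vals[["cellsize"]]
  nodata <- if ("nodata_value" %in% keys) vals[["nodata_value"]] else -9999
  dat <- scan(path, skip = 6L, quiet = TRUE)
  if (length(dat) != nr * nc) stop("ASCII grid payload size mismatch")
  m <- matrix(dat, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  origin <- c(vals[["xllcorner"]], vals[["yllcorner"]] + nr * s)
  RasterGrid(m, cellSize = s, origin = origin, crs = crs)
}

#' @rdname readAsciiGrid
#' @param raster a [RasterGrid-class] to write.
#' @param nodata sentinel written for `NA` cells.
#' @export
writeAsciiGrid <- function(raster, path, nodata = -9999) {
  v <- raster@values
  nr <- nrow(v); nc <- ncol(v); s <- raster@cellSize
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    paste("ncols", nc), paste("nrows", nr),
    paste("xllcorner", format(raster@origin[1], digits = 15)),
    paste("yllcorner", format(raster@origin[2] - nr * s, digits = 15)),
    paste("cellsize", format(s, digits = 15)),
    paste("NODATA_value", nodata)), con)
  v[is.na(v)] <- nodata
  for (i in seq_len(nr))
    writeLines(paste(format(v[i, ], trim = TRUE, digits = 10),
                     collapse = " "), con)
  invisible(path)
}
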