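#' Georeferenced raster grid
#'
#' Light container for a single-band surface (e.g. a canopy height model, in
#' meters, with an explicit no-data marker) or a 3-band color image (e.g. an
#' orthomosaic). Values are stored as a matrix (1 band) or an
#' `nrow x ncol x 3` array. The grid uses a fixed convention: the origin is
#' the minimum x/y corner, row 1 is the northernmost (maximum-y) row, and
#' cells are half-open intervals `[x0 + (j-1)*cell, x0 + j*cell)`.
#'
#' @param values Numeric matrix (1 band) or 3-dimensional array (3 bands).
#' @param origin Numeric length-2, x/y of the lower-left corner in meters.
#' @param cell Cell size in meters (square cells).
#' @param nodata No-data marker for 1-band grids (default `NA_real_`).
#'
#' @return An object of class `raster_grid`.
#' @export
raster_grid <- function(values, origin = c(0, 0), cell = 1, nodata = NA_real_) {
  if (!is.numeric(cell) || length(cell) != 1 || cell <= 0) {
    stop("`cell` must be a single positive number", call. = FALSE)
  }
  nb <- if (length(dim(values)) == 3) dim(values)[3] else 1L
  if (!nb %in% c(1L, 3L)) stop("`values` must have 1 or 3 bands", call. = FALSE)
  if (nb == 1L) values <- as.matrix(values)
  structure(
    list(values = values, origin = as.numeric(origin[1:2]), cell = cell,
         nodata = nodata, bands = nb),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf(
    "<raster_grid> %d x %d cells, %d band(s), cell %.4g m, origin (%.2f, %.2f)\n",
    nrow(x$values), ncol(x$values), x$bands, x$cell, x$origin[1], x$origin[2]
  ))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

grid_nrow <- function(g) dim(g$values)[1]
grid_ncol <- function(g) dim(g$values)[2]

#' Map x/y coordinates to raster row/column indices
#'
#' Row 1 is the maximum-y row; cells are half-open on their low edge.
#' Coordinates outside the grid return NA indices.
#'
#' @param grid A [raster_grid()].
#' @param x,y Coordinate vectors in meters.
#' @return A list with integer vectors `row` and `col`.
#' @keywords internal
#' @export
grid_rowcol <- function(grid, x, y) {
  # tiny guard keeps points on exact cell edges in the upper cell despite
  # floating-point representation of the division
  col <- floor((x - grid$origin[1]) / grid$cell + 1e-7) + 1L
  row_from_bottom <- floor((y - grid$origin[2]) / grid$cell + 1e-7) + 1L
  row <- grid_nrow(grid) - row_from_bottom + 1L
  bad <- col < 1L | col > grid_ncol(grid) | row < 1L | row > grid_nrow(grid)
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Cell-center coordinates for raster rows/columns
#'
#' @param grid A [raster_grid()].
#' @param row,col Integer index vectors.
#' @return A list with numeric vectors `x` and `y` (cell centers, meters).
#' @keywords internal
#' @export
grid_xy <- function(grid, row, col) {
  x <- grid$origin[1] + (col - 0.5) * grid$cell
  y <- grid$origin[2] + (grid_nrow(grid) - row + 0.5) * grid$cell
  list(x = x, y = y)
}

#' Write / read a raster as TIFF plus ESRI world file
#'
#' Pixel values are stored in a standard TIFF; georeferencing (cell size and
#' upper-left cell-center coordinates) is stored in a plain-text ESRI world
#' file next to it (`.tfw`), the classic sidecar convention for georeferenced
#' imagery. Color grids are stored as 8-bit samples scaled by the color bit
#' depth (lossless for 8-bit colors). Height grids (1 band) are stored as
#' 16-bit samples at millimeter precision, which covers heights 0 to
#' 65.534 m; the top code is reserved for no-data.
#'
#' @param grid A [raster_grid()].
#' @param path Output path (`.tif`); the world file replaces the extension
#'   with `.tfw`.
#' @param depth Color bit depth used to scale 3-band grids (default 8).
#' @return `write_raster`: `path`, invisibly. `read_raster`: a [raster_grid()].
#' @export
write_raster <- function(grid, path, depth = 8L) {
  stopifnot(inherits(grid, "raster_grid"))
  v <- grid$values
  if (grid$bands == 3L) {
    v <- pmin(pmax(v / (2^depth - 1), 0), 1)
    bps <- 8L
  } else {
    nodata_mask <- is.na(v) | (!is.na(grid$nodata) & v == grid$nodata)
    v <- pmin(pmax(round(v * 1000), 0), 65534) / 65535
    v[nodata_mask] <- 1
    v <- array(v, dim = c(dim(v), 1L))
    bps <- 16L
  }
  tiff::writeTIFF(v, path, bits.per.sample = bps)
  tfw <- sub("\\.[^.]+$", ".tfw", path)
  ul <- grid_xy(grid, 1L, 1L)
  writeLines(format(c(grid$cell, 0, 0, -grid$cell, ul$x, ul$y), digits = 12), tfw)
  invisible(path)
}

#' @rdname write_raster
#' @param nodata No-data marker to restore on read for 1-band rasters.
#' @export
read_raster <- function(path, depth = 8L, nodata = NA_real_) {
  v <- tiff::readTIFF(path)
  tfw <- sub("\\.[^.]+$", ".tfw", path)
  if (!file.exists(tfw)) stop("world file not found: ", tfw, call. = FALSE)
  w <- as.numeric(readLines(tfw))
  cell <- w[1]
  nb <- if (length(dim(v)) == 3 && dim(v)[3] >= 3) 3L else 1L
  if (nb == 3L) {
    v <- round(v[, , 1:3, drop = FALSE] * (2^depth - 1))
  } else {
    if (length(dim(v)) == 3) v <- v[, , 1]
    code <- round(v * 65535)
    v <- code / 1000
    v[code == 65535] <- nodata
  }
  nr <- dim(v)[1]
  origin <- c(w[5] - cell / 2, w[6] + cell / 2 - nr * cell)
  raster_grid(v, origin = origin, cell = cell, nodata = nodata)
}
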