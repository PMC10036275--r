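#' Remove near-ground points from a height-normalized cloud
#'
#' Drops every point strictly below `min_height` above ground. Points exactly
#' at the threshold are retained. Understory and ground returns below 2 m are
#' excluded from all crown analyses; plots where fire consumed every crown
#' can legitimately come out empty, so an empty result is a warning, not an
#' error. Idempotent.
#'
#' @param cloud Height-normalized point cloud data frame.
#' @param min_height Minimum height above ground to keep, meters (default 2).
#' @return The filtered point cloud; attribute `n_removed` records the count.
#' @export
preprocess <- function(cloud, min_height = 2.0) {
  keep <- cloud$z >= min_height
  out <- dplyr::filter(cloud, keep)
  if (nrow(out) == 0 && nrow(cloud) > 0) {
    warning("no points at or above ", min_height,
            " m; returning an empty cloud", call. = FALSE)
  }
  out <- as_point_cloud(out, bit_depth = bit_depth(cloud))
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Normalize elevations to height above ground by grid minima
#'
#' A simple terrain normalizer for clouds still carrying absolute elevation:
#' the ground surface is taken as the per-cell minimum elevation on a coarse
#' grid, interpolated bilinearly between cell centers, and subtracted from
#' every point. This is deliberately basic plumbing — it assumes ground is
#' visible in every cell (open or recently burned stands) — and stands in
#' for a full ground-classification workflow, which is outside this
#' package's scope.
#'
#' @param cloud Point cloud with raw `z` elevations.
#' @param cell Grid cell size in meters (default 5).
#' @return The cloud with `z` replaced by height above ground.
#' @export
normalize_by_grid_minimum <- function(cloud, cell = 5.0) {
  if (nrow(cloud) == 0) return(cloud)
  rx <- range(cloud$x); ry <- range(cloud$y)
  nx <- max(1L, ceiling((rx[2] - rx[1]) / cell))
  ny <- max(1L, ceiling((ry[2] - ry[1]) / cell))
  ix <- pmin(pmax(floor((cloud$x - rx[1]) / cell) + 1L, 1L), nx)
  iy <- pmin(pmax(floor((cloud$y - ry[1]) / cell) + 1L, 1L), ny)
  idx <- (iy - 1L) * nx + ix
  gmin <- tapply(cloud$z, idx, min)
  zmin <- matrix(NA_real_, nrow = ny, ncol = nx)
  cells <- as.integer(names(gmin))
  zmin[cbind((cells - 1L) %/% nx + 1L, (cells - 1L) %% nx + 1L)] <- gmin
  # fill cells with no points from their nearest filled neighbor
  if (anyNA(zmin)) {
    filled <- which(!is.na(zmin), arr.ind = TRUE)
    holes <- which(is.na(zmin), arr.ind = TRUE)
    for (k in seq_len(nrow(holes))) {
      d2 <- (filled[, 1] - holes[k, 1])^2 + (filled[, 2] - holes[k, 2])^2
      zmin[holes[k, 1], holes[k, 2]] <- zmin[filled[which.min(d2), , drop = FALSE]]
    }
  }
  # bilinear interpolation of the ground surface at each point
  cx <- rx[1] + (seq_len(nx) - 0.5) * cell
  cy <- ry[1] + (seq_len(ny) - 0.5) * cell
  fx <- pmin(pmax((cloud$x - cx[1]) / cell, 0), nx - 1)
  fy <- pmin(pmax((cloud$y - cy[1]) / cell, 0), ny - 1)
  x0 <- pmin(floor(fx) + 1L, nx); x1 <- pmin(x0 + 1L, nx)
  y0 <- pmin(floor(fy) + 1L, ny); y1 <- pmin(y0 + 1L, ny)
  wx <- fx - (x0 - 1L); wy <- fy - (y0 - 1L)
  ground <- (1 - wx) * (1 - wy) * zmin[cbind(y0, x0)] +
    wx * (1 - wy) * zmin[cbind(y0, x1)] +
    (1 - wx) * wy * zmin[cbind(y1, x0)] +
    wx * wy * zmin[cbind(y1, x1)]
  out <- dplyr::mutate(cloud, z = .data$z - ground)
  as_point_cloud(out, bit_depth = bit_depth(cloud))
}

#' Green Leaf Index
#'
#' The RGB greenness index `(2G - R - B) / (2G + R + B)`, in `[-1, 1]`:
#' positive for green vegetation, near zero for gray/bare surfaces, negative
#' for red/brown (scorched) material. Scale-invariant in the bands, so it is
#' insensitive to uniform brightness changes such as shading. Defined as 0
#' where the denominator is 0 (black pixels).
#'
#' @param r,g,b Non-negative band values on a common scale.
#' @return Numeric vector of GLI values.
#' @export
gli <- function(r, g, b) {
  if (any(r < 0 | g < 0 | b < 0, na.rm = TRUE)) {
    stop("negative band values are not valid colors", call. = FALSE)
  }
  num <- 2 * g - r - b
  den <- 2 * g + r + b
  out <- ifelse(den == 0, 0, num / den)
  as.numeric(out)
}
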