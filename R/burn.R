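#' Refine the point set of a crown before hull construction
#'
#' Two filters that keep the extracted crown footprint clear of ground and
#' neighboring features: (1) points below the 25th percentile of the
#' segment's point heights are dropped (linear-interpolation percentile; an
#' alternative reading, a fraction of the maximum height, is available via
#' `percentile_of_max`); (2) an isolated-voxels filter drops points whose
#' occupied voxel has no occupied neighbor among its 26 surrounding voxels.
#'
#' @param points Tibble with `x`, `y`, `z` (one segment's member points).
#' @param height_percentile Percentile of point heights below which points
#'   are removed (default 0.25).
#' @param ivf_voxel Voxel edge length for the isolation filter, meters.
#' @param percentile_of_max If `TRUE`, interpret the height cutoff as
#'   `height_percentile * max(z)` instead of a distribution percentile.
#' @return The retained points; attribute `unclassifiable` is `TRUE` when
#'   fewer than 4 points remain.
#' @export
refine_crown_points <- function(points, height_percentile = 0.25,
                                ivf_voxel = 0.5, percentile_of_max = FALSE) {
  if (nrow(points) < 4) {
    out <- points[0, ]
    attr(out, "unclassifiable") <- TRUE
    return(out)
  }
  cutoff <- if (percentile_of_max) {
    height_percentile * max(points$z)
  } else {
    stats::quantile(points$z, height_percentile, names = FALSE)
  }
  out <- points[points$z >= cutoff, , drop = FALSE]
  if (nrow(out) > 0 && ivf_voxel > 0) {
    vx <- floor(out$x / ivf_voxel)
    vy <- floor(out$y / ivf_voxel)
    vz <- floor(out$z / ivf_voxel)
    key <- paste(vx, vy, vz)
    occ <- unique(key)
    occ_set <- new.env(hash = TRUE, parent = emptyenv())
    for (k in occ) assign(k, TRUE, envir = occ_set)
    has_neighbor <- vapply(occ, function(k) {
      v <- as.numeric(strsplit(k, " ", fixed = TRUE)[[1]])
      for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
        if (dx == 0 && dy == 0 && dz == 0) next
        if (exists(paste(v[1] + dx, v[2] + dy, v[3] + dz), envir = occ_set,
                   inherits = FALSE)) {
          return(TRUE)
        }
      }
      FALSE
    }, logical(1))
    isolated <- occ[!has_neighbor]
    out <- out[!key %in% isolated, , drop = FALSE]
  }
  attr(out, "unclassifiable") <- nrow(out) < 4
  out
}

#' Concave hull of a crown's points
#'
#' Builds a detailed concave outline by rasterizing the points onto a fine
#' occupancy grid (cell size `grid_factor` times the median nearest-neighbor
#' spacing), closing single-cell gaps, and tracing the largest closed
#' contour of the occupancy mask. Degenerate geometry (fewer than 4 distinct
#' planar positions, near-collinear sets, or a failed trace) falls back to
#' the convex hull, buffered when the points are collinear.
#'
#' @param points Tibble with `x`, `y`.
#' @param grid_factor Occupancy cell size as a multiple of the median
#'   nearest-neighbor spacing (default 2).
#' @return A two-column matrix (`x`, `y`) tracing a closed polygon.
#' @export
crown_hull <- function(points, grid_factor = 2) {
  xy <- unique(cbind(points$x, points$y))
  n <- nrow(xy)
  if (n == 0) stop("no points to hull", call. = FALSE)
  if (n < 3 || all(abs(xy[, 1] - xy[1, 1]) < 1e-9) ||
      all(abs(xy[, 2] - xy[1, 2]) < 1e-9)) {
    warning("degenerate crown geometry; returning a buffered hull", call. = FALSE)
    return(buffered_hull(xy, 0.1))
  }
  ch <- grDevices::chull(xy)
  convex <- xy[c(ch, ch[1]), , drop = FALSE]
  if (abs(polygon_area(convex[, 1], convex[, 2])) < 1e-6) {
    warning("collinear crown points; returning a buffered hull", call. = FALSE)
    return(buffered_hull(xy, 0.1))
  }
  if (n < 8) return(unname_poly(convex))
  spacing <- stats::median(nn_dist(xy))
  cell <- max(grid_factor * spacing, 1e-3)
  x0 <- min(xy[, 1]) - cell; y0 <- min(xy[, 2]) - cell
  nc <- as.integer(ceiling((max(xy[, 1]) - x0) / cell)) + 2L
  nr <- as.integer(ceiling((max(xy[, 2]) - y0) / cell)) + 2L
  if (nc * nr > 4e6) return(unname_poly(convex))
  mask <- matrix(0, nr, nc)
  g <- raster_grid(mask, origin = c(x0, y0), cell = cell)
  rc <- grid_rowcol(g, xy[, 1], xy[, 2])
  mask[cbind(rc$row, rc$col)] <- 1
  mask <- binary_close(mask)
  poly <- mask_polygon(mask, g)
  if (is.null(poly)) return(unname_poly(convex))
  unname_poly(poly)
}

unname_poly <- function(m) {
  m <- unname(as.matrix(m))
  colnames(m) <- c("x", "y")
  m
}

buffered_hull <- function(xy, buffer) {
  cx <- range(xy[, 1]) + c(-buffer, buffer)
  cy <- range(xy[, 2]) + c(-buffer, buffer)
  unname_poly(cbind(x = cx[c(1, 2, 2, 1, 1)], y = cy[c(1, 1, 2, 2, 1)]))
}

# nearest-neighbor distance per point (fine for crown-sized sets)
nn_dist <- function(xy) {
  n <- nrow(xy)
  if (n > 4000) {
    # deterministic thinning keeps the spacing estimate stable
    idx <- unique(as.integer(round(seq(1, n, length.out = 4000))))
    xy_q <- xy[idx, , drop = FALSE]
  } else {
    xy_q <- xy
  }
  d <- as.matrix(stats::dist(xy_q))
  diag(d) <- Inf
  apply(d, 1, min)
}

# one pass of 3x3 dilation followed by erosion (morphological closing)
binary_close <- function(m) {
  shift_or <- function(a) {
    out <- a
    nr <- nrow(a); nc <- ncol(a)
    out[-1, ] <- pmax(out[-1, ], a[-nr, ])
    out[-nr, ] <- pmax(out[-nr, ], a[-1, ])
    out[, -1] <- pmax(out[, -1], a[, -nc])
    out[, -nc] <- pmax(out[, -nc], a[, -1])
    out
  }
  shift_and <- function(a) {
    out <- a
    nr <- nrow(a); nc <- ncol(a)
    out[-1, ] <- pmin(out[-1, ], a[-nr, ])
    out[-nr, ] <- pmin(out[-nr, ], a[-1, ])
    out[, -1] <- pmin(out[, -1], a[, -nc])
    out[, -nc] <- pmin(out[, -nc], a[, -1])
    out
  }
  shift_and(shift_or(m))
}

#' Extract orthomosaic pixels inside a crown hull
#'
#' Selects every pixel whose center falls inside the polygon
#' (center-containment rule) and returns its color bands.
#'
#' @param ortho 3-band [raster_grid()].
#' @param hull Two-column polygon matrix from [crown_hull()].
#' @return Tibble with `x`, `y`, `r`, `g`, `b`; attribute `unclassifiable`
#'   is `TRUE` when no pixel center falls inside the hull.
#' @export
extract_crown_pixels <- function(ortho, hull) {
  stopifnot(inherits(ortho, "raster_grid"), ortho$bands == 3L)
  nr <- nrow(ortho$values); nc <- ncol(ortho$values)
  cell <- ortho$cell; x0 <- ortho$origin[1]; y0 <- ortho$origin[2]
  empty <- tibble::tibble(x = numeric(0), y = numeric(0), r = numeric(0),
                          g = numeric(0), b = numeric(0))
  overlap <- max(hull[, 1]) >= x0 && min(hull[, 1]) <= x0 + nc * cell &&
    max(hull[, 2]) >= y0 && min(hull[, 2]) <= y0 + nr * cell
  if (!overlap) {
    attr(empty, "unclassifiable") <- TRUE
    return(empty)
  }
  col_lo <- max(1L, as.integer(floor((min(hull[, 1]) - x0) / cell)) + 1L)
  col_hi <- min(nc, as.integer(floor((max(hull[, 1]) - x0) / cell)) + 1L)
  row_lo <- max(1L, nr - (as.integer(floor((max(hull[, 2]) - y0) / cell)) + 1L) + 1L)
  row_hi <- min(nr, nr - (as.integer(floor((min(hull[, 2]) - y0) / cell)) + 1L) + 1L)
  if (col_lo > col_hi || row_lo > row_hi) {
    attr(empty, "unclassifiable") <- TRUE
    return(empty)
  }
  rows <- row_lo:row_hi
  cols <- col_lo:col_hi
  grid_pts <- expand.grid(row = rows, col = cols)
  xy <- grid_xy(ortho, grid_pts$row, grid_pts$col)
  inside <- mgcv::in.out(rbind(hull, hull[1, ]), cbind(xy$x, xy$y))
  if (!any(inside)) {
    attr(empty, "unclassifiable") <- TRUE
    return(empty)
  }
  rsel <- grid_pts$row[inside]; csel <- grid_pts$col[inside]
  plane <- nr * nc
  lin <- (csel - 1L) * nr + rsel
  out <- tibble::tibble(
    x = xy$x[inside], y = xy$y[inside],
    r = ortho$values[lin],
    g = ortho$values[lin + plane],
    b = ortho$values[lin + 2L * plane]
  )
  attr(out, "unclassifiable") <- FALSE
  out
}

#' Classify one crown as burned or unburned
#'
#' Computes the fraction of pixels with strictly positive Green Leaf Index
#' and labels the crown `"burned"` when that fraction is below `threshold`
#' and `"unburned"` otherwise (the boundary value maps to unburned).
#'
#' @param pixels Pixel tibble from [extract_crown_pixels()].
#' @param threshold Positive-GLI fraction at and above which a crown is
#'   called unburned (default 0.5).
#' @return One-row tibble: `positive_gli_fraction`, `label`, `n_pixels`.
#' @export
classify_burn <- function(pixels, threshold = 0.5) {
  if (nrow(pixels) < 1) {
    stop("no pixels: crown is unclassifiable", call. = FALSE)
  }
  frac <- mean(gli(pixels$r, pixels$g, pixels$b) > 0)
  tibble::tibble(
    positive_gli_fraction = frac,
    label = if (frac < threshold) "burned" else "unburned",
    n_pixels = nrow(pixels)
  )
}

#' Classify every segmented crown from the orthomosaic
#'
#' Per-segment pipeline: refine the member points, trace the concave hull,
#' extract orthomosaic pixels under the hull, and classify from the
#' positive-GLI fraction. Crowns whose refined point set or pixel set is
#' too small come back flagged `unclassifiable` with an `NA` label.
#'
#' @param segments Segment tibble from [segment_crowns()].
#' @param cloud The point cloud the segments index into.
#' @param ortho 3-band orthomosaic [raster_grid()].
#' @param threshold Positive-GLI classification threshold.
#' @param height_percentile,ivf_voxel,grid_factor Passed to the refinement
#'   and hull steps.
#' @return Tibble: `tree_id`, `positive_gli_fraction`, `label`, `n_pixels`,
#'   `unclassifiable`, plus a `hull` list-column.
#' @export
classify_crowns <- function(segments, cloud, ortho, threshold = 0.5,
                            height_percentile = 0.25, ivf_voxel = 0.5,
                            grid_factor = 2) {
  purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    idx <- segments$point_idx[[i]]
    base <- tibble::tibble(
      tree_id = segments$tree_id[i], positive_gli_fraction = NA_real_,
      label = NA_character_, n_pixels = 0L, unclassifiable = TRUE,
      hull = list(NULL)
    )
    if (length(idx) < 4) return(base)
    pts <- refine_crown_points(cloud[idx, ], height_percentile, ivf_voxel)
    if (isTRUE(attr(pts, "unclassifiable"))) return(base)
    hull <- crown_hull(pts, grid_factor)
    px <- extract_crown_pixels(ortho, hull)
    if (isTRUE(attr(px, "unclassifiable")) || nrow(px) == 0) {
      base$hull <- list(hull)
      return(base)
    }
    call <- classify_burn(px, threshold)
    tibble::tibble(
      tree_id = segments$tree_id[i],
      positive_gli_fraction = call$positive_gli_fraction,
      label = call$label, n_pixels = call$n_pixels,
      unclassifiable = FALSE, hull = list(hull)
    )
  })
}
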