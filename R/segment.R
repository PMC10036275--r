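#' Build a canopy height model from a point cloud
#'
#' Rasterizes the cloud to a grid whose cells take the maximum point height
#' within them; cells containing no points are no-data. The 10-cm default
#' matches the resolution at which crowns are segmented.
#'
#' @param cloud Preprocessed (height-normalized, ground-free) point cloud.
#' @param cell Cell size, meters.
#' @return A 1-band [raster_grid()] (heights in meters, `NA` = no data).
#' @export
build_chm <- function(cloud, cell = 0.10) {
  if (nrow(cloud) == 0) stop("cannot build a CHM from an empty cloud", call. = FALSE)
  x0 <- min(cloud$x); y0 <- min(cloud$y)
  nc <- max(1L, as.integer(ceiling((max(cloud$x) - x0) / cell + 1e-9)))
  nr <- max(1L, as.integer(ceiling((max(cloud$y) - y0) / cell + 1e-9)))
  g <- raster_grid(matrix(NA_real_, nr, nc), origin = c(x0, y0), cell = cell)
  rc <- grid_rowcol(g, cloud$x, cloud$y)
  ok <- !is.na(rc$row)
  idx <- (rc$col[ok] - 1L) * nr + rc$row[ok]
  mx <- tapply(cloud$z[ok], idx, max)
  g$values[as.integer(names(mx))] <- mx
  g
}

#' Smooth a canopy height model with a Gaussian kernel
#'
#' Separable Gaussian convolution with reflected edges. `sigma` is given in
#' map units (meters) and converted to cells by the grid's cell size, so
#' behavior is resolution-independent: the 0.05-m default is half a cell on
#' the 10-cm default CHM. No-data cells are filled with 0 (treated as
#' ground) before smoothing so the watershed sees a complete surface.
#'
#' @param chm A 1-band [raster_grid()].
#' @param sigma Gaussian standard deviation in meters.
#' @return The smoothed [raster_grid()] (no no-data cells remain).
#' @export
smooth_chm <- function(chm, sigma = 0.05) {
  stopifnot(inherits(chm, "raster_grid"), chm$bands == 1L)
  v <- chm$values
  v[is.na(v) | (!is.na(chm$nodata) & v == chm$nodata)] <- 0
  if (!is.finite(sigma) || sigma <= 0) {
    warning("`sigma` must be positive; returning the unsmoothed CHM", call. = FALSE)
    return(raster_grid(v, origin = chm$origin, cell = chm$cell))
  }
  sd_cells <- sigma / chm$cell
  half <- max(1L, as.integer(ceiling(3 * sd_cells)))
  k <- stats::dnorm(-half:half, sd = sd_cells)
  k <- k / sum(k)
  reflect_pad <- function(m, n) {
    top <- m[pmin(n:1, nrow(m)), , drop = FALSE]
    bot <- m[pmax(nrow(m) - 0:(n - 1), 1L), , drop = FALSE]
    rbind(top, m, bot)
  }
  conv_rows <- function(m) {
    p <- reflect_pad(m, half)
    out <- matrix(0, nrow(m), ncol(m))
    for (i in seq_along(k)) {
      out <- out + k[i] * p[(i - 1) + seq_len(nrow(m)), , drop = FALSE]
    }
    out
  }
  sm <- t(conv_rows(t(conv_rows(v))))
  raster_grid(sm, origin = chm$origin, cell = chm$cell)
}

#' Detect treetops with a variable-window local-maximum filter
#'
#' A cell is a treetop when it is the strict maximum of a circular window
#' whose radius grows with canopy height — taller trees claim larger
#' windows, suppressing shoulders of big crowns while keeping small trees
#' detectable. The default allometry is `radius(h) = max(0.6, 0.05 h + 0.6)`
#' meters. Equal-height neighboring maxima are resolved deterministically
#' (smallest row, then column, survives).
#'
#' @param chm_smooth Smoothed 1-band [raster_grid()].
#' @param min_height Minimum treetop height, meters.
#' @param window_fn Function mapping height (m) to window radius (m).
#' @return Tibble of treetops: `x`, `y`, `height`, `row`, `col`.
#' @export
detect_treetops <- function(chm_smooth, min_height = 2.0,
                            window_fn = function(h) pmax(0.6, 0.05 * h + 0.6)) {
  stopifnot(inherits(chm_smooth, "raster_grid"), chm_smooth$bands == 1L)
  v <- chm_smooth$values
  rad_m <- matrix(window_fn(as.vector(v)), nrow(v), ncol(v))
  rc <- local_maxima_cpp(v, rad_m / chm_smooth$cell, min_height)
  if (nrow(rc) == 0) {
    return(tibble::tibble(x = numeric(0), y = numeric(0), height = numeric(0),
                          row = integer(0), col = integer(0)))
  }
  xy <- grid_xy(chm_smooth, rc[, 1], rc[, 2])
  tibble::tibble(x = xy$x, y = xy$y, height = v[rc],
                 row = rc[, 1], col = rc[, 2])
}

# largest closed contour of a binary mask, as an (x, y) polygon in meters
mask_polygon <- function(mask, grid) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(0, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  xs <- grid$origin[1] + (seq_len(nc + 2L) - 1.5) * grid$cell
  ys <- grid$origin[2] + (seq_len(nr + 2L) - 1.5) * grid$cell
  # contourLines wants z[i, j] at (x[i], y[j]); our rows run north->south
  z <- t(pad[rev(seq_len(nr + 2L)), , drop = FALSE])
  cl <- grDevices::contourLines(x = xs, y = ys, z = z, levels = 0.5)
  if (!length(cl)) return(NULL)
  areas <- vapply(cl, function(p) abs(polygon_area(p$x, p$y)), numeric(1))
  best <- cl[[which.max(areas)]]
  cbind(x = best$x, y = best$y)
}

# signed shoelace area
polygon_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

#' Delineate crown segments by marker-controlled watershed
#'
#' Floods the smoothed CHM outward from the treetop markers (Meyer-style
#' priority flooding on the inverted surface), so that every cell at or
#' above `min_height` reachable from a marker is assigned to exactly one
#' crown. Crown boundary polygons are traced from the label map, segment
#' areas are measured from the traced polygons, and cloud points are
#' attached to segments through the label raster (plan-view containment at
#' cell resolution).
#'
#' @param chm_smooth Smoothed 1-band [raster_grid()].
#' @param tops Treetop tibble from [detect_treetops()].
#' @param cloud Optional point cloud whose points are assigned to segments.
#' @param min_height Minimum canopy height flooded, meters.
#' @return Tibble of segments (`tree_id`, apex coordinates and height,
#'   `area`, list-columns `boundary` and `point_idx`), with the label
#'   raster attached as attribute `"labels"`.
#' @export
segment_crowns <- function(chm_smooth, tops, cloud = NULL, min_height = 2.0) {
  stopifnot(inherits(chm_smooth, "raster_grid"))
  inside <- tops$row >= 1 & tops$row <= nrow(chm_smooth$values) &
    tops$col >= 1 & tops$col <= ncol(chm_smooth$values)
  if (any(!inside)) {
    warning(sum(!inside), " treetop(s) outside the CHM extent were skipped",
            call. = FALSE)
    tops <- tops[inside, ]
  }
  empty <- tibble::tibble(
    tree_id = integer(0), apex_x = numeric(0), apex_y = numeric(0),
    apex_height = numeric(0), area = numeric(0),
    boundary = list(), point_idx = list()
  )
  if (nrow(tops) == 0) {
    attr(empty, "labels") <- raster_grid(
      matrix(0L, nrow(chm_smooth$values), ncol(chm_smooth$values)),
      origin = chm_smooth$origin, cell = chm_smooth$cell)
    return(empty)
  }
  labels <- ws_flood_cpp(chm_smooth$values,
                         cbind(tops$row, tops$col), min_height)
  lab_grid <- raster_grid(labels, origin = chm_smooth$origin,
                          cell = chm_smooth$cell)
  pt_lab <- NULL
  if (!is.null(cloud) && nrow(cloud) > 0) {
    rc <- grid_rowcol(lab_grid, cloud$x, cloud$y)
    pt_lab <- rep(0L, nrow(cloud))
    ok <- !is.na(rc$row)
    pt_lab[ok] <- labels[cbind(rc$row[ok], rc$col[ok])]
    pt_lab[ok][cloud$z[ok] < min_height] <- 0L
  }
  segs <- purrr::map_dfr(seq_len(nrow(tops)), function(i) {
    mask <- labels == i
    if (!any(mask)) return(NULL)
    poly <- mask_polygon(mask * 1, lab_grid)
    area <- if (is.null(poly)) sum(mask) * lab_grid$cell^2 else
      abs(polygon_area(poly[, 1], poly[, 2]))
    tibble::tibble(
      tree_id = i, apex_x = tops$x[i], apex_y = tops$y[i],
      apex_height = tops$height[i], area = area,
      boundary = list(poly),
      point_idx = list(if (is.null(pt_lab)) integer(0) else which(pt_lab == i))
    )
  })
  if (is.null(segs) || nrow(segs) == 0) segs <- empty
  attr(segs, "labels") <- lab_grid
  segs
}

#' Filter crown segments by plot membership and minimum area
#'
#' Keeps a segment when its apex lies within the plot radius of the plot
#' center and its polygon area is at least `min_area`. Defaults match the
#' 11.28-m fixed-radius plot and 0.3-m2 sliver threshold of the workflow.
#'
#' @param segments Segment tibble from [segment_crowns()].
#' @param plot_center Length-2 x/y of the plot center.
#' @param plot_radius Plot radius, meters.
#' @param min_area Minimum crown area, square meters.
#' @return The filtered segment tibble.
#' @export
filter_segments <- function(segments, plot_center = c(0, 0),
                            plot_radius = 11.28, min_area = 0.3) {
  if (nrow(segments) == 0) return(segments)
  d <- sqrt((segments$apex_x - plot_center[1])^2 +
              (segments$apex_y - plot_center[2])^2)
  out <- segments[d <= plot_radius & segments$area >= min_area, ]
  attr(out, "labels") <- attr(segments, "labels")
  out
}

#' Match crown segments to field-measured stems
#'
#' Greedy one-to-one matching by ascending stem-to-apex distance: a pair is
#' accepted when the planimetric distance is at most `max_dist` and the
#' apex height is within `height_tol` (as a fraction) of the field-measured
#' total height. Unmatched stems are false negatives; unmatched segments
#' false positives. Recall = TP/(TP+FN); precision = TP/(TP+FP).
#'
#' @param segments Segment tibble (`tree_id`, `apex_x`, `apex_y`,
#'   `apex_height`).
#' @param field_stems Tibble with `tree_id`, `stem_x`, `stem_y`,
#'   `total_height`.
#' @param max_dist Maximum apex-to-stem distance, meters.
#' @param height_tol Fractional height tolerance.
#' @return An object of class `match_report`: list with `pairs` (tibble of
#'   `segment_id`, `field_id`, `distance`), `tp`, `fn`, `fp`, `recall`,
#'   `precision`.
#' @export
match_trees <- function(segments, field_stems, max_dist = 2.0, height_tol = 0.3) {
  ns <- nrow(segments); nf <- nrow(field_stems)
  pairs <- tibble::tibble(segment_id = integer(0), field_id = integer(0),
                          distance = numeric(0))
  if (ns > 0 && nf > 0) {
    d <- outer(seq_len(ns), seq_len(nf), function(i, j) {
      sqrt((segments$apex_x[i] - field_stems$stem_x[j])^2 +
             (segments$apex_y[i] - field_stems$stem_y[j])^2)
    })
    hok <- outer(seq_len(ns), seq_len(nf), function(i, j) {
      abs(segments$apex_height[i] - field_stems$total_height[j]) <=
        height_tol * field_stems$total_height[j]
    })
    cand <- which(d <= max_dist & hok, arr.ind = TRUE)
    if (nrow(cand)) {
      cand <- cand[order(d[cand]), , drop = FALSE]
      used_s <- logical(ns); used_f <- logical(nf)
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (used_s[i] || used_f[j]) next
        used_s[i] <- TRUE; used_f[j] <- TRUE
        pairs <- dplyr::bind_rows(pairs, tibble::tibble(
          segment_id = segments$tree_id[i],
          field_id = field_stems$tree_id[j],
          distance = d[i, j]
        ))
      }
    }
  }
  tp <- nrow(pairs)
  match_report(tp = tp, fn = nf - tp, fp = ns - tp, pairs = pairs)
}

#' Detection scores from true-positive / false-negative / false-positive counts
#'
#' @param tp,fn,fp Integer counts.
#' @param pairs Optional tibble of matched pairs.
#' @return A `match_report` object.
#' @export
match_report <- function(tp, fn, fp, pairs = NULL) {
  structure(
    list(pairs = pairs, tp = as.integer(tp), fn = as.integer(fn),
         fp = as.integer(fp),
         recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_),
    class = "match_report"
  )
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf("<match_report> TP %d, FN %d, FP %d | recall %.3f, precision %.3f\n",
              x$tp, x$fn, x$fp, x$recall, x$precision))
  invisible(x)
}
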