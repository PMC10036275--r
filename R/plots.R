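#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a raster grid
#'
#' 1-band grids are drawn as a height map; 3-band grids as a true-color
#' image.
#'
#' @param object A [raster_grid()].
#' @param ... Unused.
#' @param depth Color bit depth for 3-band grids.
#' @return A ggplot.
#' @export
autoplot.raster_grid <- function(object, ..., depth = 8L) {
  nr <- nrow(object$values); nc <- ncol(object$values)
  df <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  xy <- grid_xy(object, df$row, df$col)
  df$x <- xy$x; df$y <- xy$y
  if (object$bands == 1L) {
    df$value <- as.vector(object$values)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                     fill = .data$value)) +
      ggplot2::geom_raster() +
      ggplot2::scale_fill_viridis_c(na.value = "grey90", name = "height (m)") +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (m)", y = "y (m)")
  } else {
    hi <- 2^depth - 1
    plane <- nr * nc
    lin <- (df$col - 1L) * nr + df$row
    df$fill <- grDevices::rgb(object$values[lin] / hi,
                              object$values[lin + plane] / hi,
                              object$values[lin + 2L * plane] / hi)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
      ggplot2::scale_fill_identity() +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "x (m)", y = "y (m)")
  }
}

#' Plot a vertical profile
#'
#' Slice statistics against height, optionally overlaid with a fitted
#' spline, drawn with height on the vertical axis as crown profiles are
#' read.
#'
#' @param object A `vertical_profile`.
#' @param ... Unused.
#' @param spline Optional `profile_spline` to overlay.
#' @return A ggplot.
#' @export
autoplot.vertical_profile <- function(object, ..., spline = NULL) {
  p <- ggplot2::ggplot(object[!is.na(object$stat), ],
                       ggplot2::aes(x = .data$stat, y = .data$height)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.6) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey40") +
    ggplot2::scale_size_area(max_size = 3) +
    ggplot2::labs(x = "slice statistic", y = "height (m)")
  if (!is.null(spline)) {
    h <- seq(spline$range[1], spline$range[2], length.out = 200)
    p <- p + ggplot2::geom_path(
      data = data.frame(stat = spline$predict(h), height = h),
      color = "firebrick")
  }
  p
}

#' Plot estimated versus observed scorch heights
#'
#' @param object A `scorch_regression`.
#' @param ... Unused.
#' @return A ggplot with the fitted line and the 1:1 line.
#' @export
autoplot.scorch_regression <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$estimated, y = .data$observed)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey50") +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "firebrick", linewidth = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "estimated scorch height (m)",
                  y = "observed scorch height (m)")
}

#' Plot the distribution of crown-volume-scorched differences
#'
#' Histogram of observed-minus-estimated differences in the 10-point bins
#' of the agreement summary.
#'
#' @param object A `cvs_agreement`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cvs_agreement <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(x = .data$bin_center, y = .data$count)) +
    ggplot2::geom_col(width = 9, fill = "grey35") +
    ggplot2::labs(x = "observed - estimated CVS (percent points)",
                  y = "trees")
}

#' Map crown segments over the plot
#'
#' Crown boundary polygons with apexes, optionally against field stems.
#'
#' @param segments Segment tibble from [segment_crowns()].
#' @param stems Optional stem tibble (`stem_x`, `stem_y`).
#' @return A ggplot.
#' @export
plot_crown_map <- function(segments, stems = NULL) {
  polys <- purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    b <- segments$boundary[[i]]
    if (is.null(b)) return(NULL)
    tibble::tibble(tree_id = segments$tree_id[i], x = b[, 1], y = b[, 2])
  })
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = polys,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$tree_id),
                       color = "forestgreen") +
    ggplot2::geom_point(data = segments,
                        ggplot2::aes(x = .data$apex_x, y = .data$apex_y),
                        shape = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)")
  if (!is.null(stems)) {
    p <- p + ggplot2::geom_point(
      data = stems, ggplot2::aes(x = .data$stem_x, y = .data$stem_y),
      shape = 1, color = "grey30")
  }
  p
}
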