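#' Vertical median-GLI profile of a crown
#'
#' Slices the crown's points into uniform height bins (10 cm by default,
#' anchored at the lowest point) and records the median per-point Green
#' Leaf Index and the point count of each slice. Slices with no points are
#' kept in the table with an `NA` statistic so downstream fitting can skip
#' them explicitly.
#'
#' @param points Tibble with `z`, `r`, `g`, `b`.
#' @param slice Slice thickness, meters.
#' @return Tibble of class `vertical_profile`: `height` (slice centers),
#'   `stat` (median GLI), `n`.
#' @export
vertical_gli_profile <- function(points, slice = 0.10) {
  if (nrow(points) == 0) stop("cannot profile an empty point set", call. = FALSE)
  v <- gli(points$r, points$g, points$b)
  z0 <- min(points$z)
  bin <- pmin(floor((points$z - z0) / slice),
              floor((max(points$z) - z0) / slice))
  nbin <- max(bin) + 1L
  stat <- rep(NA_real_, nbin)
  cnt <- rep(0L, nbin)
  agg <- tapply(v, bin, stats::median)
  cn <- tapply(v, bin, length)
  at <- as.integer(names(agg)) + 1L
  stat[at] <- agg
  cnt[at] <- cn
  out <- tibble::tibble(
    height = z0 + (seq_len(nbin) - 0.5) * slice,
    stat = stat, n = cnt
  )
  class(out) <- c("vertical_profile", class(out))
  attr(out, "slice") <- slice
  out
}

#' Vertical point-count profile of a crown
#'
#' Point counts per uniform height bin (25 cm by default), the histogram
#' from which crown base height is derived.
#'
#' @param points Tibble with `z`.
#' @param bin Bin thickness, meters.
#' @return Tibble of class `vertical_profile`: `height`, `stat` (count), `n`.
#' @export
vertical_count_profile <- function(points, bin = 0.25) {
  if (nrow(points) == 0) stop("cannot profile an empty point set", call. = FALSE)
  z0 <- min(points$z)
  b <- pmin(floor((points$z - z0) / bin),
            floor((max(points$z) - z0) / bin))
  nbin <- max(b) + 1L
  cnt <- rep(0L, nbin)
  tb <- table(b)
  cnt[as.integer(names(tb)) + 1L] <- as.integer(tb)
  out <- tibble::tibble(
    height = z0 + (seq_len(nbin) - 0.5) * bin,
    stat = as.numeric(cnt), n = cnt
  )
  class(out) <- c("vertical_profile", class(out))
  attr(out, "slice") <- bin
  out
}

#' Fit a smoothing spline to a vertical profile
#'
#' Cubic smoothing spline through the non-empty slices, with the smoothing
#' parameter on the normalized \[0, 1\] scale (0 near-interpolates, 1
#' approaches a linear fit); the 0.65 default reflects the convention of
#' [stats::smooth.spline()]'s `spar`. With fewer than 4 non-empty slices no
#' spline is identifiable; a step-rule fallback is returned (piecewise value
#' of the nearest slice), flagged low-confidence.
#'
#' @param profile A `vertical_profile` from [vertical_gli_profile()].
#' @param smoothing Smoothing parameter in \[0, 1\].
#' @return A list of class `profile_spline`: `predict(h)` evaluates the
#'   fit; `range` is the fitted height range; `low_confidence` flags the
#'   fallback.
#' @export
fit_profile_spline <- function(profile, smoothing = 0.65) {
  keep <- !is.na(profile$stat)
  h <- profile$height[keep]
  s <- profile$stat[keep]
  if (length(h) < 4) {
    warning("fewer than 4 non-empty slices; using step-rule fallback",
            call. = FALSE)
    f <- function(x) s[pmax(1L, pmin(length(s), vapply(x, function(xi)
      which.min(abs(h - xi)), integer(1))))]
    return(structure(list(predict = f, range = range(h), low_confidence = TRUE),
                     class = "profile_spline"))
  }
  fit <- stats::smooth.spline(h, s, spar = smoothing)
  f <- function(x) stats::predict(fit, x)$y
  structure(list(predict = f, range = range(h), low_confidence = FALSE,
                 fit = fit),
            class = "profile_spline")
}

#' Scorch height from a fitted vertical-GLI spline
#'
#' Applies the sign rules for the fitted greenness trend: if the spline
#' takes both signs over the crown's height range, scorch height is the
#' lower end of the lowest interval on which the spline is positive (an
#' interior negative-to-positive crossing is located by bisection to 1 cm);
#' an always-negative spline means no living foliage remains and scorch
#' height is the maximum point height; an always-positive spline means no
#' scorch signal and the crown base height is returned.
#'
#' @param spline A `profile_spline` from [fit_profile_spline()].
#' @param max_point_height Maximum point height of the crown, meters.
#' @param crown_base_height Crown base height, meters.
#' @param step Scan step for sign bracketing, meters.
#' @return Scorch height in meters above ground, with attribute `rule`
#'   recording which case applied (`"crossing"`, `"all_negative"`,
#'   `"all_positive"`).
#' @export
scorch_height_from_spline <- function(spline, max_point_height,
                                      crown_base_height, step = 0.01) {
  if (is.null(spline$predict)) stop("undefined spline", call. = FALSE)
  lo <- spline$range[1]; hi <- spline$range[2]
  grid <- seq(lo, hi, by = step)
  if (length(grid) < 2) grid <- c(lo, hi)
  v <- spline$predict(grid)
  pos <- v > 0
  if (!any(pos)) {
    return(structure(max_point_height, rule = "all_negative"))
  }
  if (all(pos)) {
    return(structure(crown_base_height, rule = "all_positive"))
  }
  first_pos <- which(pos)[1]
  if (first_pos == 1) {
    # positive at the bottom of the range: lowest positive portion starts there
    return(structure(lo, rule = "crossing"))
  }
  a <- grid[first_pos - 1]; b <- grid[first_pos]
  for (i in 1:30) {
    if (b - a <= 0.001) break
    m <- (a + b) / 2
    if (spline$predict(m) > 0) b <- m else a <- m
  }
  structure((a + b) / 2, rule = "crossing")
}

#' Crown base height from a vertical point-count histogram
#'
#' Builds the 25-cm point-count histogram, smooths it with a 3-bin moving
#' average (raw counts are too jagged for stable curvature estimates), and
#' finds inflection points as sign changes of the discrete second
#' difference; crown base height is the height of the inflection closest to
#' the ground. Point sets spanning less than 1 m, or profiles with no
#' inflection, fall back to the lowest point height with a warning.
#'
#' @param points Tibble with `z`.
#' @param bin Histogram bin, meters.
#' @return Crown base height, meters; attribute `flagged` is `TRUE` on
#'   fallback.
#' @export
crown_base_height <- function(points, bin = 0.25) {
  if (nrow(points) < 8 || diff(range(points$z)) < 1) {
    warning("too few points or span < 1 m; crown base set to lowest point",
            call. = FALSE)
    return(structure(min(points$z), flagged = TRUE))
  }
  prof <- vertical_count_profile(points, bin)
  counts <- prof$stat
  n <- length(counts)
  if (n >= 3) {
    sm <- stats::filter(counts, rep(1 / 3, 3), sides = 2)
    sm[1] <- mean(counts[1:2]); sm[n] <- mean(counts[(n - 1):n])
    counts <- as.numeric(sm)
  }
  if (n < 4) {
    warning("histogram too short for inflection analysis; crown base set to lowest point",
            call. = FALSE)
    return(structure(min(points$z), flagged = TRUE))
  }
  d2 <- diff(counts, differences = 2)          # curvature at bins 2..(n-1)
  # curvature below the noise floor (sparse stem hits fluctuating by a
  # point or two) does not count as an inflection
  eps <- max(1, 0.02 * max(counts))
  d2[abs(d2) <= eps] <- 0
  s <- sign(d2)
  nz <- which(s != 0)
  flips <- integer(0)
  if (length(nz) > 1) {
    chg <- which(s[nz[-1]] != s[nz[-length(nz)]])
    flips <- nz[chg + 1]
  }
  if (!length(flips)) {
    warning("no inflection found; crown base set to lowest point", call. = FALSE)
    return(structure(min(points$z), flagged = TRUE))
  }
  # d2[i] sits at bin i+1; a flip between d2[i] and d2[j] marks curvature
  # change near bin j+1's lower edge
  k <- flips[1] + 1L
  structure(prof$height[k] - bin / 2, flagged = FALSE)
}

#' Crown volume scorched from crown lengths
#'
#' Percent of (conical) crown volume scorched, from total crown length CL
#' and crown length scorched CLS:
#' `CVS = 100 * CLS * (2 CL - CLS) / CL^2`. The cone concentrates volume
#' low in the crown, so CVS grows faster than the scorched length fraction.
#'
#' @param cl Total crown length, meters (> 0).
#' @param cls Crown length scorched, meters (0 to `cl`; larger values are
#'   clamped with a warning).
#' @return Percent in \[0, 100\]. Vectorized.
#' @export
crown_volume_scorched <- function(cl, cls) {
  if (any(!is.finite(cl) | cl <= 0)) stop("`cl` must be positive", call. = FALSE)
  if (any(cls < 0)) stop("`cls` must be non-negative", call. = FALSE)
  if (any(cls > cl + 1e-9)) {
    warning("`cls` exceeds `cl`; clamping to the crown length", call. = FALSE)
  }
  cls <- pmin(cls, cl)
  pmin(pmax(100 * cls * (2 * cl - cls) / cl^2, 0), 100)
}

#' Full scorch assessment of one tree
#'
#' For an unburned crown: scorch height equals the crown base height and
#' scorched length/volume are zero. For a burned crown: the vertical
#' median-GLI profile is fitted with a smoothing spline and the sign rules
#' give scorch height; crown base height comes from the point-count
#' histogram; crown length scorched is the scorch height above the crown
#' base clamped into the crown, and crown volume scorched follows from the
#' conical-crown formula. A burned-labelled crown whose greenness trend is
#' positive throughout is reported with zero scorch and flagged
#' `inconsistent-with-classification` rather than silently dropped.
#'
#' @param points The tree's member points (tibble with `z`, `r`, `g`, `b`).
#' @param burn_call One-row tibble with `label` (and optionally
#'   `positive_gli_fraction`).
#' @param tree_id Identifier copied into the output.
#' @param slice GLI-profile slice, meters.
#' @param smoothing Spline smoothing parameter.
#' @param cbh_bin Crown-base histogram bin, meters.
#' @return One-row tibble: `tree_id`, `label`, `scorch_height`,
#'   `crown_base_height`, `total_height`, `cl`, `cls`, `cvs`,
#'   `pct_length_scorched`, `flags`.
#' @export
assess_tree <- function(points, burn_call, tree_id = NA_integer_,
                        slice = 0.10, smoothing = 0.65, cbh_bin = 0.25) {
  empty <- tibble::tibble(
    tree_id = tree_id, label = NA_character_, scorch_height = NA_real_,
    crown_base_height = NA_real_, total_height = NA_real_, cl = NA_real_,
    cls = NA_real_, cvs = NA_real_, pct_length_scorched = NA_real_,
    flags = "unclassifiable"
  )
  if (is.na(burn_call$label) || nrow(points) == 0) return(empty)
  flags <- character(0)
  total_height <- max(points$z)
  cbh <- crown_base_height(points, bin = cbh_bin)
  if (isTRUE(attr(cbh, "flagged"))) flags <- c(flags, "cbh-fallback")
  cbh <- as.numeric(cbh)
  cl <- total_height - cbh
  if (cl <= 0) {
    cbh <- min(points$z)
    cl <- total_height - cbh
    flags <- c(flags, "cbh-above-top")
  }
  if (burn_call$label == "unburned") {
    sh <- cbh; cls <- 0
  } else {
    # profile the crown, not the stem: slices start at the crown base
    crown_pts <- points[points$z >= cbh, , drop = FALSE]
    if (nrow(crown_pts) == 0) crown_pts <- points
    prof <- vertical_gli_profile(crown_pts, slice = slice)
    sp <- withCallingHandlers(
      fit_profile_spline(prof, smoothing = smoothing),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (sp$low_confidence) flags <- c(flags, "low-confidence-spline")
    sh <- scorch_height_from_spline(sp, total_height, cbh)
    if (identical(attr(sh, "rule"), "all_positive")) {
      flags <- c(flags, "inconsistent-with-classification")
    }
    sh <- as.numeric(sh)
    cls <- pmin(pmax(sh - cbh, 0), cl)
  }
  tibble::tibble(
    tree_id = tree_id, label = burn_call$label, scorch_height = sh,
    crown_base_height = cbh, total_height = total_height, cl = cl,
    cls = cls, cvs = crown_volume_scorched(cl, cls),
    pct_length_scorched = 100 * cls / cl,
    flags = if (length(flags)) paste(flags, collapse = ";") else ""
  )
}

#' Assess every classified crown
#'
#' Maps [assess_tree()] over the segments and their burn calls.
#'
#' @param segments Segment tibble from [segment_crowns()].
#' @param burn_calls Output of [classify_crowns()] (same `tree_id`s).
#' @param cloud The point cloud the segments index into.
#' @param slice,smoothing,cbh_bin Passed to [assess_tree()].
#' @return Tibble with one assessment row per segment, joined with
#'   `positive_gli_fraction`.
#' @export
assess_trees <- function(segments, burn_calls, cloud,
                         slice = 0.10, smoothing = 0.65, cbh_bin = 0.25) {
  out <- purrr::map_dfr(seq_len(nrow(segments)), function(i) {
    id <- segments$tree_id[i]
    call <- burn_calls[burn_calls$tree_id == id, ]
    if (nrow(call) == 0) {
      call <- tibble::tibble(label = NA_character_)
    }
    assess_tree(cloud[segments$point_idx[[i]], ], call[1, ], tree_id = id,
                slice = slice, smoothing = smoothing, cbh_bin = cbh_bin)
  })
  dplyr::left_join(out,
                   dplyr::select(burn_calls, "tree_id", "positive_gli_fraction"),
                   by = "tree_id")
}
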