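#' Ground-truth description of one synthetic tree
#'
#' Builds and validates the per-tree truth record used by the scene
#' generator: stem position, total height, crown base height, scorch height
#' (height above ground below which foliage is scorched; 0 = unburned,
#' total height = fully scorched), an optional consumption height above
#' which foliage is absent entirely, crown radius, and crown class.
#'
#' @param tree_id Identifier.
#' @param stem_x,stem_y Stem position, meters.
#' @param total_height Total tree height, meters (> 2).
#' @param crown_base_height Height of the live-crown base, meters.
#' @param scorch_height Crown scorch height above ground, meters.
#' @param consumed_above Height above which foliage was consumed (NA = none).
#' @param crown_radius Crown radius at the crown base, meters.
#' @param crown_class One of dominant, codominant, intermediate, suppressed.
#' @return A one-row tibble.
#' @export
tree_truth <- function(tree_id, stem_x, stem_y, total_height,
                       crown_base_height, scorch_height,
                       consumed_above = NA_real_, crown_radius = 1.5,
                       crown_class = "codominant") {
  if (!is.finite(total_height) || total_height <= 2) {
    stop("`total_height` must be > 2 m", call. = FALSE)
  }
  if (!is.finite(crown_base_height) || crown_base_height < 0 ||
      crown_base_height >= total_height) {
    stop("`crown_base_height` must be in [0, total_height)", call. = FALSE)
  }
  if (!is.finite(scorch_height) || scorch_height < 0 ||
      scorch_height > total_height) {
    stop("`scorch_height` must be in [0, total_height]", call. = FALSE)
  }
  if (!is.finite(crown_radius) || crown_radius <= 0) {
    stop("`crown_radius` must be positive", call. = FALSE)
  }
  if (!crown_class %in% c("dominant", "codominant", "intermediate", "suppressed")) {
    stop("`crown_class` must be a standard crown class", call. = FALSE)
  }
  tibble::tibble(
    tree_id = tree_id, stem_x = stem_x, stem_y = stem_y,
    total_height = total_height, crown_base_height = crown_base_height,
    scorch_height = scorch_height, consumed_above = consumed_above,
    crown_radius = crown_radius, crown_class = crown_class
  )
}

#' Synthetic acquisition configuration
#'
#' Defaults emulate the photogrammetric acquisitions the pipeline targets:
#' 11.28-m fixed-radius plots, point clouds at ~640 points/m2, orthomosaics
#' at 4.41-cm resolution. `color_noise_sd` is additive per-band noise (8-bit
#' scale); `shadow_fraction` is the share of points darkened toward black,
#' the dominant spectral nuisance in real drone imagery of forests.
#'
#' @param plot_radius Plot radius, meters.
#' @param point_density Point density, points per square meter.
#' @param ortho_cell Orthomosaic cell size, meters.
#' @param n_trees Number of trees to place when simulating truth tables.
#' @param burned_fraction Fraction of trees with nonzero scorch.
#' @param color_noise_sd Per-band additive color noise SD (8-bit counts).
#' @param shadow_fraction Fraction of points shadowed.
#' @param seed Integer seed; fully determines generated scenes.
#' @param living_color,scorched_color,bole_color,ground_color Length-3 RGB
#'   palette anchors (8-bit). Chosen so that the sign of the Green Leaf
#'   Index separates living from scorched/ground material.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(plot_radius = 11.28, point_density = 640,
                         ortho_cell = 0.0441, n_trees = 12,
                         burned_fraction = 0.66, color_noise_sd = 10,
                         shadow_fraction = 0.2, seed = 1L,
                         living_color = c(60, 140, 60),
                         scorched_color = c(150, 90, 50),
                         bole_color = c(40, 35, 30),
                         ground_color = c(140, 100, 70)) {
  num <- c(plot_radius = plot_radius, point_density = point_density,
           ortho_cell = ortho_cell, n_trees = n_trees)
  bad <- names(num)[!is.finite(num) | num <= 0]
  if (length(bad)) stop("scene_config: `", bad[1], "` must be positive", call. = FALSE)
  if (burned_fraction < 0 || burned_fraction > 1) {
    stop("scene_config: `burned_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (shadow_fraction < 0 || shadow_fraction > 1) {
    stop("scene_config: `shadow_fraction` must be in [0, 1]", call. = FALSE)
  }
  if (color_noise_sd < 0) stop("scene_config: `color_noise_sd` must be >= 0", call. = FALSE)
  structure(
    list(plot_radius = plot_radius, point_density = point_density,
         ortho_cell = ortho_cell, n_trees = as.integer(n_trees),
         burned_fraction = burned_fraction, color_noise_sd = color_noise_sd,
         shadow_fraction = shadow_fraction, seed = as.integer(seed),
         living_color = living_color, scorched_color = scorched_color,
         bole_color = bole_color, ground_color = ground_color),
    class = "scene_config"
  )
}

# run code under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

color_block <- function(n, base, sd, shadow_fraction) {
  cols <- matrix(rep(base, each = n), ncol = 3)
  if (shadow_fraction > 0 && n > 0) {
    nsh <- stats::rbinom(1, n, shadow_fraction)
    if (nsh > 0) {
      idx <- sample.int(n, nsh)
      cols[idx, ] <- cols[idx, ] * stats::runif(nsh, 0.1, 0.4)
    }
  }
  if (sd > 0 && n > 0) {
    cols <- cols + matrix(stats::rnorm(3 * n, 0, sd), ncol = 3)
  }
  cols <- pmin(pmax(round(cols), 0), 255)
  cols
}

#' Generate the colored point cloud of a single tree
#'
#' Foliage points fill a cone from the crown base (radius `crown_radius`) to
#' the apex (radius 0), at a count matched to `point_density` over the
#' crown's projected area. Points at or above the scorch height are colored
#' living green (positive expected GLI); crown points below it scorched
#' brown (negative expected GLI). If `consumed_above` is set, foliage above
#' it is absent and replaced by sparse dark bole points. Sparse bole points
#' also run down the stem below the crown. A deterministic point is placed
#' at the exact apex. Shadowing multiplies all bands of a random subset
#' toward black before additive noise is applied.
#'
#' @param truth One-row truth table from [tree_truth()].
#' @param cfg A [scene_config()].
#' @param seed Integer seed for this tree.
#' @return A [as_point_cloud()] tibble with provenance columns `tree_id`
#'   and `source` ("foliage" or "bole") and a logical `scorched` column
#'   giving the generator's own color rule per point.
#' @export
generate_tree_points <- function(truth, cfg = scene_config(), seed = cfg$seed) {
  stopifnot(nrow(truth) == 1)
  tree_truth(truth$tree_id, truth$stem_x, truth$stem_y, truth$total_height,
             truth$crown_base_height, truth$scorch_height,
             truth$consumed_above, truth$crown_radius, truth$crown_class)
  with_seed(seed, {
    h <- truth$total_height; cbh <- truth$crown_base_height
    rad <- truth$crown_radius
    n_fol <- max(30L, as.integer(round(cfg$point_density * pi * rad^2)))
    # uniform in the cone volume: taper fraction t has density prop. to (1-t)^2
    t <- 1 - (1 - stats::runif(n_fol))^(1 / 3)
    z <- cbh + t * (h - cbh)
    rr <- rad * (1 - t) * sqrt(stats::runif(n_fol))
    th <- stats::runif(n_fol, 0, 2 * pi)
    x <- truth$stem_x + rr * cos(th)
    y <- truth$stem_y + rr * sin(th)
    # exact apex point aids treetop detection, as the densest image matching
    # in real photogrammetry does
    x <- c(x, truth$stem_x); y <- c(y, truth$stem_y); z <- c(z, h)
    src <- rep("foliage", length(z))
    consumed <- is.finite(truth$consumed_above)
    if (consumed) {
      keep <- z <= truth$consumed_above
      x <- x[keep]; y <- y[keep]; z <- z[keep]; src <- src[keep]
    }
    # sparse bole points: along the stem below the crown, and in place of
    # consumed foliage above it
    bole_z <- stats::runif(12L, 0.5, max(cbh, 0.6))
    if (consumed) {
      bole_z <- c(bole_z, stats::runif(
        10L, truth$consumed_above, h))
    }
    nb <- length(bole_z)
    x <- c(x, truth$stem_x + stats::rnorm(nb, 0, 0.05))
    y <- c(y, truth$stem_y + stats::rnorm(nb, 0, 0.05))
    z <- c(z, bole_z)
    src <- c(src, rep("bole", nb))
    # scorch covers [0, scorch_height); a fully scorched crown
    # (scorch_height = total_height) leaves no living foliage at all
    scorched <- src == "foliage" &
      (z < truth$scorch_height | truth$scorch_height >= truth$total_height)
    cols <- matrix(0, nrow = length(z), ncol = 3)
    for (grp in list(
      list(sel = src == "foliage" & !scorched, base = cfg$living_color),
      list(sel = scorched, base = cfg$scorched_color),
      list(sel = src == "bole", base = cfg$bole_color)
    )) {
      if (any(grp$sel)) {
        cols[grp$sel, ] <- color_block(sum(grp$sel), grp$base,
                                       cfg$color_noise_sd, cfg$shadow_fraction)
      }
    }
    as_point_cloud(tibble::tibble(
      x = x, y = y, z = z,
      r = cols[, 1], g = cols[, 2], b = cols[, 3],
      tree_id = truth$tree_id, source = src, scorched = scorched
    ))
  })
}

#' Generate a full synthetic plot scene
#'
#' Unions per-tree clouds with ground points (z in \[0, 0.2\] m at the
#' configured density) over the plot disc, and returns the cloud together
#' with the truth table augmented with the true crown length, crown length
#' scorched and crown volume scorched implied by each tree's geometry.
#' Deterministic given `cfg$seed`.
#'
#' @param truths Truth table (rows from [tree_truth()]).
#' @param cfg A [scene_config()].
#' @return A list with elements `cloud` and `truth`.
#' @export
generate_scene <- function(truths, cfg = scene_config()) {
  if (nrow(truths) > 0) {
    d <- sqrt(truths$stem_x^2 + truths$stem_y^2)
    if (any(d > cfg$plot_radius)) {
      stop("stem(s) outside the plot radius: ",
           paste(truths$tree_id[d > cfg$plot_radius], collapse = ", "),
           call. = FALSE)
    }
    if (anyDuplicated(truths[, c("stem_x", "stem_y")])) {
      warning("overlapping identical stems in truth table", call. = FALSE)
    }
  }
  clouds <- vector("list", nrow(truths) + 1L)
  for (i in seq_len(nrow(truths))) {
    clouds[[i]] <- generate_tree_points(truths[i, ], cfg,
                                        seed = cfg$seed + i)
  }
  clouds[[length(clouds)]] <- with_seed(cfg$seed, {
    n_ground <- as.integer(round(cfg$point_density * pi * cfg$plot_radius^2))
    rr <- cfg$plot_radius * sqrt(stats::runif(n_ground))
    th <- stats::runif(n_ground, 0, 2 * pi)
    cols <- color_block(n_ground, cfg$ground_color, cfg$color_noise_sd,
                        cfg$shadow_fraction)
    tibble::tibble(
      x = rr * cos(th), y = rr * sin(th),
      z = stats::runif(n_ground, 0, 0.2),
      r = cols[, 1], g = cols[, 2], b = cols[, 3],
      tree_id = NA_integer_, source = "ground", scorched = FALSE
    )
  })
  cloud <- as_point_cloud(dplyr::bind_rows(clouds))
  truth <- dplyr::mutate(
    truths,
    cl_true = .data$total_height - .data$crown_base_height,
    cls_true = pmin(pmax(.data$scorch_height - .data$crown_base_height, 0), .data$cl_true),
    cvs_true = crown_volume_scorched(.data$cl_true, .data$cls_true)
  )
  list(cloud = cloud, truth = truth)
}

#' Simulate a random truth table for a plot
#'
#' Places well-separated stems inside the plot and draws tree attributes
#' from ranges typical of the mixed-conifer stands the method targets:
#' total heights 9-22 m, crown bases at 15-35% of height, crown radii
#' 1.1-1.8 m. A `burned_fraction` of trees receives a scorch height; of
#' those, `full_scorch_fraction` are fully scorched (scorch = total height)
#' and the rest get scorch heights uniform over the interior of the crown.
#'
#' @param cfg A [scene_config()].
#' @param min_spacing Minimum stem separation, meters.
#' @param full_scorch_fraction Share of burned trees with 100% scorch. The
#'   default reflects severity distributions typical of stand-replacing
#'   mixed-severity fire, where most visibly burned trees are fully
#'   scorched and partial scorch is the minority case.
#' @param id_offset Added to 1..n tree ids (for multi-plot studies).
#' @return A truth table.
#' @export
simulate_truths <- function(cfg = scene_config(), min_spacing = 4.6,
                            full_scorch_fraction = 0.75, id_offset = 0L) {
  with_seed(cfg$seed, {
    n <- cfg$n_trees
    spacing <- min_spacing
    xs <- ys <- numeric(0)
    repeat {
      xs <- ys <- numeric(0)
      tries <- 0L
      while (length(xs) < n && tries < 20000L) {
        tries <- tries + 1L
        rr <- (cfg$plot_radius - 1.8) * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        px <- rr * cos(th); py <- rr * sin(th)
        if (!length(xs) || min(sqrt((xs - px)^2 + (ys - py)^2)) >= spacing) {
          xs <- c(xs, px); ys <- c(ys, py)
        }
      }
      if (length(xs) == n || spacing < 0.7 * min_spacing) break
      # dense draws can defeat rejection sampling; relax the spacing a
      # notch and retry rather than fail on an unlucky configuration
      spacing <- spacing * 0.95
    }
    if (length(xs) < n) {
      stop("could not place ", n, " stems at spacing ", spacing,
           " m inside the plot; reduce `n_trees` or `min_spacing`", call. = FALSE)
    }
    h <- stats::runif(n, 9, 22)
    cbh <- h * stats::runif(n, 0.15, 0.35)
    burned <- stats::runif(n) < cfg$burned_fraction
    full <- burned & stats::runif(n) < full_scorch_fraction
    scorch <- numeric(n)
    scorch[burned] <- cbh[burned] + 0.3 +
      stats::runif(sum(burned)) * (h[burned] - cbh[burned] - 0.6)
    scorch[full] <- h[full]
    cls <- sample(c("dominant", "codominant", "intermediate"), n,
                  replace = TRUE, prob = c(0.35, 0.45, 0.2))
    purrr::map_dfr(seq_len(n), function(i) {
      tree_truth(i + id_offset, xs[i], ys[i], h[i], cbh[i], scorch[i],
                 consumed_above = NA_real_,
                 crown_radius = stats::runif(1, 1.1, 1.8),
                 crown_class = cls[i])
    })
  })
}

#' Render an orthomosaic from a colored point cloud
#'
#' Each raster cell takes the color of the highest point whose x/y falls in
#' it. At realistic densities single points do not cover whole cells, so —
#' as photogrammetric orthomosaic generation interpolates a continuous
#' image — empty cells adjacent to painted ones are filled from the mean of
#' their painted neighbors for up to `fill_passes` dilation passes; cells
#' still empty afterwards (true gaps away from any point) take the
#' configured ground color.
#'
#' @param cloud Colored point cloud.
#' @param cell Cell size, meters.
#' @param ground_color RGB fill for cells no point influences.
#' @param fill_passes Neighbor-fill dilation passes (0 disables filling).
#' @return A 3-band [raster_grid()].
#' @export
render_orthomosaic <- function(cloud, cell = 0.0441,
                               ground_color = c(140, 100, 70),
                               fill_passes = 4L) {
  if (nrow(cloud) == 0) stop("cannot render an empty cloud", call. = FALSE)
  if (!is.finite(cell) || cell <= 0) stop("`cell` must be positive", call. = FALSE)
  x0 <- min(cloud$x); y0 <- min(cloud$y)
  nc <- max(1L, as.integer(ceiling((max(cloud$x) - x0) / cell + 1e-9)))
  nr <- max(1L, as.integer(ceiling((max(cloud$y) - y0) / cell + 1e-9)))
  g <- raster_grid(array(0, dim = c(nr, nc, 3)), origin = c(x0, y0), cell = cell)
  rc <- grid_rowcol(g, cloud$x, cloud$y)
  ok <- !is.na(rc$row)
  idx <- (rc$col[ok] - 1L) * nr + rc$row[ok]
  ord <- order(idx, -cloud$z[ok])
  first <- !duplicated(idx[ord])
  sel <- which(ok)[ord][first]
  cellpos <- idx[ord][first]
  ch <- list(matrix(NA_real_, nr, nc), matrix(NA_real_, nr, nc),
             matrix(NA_real_, nr, nc))
  ch[[1]][cellpos] <- cloud$r[sel]
  ch[[2]][cellpos] <- cloud$g[sel]
  ch[[3]][cellpos] <- cloud$b[sel]
  for (pass in seq_len(fill_passes)) {
    filled <- !is.na(ch[[1]])
    if (all(filled)) break
    nbr_sum <- function(m) {
      s <- matrix(0, nr, nc)
      s[-1, ] <- s[-1, ] + m[-nr, ]
      s[-nr, ] <- s[-nr, ] + m[-1, ]
      s[, -1] <- s[, -1] + m[, -nc]
      s[, -nc] <- s[, -nc] + m[, -1]
      s
    }
    cnt <- nbr_sum(filled * 1)
    fillable <- !filled & cnt > 0
    if (!any(fillable)) break
    for (k in 1:3) {
      mz <- ch[[k]]
      mz[is.na(mz)] <- 0
      avg <- nbr_sum(mz) / pmax(cnt, 1)
      ch[[k]][fillable] <- avg[fillable]
    }
  }
  for (k in 1:3) {
    m <- ch[[k]]
    m[is.na(m)] <- ground_color[k]
    g$values[, , k] <- round(m)
  }
  g
}
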