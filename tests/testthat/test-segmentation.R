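test_that("CHM cells take the maximum point height and the stated grid convention", {
  pc <- as_point_cloud(tibble::tibble(
    x = c(0.05, 0.06, 0.15, 0.30), y = c(0.05, 0.06, 0.15, 0.30),
    z = c(3.1, 4.2, 5.0, 6.0), r = 1, g = 1, b = 1))
  chm <- build_chm(pc, cell = 0.10)
  # extent 0.05..0.30 -> 3 cells each way; row 1 is the max-y row
  expect_equal(dim(chm$values), c(3, 3))
  rc <- grid_rowcol(chm, 0.05, 0.05)
  expect_equal(c(rc$row, rc$col), c(3L, 1L))
  expect_equal(chm$values[3, 1], 4.2)       # max of 3.1 and 4.2
  expect_equal(chm$values[1, 3], 6.0)
  expect_true(is.na(chm$values[1, 1]))      # empty cell is no-data
  expect_error(build_chm(pc[0, ]), "empty")
})

test_that("CHM apex matches the generator truth within sampling tolerance", {
  cloud <- fx_tree(total_height = 12, cbh = 3, scorch = 0)
  chm <- build_chm(preprocess(cloud))
  expect_lt(abs(max(chm$values, na.rm = TRUE) - 12), 0.05)
})

test_that("Gaussian smoothing preserves constants and spreads spikes", {
  const <- raster_grid(matrix(5, 20, 20), cell = 0.1)
  sm <- smooth_chm(const, sigma = 0.05)
  expect_equal(sm$values, const$values, tolerance = 1e-12)
  spike <- matrix(0, 21, 21); spike[11, 11] <- 10
  sp <- smooth_chm(raster_grid(spike, cell = 0.1), sigma = 0.05)
  expect_lt(sp$values[11, 11], 10)
  expect_equal(sum(sp$values), 10, tolerance = 1e-9)  # mass conserved
  expect_false(sp$values[11, 11] > max(spike))        # max cannot increase
  expect_warning(smooth_chm(const, sigma = 0), "positive")
})

test_that("sigma in meters converts to the right kernel in cells", {
  # 0.05 m on 0.10 m cells must equal a separable kernel with sd 0.5 cells
  spike <- matrix(0, 21, 21); spike[11, 11] <- 1
  sp <- smooth_chm(raster_grid(spike, cell = 0.1), sigma = 0.05)
  half <- 2L  # ceiling(3 * 0.5)
  k <- dnorm(-half:half, sd = 0.5); k <- k / sum(k)
  expected <- outer(k, k)
  got <- sp$values[(11 - half):(11 + half), (11 - half):(11 + half)]
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("no-data gaps are treated as ground before smoothing", {
  m <- matrix(NA_real_, 9, 9); m[5, 5] <- 9
  sm <- smooth_chm(raster_grid(m, cell = 0.1), sigma = 0.05)
  expect_false(anyNA(sm$values))
  expect_lt(sm$values[1, 1], 1e-6)
})

test_that("treetop detection finds isolated apices and nothing below 2 m", {
  fx <- fx_clean()
  tops <- fx$res$tops
  expect_equal(nrow(tops), nrow(fx$truth))
  # every detected top sits within a crown radius of a true stem
  d <- sapply(seq_len(nrow(tops)), function(i)
    min(sqrt((fx$truth$stem_x - tops$x[i])^2 + (fx$truth$stem_y - tops$y[i])^2)))
  expect_lt(max(d), 1.0)
  flat <- raster_grid(matrix(1, 30, 30), cell = 0.1)
  expect_equal(nrow(detect_treetops(flat)), 0)
})

test_that("two nearby cones are separated by the variable window", {
  cfg <- scene_config(n_trees = 2, seed = 13, color_noise_sd = 0,
                      shadow_fraction = 0)
  truths <- dplyr::bind_rows(
    tree_truth(1, -3, 0, 10, 3, 0, crown_radius = 2),
    tree_truth(2, 3, 0, 11, 3, 0, crown_radius = 2))
  sc <- generate_scene(truths, cfg)
  pc <- preprocess(sc$cloud)
  tops <- detect_treetops(smooth_chm(build_chm(pc)))
  expect_equal(nrow(tops), 2)
})

test_that("treetop equals the exhaustive argmax on a unimodal surface", {
  # smooth unimodal bump: grid argmax is the oracle
  xs <- seq(-3, 3, length.out = 61)
  m <- outer(xs, xs, function(a, b) 8 * exp(-(a^2 + b^2) / 2) + 0.05 * a)
  g <- raster_grid(m, cell = 0.1)
  tops <- detect_treetops(g)
  expect_equal(nrow(tops), 1)
  am <- which(m == max(m), arr.ind = TRUE)
  expect_equal(c(tops$row, tops$col), as.vector(am[1, ]))
  expect_equal(tops$height, max(m))
})

test_that("watershed labels partition the above-threshold canopy", {
  fx <- fx_clean()
  labels <- attr(fx$res$segments, "labels")$values
  chm_s <- fx$res$chm_smooth$values
  expect_true(all(labels[chm_s >= 2] > 0))          # coverage
  expect_true(all(labels[chm_s < 2] == 0))          # nothing floods below
  counts <- table(labels[labels > 0])
  expect_equal(length(counts), nrow(fx$res$tops))   # exclusivity by construction
})

test_that("separated cones give disjoint polygons containing their apices", {
  cfg <- scene_config(n_trees = 2, seed = 17, color_noise_sd = 0,
                      shadow_fraction = 0)
  truths <- dplyr::bind_rows(
    tree_truth(1, -5, 0, 10, 3, 0, crown_radius = 1.5),
    tree_truth(2, 5, 0, 12, 3, 0, crown_radius = 1.5))
  sc <- generate_scene(truths, cfg)
  pc <- preprocess(sc$cloud)
  chm_s <- smooth_chm(build_chm(pc))
  tops <- detect_treetops(chm_s)
  segs <- segment_crowns(chm_s, tops, cloud = pc)
  expect_equal(nrow(segs), 2)
  for (i in 1:2) {
    poly <- segs$boundary[[i]]
    inside <- mgcv::in.out(poly, cbind(segs$apex_x, segs$apex_y))
    expect_true(inside[i])
    expect_false(inside[3 - i])
  }
  # area close to the projected crown disc
  expect_lt(abs(segs$area[1] - pi * 1.5^2) / (pi * 1.5^2), 0.25)
  # member points are exclusive
  expect_length(intersect(segs$point_idx[[1]], segs$point_idx[[2]]), 0)
})

test_that("tops outside the CHM are skipped with a warning", {
  g <- raster_grid(matrix(3, 10, 10), cell = 0.1)
  tops <- tibble::tibble(x = c(0.5, 99), y = c(0.5, 99),
                         height = c(3, 3), row = c(5L, 500L), col = c(5L, 500L))
  expect_warning(segs <- segment_crowns(g, tops), "skipped")
  expect_equal(nrow(segs), 1)
})

test_that("segment filters apply the plot-radius and minimum-area rules", {
  segs <- tibble::tibble(
    tree_id = 1:3,
    apex_x = c(0, 11.5, 11.0), apex_y = c(0, 0, 0),
    apex_height = c(10, 10, 10),
    area = c(0.2, 1.0, 0.5),
    boundary = list(NULL, NULL, NULL), point_idx = list(1L, 1L, 1L))
  kept <- filter_segments(segs)
  expect_equal(kept$tree_id, 3L)   # 0.2 m2 removed; 11.5 m removed; kept
})

test_that("matching is greedy, one-to-one, and gated by distance and height", {
  segs <- tibble::tibble(tree_id = 1:2, apex_x = c(0, 1.4), apex_y = c(0, 0),
                         apex_height = c(10, 10))
  stems <- tibble::tibble(tree_id = c(7L, 8L), stem_x = c(0.5, 30),
                          stem_y = c(0, 0), total_height = c(10, 10))
  mr <- match_trees(segs, stems)
  expect_equal(mr$tp, 1L)
  expect_equal(mr$pairs$segment_id, 1L)   # nearest apex wins the stem
  expect_equal(mr$fn, 1L)
  expect_equal(mr$fp, 1L)
  # height gate: a 10 m apex cannot match a 20 m stem at 30% tolerance
  tall <- tibble::tibble(tree_id = 1L, stem_x = 0, stem_y = 0,
                         total_height = 20)
  expect_equal(match_trees(segs[1, ], tall)$tp, 0L)
  empty <- match_trees(segs[0, ], stems)
  expect_equal(c(empty$tp, empty$fn, empty$fp), c(0L, 2L, 0L))
  expect_equal(empty$recall, 0)
})

test_that("clean well-separated scenes are detected almost perfectly", {
  fx <- fx_clean()
  expect_gte(fx$res$match$recall, 0.95)
  expect_gte(fx$res$match$precision, 0.95)
})

test_that("segmentation is deterministic for fixed inputs", {
  fx <- fx_clean()
  chm_s <- fx$res$chm_smooth
  t1 <- detect_treetops(chm_s)
  t2 <- detect_treetops(chm_s)
  expect_identical(t1, t2)
  s1 <- segment_crowns(chm_s, t1)
  s2 <- segment_crowns(chm_s, t2)
  expect_identical(attr(s1, "labels")$values, attr(s2, "labels")$values)
})
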