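mk_pts <- function(z, glivals) {
  cols <- lapply(glivals, color_for_gli)
  tibble::tibble(z = z,
                 r = vapply(cols, `[[`, numeric(1), "r"),
                 g = vapply(cols, `[[`, numeric(1), "g"),
                 b = vapply(cols, `[[`, numeric(1), "b"))
}

test_that("profile slices take the median GLI of their points", {
  pts <- mk_pts(c(5.01, 5.05, 5.09), c(-0.2, 0.1, 0.4))
  prof <- vertical_gli_profile(pts)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$stat, 0.1)
  expect_equal(prof$n, 3L)
  const <- mk_pts(seq(2, 4, 0.05), rep(0.3, 41))
  pc <- vertical_gli_profile(const)
  expect_true(all(abs(pc$stat[!is.na(pc$stat)] - 0.3) < 1e-12))
  expect_error(vertical_gli_profile(const[0, ]), "empty")
})

test_that("empty slices carry an explicit marker and are excluded from fits", {
  pts <- mk_pts(c(2.05, 2.15, 4.05, 4.15, 4.25, 4.35), rep(0.2, 6))
  prof <- vertical_gli_profile(pts)
  expect_true(any(is.na(prof$stat)))
  expect_true(all(prof$n[is.na(prof$stat)] == 0))
  sp <- fit_profile_spline(prof)
  expect_false(sp$low_confidence)
})

test_that("half-scorched cones profile negative below and positive above", {
  cloud <- fx_tree(total_height = 12, cbh = 3, scorch = 6)
  crown <- cloud[cloud$source == "foliage", ]
  prof <- vertical_gli_profile(crown)
  below <- prof$stat[prof$height < 6 - 0.1 & !is.na(prof$stat)]
  above <- prof$stat[prof$height > 6 + 0.1 & !is.na(prof$stat)]
  expect_true(all(below < 0))
  expect_true(all(above > 0))
})

test_that("the smoothing spline reproduces constants and straight lines", {
  h <- seq(2, 8, 0.1)
  const <- tibble::tibble(height = h, stat = -0.1, n = 5L)
  sp <- fit_profile_spline(const)
  expect_lt(max(abs(sp$predict(h) + 0.1)), 1e-6)
  ramp <- tibble::tibble(height = h, stat = 0.05 * (h - 5), n = 5L)
  sp2 <- fit_profile_spline(ramp)
  expect_lt(max(abs(sp2$predict(h) - ramp$stat)), 1e-3)
})

test_that("the spline recovers a noisy sigmoid within 0.05 RMS", {
  set.seed(4)
  h <- seq(2, 14, 0.1)
  truth <- -0.05 + 0.45 / (1 + exp(-(h - 8) / 0.8))
  noisy <- tibble::tibble(height = h, stat = truth + rnorm(length(h), 0, 0.1),
                          n = 10L)
  sp <- fit_profile_spline(noisy)
  expect_lt(sqrt(mean((sp$predict(h) - truth)^2)), 0.05)
})

test_that("short profiles fall back to a flagged step rule", {
  prof <- tibble::tibble(height = c(2.05, 2.15, 2.25),
                         stat = c(-0.1, -0.1, 0.2), n = 2L)
  expect_warning(sp <- fit_profile_spline(prof), "fallback")
  expect_true(sp$low_confidence)
  expect_equal(sp$predict(2.25), 0.2)
})

fake_spline <- function(f, range) {
  structure(list(predict = f, range = range, low_confidence = FALSE),
            class = "profile_spline")
}

test_that("scorch-height sign rules follow the spline cases", {
  cross <- fake_spline(function(h) h - 6, c(3, 10))
  expect_equal(as.numeric(scorch_height_from_spline(cross, 10, 3)), 6,
               tolerance = 0.01)
  neg <- fake_spline(function(h) rep(-0.2, length(h)), c(3, 17.2))
  out <- scorch_height_from_spline(neg, 17.2, 3)
  expect_equal(as.numeric(out), 17.2)
  expect_equal(attr(out, "rule"), "all_negative")
  pos <- fake_spline(function(h) rep(0.3, length(h)), c(3, 10))
  out2 <- scorch_height_from_spline(pos, 10, 3)
  expect_equal(as.numeric(out2), 3)
  expect_equal(attr(out2, "rule"), "all_positive")
  # lowest positive portion wins when several crossings exist
  wig <- fake_spline(function(h) sin(h), c(2, 10))
  expect_equal(as.numeric(scorch_height_from_spline(wig, 10, 2)), 2)
  wig2 <- fake_spline(function(h) -sin(h), c(2.5, 9))
  expect_equal(as.numeric(scorch_height_from_spline(wig2, 9, 2.5)), pi,
               tolerance = 0.01)
})

test_that("the crossing finder agrees with a 1-mm brute-force scan", {
  set.seed(8)
  for (k in 1:20) {
    a <- runif(1, -1, 1); b <- runif(1, -1, 1); c0 <- runif(1, -0.5, 0.5)
    f <- function(h) a * sin(h) + b * cos(2 * h) + c0
    sp <- fake_spline(f, c(2, 12))
    got <- as.numeric(scorch_height_from_spline(sp, 12, 2))
    grid <- seq(2, 12, by = 0.001)
    v <- f(grid)
    oracle <- if (!any(v > 0)) 12 else if (all(v > 0)) 2 else {
      first_pos <- which(v > 0)[1]
      if (first_pos == 1) 2 else grid[first_pos]
    }
    expect_lt(abs(got - oracle), 0.01)
  }
})

test_that("crown base height recovers generator truth within two bins", {
  cloud <- fx_tree(total_height = 12, cbh = 4, scorch = 0)
  pts <- cloud[cloud$z >= 2, ]
  est <- crown_base_height(pts)
  expect_false(isTRUE(attr(est, "flagged")))
  expect_lt(abs(as.numeric(est) - 4), 0.5)
})

test_that("degenerate vertical distributions fall back with warnings", {
  col <- tibble::tibble(z = seq(2, 6, length.out = 100))
  expect_warning(est <- crown_base_height(col), "no inflection")
  expect_equal(as.numeric(est), 2)
  short <- tibble::tibble(z = seq(2, 2.5, length.out = 20))
  expect_warning(est2 <- crown_base_height(short), "span|few")
  expect_equal(as.numeric(est2), 2)
})

test_that("a constructed curvature change is located within one bin", {
  # flat low counts below 3 m, then a dense lobe tapering upward (as a
  # crown's histogram does): the curvature sign flips at the 3 m breakpoint
  z_lo <- rep(seq(1.125, 2.875, by = 0.25), each = 4)
  z_hi <- unlist(lapply(0:9, function(k)
    rep(3.125 + 0.25 * k, times = 100 - 8 * k)))
  pts <- tibble::tibble(z = c(z_lo, z_hi))
  est <- crown_base_height(pts)
  expect_lt(abs(as.numeric(est) - 3), 0.5)
})

test_that("crown volume scorched satisfies the conical-crown identities", {
  expect_equal(crown_volume_scorched(10, 0), 0)
  expect_equal(crown_volume_scorched(10, 10), 100)
  expect_equal(crown_volume_scorched(10, 5), 75)
  cls <- seq(0.5, 9.5, 0.5)
  v <- crown_volume_scorched(10, cls)
  expect_true(all(diff(v) > 0))                  # strictly increasing
  expect_true(all(v >= 100 * cls / 10))          # volume outpaces length
  expect_error(crown_volume_scorched(0, 0), "positive")
  expect_warning(out <- crown_volume_scorched(10, 11), "clamp")
  expect_equal(out, 100)
})

test_that("unburned assessments carry zero scorched length and volume", {
  cloud <- fx_tree(total_height = 12, cbh = 3, scorch = 0)
  pts <- cloud[cloud$z >= 2, ]
  out <- assess_tree(pts, tibble::tibble(label = "unburned"), tree_id = 1L)
  expect_equal(out$cls, 0)
  expect_equal(out$cvs, 0)
  expect_equal(out$scorch_height, out$crown_base_height)
})

test_that("noiseless partial scorch is recovered within one smoothing width", {
  cloud <- fx_tree(total_height = 12, cbh = 3, scorch = 6)
  pts <- cloud[cloud$z >= 2, ]
  out <- assess_tree(pts, tibble::tibble(label = "burned"), tree_id = 1L)
  # the sign-crossing of the smoothed profile sits slightly below the true
  # transition; the offset stays within one smoothing width
  expect_lt(out$scorch_height - 6, 0.1)
  expect_gt(out$scorch_height - 6, -0.7)
  expect_true(out$cls >= 0 && out$cls <= out$cl)
  expect_true(out$cvs >= 0 && out$cvs <= 100)
})

test_that("fully scorched crowns assess to full volume scorched", {
  cloud <- fx_tree(total_height = 12, cbh = 3, scorch = 12)
  pts <- cloud[cloud$z >= 2, ]
  out <- assess_tree(pts, tibble::tibble(label = "burned"), tree_id = 1L)
  expect_equal(out$scorch_height, max(pts$z))
  expect_equal(out$cvs, 100)
})

test_that("burned-labelled crowns with all-green profiles are flagged", {
  cloud <- fx_tree(total_height = 12, cbh = 3, scorch = 0)
  pts <- cloud[cloud$z >= 2, ]
  out <- assess_tree(pts, tibble::tibble(label = "burned"), tree_id = 1L)
  expect_match(out$flags, "inconsistent-with-classification")
  expect_equal(out$cvs, 0)
})

test_that("assessment invariants hold across an analyzed plot", {
  fx <- fx_clean()
  a <- fx$res$assessments
  a <- a[!is.na(a$label), ]
  expect_true(all(a$cls >= -1e-9 & a$cls <= a$cl + 1e-9))
  expect_true(all(a$cvs >= 0 & a$cvs <= 100))
  expect_equal(a$cls, pmin(pmax(a$scorch_height - a$crown_base_height, 0), a$cl),
               tolerance = 1e-9)
})
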