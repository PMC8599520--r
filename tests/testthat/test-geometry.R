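test_that("zone count is n_arms * 10 + 9 and the partition is exact", {
  g <- test_geom()
  expect_equal(nrow(g$zones), 89)
  expect_equal(nrow(g$entry_lines), 8)
  # partition: zone raster areas sum to the mask area, every zone nonempty
  expect_equal(sum(g$zones$area_px), sum(g$mask))
  expect_true(all(g$zones$area_px > 0))

  g1 <- maze_geometry(n_arms = 1, arm_angles_deg = 0)
  expect_equal(nrow(g1$zones), 19)

  g4 <- maze_geometry(n_arms = 4)
  expect_equal(nrow(g4$zones), 49)
  expect_equal(sum(g4$zones$area_px), sum(g4$mask))
})

test_that("arm segments are exactly 70 cm^2, platform pieces within 15%", {
  g <- test_geom()
  seg <- g$zones[g$zones$kind == "arm-segment", ]
  areas_cm2 <- vapply(seg$polygon, polygon_area, 0) * g$cm_per_px^2
  expect_equal(areas_cm2, rep(70, 80), tolerance = 1e-10)
  plat <- g$zones[g$zones$kind == "platform-piece", ]
  expect_true(all(abs(plat$area_cm2 - 70) / 70 < 0.15))
})

test_that("rendered mask area matches the analytic footprint area", {
  g <- test_geom()
  analytic <- pi * g$platform_radius_px^2 +
    g$n_arms * g$arm_length_px * g$arm_width_px
  expect_lt(abs(sum(g$mask) - analytic) / analytic, 0.02)
  # near-zero arms degenerate to the disc alone
  g0 <- maze_geometry(arm_length_cm = 0.36, arm_width_cm = 0.36,
                      platform_radius_cm = 14.16, cm_per_px = 0.36)
  expect_lt(abs(sum(g0$mask) - pi * g0$platform_radius_px^2) /
              (pi * g0$platform_radius_px^2), 0.05)
  # every zone-labeled pixel is inside the mask
  expect_true(all(g$mask[!is.na(g$zone_map)] == 1))
})

test_that("classify_points labels landmark points correctly", {
  g <- test_geom()
  ctr <- classify_points(g, g$center[1], g$center[2])
  expect_equal(ctr$region, "platform")
  tip <- arm_point(g, 3, g$platform_radius_px + g$arm_length_px)
  at_tip <- classify_points(g, tip[1], tip[2])
  expect_equal(at_tip$region, "arm")
  expect_equal(at_tip$arm_index, 3L)
  expect_equal(at_tip$segment_index, 9L)
  far <- classify_points(g, 1, 1)
  expect_equal(far$region, "outside")
  expect_true(is.na(far$zone_id))
})

test_that("classify_points agrees with a point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  g <- test_geom()
  set.seed(11)
  n <- 10000
  x <- runif(n, 0, g$image_size[1] - 1)
  y <- runif(n, 0, g$image_size[2] - 1)
  got <- classify_points(g, x, y)$zone_id
  # keep points whose label is stable under +/-0.6 px jitter, so polygon
  # discretization at zone borders cannot create spurious disagreement
  stable <- rep(TRUE, n)
  for (d in list(c(0.6, 0), c(-0.6, 0), c(0, 0.6), c(0, -0.6))) {
    z <- classify_points(g, x + d[1], y + d[2])$zone_id
    stable <- stable & (is.na(z) == is.na(got)) &
      (is.na(z) | z == ifelse(is.na(got), -1L, got))
  }
  oracle <- rep(NA_integer_, n)
  for (i in seq_len(nrow(g$zones))) {
    p <- g$zones$polygon[[i]]
    hit <- mgcv::in.out(rbind(p, p[1, , drop = FALSE]), cbind(x, y))
    oracle[hit & is.na(oracle)] <- g$zones$zone_id[i]
  }
  expect_gt(mean(stable), 0.9)
  expect_equal(got[stable], oracle[stable])
})

test_that("entry-line distance matches geometry and a dense oracle", {
  g <- test_geom()
  ln <- g$entry_lines[3, ]   # arm 2
  mid <- c((ln$x1 + ln$x2) / 2, (ln$y1 + ln$y2) / 2)
  expect_equal(entry_line_distance(g, 2, mid[1], mid[2]), 0)
  on_end <- c(ln$x1, ln$y1)
  expect_equal(entry_line_distance(g, 2, on_end[1], on_end[2]), 0)
  # midpoint displaced 10 px along the arm axis
  th <- g$arm_angles[3]
  p <- mid + 10 * c(cos(th), sin(th))
  expect_equal(entry_line_distance(g, 2, p[1], p[2]), 10, tolerance = 1e-9)
  # dense-sampling oracle on random points
  set.seed(4)
  tt <- seq(0, 1, length.out = 20001)
  sx <- ln$x1 + tt * (ln$x2 - ln$x1); sy <- ln$y1 + tt * (ln$y2 - ln$y1)
  for (i in 1:25) {
    px <- runif(1, 0, 479); py <- runif(1, 0, 479)
    expect_equal(entry_line_distance(g, 2, px, py),
                 min(sqrt((px - sx)^2 + (py - sy)^2)), tolerance = 0.01)
  }
  expect_error(entry_line_distance(g, 8, 0, 0), "arm_index")
})

test_that("classification is invariant under pixel rescaling", {
  g1 <- maze_geometry(cm_per_px = 0.36, image_size = c(480, 480))
  g2 <- maze_geometry(cm_per_px = 0.18, image_size = c(960, 960))
  set.seed(5)
  x <- runif(300, 0, 479); y <- runif(300, 0, 479)
  c1 <- classify_points(g1, x, y)
  c2 <- classify_points(g2, (x - g1$center[1]) * 2 + g2$center[1],
                        (y - g1$center[2]) * 2 + g2$center[2])
  expect_equal(c1$region, c2$region)
  expect_equal(c1$zone_id, c2$zone_id)
})

test_that("invalid configurations are rejected", {
  expect_error(maze_geometry(arm_width_cm = -1), "positive")
  expect_error(maze_geometry(cm_per_px = 0), "positive")
  expect_error(maze_geometry(arm_width_cm = 25), "overlap")
  expect_error(maze_geometry(arm_angles_deg = c(0, 0, 90, 180, 270, 45,
                                                135, 225)), "distinct")
  expect_error(maze_geometry(image_size = c(200, 200)), "fit")
})
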