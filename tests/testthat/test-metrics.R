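make_traj <- function(t, x, y, cm_per_px = 0.25) {
  traj <- tibble::tibble(t_s = t, x_px = x, y_px = y, found = TRUE,
                         source = "single-outline")
  attr(traj, "cm_per_px") <- cm_per_px
  traj
}

test_that("path length sums consecutive displacements", {
  expect_equal(path_length(make_traj(0, 10, 10)), 0)
  expect_equal(path_length(make_traj(c(0, 1), c(0, 100), c(0, 0))), 0.25)
  # square loop, side 1 m at 0.25 cm/px = 400 px, sampled densely
  side <- seq(0, 400, by = 4)
  x <- c(side, rep(400, 100), rev(side), rep(0, 100))
  y <- c(rep(0, 101), seq(4, 400, by = 4), rep(400, 101), rev(seq(4, 400, by = 4)))
  tr <- make_traj(seq_along(x) * 0.05, x, y)
  expect_equal(path_length(tr), 4, tolerance = 0.01)
  # rotation invariance and linear scaling
  th <- 0.7
  tr_rot <- make_traj(tr$t_s, x * cos(th) - y * sin(th),
                      x * sin(th) + y * cos(th))
  expect_equal(path_length(tr_rot), path_length(tr))
  expect_equal(path_length(tr, cm_per_px = 0.5), 2 * path_length(tr))
})

test_that("average speed is length over elapsed time", {
  static <- make_traj(seq(0, 10, 0.05), 100, 100)
  expect_equal(average_speed(static), 0)
  # constant 10 cm/s for 20 s
  t <- seq(0, 20, 0.05)
  mv <- make_traj(t, t * 10 / 0.25, 0)
  expect_equal(average_speed(mv), 10, tolerance = 0.02)
  # identity: speed * duration = length
  expect_equal(average_speed(mv) * 20 / 100, path_length(mv))
  expect_error(average_speed(make_traj(0, 1, 1)), "duration")
})

test_that("region time fractions split platform / baited / non-baited", {
  g <- test_geom()
  ctr <- make_traj(seq(0, 5, 0.05), g$center[1], g$center[2], g$cm_per_px)
  expect_equal(unlist(region_time_fractions(ctr, g, baited = c(1, 2))),
               c(pct_platform = 100, pct_baited = 0, pct_nonbaited = 0))
  a2 <- arm_point(g, 1, 100)
  n <- 100
  half <- make_traj(seq_len(n) * 0.05,
                    c(rep(g$center[1], n / 2), rep(a2[1], n / 2)),
                    c(rep(g$center[2], n / 2), rep(a2[2], n / 2)),
                    g$cm_per_px)
  fr <- region_time_fractions(half, g, baited = 2)
  expect_equal(unlist(fr), c(pct_platform = 50, pct_baited = 50,
                             pct_nonbaited = 0))
  fr2 <- region_time_fractions(half, g, baited = 5)
  expect_equal(fr2$pct_nonbaited, 50)
})

test_that("scripted dwell fractions are recovered within one period", {
  g <- test_geom()
  sp <- scripted_path(rbind(g$center, arm_point(g, 0, 150), g$center),
                      speeds = 14, fps = 20, g, dwell = c(5, 10, 5))
  traj <- path_as_trajectory(sp, g)
  dur <- max(traj$t_s)
  fr <- region_time_fractions(traj, g, baited = 1)
  in_arm_truth <- sum(classify_points(g, sp$path$x, sp$path$y)$region == "arm") /
    nrow(sp$path)
  expect_equal(fr$pct_baited, 100 * in_arm_truth, tolerance = 1e-9)
  expect_lte(fr$pct_platform + fr$pct_baited + fr$pct_nonbaited, 100 + 1e-9)
})

test_that("S spots follow the anchored greedy definition", {
  g <- test_geom()
  still <- make_traj(seq(0, 60, 0.05), 240, 240, g$cm_per_px)
  s1 <- detect_s_spots(still)
  expect_equal(nrow(s1), 1)
  expect_equal(s1$duration, 60, tolerance = 0.1)
  # constant motion at 10 cm/s leaves the radius well inside min_duration
  t <- seq(0, 30, 0.05)
  mv <- make_traj(t, t * 10 / g$cm_per_px, 0, g$cm_per_px)
  expect_equal(nrow(detect_s_spots(mv, radius_cm = 2.5)), 0)
  # move - pause(10 s) - move - pause(5 s)
  sp <- scripted_path(rbind(g$center, arm_point(g, 2, 120),
                            arm_point(g, 2, 180)),
                      speeds = 12, fps = 20, g, dwell = c(0, 10, 5))
  traj <- path_as_trajectory(sp, g)
  spots <- detect_s_spots(traj, radius_cm = 2.5, min_duration_s = 2)
  expect_equal(nrow(spots), 2)
  # each spot covers its scripted pause plus at most the in-radius travel
  # around the anchor (3 radii at 12 cm/s) and two sample periods
  expect_true(all(spots$duration >= c(10, 5)))
  expect_true(all(spots$duration <= c(10, 5) + 3 * 2.5 / 12 + 0.1))
  # non-overlap and total-duration bound hold on any input
  expect_true(all(diff(c(t(spots[, c("start", "end")]))) >= 0))
  expect_lte(sum(spots$duration), max(traj$t_s))
})

test_that("zone histogram counts samples and conserves totals", {
  g <- test_geom()
  ctr <- make_traj(seq_len(50) * 0.05, g$center[1], g$center[2], g$cm_per_px)
  zh <- zone_histogram(ctr, g)
  expect_equal(sum(zh$n), 50)
  expect_equal(zh$n[zh$zone_id == 4], 50)   # center platform piece
  # conservation for arbitrary points (some outside)
  set.seed(3)
  rnd <- make_traj(seq_len(2000) * 0.05, runif(2000, 0, 479),
                   runif(2000, 0, 479), g$cm_per_px)
  zh2 <- zone_histogram(rnd, g)
  inside <- sum(!is.na(classify_points(g, rnd$x_px, rnd$y_px)$zone_id))
  expect_equal(sum(zh2$n), inside)
})

test_that("uniform in-footprint samples fill zones proportionally to area", {
  g <- test_geom()
  set.seed(13)
  n_target <- 20000
  xs <- ys <- numeric(0)
  while (length(xs) < n_target) {
    cx <- runif(n_target, 0, 479); cy <- runif(n_target, 0, 479)
    keep <- !is.na(classify_points(g, cx, cy)$zone_id)
    xs <- c(xs, cx[keep]); ys <- c(ys, cy[keep])
  }
  xs <- xs[1:n_target]; ys <- ys[1:n_target]
  zh <- zone_histogram(make_traj(seq_along(xs), xs, ys, g$cm_per_px), g)
  p <- g$zones$area_px / sum(g$zones$area_px)
  zscore <- (zh$n - n_target * p) / sqrt(n_target * p * (1 - p))
  expect_true(all(abs(zscore) < 3.5))
  expect_gt(mean(abs(zscore) < 3), 0.98)
})

test_that("the session report assembles hand-traceable sessions", {
  g <- test_geom()
  food <- function(a) arm_point(g, a - 1,
                                g$platform_radius_px + g$arm_length_px -
                                  g$arm_width_px / 2 - 2)
  # perfect rat: each baited arm once, nothing else
  wp <- list(g$center)
  for (a in c(1, 3, 5, 7)) wp <- c(wp, list(food(a), g$center))
  sp <- scripted_path(do.call(rbind, wp), 15, 20, g, dwell = 1)
  traj <- path_as_trajectory(sp, g)
  st <- score_trajectory(traj, g, baited = c(1, 3, 5, 7))
  rep1 <- session_report(traj, st, g)
  expect_true(rep1$complete)
  expect_equal(rep1$short_term_errors + rep1$long_term_errors, 0L)
  expect_equal(sum(rep1$entries[[1]]), 4L)
  expect_equal(rep1$arm_sequence[[1]], c(1L, 3L, 5L, 7L))
  expect_equal(rep1$latency_s, latency(st))

  # impaired rat: three re-entries into arm 2 before finishing arm 4
  wp2 <- list(g$center, food(2), g$center, food(2), g$center, food(2),
              g$center, food(2), g$center, food(4), g$center)
  sp2 <- scripted_path(do.call(rbind, wp2), 15, 20, g, dwell = 1)
  st2 <- score_trajectory(path_as_trajectory(sp2, g), g, baited = c(2, 4))
  expect_equal(st2$short_term_errors, 3L)
  expect_equal(st2$long_term_errors, 0L)
})

test_that("report recomputation is exact (pure function of inputs)", {
  g <- test_geom()
  sp <- scripted_path(rbind(g$center, arm_point(g, 4, 200), g$center),
                      12, 20, g, dwell = c(2, 6, 2))
  traj <- path_as_trajectory(sp, g)
  st <- score_trajectory(traj, g, baited = 5)
  expect_identical(session_report(traj, st, g), session_report(traj, st, g))
})
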