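test_that("a single bright ellipse is located at its center", {
  g <- test_geom()
  pos <- arm_point(g, 0, g$platform_radius_px + 80)
  fr <- rat_frame(g, pos[1], pos[2], theta = 0)
  pt <- locate_rat(fr, g, tracker_params())
  expect_true(pt$found)
  expect_equal(pt$source, "single-outline")
  expect_lt(sqrt((pt$x_px - pos[1])^2 + (pt$y_px - pos[2])^2), 1)
})

test_that("dropping-sized spots do not move the located centroid", {
  g <- test_geom()
  pos <- arm_point(g, 2, g$platform_radius_px + 100)
  clean <- rat_frame(g, pos[1], pos[2], theta = g$arm_angles[3])
  noisy <- clean
  # four 2x2 bright spots inside the maze, away from the rat
  for (p in list(arm_point(g, 0, 60), arm_point(g, 4, 120),
                 arm_point(g, 6, 90), g$center + c(12, -10)))
    noisy <- ramtrack:::.paint_square(noisy, round(p[1]), round(p[2]), 2, 220)
  p1 <- locate_rat(clean, g); p2 <- locate_rat(noisy, g)
  expect_equal(c(p2$x_px, p2$y_px), c(p1$x_px, p1$y_px))
})

test_that("spots smaller than the element never affect any centroid", {
  g <- test_geom()
  set.seed(21)
  for (i in 1:5) {
    k <- sample(0:7, 1)
    pos <- arm_point(g, k, runif(1, 60, 200))
    clean <- rat_frame(g, pos[1], pos[2], theta = g$arm_angles[k + 1])
    noisy <- clean
    for (j in 1:6) {       # anywhere in the frame, 6 px clear of the rat
      repeat {
        q <- c(runif(1, 2, 470), runif(1, 2, 470))
        if (sqrt(sum((q - pos)^2)) > 15 + 6 + 4) break
      }
      noisy <- ramtrack:::.paint_square(noisy, round(q[1]), round(q[2]),
                                        sample(2:4, 1), 240)
    }
    p1 <- locate_rat(clean, g); p2 <- locate_rat(noisy, g)
    expect_equal(c(p2$x_px, p2$y_px), c(p1$x_px, p1$y_px))
  }
})

test_that("a bright strip entering over an arm edge does not steal the fix", {
  g <- test_geom()
  pos <- arm_point(g, 4, g$platform_radius_px + 90)   # rat in arm 4
  fr <- rat_frame(g, pos[1], pos[2], theta = g$arm_angles[5])
  # strip from the image edge whose tip steps 6 px onto arm 0's edge
  th <- g$arm_angles[1]
  u0 <- g$platform_radius_px + g$arm_length_px - 50
  vt <- g$arm_width_px / 2 - 6
  X <- matrix(rep(0:479, each = 480), 480)
  Y <- matrix(rep(0:479, times = 480), 480)
  af <- ramtrack:::.arm_frame(g, 0, X, Y)
  strip <- matrix(af$u, 480) >= u0 & matrix(af$u, 480) <= u0 + 40 &
    matrix(af$v, 480) >= vt
  fr2 <- fr; fr2[strip] <- 210
  p <- locate_rat(fr2, g)
  expect_true(p$found)
  expect_lt(sqrt((p$x_px - pos[1])^2 + (p$y_px - pos[2])^2), 3)
})

test_that("bright structures outside the footprint never affect the result", {
  g <- test_geom()
  pos <- g$center + c(10, 5)
  clean <- rat_frame(g, pos[1], pos[2])
  noisy <- clean
  noisy[1:60, 1:60] <- 250                    # big corner blob, off-maze
  noisy <- ramtrack:::.paint_square(noisy, 430, 430, 40, 250)
  p1 <- locate_rat(clean, g); p2 <- locate_rat(noisy, g)
  expect_equal(c(p2$x_px, p2$y_px), c(p1$x_px, p1$y_px))
})

test_that("in-maze noise smaller than the rat loses the largest-area rule", {
  g <- test_geom()
  pos <- arm_point(g, 6, g$platform_radius_px + 70)
  fr <- rat_frame(g, pos[1], pos[2], theta = g$arm_angles[7])
  q <- arm_point(g, 1, 100)                   # 8x8 survivor, area 64
  fr <- ramtrack:::.paint_square(fr, round(q[1]), round(q[2]), 8, 220)
  p <- locate_rat(fr, g)
  expect_equal(p$source, "largest-in-maze")
  expect_lt(sqrt((p$x_px - pos[1])^2 + (p$y_px - pos[2])^2), 1)
})

test_that("track_sequence logs one point per period and carries forward", {
  g <- test_geom()
  pos <- arm_point(g, 0, 100)
  blob <- rat_frame(g, pos[1], pos[2])
  dark <- matrix(30, 480, 480)
  frames <- c(rep(list(blob), 6), rep(list(dark), 5), list(blob))
  traj <- track_sequence(frames, g, tracker_params(sample_period = 0.05),
                         fps = 20)
  expect_equal(nrow(traj), 12)
  expect_equal(traj$t_s, seq(0, 0.55, by = 0.05))
  expect_equal(sum(!traj$found), 5)
  carried <- traj[traj$source == "carried-forward", ]
  expect_true(all(carried$x_px == traj$x_px[6]))
  # static blob: identical coordinates whenever found
  expect_equal(length(unique(traj$x_px[traj$found])), 1)
})

test_that("a moving blob yields the scripted per-frame displacement", {
  g <- test_geom()
  th <- g$arm_angles[1]
  frames <- lapply(0:19, function(i) {
    p <- arm_point(g, 0, 60 + 2 * i)
    rat_frame(g, p[1], p[2], theta = th)
  })
  traj <- track_sequence(frames, g, tracker_params(sample_period = 0.05),
                         fps = 20)
  expect_equal(nrow(traj), 20)
  step <- sqrt(diff(traj$x_px)^2 + diff(traj$y_px)^2)
  expect_true(all(abs(step - 2) < 0.6))
  expect_error(track_sequence(list(), g, fps = 20), "empty")
})

test_that("tracking is deterministic", {
  g <- test_geom()
  set.seed(31)
  frames <- lapply(1:4, function(i) {
    p <- arm_point(g, 3, 60 + 30 * i)
    f <- rat_frame(g, p[1], p[2], theta = g$arm_angles[4])
    f + matrix(runif(480 * 480, 0, 20), 480)   # sub-threshold texture
  })
  t1 <- track_sequence(frames, g, fps = 20)
  t2 <- track_sequence(frames, g, fps = 20)
  expect_identical(t1, t2)
})

test_that("detection rate is the percentage of close found frames", {
  traj <- tibble::tibble(t_s = 1:10, x_px = c(rep(0, 9), 50),
                         y_px = 0, found = TRUE, source = "single-outline")
  truth <- tibble::tibble(x = rep(0, 10), y = rep(0, 10))
  expect_equal(detection_rate(traj, truth, tol_px = 5), 90)
  traj$found <- FALSE
  expect_equal(detection_rate(traj, truth, tol_px = 5), 0)
  traj$found <- TRUE; traj$x_px <- 0
  expect_equal(detection_rate(traj, truth, tol_px = 5), 100)
  expect_error(detection_rate(traj, truth[1:3, ], 5), "length")
})
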