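# Shared fixtures built in code: the default maze geometry (cached; its
# rasterization is the expensive part) and simple hand-drawn frames.

.test_env <- new.env()

test_geom <- function() {
  if (is.null(.test_env$geom)) .test_env$geom <- maze_geometry()
  .test_env$geom
}

# dark frame with a bright rat ellipse at (cx, cy), heading theta
rat_frame <- function(geom, cx, cy, theta = 0, major = 30, minor = 15,
                      gray = 200, bg = 30) {
  img <- matrix(bg, nrow = geom$image_size[2], ncol = geom$image_size[1])
  ramtrack:::.paint_ellipse(img, cx, cy, major / 2, minor / 2, theta, gray)
}

# center of arm k (0-based) at along-axis offset u from the maze center
arm_point <- function(geom, k, u) {
  geom$center + u * c(cos(geom$arm_angles[k + 1]),
                      sin(geom$arm_angles[k + 1]))
}

# trajectory tibble from a scripted path (ground-truth positions as if
# they were tracker output)
path_as_trajectory <- function(sp, geom) {
  traj <- tibble::tibble(t_s = sp$path$t, x_px = sp$path$x,
                         y_px = sp$path$y, found = TRUE,
                         source = "single-outline")
  attr(traj, "cm_per_px") <- geom$cm_per_px
  attr(traj, "sample_period") <- if (nrow(traj) > 1) sp$path$t[2] else NA
  traj
}
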