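# Pixel-space model of the radial arm maze: footprint mask, arm entry lines,
# and the 89-piece statistical partition (10 segments per arm + 9 platform
# pieces). Coordinate convention throughout the package: x = column,
# y = row, 0-based, origin at the top-left pixel; a matrix m holds pixel
# (x, y) at m[y + 1, x + 1]; centroids and positions are real-valued.

#' Build a radial-arm-maze geometry
#'
#' Constructs the pixel-space model of an n-arm radial maze: a circular
#' central platform with rectangular arms attached at its rim, the filled
#' footprint mask, one entry line across the proximal end of each arm, and a
#' partition of the footprint into `n_arms * 10 + 9` statistical zones
#' (10 equal segments per arm plus 9 platform pieces of near-equal area).
#'
#' Each arm is `arm_length_cm` long and `arm_width_cm` wide; each arm
#' segment therefore covers `arm_length_cm * arm_width_cm / 10` square
#' centimeters exactly (70 cm^2 for the default maze). The default platform
#' radius is chosen so the platform area is nine times that segment area,
#' making all 89 zones close to 70 cm^2. The platform is split by a 3x3
#' grid whose lines sit at `+/- platform_grid_frac * radius` from the
#' center; the default fraction 0.279 minimizes the worst relative
#' deviation of the nine disc pieces from equal area (all within ~13%).
#'
#' @param n_arms Number of arms (default 8).
#' @param arm_angles_deg Arm axis directions in degrees (x toward +columns,
#'   y toward +rows). Default: evenly spaced every `360 / n_arms` degrees.
#' @param arm_length_cm,arm_width_cm Arm dimensions in centimeters.
#' @param platform_radius_cm Central platform radius in centimeters.
#'   Default: `sqrt(9 * arm_length_cm * arm_width_cm / 10 / pi)`, i.e. the
#'   radius at which the platform area equals nine arm segments.
#' @param cm_per_px Image scale, centimeters per pixel.
#' @param image_size Working image size `c(width, height)` in pixels.
#' @param center Maze center `c(x, y)` in pixels; default image center.
#' @param platform_grid_frac Platform grid line offset as a fraction of the
#'   platform radius.
#' @return An object of class `maze_geometry`: a list with the input
#'   parameters, derived pixel dimensions, `entry_lines` (tibble: `arm`,
#'   `x1`, `y1`, `x2`, `y2`), `mask` (integer 0/1 matrix), `zone_map`
#'   (integer matrix of zone ids, `NA` outside the footprint) and `zones`
#'   (tibble: `zone_id`, `kind`, `arm_index`, `segment_index`,
#'   `piece_index`, `area_px`, `area_cm2`, `polygon`).
#' @examples
#' geom <- maze_geometry()
#' nrow(geom$zones) # 89
#' @export
maze_geometry <- function(n_arms = 8,
                          arm_angles_deg = NULL,
                          arm_length_cm = 70,
                          arm_width_cm = 10,
                          platform_radius_cm = NULL,
                          cm_per_px = 0.36,
                          image_size = c(480, 480),
                          center = NULL,
                          platform_grid_frac = 0.279) {
  if (n_arms < 1) stop("n_arms must be >= 1", call. = FALSE)
  if (arm_length_cm <= 0 || arm_width_cm <= 0 || cm_per_px <= 0)
    stop("maze dimensions and cm_per_px must be positive", call. = FALSE)
  if (is.null(platform_radius_cm))
    platform_radius_cm <- sqrt(9 * arm_length_cm * arm_width_cm / 10 / pi)
  if (platform_radius_cm <= 0)
    stop("platform_radius_cm must be positive", call. = FALSE)
  if (is.null(arm_angles_deg))
    arm_angles_deg <- seq(0, by = 360 / n_arms, length.out = n_arms)
  if (length(arm_angles_deg) != n_arms)
    stop("need one angle per arm", call. = FALSE)
  ang <- arm_angles_deg * pi / 180
  amod <- sort(ang %% (2 * pi))
  if (n_arms > 1 && min(diff(c(amod, amod[1] + 2 * pi))) < 1e-9)
    stop("arm angles must be pairwise distinct", call. = FALSE)

  w <- as.integer(image_size[1]); h <- as.integer(image_size[2])
  if (is.null(center)) center <- c((w - 1) / 2, (h - 1) / 2)

  r_px <- platform_radius_cm / cm_per_px
  len_px <- arm_length_cm / cm_per_px
  wid_px <- arm_width_cm / cm_per_px

  # arms must not overlap where they meet the platform rim
  if (wid_px / 2 >= r_px)
    stop("arm width exceeds platform diameter", call. = FALSE)
  if (n_arms > 1) {
    half_ang <- asin((wid_px / 2) / r_px)
    gaps <- diff(c(amod, amod[1] + 2 * pi))
    if (min(gaps) <= 2 * half_ang)
      stop("arms overlap at the platform: width too large for angle spacing",
           call. = FALSE)
  }

  reach <- r_px + len_px
  if (center[1] - reach < -0.5 || center[1] + reach > w - 0.5 ||
      center[2] - reach < -0.5 || center[2] + reach > h - 0.5)
    stop("maze footprint does not fit inside image_size", call. = FALSE)

  entry_lines <- tibble::tibble(
    arm = seq_len(n_arms) - 1L,
    x1 = center[1] + r_px * cos(ang) - (wid_px / 2) * (-sin(ang)),
    y1 = center[2] + r_px * sin(ang) - (wid_px / 2) * cos(ang),
    x2 = center[1] + r_px * cos(ang) + (wid_px / 2) * (-sin(ang)),
    y2 = center[2] + r_px * sin(ang) + (wid_px / 2) * cos(ang)
  )

  geom <- structure(list(
    n_arms = as.integer(n_arms),
    arm_angles = ang,
    arm_length_cm = arm_length_cm, arm_width_cm = arm_width_cm,
    platform_radius_cm = platform_radius_cm,
    cm_per_px = cm_per_px,
    arm_length_px = len_px, arm_width_px = wid_px,
    platform_radius_px = r_px,
    image_size = c(w, h), center = center,
    platform_grid_frac = platform_grid_frac,
    entry_lines = entry_lines
  ), class = "maze_geometry")

  geom$zone_map <- .rasterize_zones(geom)
  geom$mask <- matrix(as.integer(!is.na(geom$zone_map)), nrow = h, ncol = w)
  geom$zones <- .zone_table(geom)
  geom
}

#' @export
print.maze_geometry <- function(x, ...) {
  cat(sprintf(
    "<maze_geometry> %d arms, arm %.0f x %.0f cm, platform r = %.1f cm,\n",
    x$n_arms, x$arm_length_cm, x$arm_width_cm, x$platform_radius_cm))
  cat(sprintf("  %.3g cm/px, image %d x %d px, %d zones\n",
              x$cm_per_px, x$image_size[1], x$image_size[2], nrow(x$zones)))
  invisible(x)
}

# zone id layout: platform pieces 0..8 (row-major 3x3 grid bands),
# then arm k segment s -> 9 + 10 k + s, s = 0 proximal .. 9 distal.
.n_zones <- function(geom) geom$n_arms * 10L + 9L

# vectorized core classification; returns list of equal-length vectors
.classify_xy <- function(geom, x, y) {
  dx <- x - geom$center[1]; dy <- y - geom$center[2]
  d <- sqrt(dx^2 + dy^2)
  r <- geom$platform_radius_px
  n <- length(x)
  region <- rep("outside", n)
  arm <- rep(NA_integer_, n)
  seg <- rep(NA_integer_, n)
  piece <- rep(NA_integer_, n)

  on_platform <- d <= r
  region[on_platform] <- "platform"
  a <- geom$platform_grid_frac * r
  band <- function(v) 1L + (v > -a) + (v > a)   # 1, 2, 3
  piece[on_platform] <- (band(dy[on_platform]) - 1L) * 3L +
    band(dx[on_platform]) - 1L

  seg_len <- geom$arm_length_px / 10
  for (k in seq_len(geom$n_arms)) {
    th <- geom$arm_angles[k]
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    in_arm <- !on_platform & is.na(arm) &
      u >= r & u <= r + geom$arm_length_px & abs(v) <= geom$arm_width_px / 2
    if (any(in_arm)) {
      region[in_arm] <- "arm"
      arm[in_arm] <- k - 1L
      s <- pmin(9L, pmax(0L, as.integer(floor((u[in_arm] - r) / seg_len))))
      seg[in_arm] <- s
    }
  }
  zone <- rep(NA_integer_, n)
  zone[region == "platform"] <- piece[region == "platform"]
  ia <- region == "arm"
  zone[ia] <- 9L + 10L * arm[ia] + seg[ia]
  list(region = region, arm_index = arm, segment_index = seg,
       piece_index = piece, zone_id = zone)
}

#' Classify points against the maze geometry
#'
#' Labels each point as `platform`, `arm` or `outside`, and, when inside the
#' footprint, assigns its statistical zone.
#'
#' @param geom A [maze_geometry()].
#' @param x,y Point coordinates in pixels (vectors of equal length).
#' @return A tibble with one row per point: `x`, `y`, `region`,
#'   `arm_index` (0-based, `NA` off-arm), `segment_index` (0 = proximal,
#'   9 = distal, `NA` off-arm), `piece_index` (platform piece 0-8) and
#'   `zone_id` (`NA` outside the footprint).
#' @export
classify_points <- function(geom, x, y) {
  stopifnot(inherits(geom, "maze_geometry"), length(x) == length(y))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("point coordinates must be finite", call. = FALSE)
  cl <- .classify_xy(geom, x, y)
  tibble::tibble(x = x, y = y, region = cl$region,
                 arm_index = cl$arm_index, segment_index = cl$segment_index,
                 piece_index = cl$piece_index, zone_id = cl$zone_id)
}

.rasterize_zones <- function(geom) {
  w <- geom$image_size[1]; h <- geom$image_size[2]
  xs <- rep(0:(w - 1), each = h)
  ys <- rep(0:(h - 1), times = w)
  cl <- .classify_xy(geom, xs, ys)
  matrix(cl$zone_id, nrow = h, ncol = w)
}

.zone_table <- function(geom) {
  nz <- .n_zones(geom)
  area_px <- tabulate(geom$zone_map + 1L, nbins = nz)
  ids <- 0:(nz - 1)
  kind <- ifelse(ids < 9, "platform-piece", "arm-segment")
  arm <- ifelse(ids < 9, NA_integer_, (ids - 9L) %/% 10L)
  seg <- ifelse(ids < 9, NA_integer_, (ids - 9L) %% 10L)
  piece <- ifelse(ids < 9, ids, NA_integer_)
  poly <- lapply(ids, function(i) .zone_polygon(geom, i))
  tibble::tibble(zone_id = ids, kind = kind, arm_index = as.integer(arm),
                 segment_index = as.integer(seg),
                 piece_index = as.integer(piece),
                 area_px = area_px,
                 area_cm2 = area_px * geom$cm_per_px^2,
                 polygon = poly)
}

# Zone outline as an (n x 2) matrix of (x, y) vertices. Arm segments are
# exact rectangles; platform pieces are grid cells clipped to the disc,
# sampled densely along the boundary (arc parts approximated by radial
# projection of out-of-disc boundary points onto the circle).
.zone_polygon <- function(geom, zone_id, pts_per_edge = 80) {
  cx <- geom$center[1]; cy <- geom$center[2]
  r <- geom$platform_radius_px
  if (zone_id >= 9) {
    k <- (zone_id - 9) %/% 10; s <- (zone_id - 9) %% 10
    th <- geom$arm_angles[k + 1]
    seg_len <- geom$arm_length_px / 10
    u0 <- r + s * seg_len; u1 <- u0 + seg_len
    v <- geom$arm_width_px / 2
    corners <- rbind(c(u0, -v), c(u1, -v), c(u1, v), c(u0, v))
    x <- cx + corners[, 1] * cos(th) - corners[, 2] * sin(th)
    y <- cy + corners[, 1] * sin(th) + corners[, 2] * cos(th)
    return(cbind(x = x, y = y))
  }
  a <- geom$platform_grid_frac * r
  brk <- c(-r - 1e-9, -a, a, r + 1e-9)
  col <- zone_id %% 3; row <- zone_id %/% 3
  x0 <- brk[col + 1]; x1 <- brk[col + 2]
  y0 <- brk[row + 1]; y1 <- brk[row + 2]
  rect <- rbind(
    cbind(seq(x0, x1, length.out = pts_per_edge), y0),
    cbind(x1, seq(y0, y1, length.out = pts_per_edge)),
    cbind(seq(x1, x0, length.out = pts_per_edge), y1),
    cbind(x0, seq(y1, y0, length.out = pts_per_edge)))
  d <- sqrt(rect[, 1]^2 + rect[, 2]^2)
  out <- d > r
  rect[out, ] <- rect[out, ] * (r / d[out])
  cbind(x = cx + rect[, 1], y = cy + rect[, 2])
}

#' Render the filled maze footprint mask
#'
#' @param geom A [maze_geometry()].
#' @return Integer 0/1 matrix of size `image_size`, 1 inside the maze
#'   footprint (platform plus arms), 0 outside.
#' @export
render_mask <- function(geom) {
  stopifnot(inherits(geom, "maze_geometry"))
  geom$mask
}

#' Distance from a point to an arm's entry line
#'
#' Euclidean distance from `(x, y)` to the segment spanning the proximal
#' (platform-side) end of an arm.
#'
#' @param geom A [maze_geometry()].
#' @param arm_index 0-based arm index.
#' @param x,y Point coordinates in pixels (vectorized).
#' @return Non-negative distances in pixels.
#' @export
entry_line_distance <- function(geom, arm_index, x, y) {
  stopifnot(inherits(geom, "maze_geometry"))
  if (length(arm_index) != 1 || is.na(arm_index) ||
      arm_index < 0 || arm_index >= geom$n_arms)
    stop("arm_index must be a single value in 0..n_arms-1", call. = FALSE)
  ln <- geom$entry_lines[arm_index + 1, ]
  .point_segment_distance(x, y, ln$x1, ln$y1, ln$x2, ln$y2)
}

.point_segment_distance <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx^2 + vy^2
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / len2))
  sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
}

# signed along-axis / cross-axis coordinates of points in arm k's frame:
# u measured from the maze center along the arm axis, v across it.
.arm_frame <- function(geom, arm_index, x, y) {
  th <- geom$arm_angles[arm_index + 1]
  dx <- x - geom$center[1]; dy <- y - geom$center[2]
  list(u = dx * cos(th) + dy * sin(th), v = -dx * sin(th) + dy * cos(th))
}
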