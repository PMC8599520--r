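# File interfaces: PNG frame directories in, trajectory / summary CSV and
# rendered bitmaps out, plus the YAML maze-geometry config.

#' Read a directory of frames
#'
#' Frames are PNG images named so that lexicographic order is frame order;
#' they are returned lazily as a [frame_source()] with gray levels in
#' 0-255 (RGB frames are kept as arrays and converted during tracking).
#'
#' @param path Directory containing the frames.
#' @param fps Frame rate; frame i is timestamped `(i - 1) / fps`.
#' @return A [frame_source()].
#' @export
read_frames <- function(path, fps) {
  if (!dir.exists(path))
    stop("frame directory does not exist: ", path, call. = FALSE)
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0)
    stop("no PNG frames found in ", path, call. = FALSE)
  frame_source(function(i) {
    img <- png::readPNG(files[i])
    if (length(dim(img)) == 3) img <- img[, , 1:3, drop = FALSE]
    img * 255
  }, length(files), fps)
}

#' Write frames as PNG files
#'
#' Gray matrices (0-255) are written as 8-bit grayscale PNGs named
#' `frame_00001.png`, ... Binary 0/1 images may be passed directly; they
#' are scaled to 0/255.
#'
#' @param frames List of gray matrices, or a [frame_source()].
#' @param path Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_frames <- function(frames, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (inherits(frames, "frame_source"))
    frames <- lapply(seq_len(frames$n_frames), frames$get_frame)
  out <- character(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (max(f) <= 1) f <- f * 255
    out[i] <- file.path(path, sprintf("frame_%05d.png", i))
    png::writePNG(f / 255, out[i])
  }
  invisible(out)
}

.annotate_trajectory <- function(traj, geom) {
  cl <- classify_points(geom,
                        ifelse(is.finite(traj$x_px), traj$x_px, -1),
                        ifelse(is.finite(traj$y_px), traj$y_px, -1))
  dplyr::mutate(traj,
                x_cm = traj$x_px * geom$cm_per_px,
                y_cm = traj$y_px * geom$cm_per_px,
                region = ifelse(is.finite(traj$x_px), cl$region, NA),
                zone_id = ifelse(is.finite(traj$x_px), cl$zone_id,
                                 NA_integer_))
}

#' Write session outputs
#'
#' Writes four files into `outdir`: `trajectory.csv` (columns `t_s`,
#' `x_px`, `y_px`, `x_cm`, `y_cm`, `region`, `zone_id`, `found`,
#' `source`), `summary.csv` (the session report, one row, list columns
#' flattened), `trajectory.png` (the food-search path over the maze
#' outline) and `zone_heatmap.png` (per-zone sample counts).
#'
#' @param traj Trajectory tibble.
#' @param report One-row report from [session_report()].
#' @param geom A [maze_geometry()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_outputs <- function(traj, report, geom, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(outdir, c("trajectory.csv", "summary.csv",
                               "trajectory.png", "zone_heatmap.png"))
  ann <- .annotate_trajectory(traj, geom)
  # serialize coordinates at full precision so a written trajectory reads
  # back bit-identical
  for (cc in c("t_s", "x_px", "y_px", "x_cm", "y_cm"))
    ann[[cc]] <- sprintf("%.17g", ann[[cc]])
  readr::write_csv(ann, paths[1])

  flat <- report[, !(names(report) %in% c("entries", "arm_sequence"))]
  ent <- report$entries[[1]]
  for (k in seq_along(ent)) flat[[paste0("entries_arm", k)]] <- ent[k]
  flat$arm_sequence <- paste(report$arm_sequence[[1]], collapse = ">")
  readr::write_csv(flat, paths[2])

  png::writePNG(.trajectory_bitmap(traj, geom), paths[3])
  png::writePNG(.heatmap_bitmap(zone_histogram(traj, geom), geom), paths[4])
  invisible(paths)
}

#' Read a trajectory CSV written by [write_outputs()]
#'
#' @param path CSV path.
#' @param cm_per_px Optional scale to attach to the result.
#' @return Trajectory tibble.
#' @export
read_trajectory <- function(path, cm_per_px = NULL) {
  # base parser: its decimal-to-double conversion is correctly rounded,
  # so coordinates written at full precision read back bit-identical
  traj <- tibble::as_tibble(utils::read.csv(path))
  if (!is.null(cm_per_px)) attr(traj, "cm_per_px") <- cm_per_px
  if (nrow(traj) > 1)
    attr(traj, "sample_period") <- traj$t_s[2] - traj$t_s[1]
  traj
}

# path drawn black over white, maze outline mid-gray
.trajectory_bitmap <- function(traj, geom) {
  w <- geom$image_size[1]; h <- geom$image_size[2]
  img <- matrix(1, nrow = h, ncol = w)
  edge <- geom$mask - img_erode(geom$mask, structuring_element(3))
  img[edge == 1] <- 0.6
  tr <- .traj_xy(traj)
  xi <- pmin(pmax(round(tr$x_px), 0), w - 1)
  yi <- pmin(pmax(round(tr$y_px), 0), h - 1)
  img[cbind(yi + 1, xi + 1)] <- 0
  img
}

# per-zone counts as a color ramp over the zone raster
.heatmap_bitmap <- function(zone_counts, geom) {
  w <- geom$image_size[1]; h <- geom$image_size[2]
  pal <- grDevices::colorRamp(c("navy", "cyan", "yellow", "red"))
  mx <- max(zone_counts$n, 1)
  cols <- pal(zone_counts$n / mx) / 255
  img <- array(0.15, dim = c(h, w, 3))
  zm <- geom$zone_map
  for (ch in 1:3) {
    plane <- img[, , ch]
    inside <- !is.na(zm)
    plane[inside] <- cols[zm[inside] + 1L, ch]
    img[, , ch] <- plane
  }
  img
}

#' Write / read a maze geometry config
#'
#' The geometry is stored as a small YAML file of the constructor
#' arguments (angles in degrees, lengths in centimeters, scale in
#' cm/pixel), so a config read back reproduces the geometry exactly.
#'
#' @param geom A [maze_geometry()].
#' @param path YAML file path.
#' @return `write_maze_config`: invisibly, `path`. `read_maze_config`: a
#'   [maze_geometry()].
#' @export
write_maze_config <- function(geom, path) {
  stopifnot(inherits(geom, "maze_geometry"))
  yaml::write_yaml(list(
    n_arms = geom$n_arms,
    arm_angles_deg = geom$arm_angles * 180 / pi,
    arm_length_cm = geom$arm_length_cm,
    arm_width_cm = geom$arm_width_cm,
    platform_radius_cm = geom$platform_radius_cm,
    cm_per_px = geom$cm_per_px,
    image_size = geom$image_size,
    center = geom$center,
    platform_grid_frac = geom$platform_grid_frac
  ), path)
  invisible(path)
}

#' @rdname write_maze_config
#' @export
read_maze_config <- function(path) {
  if (!file.exists(path))
    stop("config file does not exist: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  do.call(maze_geometry, cfg)
}
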