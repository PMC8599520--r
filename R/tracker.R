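# Per-frame localization: binarize the frame, duplicate it, intersect one
# copy with the maze mask, open both, intersect the results, and take the
# largest qualifying white component as the rat.

#' Tracker parameters
#'
#' @param threshold Binarization cut (gray levels above it are foreground).
#' @param se_size Side of the square structuring element used for opening
#'   (odd).
#' @param sample_period Logging period in seconds; one trajectory point is
#'   recorded per period.
#' @param min_component_area Smallest component area (pixels) accepted as a
#'   rat candidate. The default equals the area of the 5x5 element, the
#'   smallest shape that can survive the opening.
#' @param crop Optional `c(x0, y0)` top-left offset (0-based pixels) of the
#'   maze subimage within larger frames; the crop size is the geometry's
#'   `image_size`.
#' @return A list of class `tracker_params`.
#' @export
tracker_params <- function(threshold = 127, se_size = 5,
                           sample_period = 0.05,
                           min_component_area = 25, crop = NULL) {
  stopifnot(sample_period > 0, se_size %% 2 == 1, se_size >= 1,
            min_component_area >= 1)
  structure(list(threshold = threshold, se_size = as.integer(se_size),
                 sample_period = sample_period,
                 min_component_area = min_component_area, crop = crop),
            class = "tracker_params")
}

.crop_frame <- function(frame, geom, params) {
  w <- geom$image_size[1]; h <- geom$image_size[2]
  cr <- params$crop %||% c(0L, 0L)
  if (length(dim(frame)) == 3) {
    frame <- frame[cr[2] + seq_len(h), cr[1] + seq_len(w), , drop = FALSE]
    frame <- rgb_to_gray(frame)
  } else {
    frame <- frame[cr[2] + seq_len(h), cr[1] + seq_len(w), drop = FALSE]
  }
  frame
}

.centroid_in_mask <- function(geom, x, y) {
  xi <- pmin(pmax(round(x), 0), geom$image_size[1] - 1)
  yi <- pmin(pmax(round(y), 0), geom$image_size[2] - 1)
  geom$mask[cbind(yi + 1, xi + 1)] == 1
}

#' Locate the rat in one frame
#'
#' Implements the dual-image procedure: the cropped frame is converted to
#' gray (if needed) and binarized; copy 1 is intersected with the maze
#' footprint mask and opened, copy 2 is opened directly, and the two
#' results are intersected. Components of the intersection with area at
#' least `min_component_area` and centroid inside the mask are the rat
#' candidates: a single candidate is the rat; among several the largest is
#' taken (residual noise after masking and opening is smaller than the
#' rat); with none, the masked-and-opened image alone is consulted; if that
#' also yields nothing the previous position is carried forward.
#'
#' @param frame Gray matrix (0-255) or RGB array covering the crop.
#' @param geom A [maze_geometry()].
#' @param params A [tracker_params()].
#' @param prev Optional previous position `c(x, y)` used when the rat is
#'   not found.
#' @param t Timestamp (seconds) stored in the result.
#' @return One-row tibble: `t_s`, `x_px`, `y_px`, `found`, `source`
#'   (`single-outline`, `largest-in-maze`, `intersection-fallback` or
#'   `carried-forward`). When nothing is found and no `prev` exists,
#'   `found` is `FALSE` and the coordinates are `NA`.
#' @export
locate_rat <- function(frame, geom, params = tracker_params(),
                       prev = NULL, t = NA_real_) {
  stopifnot(inherits(geom, "maze_geometry"))
  g <- .crop_frame(frame, geom, params)
  se <- structuring_element(params$se_size)
  bin <- binarize(g, params$threshold)
  img1pp <- img_open(intersect_images(bin, geom$mask), se)
  img2p <- img_open(bin, se)
  comb <- intersect_images(img1pp, img2p)

  pick <- function(img) {
    comp <- extract_components(img)
    comp <- comp[comp$area >= params$min_component_area, , drop = FALSE]
    if (nrow(comp) == 0) return(NULL)
    comp <- comp[.centroid_in_mask(geom, comp$x, comp$y), , drop = FALSE]
    if (nrow(comp) == 0) return(NULL)
    comp
  }

  cand <- pick(comb)
  if (!is.null(cand)) {
    src <- if (nrow(cand) == 1) "single-outline" else "largest-in-maze"
    return(tibble::tibble(t_s = t, x_px = cand$x[1], y_px = cand$y[1],
                          found = TRUE, source = src))
  }
  cand <- pick(img1pp)
  if (!is.null(cand)) {
    return(tibble::tibble(t_s = t, x_px = cand$x[1], y_px = cand$y[1],
                          found = TRUE, source = "intersection-fallback"))
  }
  if (!is.null(prev) && all(is.finite(prev))) {
    return(tibble::tibble(t_s = t, x_px = prev[1], y_px = prev[2],
                          found = FALSE, source = "carried-forward"))
  }
  tibble::tibble(t_s = t, x_px = NA_real_, y_px = NA_real_,
                 found = FALSE, source = "carried-forward")
}

#' Lazy frame source
#'
#' Wraps a frame-producing function so sequences can be tracked without
#' materializing every frame in memory.
#'
#' @param get_frame `function(i)` returning frame `i` (1-based) as a gray
#'   matrix or RGB array.
#' @param n_frames Number of frames.
#' @param fps Frames per second (frame `i` is taken at `(i - 1) / fps`).
#' @return A list of class `frame_source`.
#' @export
frame_source <- function(get_frame, n_frames, fps) {
  stopifnot(is.function(get_frame), n_frames >= 1, fps > 0)
  structure(list(get_frame = get_frame, n_frames = as.integer(n_frames),
                 fps = fps), class = "frame_source")
}

.as_frame_source <- function(frames, fps = NULL) {
  if (inherits(frames, "frame_source")) return(frames)
  if (is.list(frames)) {
    if (length(frames) == 0) stop("empty frame source", call. = FALSE)
    if (is.null(fps)) stop("fps required for a list of frames", call. = FALSE)
    return(frame_source(function(i) frames[[i]], length(frames), fps))
  }
  stop("frames must be a frame_source or a list of frames", call. = FALSE)
}

#' Track a frame sequence
#'
#' Runs [locate_rat()] over a timed frame sequence and logs one position
#' per sample period, using the nearest frame at or before each tick.
#' Frames in which the rat is not found repeat the last known position,
#' flagged `carried-forward`.
#'
#' @param frames A [frame_source()] or list of frames.
#' @param geom A [maze_geometry()].
#' @param params A [tracker_params()].
#' @param fps Frame rate, required when `frames` is a plain list.
#' @return A trajectory tibble: `t_s`, `x_px`, `y_px`, `found`, `source`,
#'   with attributes `sample_period` and `cm_per_px`.
#' @export
track_sequence <- function(frames, geom, params = tracker_params(),
                           fps = NULL) {
  src <- .as_frame_source(frames, fps)
  duration <- src$n_frames / src$fps
  ticks <- seq(0, duration - 1e-9, by = params$sample_period)
  fidx <- pmin(src$n_frames, floor(ticks * src$fps + 1e-9) + 1L)
  out <- vector("list", length(ticks))
  prev <- NULL
  last_i <- -1L
  last_pt <- NULL
  for (k in seq_along(ticks)) {
    i <- fidx[k]
    if (i == last_i) {
      pt <- last_pt
      pt$t_s <- ticks[k]
    } else {
      pt <- locate_rat(src$get_frame(i), geom, params, prev = prev,
                       t = ticks[k])
      last_i <- i
    }
    last_pt <- pt
    if (pt$found) prev <- c(pt$x_px, pt$y_px)
    out[[k]] <- pt
  }
  traj <- dplyr::bind_rows(out)
  attr(traj, "sample_period") <- params$sample_period
  attr(traj, "cm_per_px") <- geom$cm_per_px
  traj
}

#' Detection rate against ground truth
#'
#' Percentage of samples in which the rat was found and the estimate lies
#' within `tol_px` of the true position.
#'
#' @param traj Trajectory tibble from [track_sequence()].
#' @param truth Tibble (or data frame) with columns `x`, `y`, one row per
#'   trajectory row.
#' @param tol_px Tolerance in pixels; a natural choice is half the rat
#'   blob's major axis.
#' @return Percentage in `[0, 100]`.
#' @export
detection_rate <- function(traj, truth, tol_px = 15) {
  if (nrow(traj) != nrow(truth))
    stop("trajectory and truth lengths differ", call. = FALSE)
  d <- sqrt((traj$x_px - truth$x)^2 + (traj$y_px - truth$y)^2)
  hit <- traj$found & !is.na(d) & d <= tol_px
  100 * mean(hit)
}
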