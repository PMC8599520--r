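# Trajectory-level cognition metrics: food-search path length, average
# speed, zone occupancy, still ("S") spots, per-zone dot statistics and the
# assembled session report.

.traj_scale <- function(traj, cm_per_px) {
  cm_per_px %||% attr(traj, "cm_per_px") %||%
    stop("cm_per_px not given and not attached to the trajectory",
         call. = FALSE)
}

.traj_xy <- function(traj) {
  ok <- is.finite(traj$x_px) & is.finite(traj$y_px)
  traj[ok, , drop = FALSE]
}

#' Food-search path length
#'
#' Sum of distances between consecutive detected positions, in meters.
#' Carried-forward samples repeat the previous position and therefore add
#' no displacement.
#'
#' @param traj Trajectory tibble (`t_s`, `x_px`, `y_px`, ...).
#' @param cm_per_px Image scale; defaults to the trajectory attribute.
#' @return Length in meters.
#' @export
path_length <- function(traj, cm_per_px = NULL) {
  s <- .traj_scale(traj, cm_per_px)
  tr <- .traj_xy(traj)
  if (nrow(tr) < 2) return(0)
  sum(sqrt(diff(tr$x_px)^2 + diff(tr$y_px)^2)) * s / 100
}

#' Average speed over a trajectory
#'
#' Path length divided by elapsed time, in cm/s.
#'
#' @inheritParams path_length
#' @return Speed in cm/s.
#' @export
average_speed <- function(traj, cm_per_px = NULL) {
  tr <- .traj_xy(traj)
  dur <- tr$t_s[nrow(tr)] - tr$t_s[1]
  if (!isTRUE(dur > 0)) stop("trajectory has zero duration", call. = FALSE)
  path_length(traj, cm_per_px) * 100 / dur
}

#' Time fractions per maze region
#'
#' Percentage of samples spent in the central platform, in baited arms and
#' in non-baited arms. The denominator is the total sample count, so the
#' three fractions sum to at most 100 (samples outside the footprint are
#' counted in none).
#'
#' @param traj Trajectory tibble.
#' @param geom A [maze_geometry()].
#' @param baited Baited arm numbers (1-based).
#' @return One-row tibble: `pct_platform`, `pct_baited`, `pct_nonbaited`.
#' @export
region_time_fractions <- function(traj, geom, baited) {
  n <- nrow(traj)
  tr <- .traj_xy(traj)
  cl <- .classify_xy(geom, tr$x_px, tr$y_px)
  arm_no <- cl$arm_index + 1L
  tibble::tibble(
    pct_platform = 100 * sum(cl$region == "platform") / n,
    pct_baited = 100 * sum(cl$region == "arm" & arm_no %in% baited) / n,
    pct_nonbaited = 100 * sum(cl$region == "arm" & !(arm_no %in% baited)) / n
  )
}

#' Detect S spots (staying still)
#'
#' Greedy anchored scan: an S spot opens at sample i when every sample in
#' the window `[t_i, t_i + min_duration_s]` stays within `radius_cm` of the
#' position at i; the spot then extends for as long as samples remain
#' within that radius of the anchor, and the scan resumes after it ends.
#'
#' @param traj Trajectory tibble.
#' @param radius_cm Stillness radius in centimeters.
#' @param min_duration_s Minimum stay to count as a spot, in seconds.
#' @param cm_per_px Image scale; defaults to the trajectory attribute.
#' @return Tibble of non-overlapping spots in time order: `x`, `y` (anchor,
#'   pixels), `start`, `end`, `duration` (seconds).
#' @export
detect_s_spots <- function(traj, radius_cm = 2.5, min_duration_s = 2,
                           cm_per_px = NULL) {
  stopifnot(radius_cm > 0, min_duration_s > 0)
  s <- .traj_scale(traj, cm_per_px)
  tr <- .traj_xy(traj)
  n <- nrow(tr)
  r_px <- radius_cm / s
  out <- list()
  i <- 1L
  while (i <= n) {
    d <- sqrt((tr$x_px - tr$x_px[i])^2 + (tr$y_px - tr$y_px[i])^2)
    inside <- d[i:n] <= r_px
    run_end <- if (all(inside)) n else i + which(!inside)[1] - 2L
    if (tr$t_s[run_end] - tr$t_s[i] >= min_duration_s) {
      out[[length(out) + 1L]] <- tibble::tibble(
        x = tr$x_px[i], y = tr$y_px[i],
        start = tr$t_s[i], end = tr$t_s[run_end],
        duration = tr$t_s[run_end] - tr$t_s[i])
      i <- run_end + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(x = double(), y = double(), start = double(),
                          end = double(), duration = double()))
  dplyr::bind_rows(out)
}

#' Per-zone sample counts
#'
#' Counts trajectory samples falling in each of the maze's statistical
#' zones (89 for the default maze), the per-piece dot statistics used for
#' occupancy heatmaps.
#'
#' @param traj Trajectory tibble.
#' @param geom A [maze_geometry()].
#' @return Tibble with one row per zone: `zone_id`, `kind`, `arm_index`,
#'   `segment_index`, `n`.
#' @export
zone_histogram <- function(traj, geom) {
  tr <- .traj_xy(traj)
  cl <- .classify_xy(geom, tr$x_px, tr$y_px)
  nz <- .n_zones(geom)
  counts <- tabulate(cl$zone_id + 1L, nbins = nz)
  dplyr::mutate(
    geom$zones[c("zone_id", "kind", "arm_index", "segment_index")],
    n = counts)
}

#' Assemble the session report
#'
#' Collects every cognition quantity of a session into one row: latency,
#' memory errors, path length, average speed, region time fractions, S-spot
#' count and total duration, per-arm entry counts and the sequence of
#' entered arms. When the session completed, the trajectory is truncated at
#' the completion time first.
#'
#' @param traj Trajectory tibble.
#' @param state Final [ram_state()] for the session.
#' @param geom A [maze_geometry()].
#' @param radius_cm,min_duration_s S-spot parameters, see
#'   [detect_s_spots()].
#' @return One-row tibble; `entries` and `arm_sequence` are list columns.
#' @export
session_report <- function(traj, state, geom,
                           radius_cm = 2.5, min_duration_s = 2) {
  stopifnot(inherits(state, "ram_state"))
  if (state$complete) traj <- traj[traj$t_s <= state$end_time, ]
  baited <- which(state$ever_baited == 1L)
  frac <- region_time_fractions(traj, geom, baited)
  spots <- detect_s_spots(traj, radius_cm, min_duration_s,
                          cm_per_px = geom$cm_per_px)
  ev <- tidy(state)
  tibble::tibble(
    latency_s = if (state$complete) latency(state) else NA_real_,
    short_term_errors = state$short_term_errors,
    long_term_errors = state$long_term_errors,
    path_length_m = path_length(traj, geom$cm_per_px),
    avg_speed_cm_s = average_speed(traj, geom$cm_per_px),
    pct_time_platform = frac$pct_platform,
    pct_time_baited_arms = frac$pct_baited,
    pct_time_nonbaited_arms = frac$pct_nonbaited,
    n_s_spots = nrow(spots),
    s_spot_duration_s = sum(spots$duration),
    complete = state$complete,
    entries = list(state$entry),
    arm_sequence = list(ev$arm[ev$event == "entry"])
  )
}
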