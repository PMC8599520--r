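# "Access to arms" monitoring: a per-sample state machine that detects arm
# entries and exits at the proximal entry line, keeps per-arm food flags
# (AF) and entry counters, scores working-memory (short-term) and
# reference-memory (long-term) errors, and declares the session complete
# once every baited arm has been emptied.

#' Behavioral scoring parameters
#'
#' @param entry_distance_px Distance threshold for the entry/exit line
#'   test, in pixels. Default (`NULL`): half the arm width of the geometry
#'   in use.
#' @param food_zone Arm segment index whose occupation empties the arm's
#'   food flag (default 9, the distal segment).
#' @return A list of class `behavior_params`.
#' @export
behavior_params <- function(entry_distance_px = NULL, food_zone = 9) {
  if (!is.null(entry_distance_px) && entry_distance_px <= 0)
    stop("entry_distance_px must be positive", call. = FALSE)
  stopifnot(food_zone %in% 0:9)
  structure(list(entry_distance_px = entry_distance_px,
                 food_zone = as.integer(food_zone)),
            class = "behavior_params")
}

#' Initialize a session scoring state
#'
#' @param baited Arm numbers (1-based) containing food at session start.
#' @param n_arms Number of arms.
#' @return An object of class `ram_state` holding the current arm
#'   (`maze_state`, 0 = platform/no arm), per-arm food flags `af`, entry
#'   counters, error counters, clocks and the event log.
#' @export
ram_state <- function(baited, n_arms = 8) {
  baited <- as.integer(baited)
  if (anyDuplicated(baited) || any(baited < 1) || any(baited > n_arms))
    stop("baited must be distinct arm numbers in 1..n_arms", call. = FALSE)
  af <- integer(n_arms)
  af[baited] <- 1L
  structure(list(
    n_arms = as.integer(n_arms),
    maze_state = 0L,
    af = af,
    ever_baited = af,
    entry = integer(n_arms),
    short_term_errors = 0L,
    long_term_errors = 0L,
    start_time = NA_real_,
    end_time = NA_real_,
    complete = FALSE,
    events = list()
  ), class = "ram_state")
}

#' @export
print.ram_state <- function(x, ...) {
  cat(sprintf(
    "<ram_state> arm %d | entries %s | AF %s | ST err %d | LT err %d | %s\n",
    x$maze_state, paste(x$entry, collapse = ""),
    paste(x$af, collapse = ""), x$short_term_errors, x$long_term_errors,
    if (x$complete) sprintf("complete at %.2f s", x$end_time) else "running"))
  invisible(x)
}

.log_event <- function(state, t, event, arm = NA_integer_) {
  state$events[[length(state$events) + 1L]] <- list(t = t, event = event,
                                                    arm = arm)
  state
}

# entry scoring (at entry time): re-entry into any previously entered arm
# is a short-term error; the first entry into a never-baited arm is a
# long-term error.
.score_entry <- function(state, k, t) {
  if (state$entry[k] > 0L) {
    state$short_term_errors <- state$short_term_errors + 1L
  } else if (state$ever_baited[k] == 0L) {
    state$long_term_errors <- state$long_term_errors + 1L
  }
  state$entry[k] <- state$entry[k] + 1L
  state$maze_state <- k
  .log_event(state, t, "entry", k)
}

#' Advance the scoring state by one position sample
#'
#' Entry is detected when the rat's center is on the arm side of an arm's
#' entry line — either within `entry_distance_px` of the line or anywhere
#' inside the arm (so a fast crossing sampled past the threshold band is
#' still caught). Exit is the symmetric test toward the platform. While
#' inside a baited arm, reaching the distal food segment clears the arm's
#' food flag; when the last flag clears the session is complete and the
#' state freezes.
#'
#' @param state A [ram_state()].
#' @param x,y Position in pixels.
#' @param t Time in seconds.
#' @param geom A [maze_geometry()].
#' @param params A [behavior_params()].
#' @return The updated `ram_state`.
#' @export
update_state <- function(state, x, y, t, geom,
                         params = behavior_params()) {
  stopifnot(inherits(state, "ram_state"), inherits(geom, "maze_geometry"))
  if (state$complete) return(state)
  if (is.na(state$start_time)) state$start_time <- t
  if (!is.finite(x) || !is.finite(y)) {
    return(.check_complete(state, t))
  }
  thr <- params$entry_distance_px %||% (geom$arm_width_px / 2)
  cl <- .classify_xy(geom, x, y)
  in_arm <- !is.na(cl$arm_index)

  if (state$maze_state == 0L) {
    k <- .entry_candidate(geom, x, y, cl, thr)
    if (!is.na(k)) state <- .score_entry(state, k, t)
  } else {
    k <- state$maze_state
    if (in_arm && cl$arm_index + 1L == k) {
      if (cl$segment_index == params$food_zone && state$af[k] == 1L) {
        state$af[k] <- 0L
        state <- .log_event(state, t, "food", k)
      }
    } else {
      uf <- .arm_frame(geom, k - 1L, x, y)
      near_line <- entry_line_distance(geom, k - 1L, x, y) < thr
      exits <- cl$region == "platform" || in_arm ||
        (near_line && uf$u < geom$platform_radius_px)
      if (exits) {
        state$maze_state <- 0L
        state <- .log_event(state, t, "exit", k)
        if (in_arm) state <- .score_entry(state, cl$arm_index + 1L, t)
      }
    }
  }
  .check_complete(state, t)
}

.entry_candidate <- function(geom, x, y, cl, thr) {
  if (!is.na(cl$arm_index)) return(cl$arm_index + 1L)
  best <- NA_integer_; best_d <- Inf
  for (k in seq_len(geom$n_arms)) {
    d <- entry_line_distance(geom, k - 1L, x, y)
    if (d < thr && d < best_d) {
      uf <- .arm_frame(geom, k - 1L, x, y)
      if (uf$u > geom$platform_radius_px) { best <- k; best_d <- d }
    }
  }
  best
}

.check_complete <- function(state, t) {
  if (!state$complete && max(c(state$af, 0L)) == 0L) {
    state$complete <- TRUE
    state$end_time <- t
    state <- .log_event(state, t, "complete")
  }
  state
}

#' Score a whole trajectory
#'
#' Feeds every trajectory sample through [update_state()]. Samples with
#' missing coordinates (rat never yet found) advance the clock only.
#'
#' @param traj Trajectory tibble with columns `t_s`, `x_px`, `y_px`.
#' @param geom A [maze_geometry()].
#' @param baited Baited arm numbers (1-based).
#' @param params A [behavior_params()].
#' @return The final `ram_state` (with full event log).
#' @export
score_trajectory <- function(traj, geom, baited,
                             params = behavior_params()) {
  state <- ram_state(baited, n_arms = geom$n_arms)
  for (i in seq_len(nrow(traj))) {
    state <- update_state(state, traj$x_px[i], traj$y_px[i], traj$t_s[i],
                          geom, params)
    if (state$complete) break
  }
  state
}

#' Latency of a completed session
#'
#' Time from the first position sample until the last baited arm was
#' emptied.
#'
#' @param state A completed [ram_state()].
#' @return Seconds.
#' @export
latency <- function(state) {
  stopifnot(inherits(state, "ram_state"))
  if (!state$complete) stop("session not complete", call. = FALSE)
  state$end_time - state$start_time
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Event log of a session state
#'
#' @param x A `ram_state`.
#' @param ... Unused.
#' @return Tibble with columns `t`, `event` (`entry`, `exit`, `food`,
#'   `complete`) and `arm` (1-based, `NA` for `complete`).
#' @exportS3Method generics::tidy
#' @export
tidy.ram_state <- function(x, ...) {
  if (length(x$events) == 0)
    return(tibble::tibble(t = double(), event = character(),
                          arm = integer()))
  tibble::tibble(
    t = vapply(x$events, `[[`, 0, "t"),
    event = vapply(x$events, `[[`, "", "event"),
    arm = vapply(x$events, function(e) as.integer(e$arm), 0L)
  )
}

#' One-row summary of a session state
#'
#' @param x A `ram_state`.
#' @param ... Unused.
#' @return One-row tibble: error counters, total entries, completion flag
#'   and latency (`NA` while incomplete).
#' @exportS3Method generics::glance
#' @export
glance.ram_state <- function(x, ...) {
  tibble::tibble(
    short_term_errors = x$short_term_errors,
    long_term_errors = x$long_term_errors,
    n_entries = sum(x$entry),
    n_arms_entered = sum(x$entry > 0),
    complete = x$complete,
    latency_s = if (x$complete) x$end_time - x$start_time else NA_real_
  )
}
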