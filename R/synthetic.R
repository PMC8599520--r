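# Ground-truthed synthetic infrared scenes: a dark background, a bright
# rat ellipse moving along a scripted path, persistent dropping-sized
# noise spots, bright clutter outside the maze footprint and an optional
# intruder shape, rendered as 8-bit gray frames with per-frame truth.

#' Scripted rat path
#'
#' Constant-speed linear interpolation between waypoints, with optional
#' dwell (pause) time at each waypoint, sampled at the frame rate. Events
#' are derived independently of the scoring state machine by classifying
#' each sample against the geometry: a platform-to-arm transition is an
#' entry, the reverse an exit, and the first arrival in an arm's distal
#' segment per visit a food-zone arrival; dwells are logged as pauses.
#'
#' @param waypoints Two-column matrix or data frame of (x, y) waypoints in
#'   pixels; all must lie inside the maze footprint.
#' @param speeds Speeds for each leg in cm/s (length `nrow(waypoints) - 1`,
#'   recycled).
#' @param fps Frames per second.
#' @param geom A [maze_geometry()] (classifies positions and scales
#'   speeds).
#' @param dwell Dwell time in seconds at each waypoint (recycled).
#' @return List with `path` (tibble `frame`, `t`, `x`, `y`) and `events`
#'   (tibble `t`, `event`, `arm`).
#' @export
scripted_path <- function(waypoints, speeds, fps, geom, dwell = 0) {
  wp <- as.matrix(waypoints)[, 1:2, drop = FALSE]
  n_wp <- nrow(wp)
  stopifnot(n_wp >= 1, fps > 0, all(speeds > 0))
  cl <- .classify_xy(geom, wp[, 1], wp[, 2])
  if (any(cl$region == "outside"))
    stop("waypoints must lie inside the maze footprint", call. = FALSE)
  dwell <- rep_len(dwell, n_wp)
  if (n_wp == 1 && dwell[1] <= 0)
    stop("a single-waypoint path needs a positive dwell time", call. = FALSE)
  speeds <- if (n_wp > 1) rep_len(speeds, n_wp - 1) else numeric()

  # piecewise schedule: dwell at waypoint 1, leg 1, dwell at waypoint 2, ...
  seg <- list(); t0 <- 0
  add <- function(dur, p0, p1) {
    if (dur > 0) seg[[length(seg) + 1L]] <<- c(t0, t0 + dur, p0, p1)
    t0 <<- t0 + dur
  }
  for (i in seq_len(n_wp)) {
    add(dwell[i], wp[i, ], wp[i, ])
    if (i < n_wp) {
      len_cm <- sqrt(sum((wp[i + 1, ] - wp[i, ])^2)) * geom$cm_per_px
      add(len_cm / speeds[i], wp[i, ], wp[i + 1, ])
    }
  }
  total <- t0
  sched <- do.call(rbind, seg)
  n_frames <- floor(total * fps + 1e-9) + 1L
  t <- (seq_len(n_frames) - 1L) / fps
  si <- pmax(1L, pmin(nrow(sched), findInterval(t, sched[, 1])))
  frac <- ifelse(sched[si, 2] > sched[si, 1],
                 (t - sched[si, 1]) / (sched[si, 2] - sched[si, 1]), 0)
  frac <- pmin(1, pmax(0, frac))
  x <- sched[si, 3] + frac * (sched[si, 5] - sched[si, 3])
  y <- sched[si, 4] + frac * (sched[si, 6] - sched[si, 4])
  path <- tibble::tibble(frame = seq_len(n_frames), t = t, x = x, y = y)
  if (any(.classify_xy(geom, x, y)$region == "outside"))
    stop("path leaves the maze footprint between waypoints; ",
         "route legs through the platform or along an arm", call. = FALSE)

  pcl <- .classify_xy(geom, x, y)
  arm_no <- ifelse(is.na(pcl$arm_index), 0L, pcl$arm_index + 1L)
  ev <- list()
  cur <- 0L; fed <- FALSE
  for (i in seq_len(n_frames)) {
    if (arm_no[i] != cur) {
      if (cur != 0L)
        ev[[length(ev) + 1L]] <- list(t = t[i], event = "exit", arm = cur)
      if (arm_no[i] != 0L) {
        ev[[length(ev) + 1L]] <- list(t = t[i], event = "entry",
                                      arm = arm_no[i])
        fed <- FALSE
      }
      cur <- arm_no[i]
    }
    if (cur != 0L && !fed && isTRUE(pcl$segment_index[i] == 9L)) {
      ev[[length(ev) + 1L]] <- list(t = t[i], event = "food_zone", arm = cur)
      fed <- TRUE
    }
  }
  for (i in seq_len(n_wp)) {
    if (dwell[i] > 0) {
      ts <- sum(dwell[seq_len(i - 1)]) +
        if (i > 1) sum(sapply(seq_len(i - 1), function(j)
          sqrt(sum((wp[j + 1, ] - wp[j, ])^2)) * geom$cm_per_px / speeds[j]))
        else 0
      ev[[length(ev) + 1L]] <- list(t = ts, event = "pause", arm = NA_integer_)
    }
  }
  events <- if (length(ev) == 0) {
    tibble::tibble(t = double(), event = character(), arm = integer())
  } else {
    tibble::tibble(t = vapply(ev, `[[`, 0, "t"),
                   event = vapply(ev, `[[`, "", "event"),
                   arm = vapply(ev, function(e) as.integer(e$arm), 0L))
  }
  list(path = path, events = events[order(events$t), ])
}

#' Synthetic scene configuration
#'
#' @param geom A [maze_geometry()].
#' @param fps Frames per second.
#' @param waypoints,speeds,dwell Rat path script, see [scripted_path()].
#' @param rat List: `major_px`, `minor_px` (full axes of the body ellipse)
#'   and `gray` (> 127; rat bodies are bright under infrared).
#' @param droppings List: `n` spots, `size_range` (side in px; sizes below
#'   the structuring element vanish under opening, larger ones survive and
#'   exercise the largest-area rule), `gray`, and `deposit_frac` (droppings
#'   are deposited along the path within the first fraction of the
#'   session). `n = 0` disables.
#' @param intruder `NULL`, or a list describing a bright shape entering
#'   from the image edge: `type` (`"strip"`: a rectangle crossing toward
#'   one arm whose tip steps onto the arm's edge; `"occluder"`: a
#'   half-plane covering part of the maze from one side), `arm` (1-based,
#'   for `"strip"`), `t_on`, `t_off` (seconds), `width_px`,
#'   `overlap_px` (how deep the strip tip reaches into the arm), `gray`,
#'   `depth_px` (occluder reach from the image edge).
#' @param background List: `gray` (< 127) and `clutter` (add bright static
#'   structures outside the maze footprint).
#' @param baited Baited arm numbers for the behavioral layer.
#' @param seed Integer seed driving all scene randomness.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(geom, fps, waypoints, speeds, dwell = 0,
                         rat = list(),
                         droppings = list(),
                         intruder = NULL,
                         background = list(),
                         baited = integer(),
                         seed = 1) {
  rat <- utils::modifyList(
    list(major_px = 30, minor_px = 15, gray = 200), rat)
  droppings <- utils::modifyList(
    list(n = 0, size_range = c(2, 8), gray = 180, deposit_frac = 0.6),
    droppings)
  background <- utils::modifyList(
    list(gray = 30, clutter = FALSE), background)
  if (!is.null(intruder))
    intruder <- utils::modifyList(
      list(type = "strip", arm = 1L, t_on = 0, t_off = Inf,
           width_px = 40, overlap_px = 6, gray = 200, depth_px = 80),
      intruder)
  stopifnot(rat$gray > 127, background$gray < 127, fps > 0)
  structure(list(geom = geom, fps = fps, waypoints = waypoints,
                 speeds = speeds, dwell = dwell, rat = rat,
                 droppings = droppings, intruder = intruder,
                 background = background, baited = baited,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# Realize a scene: scripted path, per-frame headings, dropping deposits,
# the static background layer and the intruder pixel mask.
compile_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  geom <- config$geom
  set.seed(config$seed)
  sp <- scripted_path(config$waypoints, config$speeds, config$fps, geom,
                      config$dwell)
  path <- sp$path
  n <- nrow(path)
  dx <- c(diff(path$x), 0); dy <- c(diff(path$y), 0)
  heading <- atan2(dy, dx)
  moving <- sqrt(dx^2 + dy^2) > 1e-9
  th <- 0
  for (i in seq_len(n)) {            # still frames keep the last heading
    if (moving[i]) th <- heading[i]
    heading[i] <- th
  }

  w <- geom$image_size[1]; h <- geom$image_size[2]
  base <- matrix(config$background$gray, nrow = h, ncol = w)
  if (isTRUE(config$background$clutter)) {
    for (cc in list(c(10, 10), c(w - 45, 12), c(12, h - 40))) {
      xs <- cc[1] + 0:29; ys <- cc[2] + 0:19
      ok <- geom$mask[ys + 1, xs + 1] == 0
      sub <- base[ys + 1, xs + 1]; sub[ok] <- 210
      base[ys + 1, xs + 1] <- sub
    }
  }

  drops <- NULL
  nd <- config$droppings$n
  if (nd > 0) {
    lim <- max(2L, floor(n * config$droppings$deposit_frac))
    dep <- sort(sample.int(lim, nd, replace = nd > lim))
    sz <- sample(seq(config$droppings$size_range[1],
                     config$droppings$size_range[2]), nd, replace = TRUE)
    px <- numeric(nd); py <- numeric(nd)
    for (j in seq_len(nd)) {
      tries <- 0
      repeat {
        tries <- tries + 1
        jit <- 12 + 4 * (tries %/% 10)   # widen if a spot is hard to place
        cx <- path$x[dep[j]] + runif(1, -jit, jit)
        cy <- path$y[dep[j]] + runif(1, -jit, jit)
        c1 <- .classify_xy(geom, c(cx, cx + sz[j] - 1, cx, cx + sz[j] - 1),
                           c(cy, cy, cy + sz[j] - 1, cy + sz[j] - 1))
        # keep spots apart: separate droppings stay individually small,
        # never piling into a blob comparable to the rat
        clear <- j == 1 ||
          all(sqrt((px[seq_len(j - 1)] - cx)^2 +
                   (py[seq_len(j - 1)] - cy)^2) > 15)
        if (all(c1$region != "outside") && clear) {
          px[j] <- cx; py[j] <- cy; break
        }
      }
    }
    drops <- data.frame(frame = dep, x = round(px), y = round(py), size = sz)
  }

  intr <- config$intruder
  intruder_mask <- NULL
  intruder_frames <- integer()
  if (!is.null(intr)) {
    X <- matrix(rep(0:(w - 1), each = h), nrow = h)
    Y <- matrix(rep(0:(h - 1), times = w), nrow = h)
    if (intr$type == "strip") {
      k <- intr$arm - 1L
      fr <- .arm_frame(geom, k, X, Y)
      u <- matrix(fr$u, nrow = h); v <- matrix(fr$v, nrow = h)
      r <- geom$platform_radius_px
      # distal placement: from there the strip's path to the image edge
      # clears every other arm, so its only in-maze trace is the small
      # patch where the tip steps onto this arm's edge
      u0 <- r + geom$arm_length_px - intr$width_px - 10
      v_tip <- geom$arm_width_px / 2 - intr$overlap_px
      intruder_mask <- u >= u0 & u <= u0 + intr$width_px & v >= v_tip
    } else {
      intruder_mask <- X >= w - intr$depth_px
    }
    f_on <- max(1L, floor(intr$t_on * config$fps) + 1L)
    f_off <- min(n, floor(intr$t_off * config$fps) + 1L)
    if (f_off >= f_on) intruder_frames <- f_on:f_off
  }

  truth <- tibble::tibble(
    frame = path$frame, t = path$t, x = path$x, y = path$y,
    heading = heading,
    a = config$rat$major_px / 2, b = config$rat$minor_px / 2)

  list(config = config, geom = geom, path = path, truth = truth,
       events = sp$events, base = base, drops = drops,
       intruder_mask = intruder_mask, intruder_frames = intruder_frames,
       n_frames = n)
}

.paint_square <- function(img, x0, y0, size, gray) {
  w <- ncol(img); h <- nrow(img)
  xs <- max(0, x0):min(w - 1, x0 + size - 1)
  ys <- max(0, y0):min(h - 1, y0 + size - 1)
  img[ys + 1, xs + 1] <- gray
  img
}

.paint_ellipse <- function(img, cx, cy, a, b, theta, gray) {
  w <- ncol(img); h <- nrow(img)
  xs <- max(0, floor(cx - a)):min(w - 1, ceiling(cx + a))
  ys <- max(0, floor(cy - a)):min(h - 1, ceiling(cy + a))
  gx <- rep(xs, each = length(ys)) - cx
  gy <- rep(ys, times = length(xs)) - cy
  u <- gx * cos(theta) + gy * sin(theta)
  v <- -gx * sin(theta) + gy * cos(theta)
  hit <- (u / a)^2 + (v / b)^2 <= 1
  sub <- img[ys + 1, xs + 1]
  sub[hit] <- gray
  img[ys + 1, xs + 1] <- sub
  img
}

# Render frame i of a compiled scene as an 8-bit gray matrix.
render_scene_frame <- function(scene, i) {
  img <- scene$base
  cfg <- scene$config
  if (!is.null(scene$drops)) {
    d <- scene$drops[scene$drops$frame <= i, , drop = FALSE]
    for (j in seq_len(nrow(d)))
      img <- .paint_square(img, d$x[j], d$y[j], d$size[j],
                           cfg$droppings$gray)
  }
  tr <- scene$truth
  img <- .paint_ellipse(img, tr$x[i], tr$y[i], tr$a[i], tr$b[i],
                        tr$heading[i], cfg$rat$gray)
  if (i %in% scene$intruder_frames)
    img[scene$intruder_mask] <- cfg$intruder$gray
  img
}

#' Render a synthetic scene
#'
#' Deterministic given the config seed: two renders of the same config are
#' bit-identical.
#'
#' @param config A [scene_config()].
#' @param materialize Return the frames as a list (`TRUE`, for small
#'   scenes) or as a lazy [frame_source()] (`FALSE`).
#' @return List with `frames` (list of gray matrices or a `frame_source`),
#'   `truth` (tibble `frame`, `t`, `x`, `y`, `heading`, `a`, `b`) and
#'   `events` (the scripted ground-truth event log).
#' @export
render_scene <- function(config, materialize = TRUE) {
  scene <- compile_scene(config)
  frames <- if (materialize) {
    lapply(seq_len(scene$n_frames), function(i) render_scene_frame(scene, i))
  } else {
    frame_source(function(i) render_scene_frame(scene, i),
                 scene$n_frames, config$fps)
  }
  list(frames = frames, truth = scene$truth, events = scene$events)
}

# is (x, y) inside the true rat ellipse of truth row i?
.inside_rat <- function(truth, i, x, y) {
  dx <- x - truth$x[i]; dy <- y - truth$y[i]
  u <- dx * cos(truth$heading[i]) + dy * sin(truth$heading[i])
  v <- -dx * sin(truth$heading[i]) + dy * cos(truth$heading[i])
  (u / truth$a[i])^2 + (v / truth$b[i])^2 <= 1 + 1e-9
}

#' Run a full synthetic tracking case
#'
#' Renders the scene frame by frame (never holding the whole sequence in
#' memory), tracks it with the full localization pipeline, scores the
#' detection rate against the ground truth — a frame counts as detected
#' when the rat was found and the reported center lies inside the true
#' body ellipse — and builds the behavioral session report.
#'
#' @param config A [scene_config()].
#' @param params A [tracker_params()]; by default the logging period is
#'   set to one frame so the detection rate is scored once per frame.
#' @return List: `detection_rate` (percent), `trajectory`, `truth`,
#'   `report` (one-row tibble), `state` (final [ram_state()]).
#' @export
run_case <- function(config, params = NULL) {
  scene <- compile_scene(config)
  if (is.null(params))
    params <- tracker_params(sample_period = 1 / config$fps)
  src <- frame_source(function(i) render_scene_frame(scene, i),
                      scene$n_frames, config$fps)
  traj <- track_sequence(src, scene$geom, params)
  fidx <- pmin(scene$n_frames,
               floor(traj$t_s * config$fps + 1e-9) + 1L)
  hit <- vapply(seq_len(nrow(traj)), function(k) {
    traj$found[k] && .inside_rat(scene$truth, fidx[k],
                                 traj$x_px[k], traj$y_px[k])
  }, logical(1))
  rate <- 100 * mean(hit)
  baited <- config$baited
  state <- NULL; report <- NULL
  if (length(baited) > 0) {
    state <- score_trajectory(traj, scene$geom, baited)
    report <- session_report(traj, state, scene$geom)
  }
  list(detection_rate = rate, trajectory = traj,
       truth = scene$truth[fidx, ], report = report, state = state)
}

#' Scene configuration for the robustness experiments
#'
#' Builds the standard evaluation scene: a scripted foraging session in
#' which the rat leaves the central platform, visits each baited arm's
#' food zone with a pause there, wanders the platform between visits, and
#' rests at the center, with 10 persistent dropping spots deposited along
#' the path and bright clutter outside the footprint. Case 2 adds a bright
#' strip entering from the image edge whose tip steps onto the edge of one
#' non-baited arm for a contiguous 22% of the session (the imaged leg of
#' an experimenter crossing an arm).
#'
#' @param case 1 (droppings only) or 2 (droppings plus intruder).
#' @param seed Scene seed.
#' @param geom A [maze_geometry()].
#' @param fps Frames per second.
#' @param duration_s Session duration in seconds (default 300; at 10 fps a
#'   5-minute session gives 3000 frames). The scripted visits need about
#'   110 s; shorter sessions are rejected.
#' @param baited Baited arm numbers. The default baits the diagonal arms,
#'   leaving the axis-aligned arms non-baited; the Case-2 strip targets
#'   the first non-baited arm, where its tip patch is axis-aligned and
#'   survives the opening as a genuine competing candidate (a 6-px-deep
#'   patch on a 45-degree arm cannot contain the 5x5 element and would
#'   simply be erased).
#' @return A [scene_config()].
#' @export
case_scene <- function(case = 1, seed = 1, geom = maze_geometry(),
                       fps = 10, duration_s = 300,
                       baited = c(2, 4, 6, 8)) {
  stopifnot(case %in% c(1, 2))
  ctr <- geom$center
  r <- geom$platform_radius_px
  food_u <- r + geom$arm_length_px - geom$arm_width_px / 2 - 2
  arm_pt <- function(k, u) ctr + u * c(cos(geom$arm_angles[k + 1]),
                                       sin(geom$arm_angles[k + 1]))
  ring_pt <- function(deg) ctr + 0.55 * r * c(cos(deg * pi / 180),
                                              sin(deg * pi / 180))
  wp <- list(ctr); dw <- c(2)
  for (b in baited) {
    wp <- c(wp, list(arm_pt(b - 1, food_u), ctr,
                     ring_pt(45 * which(baited == b)), ctr))
    dw <- c(dw, 8, 1, 4, 0)
  }
  wpm <- do.call(rbind, wp)
  # fill the remaining session time with rest at the center
  legs_cm <- sum(sqrt(rowSums(diff(wpm)^2))) * geom$cm_per_px
  t_core <- sum(dw) + legs_cm / 12
  if (duration_s <= t_core + 1)
    stop("duration_s too short for the scripted visits", call. = FALSE)
  dw[length(dw)] <- duration_s - t_core

  nonbaited <- setdiff(seq_len(geom$n_arms), baited)
  intr <- NULL
  if (case == 2) {
    intr <- list(type = "strip", arm = nonbaited[1],
                 t_on = 0.30 * duration_s, t_off = 0.52 * duration_s,
                 width_px = 40, overlap_px = 6, gray = 200)
  }
  scene_config(
    geom, fps, waypoints = wpm, speeds = 12, dwell = dw,
    rat = list(major_px = 30, minor_px = 15, gray = 200),
    droppings = list(n = 10, size_range = c(2, 8), gray = 180,
                     deposit_frac = 0.6),
    intruder = intr,
    background = list(gray = 30, clutter = TRUE),
    baited = baited, seed = seed)
}
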