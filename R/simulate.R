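# Synthetic cage ---------------------------------------------------------
#
# A ground-truthed generator with the statistical structure the analysis
# pipeline assumes: a single animal switching among three behavioral
# states in a rectangular cage (aspect taken from a 318 x 140 cm floor
# plan, normalized to the unit square), observed at 5 fps by two cameras
# whose visible regions leave partial blind spots, plus emulators of a
# 10-s interval infra-red motion detector and of 15-min manual spot
# checks. Everything downstream can be validated against the ground truth
# it emits.

#' Simulator configuration
#'
#' Defaults describe a realistic captive-canid setting: exponential dwell
#' times (minimum 10 s so labels do not flicker), per-state speed ranges
#' with disjoint supports — essentially stationary when inactive, slow
#' in-place motion when active, locomotion when highly active — small
#' Gaussian jitter on the detected box centers, two cameras covering
#' overlapping halves of the cage, and an elevated platform the animal
#' prefers for resting.
#'
#' @param duration_s Length of the simulated recording in seconds.
#' @param fps Frames per second (default 5); `fps * duration_s` must be a
#'   whole number of frames.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param states Named list (`inactive`, `active`, `high_active`), each
#'   with `mean_dwell_s` and `speed` (range in normalized units per
#'   second). Speed supports must be ordered and non-overlapping.
#' @param min_dwell_s Minimum dwell time per state visit (default 10).
#' @param jitter_sd Detection noise on box centers (normalized units).
#' @param box_w,box_h Ranges of rendered box width/height.
#' @param platform Rectangle of the preferred resting sub-region.
#' @param platform_bias Probability that a locomotion bout heads for the
#'   platform (default 0.3).
#' @param cameras Named list of camera visible-region rectangles.
#' @param motion_region Coverage rectangle of the motion detector.
#' @param motion_threshold Path length (normalized units) within one
#'   detector interval that counts as motion.
#' @param state_script Optional data.frame (`level`, `duration_s`) that
#'   replaces the random state sequence with a scripted one.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(duration_s = 1800,
                       fps = 5,
                       seed = NULL,
                       states = list(
                         inactive    = list(mean_dwell_s = 240, speed = c(0, 0.002)),
                         active      = list(mean_dwell_s = 90,  speed = c(0.06, 0.12)),
                         high_active = list(mean_dwell_s = 120, speed = c(0.3, 0.6))
                       ),
                       min_dwell_s = 10,
                       jitter_sd = 0.002,
                       box_w = c(0.10, 0.18),
                       box_h = c(0.12, 0.22),
                       platform = list(xmin = 0, xmax = 0.29, ymin = 0.05, ymax = 0.45),
                       platform_bias = 0.3,
                       cameras = list(
                         A = list(xmin = 0, xmax = 0.65, ymin = 0, ymax = 1),
                         B = list(xmin = 0.35, xmax = 1, ymin = 0, ymax = 1)
                       ),
                       motion_region = list(xmin = 0.2, xmax = 0.9, ymin = 0, ymax = 1),
                       motion_threshold = 0.03,
                       state_script = NULL) {
  stopifnot(duration_s > 0, fps > 0)
  n_frames <- fps * duration_s
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    stop_fw("fps * duration_s must be an integer frame count")
  }
  need <- c("inactive", "active", "high_active")
  if (!all(need %in% names(states))) stop_fw("states must name %s", paste(need, collapse = ", "))
  sp <- lapply(states[need], `[[`, "speed")
  if (!(sp$inactive[2] < sp$active[1] && sp$active[2] < sp$high_active[1])) {
    stop_fw("state speed ranges must be ordered with non-overlapping supports")
  }
  for (nm in names(cameras)) cameras[[nm]] <- as_rect(cameras[[nm]])
  cfg <- list(duration_s = duration_s, fps = fps, seed = seed, states = states[need],
              min_dwell_s = min_dwell_s, jitter_sd = jitter_sd,
              box_w = box_w, box_h = box_h,
              platform = as_rect(platform), platform_bias = platform_bias,
              cameras = cameras, motion_region = as_rect(motion_region),
              motion_threshold = motion_threshold, state_script = state_script)
  class(cfg) <- c("sim_config", "list")
  cfg
}

#' @rdname sim_config
#' @param path YAML file with keys as in [sim_config()].
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$state_script)) x$state_script <- as.data.frame(x$state_script)
  do.call(sim_config, x)
}

#' @rdname sim_config
#' @param config A `"sim_config"` object.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  x <- unclass(config)
  if (!is.null(x$state_script)) x$state_script <- as.list(x$state_script)
  yaml::write_yaml(x, path)
  invisible(path)
}

# state sequence as rle-style (level, duration_s) blocks
draw_state_blocks <- function(config) {
  if (!is.null(config$state_script)) {
    script <- config$state_script
    stopifnot(all(c("level", "duration_s") %in% names(script)))
    total <- sum(script$duration_s)
    if (abs(total - config$duration_s) > 1e-9) {
      stop_fw("state script covers %g s but duration_s is %g s", total, config$duration_s)
    }
    return(data.frame(level = as.character(script$level),
                      duration_s = script$duration_s))
  }
  levels <- names(config$states)
  blocks <- data.frame(level = character(0), duration_s = numeric(0))
  t <- 0
  lv <- sample(levels, 1)
  while (t < config$duration_s) {
    mean_dwell <- config$states[[lv]]$mean_dwell_s
    extra <- max(mean_dwell - config$min_dwell_s, 0)
    dwell <- config$min_dwell_s + if (extra > 0) stats::rexp(1, 1 / extra) else 0
    dwell <- min(dwell, config$duration_s - t)
    blocks[nrow(blocks) + 1L, ] <- list(lv, dwell)
    t <- t + dwell
    lv <- sample(setdiff(levels, lv), 1)
  }
  blocks
}

#' Simulate a ground-truth animal trajectory
#'
#' Semi-Markov behavioral model: the animal holds each state for a random
#' dwell time (exponential beyond a minimum dwell), then switches to one of
#' the other states. Within a bout, per-frame displacement magnitudes are
#' drawn uniformly from the state's speed range and the heading performs a
#' random walk; locomotion bouts head for the platform with probability
#' `platform_bias`. Positions are folded back into the cage by reflection.
#' Deterministic under a fixed `seed`.
#'
#' @param config A [sim_config()].
#' @return Data.frame of class `"sim_trajectory"` with per-frame columns
#'   `frame`, `time_s`, `x`, `y`, `state`, plus one logical visibility
#'   column `visible_<camera>` per configured camera; the configuration is
#'   attached as attribute `"config"`.
#' @export
simulate_trajectory <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(round(config$fps * config$duration_s))
  margin <- 0.02
  with_seed(config$seed, {
    blocks <- draw_state_blocks(config)
    frames_per_block <- round(blocks$duration_s * config$fps)
    # rounding may drop/add a frame; pin the total
    diff_n <- n - sum(frames_per_block)
    frames_per_block[length(frames_per_block)] <-
      frames_per_block[length(frames_per_block)] + diff_n
    state <- rep(blocks$level, times = frames_per_block)
    x <- numeric(n)
    y <- numeric(n)
    pos <- c(stats::runif(1, 0.1, 0.9), stats::runif(1, 0.1, 0.9))
    i <- 1L
    for (b in seq_len(nrow(blocks))) {
      nb <- frames_per_block[[b]]
      if (nb <= 0) next
      lv <- blocks$level[[b]]
      speed <- config$states[[lv]]$speed
      step_len <- stats::runif(nb, speed[1], speed[2]) / config$fps
      if (lv == "inactive") {
        # resting: small wobble tethered to the rest position — a lying
        # animal does not drift across the cage however long the bout
        anchor <- pos
        tether <- 0.005
        bx <- numeric(nb); by <- numeric(nb)
        cur <- pos
        noise <- stats::rnorm(nb, 0, 0.4)
        base_ang <- stats::runif(nb, 0, 2 * pi)
        for (t in seq_len(nb)) {
          off <- cur - anchor
          ang <- if (sqrt(sum(off^2)) > tether) {
            atan2(anchor[2] - cur[2], anchor[1] - cur[1]) + noise[t]
          } else {
            base_ang[t]
          }
          cur <- cur + step_len[t] * c(cos(ang), sin(ang))
          bx[t] <- cur[1]; by[t] <- cur[2]
        }
        bx <- reflect_into(bx, margin, 1 - margin)
        by <- reflect_into(by, margin, 1 - margin)
      } else {
        to_platform <- stats::runif(1) < config$platform_bias
        heading0 <- if (to_platform) {
          cx <- (config$platform$xmin + config$platform$xmax) / 2
          cy <- (config$platform$ymin + config$platform$ymax) / 2
          atan2(cy - pos[2], cx - pos[1])
        } else {
          stats::runif(1, 0, 2 * pi)
        }
        heading <- heading0 + cumsum(stats::rnorm(nb, 0, 0.25))
        bx <- pos[1] + cumsum(step_len * cos(heading))
        by <- pos[2] + cumsum(step_len * sin(heading))
        bx <- reflect_into(bx, margin, 1 - margin)
        by <- reflect_into(by, margin, 1 - margin)
      }
      x[i:(i + nb - 1L)] <- bx
      y[i:(i + nb - 1L)] <- by
      pos <- c(bx[nb], by[nb])
      i <- i + nb
    }
    out <- data.frame(frame = 0:(n - 1L),
                      time_s = (0:(n - 1L)) / config$fps,
                      x = x, y = y,
                      state = state)
    for (nm in names(config$cameras)) {
      out[[paste0("visible_", nm)]] <- in_rect(x, y, config$cameras[[nm]])
    }
    class(out) <- c("sim_trajectory", "data.frame")
    attr(out, "config") <- config
    out
  })
}

#' Render a camera's detection stream from a trajectory
#'
#' Frames where the true position lies outside the camera's visible region
#' yield no-detection records (absent box); visible frames get a box whose
#' center is the true position plus Gaussian jitter, a box size drawn from
#' the configured range, and a confidence drawn close to 1.
#'
#' @param trajectory A [simulate_trajectory()] result.
#' @param camera_id Name of a camera in the trajectory's configuration.
#' @param seed Integer seed for the rendering noise (`NULL`: current RNG).
#' @return A detection-stream data.frame (see [read_detection_stream()]).
#' @export
render_detections <- function(trajectory, camera_id, seed = NULL) {
  config <- attr(trajectory, "config")
  if (is.null(config) || !camera_id %in% names(config$cameras)) {
    stop_fw("unknown camera '%s'", camera_id)
  }
  n <- nrow(trajectory)
  region <- config$cameras[[camera_id]]
  with_seed(seed, {
    visible <- in_rect(trajectory$x, trajectory$y, region)
    cx <- pmin(pmax(trajectory$x + stats::rnorm(n, 0, config$jitter_sd), 1e-6), 1)
    cy <- pmin(pmax(trajectory$y + stats::rnorm(n, 0, config$jitter_sd), 1e-6), 1)
    w <- stats::runif(n, config$box_w[1], config$box_w[2])
    h <- stats::runif(n, config$box_h[1], config$box_h[2])
    confidence <- stats::rbeta(n, 30, 2)
    out <- data.frame(camera_id = camera_id,
                      frame_index = trajectory$frame,
                      time_s = trajectory$time_s,
                      cx = ifelse(visible, cx, NA_real_),
                      cy = ifelse(visible, cy, NA_real_),
                      w = ifelse(visible, w, NA_real_),
                      h = ifelse(visible, h, NA_real_),
                      confidence = ifelse(visible, confidence, NA_real_))
    validate_detection_stream(out)
  })
}

#' Ground-truth per-second activity labels
#'
#' The modal true state within each second (ties broken toward the lower
#' activity level, deterministically). Ground truth has no `out` seconds:
#' the animal always exists, only the sensors lose it.
#'
#' @param trajectory A [simulate_trajectory()] result.
#' @return Data.frame with columns `time_s`, `level`.
#' @export
true_activity_labels <- function(trajectory) {
  sec <- floor(trajectory$time_s + 1e-9)
  seconds <- seq(min(sec), max(sec))
  lv <- tapply(factor(trajectory$state, levels = activity_levels),
               factor(sec, levels = seconds),
               function(s) names(which.max(table(s))))
  data.frame(time_s = as.numeric(seconds),
             level = factor(as.character(lv), levels = activity_levels))
}

#' Emulate an interval motion detector
#'
#' One boolean per fixed interval (default 10 s): `TRUE` when the animal
#' was inside the detector's coverage region and its path length over the
#' covered frames of that interval exceeded the threshold. Movement inside
#' the detector's blind spot is invisible to it. One hour yields 360
#' readings.
#'
#' @param trajectory A [simulate_trajectory()] result.
#' @param interval_s Reporting interval in seconds (default 10).
#' @param region Coverage rectangle (default: the configuration's
#'   `motion_region`).
#' @param threshold Path length in normalized units that counts as motion
#'   (default: the configuration's `motion_threshold`).
#' @return Data.frame with columns `interval_start_s`, `motion` (logical).
#' @export
emulate_motion_detector <- function(trajectory, interval_s = 10,
                                    region = NULL, threshold = NULL) {
  stopifnot(interval_s > 0)
  config <- attr(trajectory, "config")
  region <- as_rect(region %||% config$motion_region)
  threshold <- threshold %||% config$motion_threshold
  n <- nrow(trajectory)
  inside <- in_rect(trajectory$x, trajectory$y, region)
  step <- c(NA_real_, sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2))
  covered_step <- ifelse(inside & c(FALSE, inside[-n]), step, 0)
  interval <- floor(trajectory$time_s / interval_s)
  starts <- seq(min(interval), max(interval))
  path <- tapply(covered_step, factor(interval, levels = starts),
                 function(v) sum(v, na.rm = TRUE))
  data.frame(interval_start_s = as.numeric(starts) * interval_s,
             motion = as.numeric(path) > threshold)
}

#' Emulate periodic manual spot checks
#'
#' The manual scoring protocol: every `period_s` (default 15 min) an
#' observer watches `half_window_s` seconds before and after the sample
#' point and the modal observed label is extrapolated to the whole
#' interval. One hour yields 4 interval labels; mixed behavior inside an
#' interval is over- or under-represented by construction.
#'
#' @param timeline Per-second labels (data.frame `time_s`, `level`) — the
#'   truth, or any classified timeline.
#' @param period_s Sampling period in seconds (default 900).
#' @param half_window_s Seconds watched on each side of the sample point
#'   (default 30); `period_s` must exceed `2 * half_window_s`.
#' @return Data.frame with columns `interval_start_s`, `sample_time_s`,
#'   `level`.
#' @export
emulate_manual_sampling <- function(timeline, period_s = 900, half_window_s = 30) {
  if (period_s <= 2 * half_window_s) {
    stop_fw("period_s must exceed twice half_window_s")
  }
  stopifnot(all(c("time_s", "level") %in% names(timeline)))
  t0 <- min(timeline$time_s)
  t1 <- max(timeline$time_s)
  n_periods <- ceiling((t1 - t0 + 1) / period_s)
  starts <- t0 + (seq_len(n_periods) - 1) * period_s
  sample_pts <- starts + period_s / 2
  level <- vapply(sample_pts, function(tp) {
    sel <- abs(timeline$time_s - tp) <= half_window_s
    obs <- factor(as.character(timeline$level[sel]), levels = activity_levels)
    names(which.max(table(obs)))
  }, character(1))
  data.frame(interval_start_s = starts,
             sample_time_s = sample_pts,
             level = factor(level, levels = activity_levels))
}
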