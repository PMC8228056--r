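# Activity levels --------------------------------------------------------
#
# Four per-second labels: `inactive` (animal visible, essentially no box
# movement), `active` (in-place movement such as scratching or stretching),
# `high_active` (locomotion; the box changes location) and `out` (the
# animal was not detected — hut, blind spot, detector miss).

activity_levels <- c("inactive", "active", "high_active", "out")

#' Activity thresholds on the windowed mean vector norm
#'
#' @param theta_inactive_active Boundary between `inactive` and `active`
#'   (normalized units per frame pair).
#' @param theta_active_high Boundary between `active` and `high_active`.
#' @return Object of class `"activity_thresholds"`.
#' @export
activity_thresholds <- function(theta_inactive_active, theta_active_high) {
  if (!(theta_inactive_active > 0 && theta_active_high > theta_inactive_active)) {
    stop_fw("thresholds must satisfy 0 < theta_inactive_active < theta_active_high")
  }
  structure(list(theta_inactive_active = theta_inactive_active,
                 theta_active_high = theta_active_high),
            class = "activity_thresholds")
}

#' @export
print.activity_thresholds <- function(x, ...) {
  cat(sprintf("activity thresholds: inactive|active %.5g, active|high_active %.5g\n",
              x$theta_inactive_active, x$theta_active_high))
  invisible(x)
}

#' Calibrate activity thresholds from labeled reference segments
#'
#' Each reference segment is a stretch of footage whose activity level is
#' known; its summary statistic is the *maximum* of the 30-s windowed mean
#' vector norm over the segment. A threshold between two adjacent levels is
#' placed at the midpoint of the separating gap — between the largest
#' summary of the lower level and the smallest summary of the higher level.
#' Overlapping level ranges mean the reference material does not separate
#' the levels and calibration fails.
#'
#' @param segments Data.frame with columns `level` (one of `inactive`,
#'   `active`, `high_active`) and `summary` (the segment's maximal windowed
#'   norm). Use [segment_summary()] to compute summaries from series.
#' @return An [activity_thresholds()] object.
#' @export
#' @examples
#' segs <- data.frame(level = c("inactive", "active", "high_active"),
#'                    summary = c(0.0, 0.1, 0.2))
#' calibrate_thresholds(segs)  # thresholds 0.05 and 0.15
calibrate_thresholds <- function(segments) {
  stopifnot(all(c("level", "summary") %in% names(segments)))
  need <- c("inactive", "active", "high_active")
  segments$level <- as.character(segments$level)
  if (!all(need %in% segments$level)) {
    stop_fw("calibration needs at least one segment per level (%s); missing: %s",
            paste(need, collapse = ", "),
            paste(setdiff(need, segments$level), collapse = ", "))
  }
  if (anyNA(segments$summary)) stop_fw("segment summaries must not be missing")
  rng <- function(lv) range(segments$summary[segments$level == lv])
  midpoint <- function(lower, upper) {
    lo <- rng(lower); hi <- rng(upper)
    if (hi[1] <= lo[2]) {
      stop_fw(paste0("activity levels '%s' and '%s' are not separable: ",
                     "min(%s) = %.5g <= max(%s) = %.5g"),
              lower, upper, upper, hi[1], lower, lo[2])
    }
    (lo[2] + hi[1]) / 2
  }
  activity_thresholds(midpoint("inactive", "active"),
                      midpoint("active", "high_active"))
}

#' Summary statistic of a reference segment
#'
#' The maximum of the non-missing windowed mean vector norms in the
#' segment, the statistic [calibrate_thresholds()] consumes.
#'
#' @param series Windowed [motion_series()] excerpt covering the segment.
#' @return A single number; error if every value is missing.
#' @export
segment_summary <- function(series) {
  v <- series$value[!is.na(series$value)]
  if (!length(v)) stop_fw("reference segment contains no observed samples")
  max(v)
}

#' Extract calibration segments from a ground-truth timeline
#'
#' For simulated (or otherwise annotated) footage: finds contiguous runs of
#' a single true activity level of at least `min_len_s` seconds and
#' summarizes each with the maximum windowed norm over the run, skipping
#' the first `window_s` seconds of the run so the window no longer mixes in
#' the previous behavior.
#'
#' @param truth Data.frame with per-second columns `time_s`, `level`
#'   (ground-truth labels; `out` runs are ignored).
#' @param windowed Windowed [motion_series()] on the same clock.
#' @param window_s Window length used to compute `windowed` (default 30).
#' @param min_len_s Minimum run length to use as a reference (default 60).
#' @return Data.frame with columns `level`, `summary`, `start_s`, `end_s`.
#' @export
reference_segments <- function(truth, windowed, window_s = 30, min_len_s = 60) {
  stopifnot(all(c("time_s", "level") %in% names(truth)))
  runs <- rle(as.character(truth$level))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  out <- data.frame(level = character(0), summary = numeric(0),
                    start_s = numeric(0), end_s = numeric(0))
  for (i in seq_along(runs$values)) {
    lv <- runs$values[[i]]
    if (lv == "out" || runs$lengths[[i]] < min_len_s) next
    t0 <- truth$time_s[[starts[[i]]]] + window_s
    t1 <- truth$time_s[[ends[[i]]]]
    sel <- windowed$time_s >= t0 & windowed$time_s <= t1
    vals <- windowed$value[sel]
    if (all(is.na(vals))) next
    out[nrow(out) + 1L, ] <- list(lv, max(vals, na.rm = TRUE), t0 - window_s, t1)
  }
  out
}

#' Classify a windowed motion series into activity levels
#'
#' The threshold decision tree on the windowed mean vector norm: a missing
#' sample is `out`; a value below the inactive/active threshold is
#' `inactive`; below the active/high threshold, `active`; otherwise
#' `high_active`. A value exactly on a boundary classifies upward.
#'
#' @param series Windowed [motion_series()] (typically fused across
#'   cameras).
#' @param thresholds An [activity_thresholds()] object.
#' @return Data.frame (an *activity timeline*) with columns `time_s` and
#'   `level` (factor with levels inactive, active, high_active, out).
#' @export
classify_activity <- function(series, thresholds) {
  stopifnot(inherits(thresholds, "activity_thresholds"))
  v <- series$value
  lv <- ifelse(is.na(v), "out",
               ifelse(v < thresholds$theta_inactive_active, "inactive",
                      ifelse(v < thresholds$theta_active_high, "active", "high_active")))
  data.frame(time_s = series$time_s,
             level = factor(lv, levels = activity_levels))
}

#' Duration of each activity level
#'
#' Counts the seconds spent at each level. Labels are expected at 1 Hz, so
#' the counts are integer seconds and sum to the observation length.
#'
#' @param timeline Activity timeline from [classify_activity()], or a bare
#'   vector of labels.
#' @return Named numeric vector of seconds, one entry per level (including
#'   zero-duration levels).
#' @export
activity_durations <- function(timeline) {
  labels <- if (is.data.frame(timeline)) timeline$level else timeline
  labels <- factor(as.character(labels), levels = activity_levels)
  if (anyNA(labels)) stop_fw("unknown activity label")
  counts <- table(labels)
  stats::setNames(as.numeric(counts), names(counts))
}

#' Binned activity overview
#'
#' The classic 24-h activity overview: the observation period is cut into
#' fixed bins (default 30 min) and the seconds spent at each level are
#' accounted per bin. Re-binning is additive: an hourly bin equals the sum
#' of its two half-hour bins.
#'
#' @param timeline Activity timeline from [classify_activity()].
#' @param bin_s Bin width in seconds (default 1800 = 30 min).
#' @return Data.frame with columns `bin_start_s`, `level`, `seconds`,
#'   complete over every (bin, level) pair; attribute `"partial_bins"`
#'   lists bins shorter than `bin_s`.
#' @export
activity_overview <- function(timeline, bin_s = 1800) {
  if (bin_s < 1) stop_fw("bin_s must be at least 1 second")
  stopifnot(all(c("time_s", "level") %in% names(timeline)))
  labels <- factor(as.character(timeline$level), levels = activity_levels)
  bin <- floor(timeline$time_s / bin_s) * bin_s
  bins <- seq(min(bin), max(bin), by = bin_s)
  tab <- table(factor(bin, levels = bins), labels)
  out <- data.frame(bin_start_s = rep(as.numeric(bins), times = length(activity_levels)),
                    level = factor(rep(activity_levels, each = length(bins)),
                                   levels = activity_levels),
                    seconds = as.numeric(tab))
  out <- out[order(out$bin_start_s, out$level), ]
  rownames(out) <- NULL
  per_bin <- tapply(out$seconds, out$bin_start_s, sum)
  attr(out, "partial_bins") <- as.numeric(names(per_bin)[per_bin < bin_s])
  out
}

#' Read or write activity thresholds
#'
#' Two-key YAML config (`theta_inactive_active`, `theta_active_high`).
#'
#' @param thresholds An [activity_thresholds()] object.
#' @param path File path.
#' @export
write_thresholds <- function(thresholds, path) {
  stopifnot(inherits(thresholds, "activity_thresholds"))
  yaml::write_yaml(unclass(thresholds), path)
  invisible(path)
}

#' @rdname write_thresholds
#' @export
read_thresholds <- function(path) {
  x <- yaml::read_yaml(path)
  activity_thresholds(x$theta_inactive_active, x$theta_active_high)
}
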