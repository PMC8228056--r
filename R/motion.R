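# Movement series -------------------------------------------------------
#
# A motion series is a data.frame with columns `time_s` (strictly
# increasing, uniformly spaced) and `value` (non-negative vector norms in
# normalized units, NA for samples where the animal was not observed). The
# largest possible displacement inside the unit square is sqrt(2).

#' Construct and validate a motion series
#'
#' @param time_s Strictly increasing, uniformly spaced timestamps (seconds).
#' @param value Non-negative vector norms; `NA` marks a missing sample
#'   (animal not detected), never a zero.
#' @return Data.frame of class `"motion_series"` with columns `time_s`,
#'   `value`.
#' @export
motion_series <- function(time_s, value) {
  stopifnot(length(time_s) == length(value))
  check_uniform_times(time_s, "motion series")
  v <- value[!is.na(value)]
  if (any(v < 0) || any(v > sqrt(2) + 1e-9)) {
    stop_fw("vector norms must lie in [0, sqrt(2)]")
  }
  out <- data.frame(time_s = as.numeric(time_s), value = as.numeric(value))
  class(out) <- c("motion_series", "data.frame")
  out
}

series_step <- function(series) {
  check_uniform_times(series$time_s, "motion series")
}

#' Frame-pair movement norms of one camera stream
#'
#' The movement signal of the animal: for every pair of consecutive frames
#' the Euclidean distance between the bounding-box centers,
#' `sqrt((x_{f+1}-x_f)^2 + (y_{f+1}-y_f)^2)`, in normalized image units.
#' A pair in which either frame has no detection yields a missing entry —
#' an unobserved animal is never treated as a stationary one.
#'
#' @param stream Detection records of a single camera (one row per frame,
#'   consecutive `frame_index`), as produced by [read_detection_stream()]
#'   or [render_detections()].
#' @return A [motion_series()] with one entry per frame pair, stamped with
#'   the leading frame's time; empty for streams of fewer than two frames.
#' @export
frame_pair_norms <- function(stream) {
  validate_detection_stream(stream)
  if (length(unique(stream$camera_id)) > 1) {
    stop_fw("frame_pair_norms expects a single-camera stream")
  }
  stream <- stream[order(stream$frame_index), , drop = FALSE]
  n <- nrow(stream)
  if (n < 2) return(motion_series(numeric(0), numeric(0)))
  if (any(diff(stream$frame_index) != 1)) {
    stop_fw("frame indices must be consecutive")
  }
  dx <- diff(stream$cx)
  dy <- diff(stream$cy)
  motion_series(stream$time_s[-n], sqrt(dx^2 + dy^2))
}

#' Aggregate frame-pair norms to one value per second
#'
#' Each second's value is the arithmetic mean of the non-missing frame-pair
#' norms whose leading frame falls inside that second; a second in which
#' every pair is missing stays missing. One hour of 5 fps input yields
#' 3600 entries.
#'
#' @param norms Frame-pair [motion_series()] from [frame_pair_norms()].
#' @param fps Frame rate of the underlying stream; must match the series
#'   spacing.
#' @return A [motion_series()] at one entry per second.
#' @export
per_second_series <- function(norms, fps = 5) {
  stopifnot(fps > 0)
  if (nrow(norms) == 0) return(motion_series(numeric(0), numeric(0)))
  step <- series_step(norms)
  if (!is.na(step) && abs(step - 1 / fps) > 1e-6 / fps) {
    stop_fw("series spacing %.6g s does not match fps = %g", step, fps)
  }
  sec <- floor(norms$time_s + 1e-9)
  seconds <- seq(min(sec), max(sec))
  sums <- tapply(norms$value, factor(sec, levels = seconds),
                 function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  motion_series(seconds, as.numeric(sums))
}

#' Trailing sliding-window mean of a per-second series
#'
#' The mean vector norm over a sliding time window: the value at time `t`
#' averages the non-missing entries of the `window_s` seconds ending at
#' (and including) `t`, stepped every `step_s` seconds. A window in which
#' the fraction of observed entries falls below `min_coverage` is reported
#' missing rather than extrapolated; the coverage denominator counts only
#' window positions that overlap the series, so the opening seconds of a
#' recording are not penalized.
#'
#' @param series Per-second [motion_series()].
#' @param window_s Window length in seconds (default 30).
#' @param step_s Output step in seconds (default 1); must be a multiple of
#'   the series spacing.
#' @param min_coverage Minimum observed fraction of the window (default 0.5).
#' @return A [motion_series()] at `step_s` resolution.
#' @export
sliding_mean <- function(series, window_s = 30, step_s = 1, min_coverage = 0.5) {
  stopifnot(window_s > 0, step_s > 0, min_coverage > 0, min_coverage <= 1)
  n <- nrow(series)
  if (n == 0) return(motion_series(numeric(0), numeric(0)))
  dt <- series_step(series)
  if (is.na(dt)) dt <- 1
  if (window_s < dt - 1e-9) {
    stop_fw("window_s (%g s) is shorter than the sample period (%g s)", window_s, dt)
  }
  k <- round(window_s / dt)
  stride <- round(step_s / dt)
  if (abs(stride * dt - step_s) > 1e-9) {
    stop_fw("step_s must be a multiple of the series spacing")
  }
  present <- !is.na(series$value)
  cs <- c(0, cumsum(ifelse(present, series$value, 0)))  # 0-padded cumsums
  cn <- c(0, cumsum(present))
  idx <- seq(1L, n, by = stride)
  lo <- pmax(idx - k, 0L)  # exclusive lower index into the cumsums
  wsum <- cs[idx + 1L] - cs[lo + 1L]
  wcnt <- cn[idx + 1L] - cn[lo + 1L]
  wlen <- idx - lo  # window positions that overlap the series
  value <- ifelse(wcnt / wlen >= min_coverage & wcnt > 0, wsum / wcnt, NA_real_)
  motion_series(series$time_s[idx], value)
}

#' Read or write a motion series CSV
#'
#' Columns `time_s`, `value`, `missing`; a missing sample has an empty
#' `value` field and `missing = TRUE`.
#'
#' @param series A [motion_series()].
#' @param path CSV file path.
#' @export
write_motion_series <- function(series, path) {
  out <- data.frame(time_s = series$time_s,
                    value = ifelse(is.na(series$value), NA_character_,
                                   sprintf("%.15g", series$value)),
                    missing = is.na(series$value))
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_motion_series
#' @export
read_motion_series <- function(path) {
  tab <- utils::read.csv(path)
  motion_series(tab$time_s, as.numeric(tab$value))
}
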