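#' Fuse the motion series of two cameras
#'
#' Per-sample merge of the two cameras watching one cage, following the
#' larger-norm decision rule: if only one camera observed the animal its
#' value is taken; if both did and they disagree, the larger vector norm
#' wins (the camera seeing less of the movement underestimates it); only
#' when neither camera saw the animal is the fused sample missing.
#' Equality is tested exactly — any numeric difference counts as a
#' mismatch.
#'
#' @param series_a,series_b Two [motion_series()] with identical timestamps
#'   and sample rate (use [align_series()] first if the clocks are skewed).
#' @return A [motion_series()] with additional columns `value_a`,
#'   `value_b` and `source` (factor in `A`, `B`, `both`, `none`) recording
#'   the per-sample provenance.
#' @export
#' @examples
#' a <- motion_series(0:2, c(NA, 0.1, NA))
#' b <- motion_series(0:2, c(0.2, 0.3, NA))
#' fuse_series(a, b)
fuse_series <- function(series_a, series_b) {
  if (nrow(series_a) != nrow(series_b)) {
    stop_fw("camera series have unequal length (%d vs %d)",
            nrow(series_a), nrow(series_b))
  }
  if (nrow(series_a) > 0 && max(abs(series_a$time_s - series_b$time_s)) > 1e-8) {
    stop_fw("camera series timestamps are misaligned")
  }
  va <- series_a$value
  vb <- series_b$value
  fused <- pmax(va, vb, na.rm = TRUE)
  fused[is.na(va) & is.na(vb)] <- NA_real_
  source <- factor(
    ifelse(is.na(va) & is.na(vb), "none",
           ifelse(is.na(vb), "A", ifelse(is.na(va), "B", "both"))),
    levels = c("A", "B", "both", "none")
  )
  out <- motion_series(series_a$time_s, fused)
  out$value_a <- va
  out$value_b <- vb
  out$source <- source
  out
}

#' Align two camera series onto a common per-second clock
#'
#' Snaps each series' timestamps to the nearest whole second and intersects
#' the covered ranges. Residual skew above `max_skew_s` (cameras not
#' clock-synchronized) is an error rather than silently resampled.
#'
#' @param series_a,series_b Two [motion_series()] at roughly 1 Hz.
#' @param max_skew_s Largest tolerated distance to the snapped second
#'   (default 0.5).
#' @return List with elements `a` and `b`, aligned and equal-length.
#' @export
align_series <- function(series_a, series_b, max_skew_s = 0.5) {
  snap <- function(s, label) {
    sec <- round(s$time_s)
    skew <- abs(s$time_s - sec)
    if (any(skew > max_skew_s)) {
      stop_fw("camera %s clock skew %.3f s exceeds %.3f s", label, max(skew), max_skew_s)
    }
    data.frame(time_s = sec, value = s$value)
  }
  a <- snap(series_a, "A")
  b <- snap(series_b, "B")
  common <- intersect(a$time_s, b$time_s)
  if (!length(common)) stop_fw("camera series share no common seconds")
  common <- sort(common)
  list(a = motion_series(common, a$value[match(common, a$time_s)]),
       b = motion_series(common, b$value[match(common, b$time_s)]))
}
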