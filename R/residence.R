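#' Residence trace of bounding-box centers
#'
#' The center-y versus center-x trace over a time period: one point per
#' frame with a detection, in time order. Frames without a detection
#' contribute nothing. Plotted over the cage image, the trace reveals the
#' places of residence.
#'
#' @param stream Detection records of one camera (or any concatenation).
#' @return Data.frame with columns `time_s`, `cx`, `cy`.
#' @export
residence_trace <- function(stream) {
  validate_detection_stream(stream)
  keep <- !is.na(stream$cx)
  out <- stream[keep, c("time_s", "cx", "cy")]
  out <- out[order(stream$time_s[keep]), ]
  rownames(out) <- NULL
  out
}

#' Gridded occupancy of the unit square
#'
#' A 2-D histogram of residence points over a uniform `nx` by `ny`
#' partition of the normalized image: cell counts, and densities that sum
#' to one — the empirical likelihood of residence that a heat map renders.
#' Bin edges are half-open `[lo, hi)` with the top/right edge closed, so
#' every (clipped) point is counted exactly once.
#'
#' @param points Data.frame with columns `cx`, `cy` (e.g. from
#'   [residence_trace()]); points are clipped into the unit square.
#' @param nx,ny Number of grid cells horizontally / vertically. The
#'   default 32 x 18 roughly matches a 16:9 camera image.
#' @return Object of class `"occupancy_grid"`: list with `nx`, `ny`,
#'   `counts` and `density` (`ny` x `nx` matrices, row 1 = top of the
#'   image), and `n_points`.
#' @export
occupancy_grid <- function(points, nx = 32, ny = 18) {
  if (!is_count(nx) || !is_count(ny) || nx < 1 || ny < 1) {
    stop_fw("nx and ny must be positive integers")
  }
  stopifnot(all(c("cx", "cy") %in% names(points)))
  x <- pmin(pmax(points$cx, 0), 1)
  y <- pmin(pmax(points$cy, 0), 1)
  ix <- pmin(floor(x * nx) + 1L, nx)
  iy <- pmin(floor(y * ny) + 1L, ny)
  counts <- matrix(0, nrow = ny, ncol = nx)
  if (length(ix)) {
    tab <- table(factor(iy, levels = seq_len(ny)), factor(ix, levels = seq_len(nx)))
    counts <- matrix(as.numeric(tab), nrow = ny, ncol = nx)
  }
  total <- sum(counts)
  structure(list(nx = as.integer(nx), ny = as.integer(ny),
                 counts = counts,
                 density = if (total > 0) counts / total else counts,
                 n_points = as.integer(total)),
            class = "occupancy_grid")
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf("occupancy grid %d x %d, %d points; peak density %.3f\n",
              x$nx, x$ny, x$n_points,
              if (x$n_points > 0) max(x$density) else 0))
  invisible(x)
}

#' Write an occupancy grid as a CSV matrix
#'
#' One row per grid row (top of the image first), cells are counts; the
#' densities can be recomputed by dividing by the total.
#'
#' @param grid An [occupancy_grid()] object.
#' @param path CSV file path.
#' @export
write_occupancy_grid <- function(grid, path) {
  stopifnot(inherits(grid, "occupancy_grid"))
  utils::write.table(grid$counts, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
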