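# Optional ggplot2 renderings of the two headline figures: the binned
# activity overview and the residence heat map.

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop_fw("plotting requires the ggplot2 package")
  }
}

#' Plot a binned activity overview
#'
#' Stacked bars of seconds per activity level per time bin — the 24-h
#' activity overview, at whatever bin width the table was built with.
#'
#' @param overview Output of [activity_overview()].
#' @return A ggplot object.
#' @export
plot_activity_overview <- function(overview) {
  need_ggplot2()
  overview$hours <- overview$bin_start_s / 3600
  overview$minutes <- overview$seconds / 60
  ggplot2::ggplot(overview,
                  ggplot2::aes(x = hours, y = minutes, fill = level)) +
    ggplot2::geom_col(width = diff(range(overview$hours)) /
                        max(1, length(unique(overview$hours)) - 1) * 0.9) +
    ggplot2::scale_fill_manual(values = c(inactive = "#1b7837", active = "#fdb863",
                                          high_active = "#b2182b", out = "grey70")) +
    ggplot2::labs(x = "time [h]", y = "duration [min]", fill = "activity level")
}

#' Plot an occupancy heat map
#'
#' Residence-likelihood heat map of the cage; the y axis is flipped for
#' display so the image's top row appears on top.
#'
#' @param grid An [occupancy_grid()] object.
#' @return A ggplot object.
#' @export
plot_occupancy <- function(grid) {
  need_ggplot2()
  stopifnot(inherits(grid, "occupancy_grid"))
  df <- expand.grid(ix = seq_len(grid$nx), iy = seq_len(grid$ny))
  df$x <- (df$ix - 0.5) / grid$nx
  df$y <- (df$iy - 0.5) / grid$ny
  df$density <- grid$density[cbind(df$iy, df$ix)]
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = density)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "residence\nlikelihood") +
    ggplot2::coord_fixed(ratio = 140 / 318) +
    ggplot2::labs(x = "center x", y = "center y")
}
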