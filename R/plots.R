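# ggplot2 views of the maze, trajectories and zone occupancy.

.zone_polygon_df <- function(geom) {
  dplyr::bind_rows(lapply(seq_len(nrow(geom$zones)), function(i) {
    p <- geom$zones$polygon[[i]]
    tibble::tibble(zone_id = geom$zones$zone_id[i],
                   x = p[, 1], y = p[, 2])
  }))
}

#' Plot a trajectory over the maze outline
#'
#' @param traj Trajectory tibble.
#' @param geom A [maze_geometry()].
#' @return A ggplot object (y axis reversed to match image coordinates).
#' @export
plot_trajectory <- function(traj, geom) {
  zp <- .zone_polygon_df(geom)
  tr <- .traj_xy(traj)
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = zp, ggplot2::aes(x = .data$x, y = .data$y,
                              group = .data$zone_id),
      fill = "grey95", colour = "grey70", linewidth = 0.2) +
    ggplot2::geom_path(
      data = tr, ggplot2::aes(x = .data$x_px, y = .data$y_px),
      colour = "firebrick", linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Food search trajectory")
}

#' Plot per-zone occupancy as a heatmap
#'
#' @param zone_counts Output of [zone_histogram()].
#' @param geom A [maze_geometry()].
#' @return A ggplot object.
#' @export
plot_zone_heatmap <- function(zone_counts, geom) {
  zp <- dplyr::left_join(.zone_polygon_df(geom),
                         zone_counts[c("zone_id", "n")], by = "zone_id")
  ggplot2::ggplot(zp, ggplot2::aes(x = .data$x, y = .data$y,
                                   group = .data$zone_id,
                                   fill = .data$n)) +
    ggplot2::geom_polygon(colour = "grey30", linewidth = 0.15) +
    ggplot2::scale_fill_viridis_c(option = "inferno") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Zone occupancy", fill = "samples")
}

#' @importFrom rlang .data
NULL
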