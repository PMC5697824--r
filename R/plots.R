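#' Plot normalized-time courses
#'
#' Speed, polarization, mean number of influential neighbors and its
#' relative variation against normalized event time.
#'
#' @param object a `time_course` tibble from [time_course()].
#' @param ... unused.
#' @return a ggplot object (faceted by variable).
#' @export
autoplot.time_course <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select("t_bar", "V", "P", "N", "eta") |>
    tidyr::pivot_longer(-"t_bar", names_to = "variable",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  ggplot2::ggplot(long, ggplot2::aes(.data$t_bar, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(0, 1), linetype = "dashed",
                        color = "grey50") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "normalized time", y = NULL,
                  title = "Collective U-turn time courses")
}

#' Plot rank histograms
#'
#' @param object tibble from [rank_histograms()].
#' @param ... unused.
#' @return a ggplot object, one panel per histogram block.
#' @export
plot_rank_histograms <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(factor(.data$value), .data$proportion)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~block, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "proportion of U-turn time",
                  title = "Influential-neighbor counts and ranks")
}

#' Plot the focal-frame spatial map
#'
#' Cell occupancy of influential-neighbor positions around the focal fish
#' (at the origin, heading up), with mean relative-velocity arrows.
#'
#' @param object a `spatial_map` from [spatial_map()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.spatial_map <- function(object, ...) {
  cells <- object$cells
  ggplot2::ggplot(cells, ggplot2::aes(.data$cx, .data$cy)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count)) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$cx + 0.2 * .data$mean_dvx,
                   yend = .data$cy + 0.2 * .data$mean_dvy),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
      color = "white", linewidth = 0.2) +
    ggplot2::annotate("point", x = 0, y = 0, color = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (mm, focal frame)", y = "y (mm, focal frame)",
                  fill = "records",
                  title = "Influential neighbors around the focal fish")
}

#' Plot the mean-delay map over heading difference and distance
#'
#' @param object tibble from [delay_map()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_delay_map <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$phi_lo + (.data$phi_hi - .data$phi_lo) / 2,
                               .data$d_lo + (.data$d_hi - .data$d_lo) / 2,
                               fill = .data$mean_tau)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "|heading difference| (deg)", y = "distance (mm)",
                  fill = "mean delay (s)",
                  title = "Delay versus pair geometry")
}

#' Plot burst/influence raster timelines
#'
#' Each fish's bursting frames at integer rows; frames where its
#' influencer was bursting at emission time at the half-offset row below,
#' colored by influencer identity.
#'
#' @param overlap output of [burst_influence_overlap()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot_burst_raster <- function(overlap, ...) {
  r <- overlap$raster
  ggplot2::ggplot(r, ggplot2::aes(.data$time, .data$row)) +
    ggplot2::geom_point(ggplot2::aes(color = dplyr::coalesce(
      .data$influencer, .data$fish)), size = 0.6, shape = 15) +
    ggplot2::labs(x = "time (s)", y = "fish (rows) / influencer (half rows)",
                  color = "fish",
                  title = "Bursting and influential-neighbor activity")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
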