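# Diagnostic ggplot2 views of the main result types.

#' Plot accepted corrections per iteration
#'
#' @param x a `correction_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.correction_result <- function(x, ...) {
  long <- tidyr::pivot_longer(x$report,
                              c("missing_redetect", "split_underseg",
                                "merge_overseg"),
                              names_to = "kind", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$count,
                                     fill = .data$kind)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "correction iteration", y = "accepted corrections",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a lineage forest as a 2D (x, y) track projection
#'
#' @param x a `lineage_forest`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lineage_forest <- function(x, ...) {
  n <- x$nodes
  ggplot2::ggplot(n, ggplot2::aes(x = .data$x, y = .data$y,
                                  group = .data$track_id,
                                  colour = factor(.data$track_id %% 12))) +
    ggplot2::geom_path(alpha = 0.7, show.legend = FALSE) +
    ggplot2::geom_point(data = n[is.na(n$parent_id), ], size = 0.8,
                        show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' Plot a velocity field (x, y projection)
#'
#' @param vf tibble from [velocity_field()].
#' @param scale arrow scale (min per displayed um).
#' @return a ggplot object.
#' @export
plot_velocity_field <- function(vf, scale = 1) {
  ggplot2::ggplot(vf, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x + scale * .data$vx,
                                       yend = .data$y + scale * .data$vy,
                                       colour = .data$local_mean_speed),
                          arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c(name = "local speed (um/min)") +
    ggplot2::labs(x = "x (um)", y = "y (um)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
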