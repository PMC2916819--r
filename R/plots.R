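#' Plot basin sizes
#'
#' Bar chart of absolute or relative attraction-basin sizes.
#'
#' @param object A [enumerate_basins()] partition.
#' @param relative Plot relative (default) or absolute sizes.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.basin_partition <- function(object, relative = TRUE, ...) {
  dat <- basin_sizes(object)
  y <- if (relative) "relative_size" else "size"
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$basin, y = .data[[y]])) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = "attraction basin",
      y = if (relative) "relative size" else "absolute size",
      title = "Attraction-basin sizes"
    ) +
    ggplot2::theme_minimal()
}

#' Plot passage-probability curves
#'
#' Curves of the characteristic polynomials \eqn{P(B_i \to B_j)(p)} over
#' the perturbation rate, faceted by origin basin.
#'
#' @param object A [passage_matrix()].
#' @param p Grid of perturbation rates.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.passage_matrix <- function(object, p = seq(0, 1, by = 0.01), ...) {
  dat <- tidy(object, p = p)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$p, y = .data$probability,
                                    colour = .data$target)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$origin)) +
    ggplot2::labs(x = "state perturbation rate p",
                  y = "probability of passage", colour = "target basin") +
    ggplot2::theme_minimal()
}

#' Plot a distance distribution
#'
#' @param dist A [distance_distribution()] tibble (or several row-bound
#'   ones with `origin`/`target`/`regime` columns).
#' @return A ggplot object.
#' @export
plot_distance_distribution <- function(dist) {
  p <- ggplot2::ggplot(dist, ggplot2::aes(x = .data$d, y = .data$percent)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "minimal Hamming distance d",
                  y = "% of origin configurations") +
    ggplot2::theme_minimal()
  if (all(c("origin", "target") %in% names(dist)))
    p <- p + ggplot2::facet_grid(
      rows = ggplot2::vars(.data$origin), cols = ggplot2::vars(.data$target))
  p
}
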