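# ggplot2 presentation layer.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a block matrix as a heat map
#'
#' @param object a `block_matrix`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.block_matrix <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(as.table(object$B)),
                          .name_repair = ~ c("u", "v", "weight"))
  df$u <- as.integer(df$u); df$v <- as.integer(df$v)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$v, y = .data$u,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = expression(B[uv])) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "community", y = "community") +
    ggplot2::theme_minimal()
}

#' Plot angular positions of a sampled graph
#'
#' Projects nodes on their first two unit-vector components, colored by
#' community when present (for `D = 1` this is the circle itself).
#'
#' @param object an `sd_graph`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.sd_graph <- function(object, ...) {
  nodes <- object$nodes
  aes <- if ("community" %in% names(nodes)) {
    ggplot2::aes(x = .data$x_1, y = .data$x_2,
                 colour = factor(.data$community), size = .data$kappa)
  } else {
    ggplot2::aes(x = .data$x_1, y = .data$x_2, size = .data$kappa)
  }
  ggplot2::ggplot(nodes, aes) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_continuous(range = c(0.3, 3), name = expression(kappa)) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "community") +
    ggplot2::theme_minimal()
}

#' Plot tabulated analytic curves
#'
#' Line plot of a [tabulate_analytic_curves()] table, one curve per
#' dimension (density curves over the angle, or the nearest-neighbor count
#' over the number of points on a log axis).
#'
#' @param curves a tibble from [tabulate_analytic_curves()].
#' @return a ggplot object.
#' @export
plot_analytic_curves <- function(curves) {
  if (unique(curves$kind) == "nnn") {
    return(
      ggplot2::ggplot(curves, ggplot2::aes(x = .data$n, y = .data$value,
                                           colour = factor(.data$D))) +
        ggplot2::geom_line() +
        ggplot2::scale_x_log10() +
        ggplot2::labs(x = "number of points n", y = "nearest neighbors",
                      colour = "D") +
        ggplot2::theme_minimal())
  }
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$theta, y = .data$value,
                                       colour = factor(.data$D))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(theta), y = "density", colour = "D") +
    ggplot2::theme_minimal()
}

#' Plot a dispersion-sweep metric
#'
#' Replicate-averaged metric against `sigma`, one panel per community
#' count, colored by dimension.
#'
#' @param results a [run_sigma_sweep()] tibble.
#' @param metric column name: `"srank_ratio"`, `"entropy_bits"` or
#'   `"avg_community_degree"`.
#' @return a ggplot object.
#' @export
plot_sweep <- function(results, metric = "srank_ratio") {
  summ <- results |>
    dplyr::filter(.data$converged) |>
    dplyr::group_by(.data$D, .data$n_communities, .data$sigma) |>
    dplyr::summarise(value = mean(.data[[metric]]), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$sigma, y = .data$value,
                                     colour = factor(.data$D))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~ n_communities, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(sigma), y = metric, colour = "D") +
    ggplot2::theme_minimal()
}
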