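# broom-style tidiers for sampled graphs and block matrices.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a sampled graph
#'
#' Returns the node table, augmented with each node's realized degree.
#'
#' @param x an `sd_graph`.
#' @param ... unused.
#' @return a tibble with one row per node.
#' @export
tidy.sd_graph <- function(x, ...) {
  deg <- table(factor(c(x$edges$from, x$edges$to), levels = x$nodes$id))
  dplyr::mutate(x$nodes, degree = as.integer(deg))
}

#' One-row summary of a sampled graph
#'
#' @param x an `sd_graph`.
#' @param ... unused.
#' @return tibble with `N`, `D`, `beta`, `n_edges`, `mean_degree`,
#'   `max_degree`, plus calibration diagnostics when the graph was built
#'   with soft communities.
#' @export
glance.sd_graph <- function(x, ...) {
  deg <- table(factor(c(x$edges$from, x$edges$to), levels = x$nodes$id))
  out <- tibble::tibble(
    N = nrow(x$nodes), D = x$params$D, beta = x$params$beta,
    n_edges = nrow(x$edges),
    mean_degree = 2 * nrow(x$edges) / nrow(x$nodes),
    max_degree = as.integer(max(deg)))
  if (!is.null(x$calibration)) {
    out$calibration_converged <- x$calibration$converged
    out$calibration_residual <- x$calibration$residual
  }
  out
}

#' Tidy a block matrix
#'
#' @param x a `block_matrix`.
#' @param ... unused.
#' @return long tibble of unordered community pairs: `u`, `v` (`u < v`),
#'   normalized `weight`, and expected inter-community edge count
#'   `expected_edges = weight * m`.
#' @export
tidy.block_matrix <- function(x, ...) {
  idx <- which(upper.tri(x$B), arr.ind = TRUE)
  tibble::tibble(u = idx[, 1], v = idx[, 2],
                 weight = x$B[idx],
                 expected_edges = x$B[idx] * x$m)
}

#' One-row summary of a block matrix
#'
#' @param x a `block_matrix`.
#' @param ... unused.
#' @return the [block_metrics()] tibble.
#' @export
glance.block_matrix <- function(x, ...) block_metrics(x)
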