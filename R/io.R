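# Plain-text artifacts: node tables and edge lists as TSV, block matrices
# as CSV, metrics as JSON, sweep configurations as YAML, optional GraphML.

#' Read and write node tables
#'
#' Node tables are TSV with columns `id`, optional `community`/`cluster`,
#' `kappa` (if set), angles `phi_1..phi_D` and unit-vector components
#' `x_1..x_{D+1}`. Floating-point columns survive the round trip to full
#' double precision.
#'
#' @param nodes node tibble.
#' @param path file path.
#' @return `read_node_table()` returns the tibble; writers return `path`
#'   invisibly.
#' @export
write_node_table <- function(nodes, path) {
  readr::write_tsv(dplyr::mutate(nodes, dplyr::across(
    dplyr::where(is.double), ~ format(.x, digits = 17, trim = TRUE))), path)
  invisible(path)
}

#' @rdname write_node_table
#' @export
read_node_table <- function(path) {
  nodes <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"id" %in% names(nodes)) {
    stop("malformed node table (missing `id` column): ", path, call. = FALSE)
  }
  nodes
}

#' Read and write edge lists
#'
#' Two-column TSV of 0-based node ids (`from`, `to`). The simple-graph
#' contract is enforced on read: self-loops and duplicate (unordered)
#' edges are rejected with the offending line reported.
#'
#' @param edges edge tibble with `from` and `to`.
#' @param path file path.
#' @export
write_edge_list <- function(edges, path) {
  readr::write_tsv(edges[, c("from", "to")], path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  edges <- readr::read_tsv(path, show_col_types = FALSE)
  if (!all(c("from", "to") %in% names(edges))) {
    stop("malformed edge list (need `from` and `to` columns): ", path,
         call. = FALSE)
  }
  loop <- which(edges$from == edges$to)
  if (length(loop) > 0) {
    stop(sprintf("self-loop at line %d of %s", loop[1] + 1L, path),
         call. = FALSE)
  }
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop(sprintf("duplicate edge at line %d of %s", dup[1] + 1L, path),
         call. = FALSE)
  }
  edges
}

#' Read and write block matrices
#'
#' Plain CSV with a header of community ids; the inter-community mass `m`
#' is carried in a `# m=<value>` comment line so the object round-trips.
#'
#' @param block a `block_matrix`.
#' @param path file path.
#' @export
write_block_matrix <- function(block, path) {
  stopifnot(inherits(block, "block_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# m=%s", format(block$m, digits = 17)), con)
  utils::write.csv(as.data.frame(block$B), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_block_matrix
#' @export
read_block_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^# m=", first)) {
    stop("malformed block-matrix file (missing `# m=` header): ", path,
         call. = FALSE)
  }
  m <- as.numeric(sub("^# m=", "", first))
  B <- as.matrix(utils::read.csv(path, comment.char = "#",
                                 check.names = FALSE))
  dimnames(B) <- list(seq_len(nrow(B)), seq_len(ncol(B)))
  structure(list(B = B, m = m, n = nrow(B)), class = "block_matrix")
}

#' Read and write metrics records as JSON
#'
#' Serializes a metrics tibble (e.g. a [run_sigma_sweep()] result) to JSON
#' and back, preserving records and numeric precision.
#'
#' @param metrics a data frame of metrics.
#' @param path file path.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, digits = NA, auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_metrics_json
#' @export
read_metrics_json <- function(path) {
  tibble::as_tibble(jsonlite::fromJSON(path))
}

#' Read and write sweep configurations as YAML
#'
#' @param config a [sweep_config()].
#' @param path file path.
#' @export
write_sweep_config <- function(config, path) {
  stopifnot(inherits(config, "sweep_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sweep_config
#' @export
read_sweep_config <- function(path) {
  do.call(sweep_config, yaml::read_yaml(path))
}

#' Export a sampled graph as GraphML
#'
#' Thin convenience wrapper over igraph (suggested dependency); node
#' attributes carry the coordinates, latent degree and community label.
#'
#' @param graph an `sd_graph`.
#' @param path file path.
#' @export
write_graphml <- function(graph, path) {
  if (!requireNamespace("igraph", quietly = TRUE)) {
    stop("GraphML export needs the `igraph` package", call. = FALSE)
  }
  g <- igraph::graph_from_data_frame(
    dplyr::mutate(graph$edges, from = as.character(from),
                  to = as.character(to)),
    directed = FALSE,
    vertices = dplyr::mutate(graph$nodes, id = as.character(id)))
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
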