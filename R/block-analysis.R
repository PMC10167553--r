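# Coarse-graining a (probabilistic) graph into an inter-community block
# matrix, and its diagnostics: stable rank, Shannon entropy, binarization
# and community degrees.

#' Inter-community block matrix
#'
#' Aggregates pairwise connection probabilities (or realized edge
#' indicators) into an `n x n` community-level matrix: entry `(u, v)` is
#' the total probability mass on pairs spanning communities `u` and `v`,
#' normalized by `m`, the total inter-community mass over unordered pairs.
#' The diagonal (within-community mass) is set to zero, so
#' `sum over u < v of B_uv = 1` and `B_uv` is the probability that a
#' uniformly drawn inter-community edge joins `u` and `v`.
#'
#' @param prob_matrix symmetric matrix with zero diagonal: connection
#'   probabilities, or a 0/1 adjacency matrix for a realized graph.
#' @param labels community labels in `1..n`, one per row of `prob_matrix`.
#' @param n number of communities (default: `max(labels)`; communities with
#'   no members yield all-zero rows).
#' @return an object of class `block_matrix`: list with `B` (the matrix),
#'   `m` (inter-community mass) and `n`.
#' @examples
#' p <- matrix(0, 3, 3); p[1, 3] <- p[3, 1] <- 0.5
#' block_matrix(p, labels = c(1, 1, 2))
#' @export
block_matrix <- function(prob_matrix, labels, n = max(labels)) {
  stopifnot(nrow(prob_matrix) == ncol(prob_matrix),
            length(labels) == nrow(prob_matrix),
            all(labels >= 1), all(labels <= n))
  if (max(abs(prob_matrix - t(prob_matrix))) > 1e-10) {
    stop("`prob_matrix` must be symmetric", call. = FALSE)
  }
  f <- factor(labels, levels = seq_len(n))
  M <- rowsum(t(rowsum(prob_matrix, f, reorder = TRUE)), f, reorder = TRUE)
  M <- as.matrix(M)
  diag(M) <- 0
  m <- sum(M) / 2
  if (m <= 0) stop("no inter-community probability mass (m = 0)", call. = FALSE)
  dimnames(M) <- list(seq_len(n), seq_len(n))
  structure(list(B = M / m, m = m, n = n), class = "block_matrix")
}

#' @export
print.block_matrix <- function(x, ...) {
  cat(sprintf("block matrix on %d communities (inter-community mass m = %.4g)\n",
              x$n, x$m))
  print(round(x$B, 4))
  invisible(x)
}

as_block_entries <- function(B) {
  if (inherits(B, "block_matrix")) B$B else as.matrix(B)
}

#' Stable rank of a matrix
#'
#' `srank(B) = sum(s_i^2) / s_1^2` over singular values in non-increasing
#' order — a noise-robust surrogate for rank, maximal (`= n`) for diagonal
#' matrices and invariant under simultaneous row/column permutation. The
#' null matrix has stable rank 0 by convention. `srank_ratio()` divides by
#' the order `n`, giving a `[0, 1]` score of how "diagonal" a block matrix
#' is: values near 1 mean inter-community mass is pinned near a diagonal
#' band (the circle's signature), lower values mean richer mixing.
#'
#' @param B a `block_matrix` or plain square matrix.
#' @return a scalar.
#' @export
stable_rank <- function(B) {
  M <- as_block_entries(B)
  s <- svd(M, nu = 0, nv = 0)$d
  if (s[1] <= 0) return(0)
  sum(s^2) / s[1]^2
}

#' @rdname stable_rank
#' @export
srank_ratio <- function(B) {
  M <- as_block_entries(B)
  stable_rank(M) / nrow(M)
}

#' Shannon entropy of a block matrix
#'
#' `S(B) = - sum over u < v of B_uv log2(B_uv)` (bits), with the
#' `0 log 0 = 0` convention. Since the upper-triangular entries form a
#' probability mass function over community pairs, the entropy is 0 when a
#' single pair carries all inter-community mass and maximal,
#' `log2(n(n-1)/2)`, when the mass is uniform. Requires the entries to be
#' normalized (checked to 1e-6).
#'
#' @param B a `block_matrix` or a square matrix whose upper triangle sums
#'   to 1.
#' @return entropy in bits.
#' @export
block_entropy <- function(B) {
  M <- as_block_entries(B)
  w <- M[upper.tri(M)]
  if (abs(sum(w) - 1) > 1e-6) {
    stop("block entries must sum to 1 over unordered pairs", call. = FALSE)
  }
  w <- w[w > 0]
  -sum(w * log2(w))
}

#' Binarize a block matrix at the one-expected-edge threshold
#'
#' `C_uv = 1` iff `B_uv > 1/m`, i.e. iff the expected number of edges
#' between communities `u` and `v` exceeds one — a deliberately liberal
#' notion of two communities being "related". The comparison is strict:
#' exactly one expected edge maps to 0. Other thresholds can be supplied.
#'
#' @param B a `block_matrix`, or a plain matrix with `m` given.
#' @param m inter-community mass (taken from `B` when it is a
#'   `block_matrix`).
#' @param threshold cutoff on the normalized entries (default `1/m`).
#' @return an integer 0/1 matrix with zero diagonal.
#' @export
binarize_blocks <- function(B, m = NULL, threshold = NULL) {
  if (inherits(B, "block_matrix")) {
    if (is.null(m)) m <- B$m
    B <- B$B
  }
  if (is.null(threshold)) {
    if (is.null(m) || m <= 0) stop("`m` must be positive", call. = FALSE)
    threshold <- 1 / m
  }
  C <- (as.matrix(B) > threshold) * 1L
  diag(C) <- 0L
  C
}

#' Community degrees of a binarized block matrix
#'
#' Row sums of the 0/1 relation matrix: how many other communities each
#' community is related to, plus their average — the community-level
#' analogue of the nearest-neighbor count of points on the sphere.
#'
#' @param C binary symmetric matrix with zero diagonal (from
#'   [binarize_blocks()]).
#' @return list with `k` (integer vector) and `average`.
#' @export
community_degrees <- function(C) {
  C <- as.matrix(C)
  stopifnot(all(C %in% c(0, 1)), all(diag(C) == 0))
  k <- as.integer(rowSums(C))
  list(k = k, average = mean(k))
}

#' Full set of block diagnostics
#'
#' One-stop summary: stable rank (and its ratio to the order), Shannon
#' entropy in bits, and community degrees after the default binarization.
#'
#' @param block a `block_matrix`.
#' @return one-row tibble: `n`, `m`, `stable_rank`, `srank_ratio`,
#'   `entropy_bits`, `avg_community_degree`, and `community_degrees`
#'   (list column).
#' @export
block_metrics <- function(block) {
  stopifnot(inherits(block, "block_matrix"))
  cd <- community_degrees(binarize_blocks(block))
  tibble::tibble(
    n = block$n, m = block$m,
    stable_rank = stable_rank(block),
    srank_ratio = srank_ratio(block),
    entropy_bits = block_entropy(block),
    avg_community_degree = cd$average,
    community_degrees = list(cd$k))
}
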