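# Geometry of the similarity space S^D: uniform sampling, angular distances,
# hyperspherical cap volumes and the characteristic-neighborhood count.

#' Hyperspherical angle/vector conversions
#'
#' Points on the unit D-sphere embedded in R^(D+1) are parameterized by
#' hyperspherical angles `phi_1, ..., phi_{D-1}` in `[0, pi)` (polar) and
#' `phi_D` in `[0, 2*pi)` (azimuthal):
#' `x_1 = cos(phi_1)`, `x_2 = sin(phi_1) cos(phi_2)`, ...,
#' `x_{D+1} = sin(phi_1) ... sin(phi_{D-1}) sin(phi_D)`.
#' Internal computations use unit vectors throughout to avoid the coordinate
#' singularities at the poles; angles are a presentation layer.
#'
#' @param phi numeric matrix with `D` columns (one row per point), or a
#'   numeric vector for a single point.
#' @param x numeric matrix with `D + 1` columns of unit vectors, or a vector.
#' @return `angles_to_unit()` returns a matrix of unit vectors with `D + 1`
#'   columns; `unit_to_angles()` returns a matrix of angles with `D` columns.
#' @examples
#' x <- angles_to_unit(cbind(pi / 3, 1.0))
#' unit_to_angles(x)
#' @export
angles_to_unit <- function(phi) {
  if (is.null(dim(phi))) phi <- matrix(phi, nrow = 1L)
  D <- ncol(phi)
  n <- nrow(phi)
  x <- matrix(0, n, D + 1L)
  run <- rep(1, n)                  # running product of sines
  for (d in seq_len(D)) {
    x[, d] <- run * cos(phi[, d])
    run <- run * sin(phi[, d])
  }
  x[, D + 1L] <- run
  x
}

#' @rdname angles_to_unit
#' @export
unit_to_angles <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  D <- ncol(x) - 1L
  stopifnot(D >= 1L)
  phi <- matrix(0, nrow(x), D)
  # tail norms: r_d = |(x_d, ..., x_{D+1})|
  tail_norm <- sqrt(t(apply(x[, rev(seq_len(D + 1L)), drop = FALSE]^2, 1L, cumsum)))
  tail_norm <- tail_norm[, rev(seq_len(D + 1L)), drop = FALSE]
  for (d in seq_len(D - 1L)) {
    phi[, d] <- acos(clamp_unit(ifelse(tail_norm[, d] > 0, x[, d] / tail_norm[, d], 1)))
  }
  phi[, D] <- atan2(x[, D + 1L], x[, D]) %% (2 * pi)
  phi
}

clamp_unit <- function(z) pmin(pmax(z, -1), 1)  # arg order keeps dim attributes

#' Angular (great-circle) distance between points on S^D
#'
#' Returns `acos(u . v)` for unit vectors, the great-circle angle in
#' `[0, pi]`. Dot products are clamped to `[-1, 1]` before `acos()` for
#' floating-point safety.
#'
#' @param u,v unit vectors (or matrices of row vectors) in R^(D+1) of equal
#'   dimension. When both are matrices the distance is computed row-wise.
#' @param tol tolerance on the unit-norm check.
#' @return angular distance(s) in radians, in `[0, pi]`.
#' @examples
#' angular_distance(c(1, 0), c(0, 1))  # pi / 2
#' @export
angular_distance <- function(u, v, tol = 1e-8) {
  if (is.null(dim(u))) u <- matrix(u, nrow = 1L)
  if (is.null(dim(v))) v <- matrix(v, nrow = 1L)
  if (ncol(u) != ncol(v)) {
    stop("`u` and `v` must live on a sphere of the same dimension", call. = FALSE)
  }
  bad <- c(abs(rowSums(u^2) - 1), abs(rowSums(v^2) - 1))
  if (any(bad > tol)) {
    stop("inputs must be unit vectors (norm deviates by more than `tol`)", call. = FALSE)
  }
  acos(clamp_unit(rowSums(u * v)))
}

# Full pairwise angular distance matrix for a matrix of unit row vectors.
pairwise_angles <- function(x) {
  th <- acos(clamp_unit(tcrossprod(x)))
  diag(th) <- 0
  th
}

#' Sample points uniformly on S^D
#'
#' Draws i.i.d. points uniform with respect to the spherical measure, by
#' normalizing standard Gaussian vectors in R^(D+1).
#'
#' @param count number of points (>= 1).
#' @param D sphere dimension (>= 1).
#' @param seed optional integer seed for reproducibility.
#' @return a tibble with columns `id` (0-based), unit-vector components
#'   `x_1 ... x_{D+1}` and angles `phi_1 ... phi_D`.
#' @examples
#' sample_uniform_sphere(5, D = 2, seed = 1)
#' @export
sample_uniform_sphere <- function(count, D, seed = NULL) {
  check_dimension(D)
  stopifnot(count >= 1)
  if (!is.null(seed)) set.seed(seed)
  x <- runif_sphere(count, D)
  sphere_tibble(x)
}

runif_sphere <- function(count, D) {
  g <- matrix(stats::rnorm(count * (D + 1L)), count, D + 1L)
  g / sqrt(rowSums(g^2))
}

sphere_tibble <- function(x, id = seq_len(nrow(x)) - 1L) {
  D <- ncol(x) - 1L
  colnames(x) <- paste0("x_", seq_len(D + 1L))
  phi <- unit_to_angles(x)
  colnames(phi) <- paste0("phi_", seq_len(D))
  dplyr::bind_cols(tibble::tibble(id = id),
                   tibble::as_tibble(x), tibble::as_tibble(phi))
}

# Extract the unit-vector matrix from a node tibble.
node_coords <- function(nodes) {
  cols <- grep("^x_[0-9]+$", names(nodes), value = TRUE)
  cols <- cols[order(as.integer(sub("^x_", "", cols)))]
  as.matrix(nodes[, cols])
}

check_dimension <- function(D) {
  if (length(D) != 1L || D < 1 || D != round(D)) {
    stop("`D` must be a single integer >= 1", call. = FALSE)
  }
  invisible(as.integer(D))
}

#' Sine-power integral constant
#'
#' `I_D = integral of sin^(D-1)(theta) over [0, pi]`, the normalizer of the
#' uniform pairwise-distance density. Computed from the closed form
#' `sqrt(pi) * gamma(D/2) / gamma((D+1)/2)`.
#'
#' @param D sphere dimension (>= 1); vectorized.
#' @return positive scalar(s): `I_1 = pi`, `I_2 = 2`, `I_3 = pi/2`, ...
#' @export
sine_integral_constant <- function(D) {
  stopifnot(all(D >= 1))
  sqrt(pi) * gamma(D / 2) / gamma((D + 1) / 2)
}

# Incomplete version: integral of sin^(D-1) over [0, phi]. Vectorized in phi.
sine_integral <- function(phi, D) {
  vapply(phi, function(p) {
    if (p <= 0) return(0)
    if (p >= pi) return(sine_integral_constant(D))
    stats::integrate(function(t) sin(t)^(D - 1), 0, p,
                     rel.tol = 1e-12, abs.tol = 1e-14)$value
  }, numeric(1))
}

#' Density of the angular distance between uniform random points
#'
#' For two points drawn uniformly on S^D, the angular distance has density
#' `f_X(theta) = sin^(D-1)(theta) / I_D` on `[0, pi]`. For `D = 1` this is
#' the constant `1/pi`; for `D >= 2` it is unimodal with mode `pi/2`, and
#' concentrates sharply there as `D` grows (concentration of measure).
#'
#' @param theta angle(s) in `[0, pi]`.
#' @param D sphere dimension.
#' @return density value(s).
#' @export
uniform_pair_pdf <- function(theta, D) {
  check_dimension(D)
  if (any(theta < 0 | theta > pi)) {
    stop("`theta` must lie in [0, pi]", call. = FALSE)
  }
  sin(theta)^(D - 1) / sine_integral_constant(D)
}

#' Volume of a hyperspherical cap
#'
#' The D-dimensional volume of an open ball of angular radius `phi` on a
#' D-sphere of radius `R_hat`:
#' `Vol(B(phi)) = 2 pi^(D/2) R_hat^D / gamma(D/2) * integral_0^phi sin^(D-1)`.
#' At `phi = pi` this is the full sphere volume
#' `2 pi^((D+1)/2) R_hat^D / gamma((D+1)/2)`.
#'
#' @param phi angular radius in `[0, pi]` (vectorized).
#' @param D sphere dimension.
#' @param R_hat sphere radius (> 0).
#' @return cap volume(s).
#' @export
cap_volume <- function(phi, D, R_hat = 1) {
  check_dimension(D)
  stopifnot(R_hat > 0)
  if (any(phi < 0 | phi > pi)) {
    stop("`phi` must lie in [0, pi]", call. = FALSE)
  }
  2 * pi^(D / 2) * R_hat^D / gamma(D / 2) * sine_integral(phi, D)
}

#' Characteristic angular radius of an n-th of the sphere
#'
#' Solves `Vol(B(phi_n)) = Vol(S^D) / n` for `phi_n`; the sphere radius
#' cancels. Closed forms are used for `D = 1` (`pi/n`) and `D = 2`
#' (`acos(1 - 2/n)`); higher dimensions use bracketed root finding on the
#' incomplete sine integral.
#'
#' @param n number of points (>= 1); vectorized.
#' @param D sphere dimension.
#' @return angular radius in `(0, pi]`.
#' @export
characteristic_angle <- function(n, D) {
  check_dimension(D)
  stopifnot(all(n >= 1))
  if (D == 1) return(pi / n)
  if (D == 2) return(acos(clamp_unit(1 - 2 / n)))
  ID <- sine_integral_constant(D)
  vapply(n, function(nn) {
    if (nn == 1) return(pi)
    stats::uniroot(function(p) sine_integral(p, D) - ID / nn,
                   interval = c(1e-12, pi), tol = 1e-14)$root
  }, numeric(1))
}

#' Number of nearest neighbors on S^D
#'
#' Divide the sphere into `n` regions of equal volume; the characteristic
#' neighborhood `B(phi_n)` holds one point. The count of nearest neighbors
#' is `nnn = Vol(B(3 phi_n)) / Vol(B(phi_n)) - 1`: the tripled ball is
#' assumed to hold a central point plus its neighbors. When `3 phi_n >= pi`
#' the tripled ball is the whole sphere and `nnn = n - 1` (the saturation
#' ceiling). On the circle `nnn = 2` for every `n > 2`; as `n` grows,
#' `nnn` approaches `3^D - 1` (see [nearest_neighbor_asymptote()]).
#'
#' @param n number of points (> 2); vectorized.
#' @param D sphere dimension.
#' @return a tibble with columns `n`, `D`, `phi_n` and `nnn`.
#' @examples
#' nearest_neighbor_count(c(10, 100, 1e4), D = 2)
#' @export
nearest_neighbor_count <- function(n, D) {
  check_dimension(D)
  if (any(n <= 2)) stop("`n` must exceed 2", call. = FALSE)
  phi_n <- characteristic_angle(n, D)
  inner <- sine_integral_constant(D) / n     # = sine_integral(phi_n, D)
  outer_int <- sine_integral(pmin(3 * phi_n, pi), D)
  nnn <- pmin(outer_int / inner - 1, n - 1)
  tibble::tibble(n = n, D = D, phi_n = phi_n, nnn = nnn)
}

#' Large-n nearest-neighbor asymptote
#'
#' In the many-points regime the characteristic neighborhood is locally
#' Euclidean and `nnn` tends to `3^D - 1` (2 on the circle, 8 on the sphere,
#' 26 in D = 3, the grid-neighbor counts of Euclidean lattices).
#'
#' @param D sphere dimension (vectorized).
#' @return integer(s) `3^D - 1`.
#' @export
nearest_neighbor_asymptote <- function(D) {
  stopifnot(all(D >= 1))
  3^D - 1
}

# D = 2 closed form for nnn (triple-angle identity applied to the spherical
# cap area); agrees with the quadrature route to machine precision.
nnn_closed_form_d2 <- function(n) 8 - 24 / n + 16 / n^2
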