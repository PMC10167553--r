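# The S^D latent-space random-graph model: parameters, Pareto latent degrees,
# connection probabilities, the H^(D+1) correspondence, mean-degree
# calibration, and graph sampling.

#' Construct S^D model parameters
#'
#' Holds every scalar parameter of the model and enforces their consistency.
#' Nodes live on a D-sphere of radius `R_hat`; each node carries a latent
#' degree `kappa` (popularity). A pair at angular distance `theta` with
#' latent degrees `kappa`, `kappa'` connects with probability
#' `1 / (1 + (theta/eta)^beta)` where
#' `eta = (mu_hat * kappa * kappa')^(1/D) / R_hat` is the pair's angular
#' connectivity threshold. The model works in the cold regime `beta/D > 1`
#' (power-law degrees, sparse clustered graphs) and refuses `beta <= D`.
#'
#' Latent degrees are Pareto with exponent `gamma > 2` and lower bound
#' `kappa0 = mean_kappa * (gamma - 2) / (gamma - 1)`, so their mean is
#' `mean_kappa`. By default `R_hat` follows the unit-density convention:
#' the sphere's volume equals `N` (see [sphere_radius_for_unit_density()]),
#' under which `eta` scales as `(kappa kappa' / N)^(1/D)`.
#'
#' @param D similarity dimension (>= 1).
#' @param N number of nodes.
#' @param beta inverse temperature; controls how sharply connection
#'   probability decays with angular distance (`Inf` gives a hard cutoff at
#'   `eta`). Give either `beta` or `beta_over_d`.
#' @param beta_over_d `beta / D`; the ratio is the natural quantity to hold
#'   fixed when comparing dimensions (default 3.5).
#' @param gamma Pareto exponent of the latent-degree law (> 2).
#' @param mean_kappa mean latent degree.
#' @param mean_degree optional target mean degree; when supplied, `mu_hat`
#'   is calibrated numerically so the analytic expected mean degree
#'   `(N - 1) * f_A(1)` hits the target (see [calibrate_mu_hat()]).
#' @param mu_hat connection-scale parameter; ignored when `mean_degree`
#'   is given.
#' @param R_hat sphere radius; defaults to the unit-density convention.
#' @param zeta curvature scale of the hyperboloid representation (only used
#'   by [hyperbolic_distance()] and the H/S correspondence helpers).
#' @return an object of class `sd_model` (a named list of parameters).
#' @examples
#' params <- sd_model(D = 1, N = 200, gamma = 2.5, mean_kappa = 10,
#'                    mu_hat = 0.01)
#' params$kappa0
#' @export
sd_model <- function(D, N, beta = NULL, beta_over_d = 3.5, gamma = 2.5,
                     mean_kappa = 10, mean_degree = NULL, mu_hat = NULL,
                     R_hat = NULL, zeta = 1) {
  D <- check_dimension(D)
  stopifnot(N >= 1, gamma > 2, mean_kappa > 0, zeta > 0)
  if (is.null(beta)) beta <- beta_over_d * D
  if (is.finite(beta) && beta / D <= 1) {
    stop("cold regime required: `beta / D` must exceed 1", call. = FALSE)
  }
  if (is.null(R_hat)) R_hat <- sphere_radius_for_unit_density(N, D)
  stopifnot(R_hat > 0)
  kappa0 <- mean_kappa * (gamma - 2) / (gamma - 1)
  params <- structure(
    list(D = D, N = as.integer(N), beta = beta, gamma = gamma,
         mean_kappa = mean_kappa, kappa0 = kappa0, mu_hat = mu_hat,
         R_hat = R_hat, zeta = zeta, mean_degree = mean_degree),
    class = "sd_model")
  if (!is.null(mean_degree)) {
    params$mu_hat <- calibrate_mu_hat(params, mean_degree)
  } else if (is.null(mu_hat)) {
    stop("supply either `mu_hat` or `mean_degree`", call. = FALSE)
  }
  params
}

#' @export
print.sd_model <- function(x, ...) {
  cat("S^D hyperbolic random-graph model\n")
  cat(sprintf("  D = %d, N = %d, beta = %g (beta/D = %g)\n",
              x$D, x$N, x$beta, x$beta / x$D))
  cat(sprintf("  gamma = %g, mean kappa = %g (kappa0 = %g)\n",
              x$gamma, x$mean_kappa, x$kappa0))
  cat(sprintf("  mu_hat = %g, R_hat = %g\n", x$mu_hat, x$R_hat))
  invisible(x)
}

#' Sphere radius under the unit-density convention
#'
#' Radius `R_hat` such that the D-dimensional volume of the sphere equals
#' the number of nodes `N`, giving node density 1:
#' `R_hat = (N * gamma((D+1)/2) / (2 * pi^((D+1)/2)))^(1/D)`.
#'
#' @param N node count.
#' @param D sphere dimension.
#' @return radius.
#' @export
sphere_radius_for_unit_density <- function(N, D) {
  check_dimension(D)
  stopifnot(N >= 1)
  (N * gamma((D + 1) / 2) / (2 * pi^((D + 1) / 2)))^(1 / D)
}

#' Sample Pareto latent degrees
#'
#' i.i.d. draws from the Pareto law with exponent `gamma` and lower bound
#' `kappa0 = mean_kappa (gamma - 2) / (gamma - 1)`, so the sample mean
#' targets `mean_kappa`. Inverse-CDF sampling.
#'
#' @param N number of draws.
#' @param gamma Pareto exponent (> 2 so the mean exists).
#' @param mean_kappa target mean.
#' @param seed optional integer seed.
#' @return numeric vector of latent degrees (all >= `kappa0`).
#' @export
sample_latent_degrees <- function(N, gamma, mean_kappa, seed = NULL) {
  if (gamma <= 2) stop("`gamma` must exceed 2 (finite-mean Pareto)", call. = FALSE)
  stopifnot(mean_kappa > 0)
  if (!is.null(seed)) set.seed(seed)
  kappa0 <- mean_kappa * (gamma - 2) / (gamma - 1)
  kappa0 * stats::runif(N)^(-1 / (gamma - 1))
}

#' Pairwise angular connectivity threshold
#'
#' `eta(kappa, kappa') = (mu_hat * kappa * kappa')^(1/D) / R_hat`, the
#' angular scale below which a pair connects with probability above 1/2.
#' Symmetric in the two latent degrees.
#'
#' @param kappa,kappa_prime latent degrees (> 0, vectorized).
#' @param mu_hat connection-scale parameter (> 0).
#' @param R_hat sphere radius (> 0).
#' @param D sphere dimension.
#' @return threshold(s) on the angular scale.
#' @export
eta_threshold <- function(kappa, kappa_prime, mu_hat, R_hat, D) {
  check_dimension(D)
  if (any(c(kappa, kappa_prime, mu_hat, R_hat) <= 0)) {
    stop("all arguments must be positive", call. = FALSE)
  }
  (mu_hat * kappa * kappa_prime)^(1 / D) / R_hat
}

#' Connection probability of the S^D model
#'
#' `p(theta, eta) = 1 / (1 + (theta/eta)^beta)`, decreasing in the angular
#' distance `theta`; at `theta = eta` the probability is 1/2. `beta = Inf`
#' gives the hard-threshold (step) limit: connect iff `theta < eta`.
#'
#' @param theta angular distance(s) in `[0, pi]`.
#' @param eta pairwise threshold(s) (> 0).
#' @param beta inverse temperature (> 0; `Inf` allowed).
#' @return probability value(s).
#' @export
connection_probability <- function(theta, eta, beta) {
  stopifnot(all(theta >= 0 & theta <= pi), all(eta > 0), beta > 0)
  if (is.infinite(beta)) return(as.numeric(theta < eta))
  1 / (1 + (theta / eta)^beta)
}

#' Hyperbolic distance in H^(D+1)
#'
#' Exact mode evaluates the hyperbolic law of cosines
#' `acosh(cosh(zeta r) cosh(zeta r') - sinh(zeta r) sinh(zeta r') cos(theta)) / zeta`;
#' approximate mode uses `r + r' + (2/zeta) log(theta/2)`, accurate for
#' large radii and small angles (the regime in which the S^D and H^(D+1)
#' formulations agree).
#'
#' @param r,r_prime radial coordinates (>= 0, vectorized).
#' @param theta angular distance(s) in `[0, pi]`.
#' @param zeta curvature scale (> 0).
#' @param approximate use the large-radius approximation.
#' @return distance(s).
#' @export
hyperbolic_distance <- function(r, r_prime, theta, zeta = 1,
                                approximate = FALSE) {
  stopifnot(all(r >= 0), all(r_prime >= 0), zeta > 0,
            all(theta >= 0 & theta <= pi))
  if (approximate) {
    if (any(theta == 0)) {
      stop("approximate mode is singular at `theta = 0`", call. = FALSE)
    }
    return(r + r_prime + (2 / zeta) * log(theta / 2))
  }
  arg <- cosh(zeta * r) * cosh(zeta * r_prime) -
    sinh(zeta * r) * sinh(zeta * r_prime) * cos(theta)
  acosh(pmax(arg, 1)) / zeta
}

#' Map between latent degree and hyperbolic radius
#'
#' The change of variables `kappa = kappa0 * exp(zeta * D * (R - r) / 2)`
#' identifies the S^D latent degree with the H^(D+1) radial coordinate:
#' central nodes (small `r`) have large latent degree.
#'
#' @param value the coordinate to map (vectorized).
#' @param direction `"r_to_kappa"` or `"kappa_to_r"`.
#' @param kappa0 latent-degree lower bound.
#' @param zeta curvature scale.
#' @param D dimension.
#' @param R hyperbolic ball radius.
#' @return the mapped coordinate(s); the round trip is the identity.
#' @export
kappa_radial_map <- function(value, direction = c("r_to_kappa", "kappa_to_r"),
                             kappa0, zeta, D, R) {
  direction <- match.arg(direction)
  check_dimension(D)
  stopifnot(kappa0 > 0, zeta > 0, R > 0)
  if (direction == "r_to_kappa") {
    stopifnot(all(value >= 0), all(value <= R))
    kappa0 * exp(zeta * D * (R - value) / 2)
  } else {
    if (any(value < kappa0 * (1 - 1e-12))) {
      stop("`kappa` must be at least `kappa0`", call. = FALSE)
    }
    R - 2 * log(pmax(value, kappa0) / kappa0) / (zeta * D)
  }
}

# mu of the H^(D+1) connection probability matched to the S^D one through
# the kappa <-> r change of variables and the large-radius distance
# approximation. Derived by equating exponents; used in the representation
# equivalence tests.
hyperboloid_mu <- function(mu_hat, kappa0, zeta, D, R, R_hat) {
  2 * R + (2 / zeta) * log((mu_hat * kappa0^2)^(1 / D) / (2 * R_hat))
}

# H^(D+1) connection probability (Fermi-Dirac in hyperbolic distance).
hyperboloid_probability <- function(d_h, mu, beta, zeta) {
  1 / (1 + exp(beta * zeta * (d_h - mu) / 2))
}

#' Calibrate the connection scale to a target mean degree
#'
#' Finds `mu_hat` such that the model's analytic expected mean degree,
#' `(N - 1) * f_A(1)` with `f_A(1)` the marginal connection probability of
#' a uniformly random pair (see [edge_probability_marginal()]), equals
#' `target_mean_degree`. The expected degree is monotone increasing in
#' `mu_hat`, so bisection on `log(mu_hat)` converges reliably.
#'
#' @param params an `sd_model` (its `mu_hat` is ignored).
#' @param target_mean_degree desired mean degree (> 0).
#' @param rel_tol relative tolerance on the achieved mean degree.
#' @return the calibrated `mu_hat`.
#' @export
calibrate_mu_hat <- function(params, target_mean_degree, rel_tol = 1e-3) {
  stopifnot(inherits(params, "sd_model"), target_mean_degree > 0)
  mean_deg <- function(log_mu) {
    (params$N - 1) * edge_probability_marginal(
      gamma = params$gamma, mean_kappa = params$mean_kappa,
      mu_hat = exp(log_mu), R_hat = params$R_hat,
      D = params$D, beta = params$beta)
  }
  lo <- log(1e-8); hi <- log(1)
  it <- 0
  while (mean_deg(lo) > target_mean_degree && it < 60) { lo <- lo - 2; it <- it + 1 }
  it <- 0
  while (mean_deg(hi) < target_mean_degree && it < 60) { hi <- hi + 2; it <- it + 1 }
  if (mean_deg(lo) > target_mean_degree || mean_deg(hi) < target_mean_degree) {
    stop(sprintf(
      "failed to bracket mu_hat for target mean degree %g (range [%g, %g])",
      target_mean_degree, mean_deg(lo), mean_deg(hi)), call. = FALSE)
  }
  root <- stats::uniroot(function(lm) mean_deg(lm) - target_mean_degree,
                         c(lo, hi), tol = 1e-12)$root
  mu <- exp(root)
  achieved <- mean_deg(root)
  if (abs(achieved - target_mean_degree) / target_mean_degree > rel_tol) {
    stop("mu_hat calibration did not reach the requested tolerance", call. = FALSE)
  }
  mu
}

# Pairwise connection-probability matrix for unit-vector coordinates `x`
# and latent degrees `kappa`. Factorized so that repeated calls with new
# kappa (degree calibration) avoid recomputing powers of the angle matrix:
# p_ij = 1 / (1 + A_ij / (b_i b_j)) with A = (theta * R_hat)^beta / mu_hat^(beta/D)
# and b_i = kappa_i^(beta/D).
connection_prob_matrix <- function(x, kappa, params, theta = NULL) {
  if (is.null(theta)) theta <- pairwise_angles(x)
  if (is.infinite(params$beta)) {
    eta <- (params$mu_hat * tcrossprod(kappa))^(1 / params$D) / params$R_hat
    p <- (theta < eta) * 1
    diag(p) <- 0
    return(p)
  }
  A <- prob_kernel(theta, params)
  kernel_to_prob(A, kappa, params)
}

prob_kernel <- function(theta, params) {
  A <- (theta * params$R_hat)^params$beta / params$mu_hat^(params$beta / params$D)
  diag(A) <- Inf                      # no self-loops
  A
}

kernel_to_prob <- function(A, kappa, params) {
  b <- kappa^(params$beta / params$D)
  1 / (1 + A / tcrossprod(b))
}

#' Expected degrees of a node configuration
#'
#' For each node, the sum over all other nodes of the pairwise connection
#' probability (the Poisson-binomial mean of its degree).
#'
#' @param nodes node tibble with unit-vector columns `x_*` and a `kappa`
#'   column (as produced by [sample_sd_network()] and friends).
#' @param params an `sd_model`.
#' @return numeric vector of expected degrees, one per row of `nodes`.
#' @export
expected_degrees <- function(nodes, params) {
  x <- node_coords(nodes)
  p <- connection_prob_matrix(x, nodes$kappa, params)
  rowSums(p)
}

#' Sample a graph from node coordinates and latent degrees
#'
#' Every unordered pair is an independent Bernoulli edge with the S^D
#' connection probability. Returns an `sd_graph` holding the node table,
#' the edge list and (optionally) the full probability matrix.
#'
#' @param nodes node tibble with `id`, `x_*` coordinates and `kappa`.
#' @param params an `sd_model`.
#' @param seed optional integer seed.
#' @param keep_prob retain the N x N probability matrix (needed by
#'   [block_matrix()] on the probabilistic route).
#' @return an object of class `sd_graph`: list with `nodes` (tibble),
#'   `edges` (tibble of 0-based `from`/`to` id pairs, `from < to`),
#'   `prob` (matrix or NULL), `params`, `seed`.
#' @export
sample_graph <- function(nodes, params, seed = NULL, keep_prob = FALSE) {
  x <- node_coords(nodes)
  p <- connection_prob_matrix(x, nodes$kappa, params)
  if (!is.null(seed)) set.seed(seed)
  up <- upper.tri(p)
  hit <- up & (matrix(stats::runif(length(p)), nrow(p)) < p)
  idx <- which(hit, arr.ind = TRUE)
  edges <- tibble::tibble(from = nodes$id[idx[, 1]], to = nodes$id[idx[, 2]])
  structure(list(nodes = nodes, edges = edges,
                 prob = if (keep_prob) p else NULL,
                 params = params, seed = seed),
            class = "sd_graph")
}

#' @export
print.sd_graph <- function(x, ...) {
  cat(sprintf("S^%d random graph: %d nodes, %d edges (mean degree %.3f)\n",
              x$params$D, nrow(x$nodes), nrow(x$edges),
              2 * nrow(x$edges) / nrow(x$nodes)))
  invisible(x)
}

#' Generate a full S^D network in one call
#'
#' Pipeline wrapper: build parameters, sample angular coordinates (uniform,
#' or clustered into soft communities when `n_communities` is given), draw
#' or calibrate latent degrees, and sample the graph.
#'
#' With `n_communities = NULL`, latent degrees are i.i.d. Pareto and
#' `mu_hat` is calibrated analytically to `mean_degree`. With communities,
#' per-node Pareto *target* degrees are drawn and latent degrees are
#' optimized against them (see [calibrate_latent_degrees()]), since
#' clustered coordinates break the uniform-case calibration.
#'
#' @param N nodes; @param D dimension.
#' @param beta_over_d,gamma,mean_degree model parameters (see [sd_model()]);
#'   `mean_degree` doubles as the Pareto target-degree mean.
#' @param mean_kappa mean latent degree for the uniform variant.
#' @param n_communities,sigma soft-community count and angular dispersion
#'   in `[0, 1]` (see [sample_community_coords()]).
#' @param seed master seed; coordinate, degree and edge sub-streams are
#'   derived from it deterministically.
#' @param keep_prob retain the probability matrix on the result.
#' @param ... passed on to [calibrate_latent_degrees()] (e.g. `tolerance`).
#' @return an `sd_graph`; with communities the node table carries a
#'   `community` label column and the object records calibration
#'   diagnostics under `$calibration`.
#' @examples
#' g <- sample_sd_network(N = 150, D = 1, mean_degree = 4, seed = 7)
#' glance(g)
#' @export
sample_sd_network <- function(N, D, beta_over_d = 3.5, gamma = 2.5,
                              mean_degree = 4, mean_kappa = 10,
                              n_communities = NULL, sigma = NULL,
                              seed = NULL, keep_prob = FALSE, ...) {
  if (is.null(seed)) seed <- sample.int(2^31 - 2, 1)
  if (is.null(n_communities)) {
    params <- sd_model(D = D, N = N, beta_over_d = beta_over_d, gamma = gamma,
                       mean_kappa = mean_kappa, mean_degree = mean_degree)
    nodes <- sample_uniform_sphere(N, D, seed = derive_seed(seed, "coords"))
    nodes$kappa <- sample_latent_degrees(N, gamma, mean_kappa,
                                         seed = derive_seed(seed, "degrees"))
    g <- sample_graph(nodes, params, seed = derive_seed(seed, "edges"),
                      keep_prob = keep_prob)
  } else {
    stopifnot(!is.null(sigma))
    params <- sd_model(D = D, N = N, beta_over_d = beta_over_d, gamma = gamma,
                       mean_kappa = mean_degree, mean_degree = mean_degree)
    layout <- community_layout(n_communities, N, sigma, D,
                               seed = derive_seed(seed, "centroids"))
    nodes <- sample_community_coords(layout, D,
                                     seed = derive_seed(seed, "coords"))
    targets <- sample_latent_degrees(N, gamma, mean_degree,
                                     seed = derive_seed(seed, "targets"))
    calib <- calibrate_latent_degrees(nodes, targets, params,
                                      seed = derive_seed(seed, "calibration"),
                                      ...)
    nodes$kappa <- calib$kappa
    g <- sample_graph(nodes, params, seed = derive_seed(seed, "edges"),
                      keep_prob = keep_prob)
    g$calibration <- calib[c("converged", "residual", "iterations")]
    g$layout <- layout
  }
  g$seed <- seed
  g
}

# Deterministic sub-stream seeds below 2^31, derived from a master seed and
# a string key (documented: coords / degrees / targets / calibration / edges).
derive_seed <- function(seed, ...) {
  key <- paste(c(format(seed), ...), collapse = "/")
  h <- 0
  for (cc in utf8ToInt(key)) h <- (h * 31 + cc) %% 2147483647
  as.integer(h)
}
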