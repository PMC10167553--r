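# Soft angular communities on S^D: homogeneous centroid placement,
# dispersion-controlled cluster sampling, nearest-centroid labels, and
# latent-degree calibration against a target expected-degree sequence.

#' Place community centroids homogeneously on S^D
#'
#' `D = 1`: equally spaced angles `2*pi*u/n`. `D = 2`: Fibonacci-lattice
#' points (near-optimal spread). `D >= 3`: greedy max-min selection from
#' 10^4 uniform candidates under the given seed. Deterministic given
#' `(n, D, seed)`.
#'
#' @param n number of centroids (>= 1).
#' @param D sphere dimension.
#' @param seed integer seed (used for `D >= 3` only).
#' @return matrix of `n` unit row vectors in R^(D+1).
#' @export
place_centroids <- function(n, D, seed = NULL) {
  check_dimension(D)
  stopifnot(n >= 1)
  if (D == 1) {
    ang <- 2 * pi * (seq_len(n) - 1) / n
    return(cbind(cos(ang), sin(ang)))
  }
  if (D == 2) {
    i <- seq_len(n) - 1
    z <- 1 - (2 * i + 1) / n
    golden <- pi * (3 - sqrt(5))
    lon <- i * golden
    rho <- sqrt(pmax(0, 1 - z^2))
    return(cbind(z, rho * cos(lon), rho * sin(lon)))
  }
  if (!is.null(seed)) set.seed(seed)
  cand <- runif_sphere(10000L, D)
  chosen <- integer(n)
  chosen[1] <- 1L
  if (n > 1) {
    mind <- acos(clamp_unit(cand %*% cand[1, ]))
    for (k in 2:n) {
      chosen[k] <- which.max(mind)
      mind <- pmin(mind, acos(clamp_unit(cand %*% cand[chosen[k], ])))
    }
  }
  cand[chosen, , drop = FALSE]
}

#' Community layout: centroids plus near-even size allocation
#'
#' Splits `N` nodes as evenly as possible across `n` clusters (remainder
#' to the lowest-index clusters), matching the modeling assumption of
#' communities of similar, though not identical, sizes.
#'
#' @param n number of communities.
#' @param N total nodes.
#' @param sigma angular dispersion in `[0, 1]`.
#' @param D sphere dimension.
#' @param seed seed for centroid placement (`D >= 3`).
#' @return an object of class `community_layout`: list with `n`, `sigma`,
#'   `centroids` (matrix) and `sizes` (integer vector summing to `N`).
#' @export
community_layout <- function(n, N, sigma, D, seed = NULL) {
  stopifnot(n >= 1, N >= n, sigma >= 0, sigma <= 1)
  sizes <- rep(N %/% n, n)
  r <- N %% n
  if (r > 0) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  structure(list(n = n, sigma = sigma, D = check_dimension(D),
                 centroids = place_centroids(n, D, seed = seed),
                 sizes = as.integer(sizes)),
            class = "community_layout")
}

# von Mises-Fisher sampler on the sphere in R^p (Wood 1994 rejection scheme
# for the cosine component, uniform tangent direction). kappa_conc = 0 is
# uniform; very large kappa_conc approaches a point mass at `mu`.
rvmf <- function(n, mu, kappa_conc) {
  p <- length(mu)
  if (kappa_conc == 0) return(runif_sphere(n, p - 1L))
  b <- (-2 * kappa_conc + sqrt(4 * kappa_conc^2 + (p - 1)^2)) / (p - 1)
  x0 <- (1 - b) / (1 + b)
  c0 <- kappa_conc * x0 + (p - 1) * log(1 - x0^2)
  w <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    z <- stats::rbeta(m, (p - 1) / 2, (p - 1) / 2)
    ww <- (1 - (1 + b) * z) / (1 - (1 - b) * z)
    u <- stats::runif(m)
    ok <- kappa_conc * ww + (p - 1) * log1p(-x0 * ww) - c0 >= log(u)
    nok <- sum(ok)
    if (nok > 0) {
      w[(got + 1):(got + nok)] <- ww[ok]
      got <- got + nok
    }
  }
  v <- matrix(stats::rnorm(n * p), n, p)
  v <- v - outer(drop(v %*% mu), mu)          # project out mu
  v <- v / sqrt(rowSums(v^2))
  w * matrix(mu, n, p, byrow = TRUE) + sqrt(pmax(0, 1 - w^2)) * v
}

# Dispersion parameter sigma in [0, 1] -> vMF concentration. Endpoints:
# sigma = 0 is a point mass (handled upstream), sigma = 1 gives
# concentration 0, i.e. uniform sampling. The D factor keeps the angular
# spread ~ sigma/sqrt(D) * const at small sigma, comparable across
# dimensions like the standard deviation of a normal.
sigma_concentration <- function(sigma, D) {
  stopifnot(sigma >= 0, sigma <= 1)
  D * (1 / sigma^2 - 1)
}

#' Sample clustered angular coordinates
#'
#' Each node is drawn from a rotationally symmetric von Mises-Fisher
#' distribution centered on its cluster centroid, with concentration
#' `D * (1/sigma^2 - 1)`. At `sigma = 0` all nodes of a cluster sit exactly
#' on the centroid; at `sigma = 1` sampling is uniform on the sphere.
#'
#' @param layout a [community_layout()].
#' @param D sphere dimension (must match the layout).
#' @param seed optional integer seed.
#' @return node tibble (as [sample_uniform_sphere()]) with an extra
#'   `community` column: the *generating* cluster of each node, relabeled
#'   to the nearest centroid (see [assign_labels()]); a `cluster` column
#'   keeps the generating assignment.
#' @export
sample_community_coords <- function(layout, D = layout$D, seed = NULL) {
  stopifnot(inherits(layout, "community_layout"), D == layout$D)
  if (!is.null(seed)) set.seed(seed)
  sigma <- layout$sigma
  pieces <- vector("list", layout$n)
  for (k in seq_len(layout$n)) {
    nk <- layout$sizes[k]
    if (nk == 0L) next
    mu <- layout$centroids[k, ]
    pieces[[k]] <-
      if (sigma == 0) matrix(mu, nk, length(mu), byrow = TRUE)
      else rvmf(nk, mu, sigma_concentration(sigma, D))
  }
  x <- do.call(rbind, pieces)
  nodes <- sphere_tibble(x)
  nodes$cluster <- rep(seq_len(layout$n), layout$sizes)
  nodes$community <- assign_labels(nodes, layout$centroids)
  nodes
}

#' Label nodes by nearest centroid
#'
#' Each node gets the label of the angularly closest centroid; exact ties
#' break toward the lowest centroid index. After relabeling, communities
#' have no overlap but need not coincide with the generating clusters.
#'
#' @param points node tibble with `x_*` columns, or a matrix of unit row
#'   vectors.
#' @param centroids matrix of centroid unit row vectors.
#' @return integer vector of labels in `1..nrow(centroids)`.
#' @export
assign_labels <- function(points, centroids) {
  if (is.data.frame(points)) points <- node_coords(points)
  if (nrow(centroids) < 1) stop("no centroids given", call. = FALSE)
  sims <- points %*% t(centroids)          # max dot = min angular distance
  max.col(sims, ties.method = "first")
}

#' Calibrate latent degrees to a target expected-degree sequence
#'
#' With angular coordinates fixed (possibly clustered), finds latent
#' degrees `kappa` such that every node's expected degree matches its
#' target within an absolute tolerance. Iterative stochastic scheme: each
#' sweep updates `kappa_i <- |kappa_i + u_i * (k_i_target - E[k_i])|` with
#' `u_i` uniform on (0, 1), then recomputes all expected degrees; stops
#' when `max_i |E[k_i] - k_i_target| < tolerance` (default 0.2).
#'
#' The expected degrees are maintained incrementally: when node `i`'s
#' latent degree changes, only row/column `i` of the probability matrix is
#' recomputed, so a full sweep costs one pass over the matrix. Because the
#' expected degree scales like `kappa^(beta/D)` through saturating pairwise
#' probabilities, unrestricted steps can overshoot badly in clustered
#' configurations; each stochastic step is therefore capped at half the
#' node's current latent degree, only nodes still outside half the
#' tolerance are updated, and nodes that remain off target after
#' `stochastic_iter` sweeps are refined by an exact one-dimensional root
#' solve of their own expected-degree equation (Gauss-Seidel style, one
#' node at a time). Fixed points and the convergence criterion are those
#' of the plain stochastic scheme.
#'
#' @param nodes node tibble with `x_*` coordinates.
#' @param target_degrees positive target expected degrees, one per node.
#' @param params an `sd_model` (its `mu_hat` sets the overall scale; the
#'   kappas absorb any clustering-induced distortion).
#' @param tolerance absolute expected-degree tolerance (default 0.2).
#' @param max_iter maximum number of sweeps.
#' @param stochastic_iter sweeps of the stochastic scheme before root-solve
#'   refinement kicks in.
#' @param seed optional integer seed for the update stream.
#' @param on_failure `"error"` (default) or `"warn"`: what to do if the
#'   tolerance is not met within `max_iter` sweeps. The residual vector is
#'   attached to the error condition / returned object either way.
#' @return list with `kappa`, `expected` (final expected degrees),
#'   `residual` (max absolute deviation), `iterations`, `converged`.
#' @export
calibrate_latent_degrees <- function(nodes, target_degrees, params,
                                     tolerance = 0.2, max_iter = 500L,
                                     stochastic_iter = 50L, seed = NULL,
                                     on_failure = c("error", "warn")) {
  on_failure <- match.arg(on_failure)
  stopifnot(all(target_degrees > 0), nrow(nodes) == length(target_degrees),
            is.finite(params$beta))
  if (!is.null(seed)) set.seed(seed)
  x <- node_coords(nodes)
  A <- prob_kernel(pairwise_angles(x), params)
  expo <- params$beta / params$D
  kappa <- target_degrees                      # natural starting scale
  b <- kappa^expo
  P <- 1 / (1 + A / tcrossprod(b))
  ek <- rowSums(P)

  # refresh row/column i after a latent-degree change
  poke <- function(i, ki) {
    bi <- ki^expo
    pi_new <- 1 / (1 + A[i, ] / (bi * b))
    pi_new[i] <- 0
    ek <<- ek + (pi_new - P[i, ])
    ek[i] <<- sum(pi_new)
    P[i, ] <<- pi_new
    P[, i] <<- pi_new
    kappa[i] <<- ki
    b[i] <<- bi
  }

  res <- max(abs(ek - target_degrees))
  iter <- 0L
  while (res >= tolerance && iter < max_iter) {
    active <- which(abs(ek - target_degrees) > 0.5 * tolerance)
    for (i in active) {
      if (iter < stochastic_iter) {
        step <- stats::runif(1) * (target_degrees[i] - ek[i])
        step <- sign(step) * min(abs(step), 0.5 * kappa[i])
        poke(i, max(abs(kappa[i] + step), 1e-10))
      } else {
        # exact local solve: expected degree is monotone in own kappa
        Ai <- A[i, ]
        f <- function(lk) {
          p <- 1 / (1 + Ai / (exp(expo * lk) * b))
          p[i] <- 0
          sum(p) - target_degrees[i]
        }
        lk <- log(kappa[i])
        lo <- lk - 3; hi <- lk + 3
        while (f(lo) > 0 && lo > -30) lo <- lo - 3
        while (f(hi) < 0 && hi < 30) hi <- hi + 3
        if (f(lo) <= 0 && f(hi) >= 0) {
          poke(i, exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root))
        }
      }
    }
    res <- max(abs(ek - target_degrees))
    iter <- iter + 1L
  }
  out <- list(kappa = kappa, expected = ek, residual = res,
              iterations = iter, converged = res < tolerance)
  if (!out$converged) {
    msg <- sprintf(
      "latent-degree calibration did not reach tolerance %g in %d sweeps (residual %.3g)",
      tolerance, max_iter, res)
    if (on_failure == "error") {
      cond <- structure(class = c("sdcomm_calibration_error", "error",
                                  "condition"),
                        list(message = msg, call = sys.call(-1),
                             residuals = abs(ek - target_degrees)))
      stop(cond)
    }
    warning(msg, call. = FALSE)
  }
  out
}
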