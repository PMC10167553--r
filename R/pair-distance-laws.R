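# Analytic laws of the angular distance between connected nodes: conditional
# on the pair threshold eta, in the hard-threshold limit, and marginalized
# over the Pareto latent-degree distribution.

# Cache for Z(eta) normalizers, keyed on (eta, D, beta).
.z_cache <- new.env(parent = emptyenv())

# integral over [0, pi] of sin^(D-1)(theta) / (1 + (theta/eta)^beta).
# The integrand has a boundary layer at the threshold, so the domain is
# split there; each piece is handled well by adaptive quadrature.
threshold_integral <- function(eta, D, beta) {
  f <- function(t) sin(t)^(D - 1) / (1 + (t / eta)^beta)
  # geometric cut sequence from the threshold out: the tail decays like
  # (theta/eta)^(-beta), so each piece spans a bounded dynamic range
  cuts <- eta * 3^(0:max(0, ceiling(log(pi / eta) / log(3))))
  cuts <- unique(pmin(pi, c(0, cuts, pi)))
  cuts <- cuts[!duplicated(signif(cuts, 15))]
  total <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    total <- total + stats::integrate(
      f, cuts[i], cuts[i + 1L], rel.tol = 1e-10, abs.tol = 1e-14,
      subdivisions = 400L)$value
  }
  total
}

# Z(eta): cached normalizer of the connected-pair density.
z_normalizer <- function(eta, D, beta) {
  key <- paste(format(c(eta, D, beta), digits = 17), collapse = "|")
  hit <- .z_cache[[key]]
  if (!is.null(hit)) return(hit)
  val <- threshold_integral(eta, D, beta)
  .z_cache[[key]] <- val
  val
}

#' Density of the angular distance between a connected pair
#'
#' For two nodes with fixed threshold `eta`, conditional on their being
#' connected, the angular distance has density
#' `sin^(D-1)(theta) / (Z(eta) * (1 + (theta/eta)^beta))` on `[0, pi]`.
#' For `D = 1` this is proportional to the connection probability itself,
#' hence strictly decreasing with its maximum at `theta = 0`; for `D > 1`
#' it is unimodal with an interior mode that moves right as `D` grows
#' (see [pdf_mode()]).
#'
#' @param theta angle(s) in `[0, pi]`.
#' @param eta pair threshold (> 0).
#' @param D sphere dimension.
#' @param beta inverse temperature.
#' @return density value(s); the normalizer is computed by adaptive
#'   quadrature and cached per `(eta, D, beta)`.
#' @export
connected_pair_pdf <- function(theta, eta, D, beta) {
  check_dimension(D)
  if (eta <= 0) stop("`eta` must be positive", call. = FALSE)
  stopifnot(all(theta >= 0 & theta <= pi))
  sin(theta)^(D - 1) / (1 + (theta / eta)^beta) / z_normalizer(eta, D, beta)
}

#' Connection probability of a pair with threshold eta
#'
#' `f_{A|Y}(1|eta)`: the probability that a uniformly placed pair with
#' threshold `eta` is connected, i.e. the uniform pairwise-distance density
#' integrated against the connection probability.
#'
#' @param eta threshold(s) (> 0, vectorized).
#' @param D sphere dimension.
#' @param beta inverse temperature (`Inf` gives the cap fraction
#'   `Vol-fraction of the eta-ball`).
#' @return probability value(s) in `(0, 1]`.
#' @export
connection_prob_given_eta <- function(eta, D, beta) {
  check_dimension(D)
  stopifnot(all(eta > 0))
  ID <- sine_integral_constant(D)
  if (is.infinite(beta)) {
    return(sine_integral(pmin(eta, pi), D) / ID)
  }
  vapply(eta, function(e) threshold_integral(e, D, beta) / ID, numeric(1))
}

#' Mode of the connected-pair density
#'
#' For `D = 1` the density is strictly decreasing and the mode is 0. For
#' `D > 1` the mode `theta*` is the interior root of
#' `(D - 1) * ((eta/theta*)^beta + 1) = beta * tan(theta*) / theta*`,
#' solved by bracketed root finding on `(0, pi/2)`; a dense grid scan of the
#' density is the fallback if bracketing fails. When the threshold is small,
#' `theta* ~ eta * (beta/(D-1) - 1)^(-1/beta)` (requested with
#' `method = "approximate"`; requires `D > 1` and `beta > D - 1`).
#'
#' @param eta pair threshold (> 0).
#' @param D sphere dimension.
#' @param beta inverse temperature (finite).
#' @param method `"exact"` (root of the stationarity equation) or
#'   `"approximate"` (small-threshold closed form).
#' @return mode location in radians.
#' @export
pdf_mode <- function(eta, D, beta, method = c("exact", "approximate")) {
  method <- match.arg(method)
  check_dimension(D)
  stopifnot(eta > 0, beta > 0, is.finite(beta))
  if (method == "approximate") {
    if (D == 1 || beta <= D - 1) {
      stop("approximate mode requires `D > 1` and `beta > D - 1`",
           call. = FALSE)
    }
    return(eta * (beta / (D - 1) - 1)^(-1 / beta))
  }
  if (D == 1) return(0)
  crit <- function(th) (D - 1) * ((eta / th)^beta + 1) - beta * tan(th) / th
  root <- tryCatch(
    stats::uniroot(crit, c(1e-9, pi / 2 - 1e-9), tol = 1e-13)$root,
    error = function(e) NULL)
  if (!is.null(root)) return(root)
  grid <- seq(1e-7, pi - 1e-7, length.out = 200000L)
  grid[which.max(connected_pair_pdf(grid, eta, D, beta))]
}

#' Hard-threshold limit of the connected-pair density
#'
#' In the `beta -> Inf` limit the connection probability is a step at
#' `eta`, so the connected-pair density is `sin^(D-1)` truncated to
#' `[0, min(eta, pi)]` and renormalized. For small `eta` this is
#' `D * theta^(D-1) / eta^D` (the `small_eta` variant): constant on the
#' circle, but with a sharp maximum *at* the threshold for `D > 1`.
#'
#' @param theta angle(s); density is 0 beyond the threshold.
#' @param eta threshold in `(0, pi]`.
#' @param D sphere dimension.
#' @param small_eta use the small-threshold power-law form.
#' @return density value(s).
#' @export
hard_threshold_pdf <- function(theta, eta, D, small_eta = FALSE) {
  check_dimension(D)
  stopifnot(eta > 0, eta <= pi)
  if (any(theta > pi)) stop("`theta` must not exceed pi", call. = FALSE)
  inside <- theta >= 0 & theta < eta
  if (small_eta) {
    return(ifelse(inside, D * theta^(D - 1) / eta^D, 0))
  }
  ifelse(inside, sin(theta)^(D - 1) / sine_integral(eta, D), 0)
}

# Parameters of the eta marginal implied by Pareto latent degrees: with
# kappa, kappa' i.i.d. Pareto(gamma, kappa0) and
# eta = (mu_hat kappa kappa')^(1/D)/R_hat, the variable t = log(eta/eta0)
# is Gamma(shape 2, rate D*(gamma-1)) distributed (sum of two exponentials).
eta_law_params <- function(gamma, mean_kappa, mu_hat, R_hat, D) {
  stopifnot(gamma > 2)
  kappa0 <- mean_kappa * (gamma - 2) / (gamma - 1)
  list(eta0 = (mu_hat * kappa0^2)^(1 / D) / R_hat,
       rate = D * (gamma - 1))
}

#' Marginal density of the pairwise threshold eta
#'
#' With Pareto latent degrees, `log(eta/eta0)` for a random pair is the sum
#' of two independent exponentials, i.e. Gamma(shape 2, rate `D (gamma-1)`),
#' with `eta0 = (mu_hat kappa0^2)^(1/D) / R_hat` the smallest attainable
#' threshold. In `eta` itself the density is
#' `D^2 (gamma-1)^2 log(eta/eta0) (eta0/eta)^(D(gamma-1)) / eta` on
#' `[eta0, Inf)` and 0 below. Validated against Monte-Carlo histograms of
#' transformed Pareto pairs in the test suite.
#'
#' @param eta evaluation point(s).
#' @param gamma,mean_kappa Pareto latent-degree parameters.
#' @param mu_hat,R_hat connection scale and sphere radius.
#' @param D sphere dimension.
#' @return density value(s).
#' @export
eta_marginal_pdf <- function(eta, gamma, mean_kappa, mu_hat, R_hat, D) {
  lp <- eta_law_params(gamma, mean_kappa, mu_hat, R_hat, D)
  out <- numeric(length(eta))
  ok <- eta >= lp$eta0
  out[ok] <- stats::dgamma(log(eta[ok] / lp$eta0), shape = 2,
                           rate = lp$rate) / eta[ok]
  out
}

#' @rdname eta_marginal_pdf
#' @param q probability for the quantile function.
#' @export
eta_marginal_cdf <- function(eta, gamma, mean_kappa, mu_hat, R_hat, D) {
  lp <- eta_law_params(gamma, mean_kappa, mu_hat, R_hat, D)
  ifelse(eta < lp$eta0, 0,
         stats::pgamma(log(pmax(eta, lp$eta0) / lp$eta0), shape = 2,
                       rate = lp$rate))
}

#' @rdname eta_marginal_pdf
#' @export
eta_marginal_quantile <- function(q, gamma, mean_kappa, mu_hat, R_hat, D) {
  lp <- eta_law_params(gamma, mean_kappa, mu_hat, R_hat, D)
  lp$eta0 * exp(stats::qgamma(q, shape = 2, rate = lp$rate))
}

#' Marginal connection probability of a uniformly random pair
#'
#' `f_A(1)`: the probability that a random pair (uniform coordinates,
#' Pareto latent degrees) is connected — the eta marginal integrated
#' against the per-threshold connection probability. Multiplying by
#' `N - 1` gives the model's expected mean degree, which is what
#' [calibrate_mu_hat()] inverts. The quadrature integrates in the
#' Gamma-distributed variable `t = log(eta/eta0)` with the heavy tail
#' truncated at the `1 - 1e-8` quantile.
#'
#' @inheritParams eta_marginal_pdf
#' @param beta inverse temperature.
#' @return a probability in `(0, 1)`.
#' @export
edge_probability_marginal <- function(gamma, mean_kappa, mu_hat, R_hat, D,
                                      beta) {
  lp <- eta_law_params(gamma, mean_kappa, mu_hat, R_hat, D)
  t_max <- stats::qgamma(1 - 1e-8, shape = 2, rate = lp$rate)
  val <- stats::integrate(
    function(t) stats::dgamma(t, shape = 2, rate = lp$rate) *
      connection_prob_given_eta(lp$eta0 * exp(t), D, beta),
    0, t_max, rel.tol = 1e-8, abs.tol = 1e-10, subdivisions = 400L)
  if (val$message != "OK") {
    stop("marginal connection-probability quadrature failed: ", val$message,
         call. = FALSE)
  }
  val$value
}

#' Degree-marginalized density of the angular distance between connected nodes
#'
#' `f_{X|A}(theta|1)`: sample a graph from the model, pick an edge uniformly
#' at random — this is the density of the angular distance spanned by that
#' edge. Computed as
#' `f_X(theta) / f_A(1) * integral of f_Y(eta) / (1 + (theta/eta)^beta)`,
#' with the same Gamma substitution and `1 - 1e-8` tail truncation as
#' [edge_probability_marginal()]. The qualitative contrast of dimensions
#' lives here: mass piles up at `theta ~ 0` for `D = 1`, while for
#' `D >= 2` the mode detaches from zero.
#'
#' @param theta angle(s) in `[0, pi]`.
#' @inheritParams edge_probability_marginal
#' @return density value(s).
#' @export
marginal_connected_pdf <- function(theta, gamma, mean_kappa, mu_hat, R_hat,
                                   D, beta) {
  stopifnot(all(theta >= 0 & theta <= pi))
  lp <- eta_law_params(gamma, mean_kappa, mu_hat, R_hat, D)
  fa1 <- edge_probability_marginal(gamma, mean_kappa, mu_hat, R_hat, D, beta)
  t_max <- stats::qgamma(1 - 1e-8, shape = 2, rate = lp$rate)
  inner <- vapply(theta, function(th) {
    stats::integrate(
      function(t) stats::dgamma(t, shape = 2, rate = lp$rate) /
        (1 + (th / (lp$eta0 * exp(t)))^beta),
      0, t_max, rel.tol = 1e-8, abs.tol = 1e-12,
      subdivisions = 400L)$value
  }, numeric(1))
  uniform_pair_pdf(theta, D) * inner / fa1
}

#' Numeric CDF of a density on an interval
#'
#' Builds an interpolated distribution function from a vectorized density by
#' cumulative trapezoidal integration on a fine grid, normalized to end at 1.
#' Used to compare analytic laws against sampled distances (KS tests).
#'
#' @param pdf vectorized density function of one argument.
#' @param lower,upper support interval.
#' @param n grid size.
#' @return a function: the CDF.
#' @export
law_cdf <- function(pdf, lower, upper, n = 4096L) {
  grid <- seq(lower, upper, length.out = n)
  f <- pdf(grid)
  cum <- c(0, cumsum((f[-1] + f[-n]) / 2 * diff(grid)))
  cum <- cum / cum[n]
  stats::approxfun(grid, cum, yleft = 0, yright = 1, rule = 2)
}
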