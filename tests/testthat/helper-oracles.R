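# Shared oracles and fixtures, built in code.

# Pareto sampler (inverse CDF) used as an independent route to the
# package's latent-degree law.
rpareto <- function(n, gamma, kappa0) kappa0 * runif(n)^(-1 / (gamma - 1))

# Independent distances of disjoint random pairs among sampled points
# (keeps KS tests on i.i.d. observations).
disjoint_pair_distances <- function(x) {
  n <- nrow(x) - nrow(x) %% 2L
  i <- seq(1L, n, by = 2L)
  acos(pmin(pmax(rowSums(x[i, ] * x[i + 1L, ]), -1), 1))
}

# Reference quadrature for the incomplete sine integral, independent of the
# package's closed forms.
quad_sine_integral <- function(phi, D) {
  integrate(function(t) sin(t)^(D - 1), 0, phi, rel.tol = 1e-12)$value
}

# Small deterministic model used across tests.
tiny_params <- function(D = 1, N = 100, mu_hat = 0.02, ...) {
  sd_model(D = D, N = N, mu_hat = mu_hat, ...)
}
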