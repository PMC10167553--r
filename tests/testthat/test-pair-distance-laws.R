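test_that("connected-pair density is normalized and strictly decreasing on the circle", {
  for (D in 1:5) for (eta in c(0.01, 0.1, 1)) {
    total <- integrate(function(t) connected_pair_pdf(t, eta, D, 3.5 * D),
                       0, pi, rel.tol = 1e-9, subdivisions = 400L)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  th <- seq(0, pi, length.out = 2000)
  f1 <- connected_pair_pdf(th, 0.05, 1, 3.5)
  expect_true(all(diff(f1) < 0))
  expect_equal(th[which.max(f1)], 0)
  expect_error(connected_pair_pdf(0.1, -1, 2, 7), "eta")
})

test_that("per-threshold connection probability has the right limits", {
  expect_gt(connection_prob_given_eta(1e3, 2, 7), 0.999)
  expect_lt(connection_prob_given_eta(1e-6, 2, 7), 1e-3)
  # hard-threshold circle: eta / pi
  for (eta in c(0.3, 1, 2)) {
    expect_equal(connection_prob_given_eta(eta, 1, Inf), eta / pi,
                 tolerance = 1e-10)
  }
})

test_that("density mode: zero on the circle, interior and D-increasing above", {
  expect_equal(pdf_mode(0.05, 1, 3.5), 0)
  expect_equal(pdf_mode(0.9, 1, 7), 0)
  modes <- sapply(2:5, function(D) pdf_mode(0.02, D, 3.5 * D))
  expect_true(all(modes > 0))
  expect_true(all(diff(modes) > 0))   # increasing with dimension

  # the root matches a brute-force grid maximum of the density
  for (D in c(2, 3)) {
    grid <- seq(1e-6, pi - 1e-6, length.out = 200000)
    gm <- grid[which.max(connected_pair_pdf(grid, 0.05, D, 3.5 * D))]
    expect_equal(pdf_mode(0.05, D, 3.5 * D), gm, tolerance = 1e-4)
  }
})

test_that("small-threshold mode approximation tracks the exact root", {
  exact <- pdf_mode(0.01, 2, 7)
  approx <- pdf_mode(0.01, 2, 7, method = "approximate")
  expect_lt(abs(exact - approx) / exact, 0.02)
  expect_error(pdf_mode(0.01, 1, 7, method = "approximate"), "D > 1")
  expect_error(pdf_mode(0.01, 3, 1.5, method = "approximate"), "beta")
})

test_that("hard-threshold density is supported on [0, eta] with boundary maximum", {
  th <- seq(0, pi, length.out = 1000)
  f <- hard_threshold_pdf(th, 0.4, 3)
  expect_true(all(f[th > 0.4] == 0))
  expect_equal(sum(f[th >= 0.39 & th < 0.4] > 0), sum(th >= 0.39 & th < 0.4))
  inside <- th[th < 0.4 & th > 0]
  expect_equal(which.max(hard_threshold_pdf(inside, 0.4, 3)), length(inside))
  # D = 1 small-eta form is flat at 1/eta
  expect_equal(hard_threshold_pdf(c(0.1, 0.3), 0.4, 1, small_eta = TRUE),
               rep(2.5, 2))
  expect_equal(integrate(function(t) hard_threshold_pdf(t, 0.4, 3), 0, pi,
                         rel.tol = 1e-9)$value, 1, tolerance = 1e-6)
})

test_that("finite-beta density approaches the hard-threshold limit", {
  th <- seq(0, pi, length.out = 2001)
  f_soft <- connected_pair_pdf(th, 0.1, 2, 1e4)
  f_hard <- hard_threshold_pdf(th, 0.1, 2)
  away <- abs(th - 0.1) > 0.02
  expect_lt(max(abs(f_soft[away] - f_hard[away])), 0.05)
})

test_that("eta marginal matches its Monte-Carlo oracle and support bound", {
  gamma <- 2.5; kbar <- 10; D <- 2
  params <- sd_model(D = D, N = 1000, gamma = gamma, mean_kappa = kbar,
                     mu_hat = 0.05)
  kappa0 <- kbar * (gamma - 2) / (gamma - 1)
  eta0 <- (params$mu_hat * kappa0^2)^(1 / D) / params$R_hat
  expect_equal(eta_marginal_pdf(eta0 * 0.999, gamma, kbar, params$mu_hat,
                                params$R_hat, D), 0)
  total <- integrate(function(e) eta_marginal_pdf(e, gamma, kbar,
                                                  params$mu_hat,
                                                  params$R_hat, D),
                     eta0, eta_marginal_quantile(1 - 1e-10, gamma, kbar,
                                                 params$mu_hat,
                                                 params$R_hat, D),
                     rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)

  set.seed(61)
  k1 <- rpareto(1e5, gamma, kappa0)
  k2 <- rpareto(1e5, gamma, kappa0)
  eta_mc <- (params$mu_hat * k1 * k2)^(1 / D) / params$R_hat
  expect_gte(min(eta_mc), eta0)
  ks <- suppressWarnings(ks.test(eta_mc, function(q)
    eta_marginal_cdf(q, gamma, kbar, params$mu_hat, params$R_hat, D)))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("marginal connection probability is bounded, monotone and degree-consistent", {
  R <- sphere_radius_for_unit_density(1000, 2)
  f1 <- edge_probability_marginal(2.5, 10, 0.01, R, 2, 7)
  f2 <- edge_probability_marginal(2.5, 10, 0.02, R, 2, 7)
  expect_gt(f1, 0); expect_lt(f1, 1)
  expect_gt(f2, f1)

  # (N - 1) f_A(1) vs empirical mean degree over seeds
  deg <- sapply(1:10, function(s) {
    g <- sample_sd_network(N = 1000, D = 2, mean_degree = 4, seed = 700 + s)
    glance(g)$mean_degree
  })
  expect_lt(abs(mean(deg) - 4), 3 * sd(deg) / sqrt(10))
})

test_that("degree-marginalized connected-pair density: normalization and D contrast", {
  for (D in 1:2) {
    params <- sd_model(D = D, N = 1000, gamma = 2.5, mean_kappa = 10,
                       mean_degree = 10)
    total <- integrate(function(t) marginal_connected_pdf(
      t, 2.5, 10, params$mu_hat, params$R_hat, D, params$beta),
      0, pi, rel.tol = 1e-7, subdivisions = 400L)$value
    expect_equal(total, 1, tolerance = 1e-5)
  }
  p1 <- sd_model(D = 1, N = 1000, gamma = 2.5, mean_kappa = 10,
                 mean_degree = 10)
  p2 <- sd_model(D = 2, N = 1000, gamma = 2.5, mean_kappa = 10,
                 mean_degree = 10)
  d1 <- marginal_connected_pdf(0.01, 2.5, 10, p1$mu_hat, p1$R_hat, 1, p1$beta)
  d2 <- marginal_connected_pdf(0.01, 2.5, 10, p2$mu_hat, p2$R_hat, 2, p2$beta)
  expect_gt(d1, d2)   # connected pairs concentrate at tiny angles on the circle
})

test_that("per-edge angular distances from sampled graphs follow the marginal law", {
  params <- sd_model(D = 2, N = 1000, gamma = 2.5, mean_kappa = 10,
                     mean_degree = 4)
  set.seed(77)
  pooled <- unlist(lapply(1:10, function(s) {
    g <- sample_sd_network(N = 1000, D = 2, mean_degree = 4, mean_kappa = 10,
                           seed = 900 + s)
    x <- node_coords(g$nodes)
    i <- match(g$edges$from, g$nodes$id)
    j <- match(g$edges$to, g$nodes$id)
    acos(pmin(pmax(rowSums(x[i, ] * x[j, ]), -1), 1))
  }))
  cdf <- law_cdf(function(t) marginal_connected_pdf(
    t, 2.5, 10, params$mu_hat, params$R_hat, 2, params$beta), 0, pi,
    n = 2048)
  ks <- suppressWarnings(ks.test(pooled, cdf))
  expect_lt(unname(ks$statistic), 0.03)
})
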