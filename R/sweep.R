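# Orchestration of the sigma-sweep experiment (community structure vs
# angular dispersion, across dimensions) and tabulation of the analytic
# curves.

#' Sweep configuration
#'
#' Grid of experimental conditions for the dispersion sweep: for every
#' combination of dimension, community count, dispersion `sigma` and
#' replicate seed, a clustered network is generated, its latent degrees are
#' calibrated, and block-matrix diagnostics are recorded.
#'
#' @param dimensions similarity dimensions to compare (default `c(1, 2)`).
#' @param community_counts numbers of communities (default `c(5, 15, 25)`).
#' @param sigma_grid dispersions in `[0, 1]`.
#' @param replicates seeds per grid cell (>= 1).
#' @param N nodes per network.
#' @param beta_over_d,gamma,mean_degree model parameters; defaults match
#'   the headline study conditions (`beta/D = 3.5`, Pareto expected degrees
#'   with mean 4.0 and exponent 2.5).
#' @param tolerance,max_iter latent-degree calibration controls.
#' @return a `sweep_config` list.
#' @export
sweep_config <- function(dimensions = c(1, 2),
                         community_counts = c(5, 15, 25),
                         sigma_grid = seq(0.1, 0.9, by = 0.1),
                         replicates = 10L,
                         N = 1000L, beta_over_d = 3.5, gamma = 2.5,
                         mean_degree = 4.0, tolerance = 0.2,
                         max_iter = 500L) {
  stopifnot(length(dimensions) > 0, length(community_counts) > 0,
            length(sigma_grid) > 0, replicates >= 1,
            all(sigma_grid >= 0 & sigma_grid <= 1), beta_over_d > 1)
  structure(list(dimensions = dimensions,
                 community_counts = community_counts,
                 sigma_grid = sigma_grid, replicates = as.integer(replicates),
                 N = as.integer(N), beta_over_d = beta_over_d, gamma = gamma,
                 mean_degree = mean_degree, tolerance = tolerance,
                 max_iter = as.integer(max_iter)),
            class = "sweep_config")
}

#' Run the dispersion sweep
#'
#' For each cell `(D, n, sigma, replicate)`: place centroids, sample
#' clustered coordinates, relabel to nearest centroids, draw Pareto target
#' degrees, calibrate latent degrees (absolute tolerance, default 0.2),
#' build the connection-probability matrix, coarse-grain it into a block
#' matrix, and record diagnostics. Calibration failures are recorded (with
#' `NA` metrics) rather than aborting the sweep. The whole sweep is a pure
#' function of `(config, seed)`.
#'
#' @param config a [sweep_config()].
#' @param seed master seed; every cell derives its own sub-streams.
#' @param verbose print per-cell progress.
#' @return long-format tibble, one row per cell and replicate: the grid
#'   coordinates, calibration diagnostics (`converged`, `residual`,
#'   `iterations`), realized `m`, and the block metrics.
#' @export
run_sigma_sweep <- function(config, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  grid <- tidyr::expand_grid(D = config$dimensions,
                             n_communities = config$community_counts,
                             sigma = config$sigma_grid,
                             replicate = seq_len(config$replicates))
  mu_cache <- new.env(parent = emptyenv())
  rows <- purrr::pmap(grid, function(D, n_communities, sigma, replicate) {
    key <- paste0("D", D)
    params <- mu_cache[[key]]
    if (is.null(params)) {
      params <- sd_model(D = D, N = config$N,
                         beta_over_d = config$beta_over_d,
                         gamma = config$gamma,
                         mean_kappa = config$mean_degree,
                         mean_degree = config$mean_degree)
      mu_cache[[key]] <- params
    }
    cell_seed <- derive_seed(seed, "cell", D, n_communities,
                             format(sigma), replicate)
    if (verbose) {
      message(sprintf("cell D=%d n=%d sigma=%.2f rep=%d", D, n_communities,
                      sigma, replicate))
    }
    layout <- community_layout(n_communities, config$N, sigma, D,
                               seed = derive_seed(cell_seed, "centroids"))
    nodes <- sample_community_coords(layout, D,
                                     seed = derive_seed(cell_seed, "coords"))
    targets <- sample_latent_degrees(config$N, config$gamma,
                                     config$mean_degree,
                                     seed = derive_seed(cell_seed, "targets"))
    calib <- calibrate_latent_degrees(
      nodes, targets, params, tolerance = config$tolerance,
      max_iter = config$max_iter,
      seed = derive_seed(cell_seed, "calibration"), on_failure = "warn")
    base <- tibble::tibble(D = D, n_communities = n_communities,
                           sigma = sigma, replicate = replicate,
                           seed = cell_seed,
                           converged = calib$converged,
                           residual = calib$residual,
                           iterations = calib$iterations)
    if (!calib$converged) {
      return(dplyr::bind_cols(base, tibble::tibble(
        n = n_communities, m = NA_real_, stable_rank = NA_real_,
        srank_ratio = NA_real_, entropy_bits = NA_real_,
        avg_community_degree = NA_real_,
        community_degrees = list(NULL))))
    }
    p <- connection_prob_matrix(node_coords(nodes), calib$kappa, params)
    blk <- block_matrix(p, nodes$community, n = n_communities)
    dplyr::bind_cols(base, block_metrics(blk))
  })
  dplyr::bind_rows(rows)
}

#' Tabulate the analytic curves
#'
#' Dense tables of the package's analytic laws across dimensions, ready
#' for plotting: the uniform pairwise-distance density, the connected-pair
#' density at fixed latent degrees, its degree-marginalized version, the
#' hard-threshold limit, and the nearest-neighbor count against the number
#' of points.
#'
#' @param kind one of `"uniform"`, `"conditional"`, `"marginal"`, `"hard"`,
#'   `"nnn"`.
#' @param dimensions dimensions to tabulate (default `1:5`).
#' @param grid number of abscissa points.
#' @param N,beta_over_d,gamma,mean_kappa,kappa model parameters used where
#'   the kind needs them (`kappa` is the fixed latent degree of both nodes
#'   for `"conditional"`; `mean_kappa` feeds the Pareto law and the
#'   `mean-degree` scale for `"marginal"`; `mu_hat` is calibrated per
#'   dimension so dimensions are compared at equal expected degree).
#' @param eta fixed threshold for `"hard"`.
#' @param n_range range of point counts for `"nnn"` (log-spaced grid).
#' @return long tibble: `kind`, `D`, abscissa (`theta` or `n`), `value`.
#' @export
tabulate_analytic_curves <- function(kind = c("uniform", "conditional",
                                              "marginal", "hard", "nnn"),
                                     dimensions = 1:5, grid = 512L,
                                     N = 1000L, beta_over_d = 3.5,
                                     gamma = 2.5, mean_kappa = 10,
                                     kappa = 10, eta = 0.1,
                                     n_range = c(3, 1e6)) {
  kind <- match.arg(kind)
  if (kind == "nnn") {
    n <- unique(round(10^seq(log10(n_range[1]), log10(n_range[2]),
                             length.out = grid)))
    n <- n[n > 2]
    return(dplyr::bind_rows(lapply(dimensions, function(D) {
      dplyr::mutate(nearest_neighbor_count(n, D), kind = "nnn",
                    value = .data$nnn, .keep = "unused")
    })))
  }
  theta <- seq(1e-4, pi - 1e-4, length.out = grid)
  rows <- lapply(dimensions, function(D) {
    value <- switch(
      kind,
      uniform = uniform_pair_pdf(theta, D),
      conditional = {
        params <- sd_model(D = D, N = N, beta_over_d = beta_over_d,
                           gamma = gamma, mean_kappa = mean_kappa,
                           mean_degree = mean_kappa)
        e <- eta_threshold(kappa, kappa, params$mu_hat, params$R_hat, D)
        connected_pair_pdf(theta, e, D, params$beta)
      },
      marginal = {
        params <- sd_model(D = D, N = N, beta_over_d = beta_over_d,
                           gamma = gamma, mean_kappa = mean_kappa,
                           mean_degree = mean_kappa)
        marginal_connected_pdf(theta, gamma, mean_kappa, params$mu_hat,
                               params$R_hat, D, params$beta)
      },
      hard = hard_threshold_pdf(theta, eta, D))
    tibble::tibble(kind = kind, D = D, theta = theta, value = value)
  })
  dplyr::bind_rows(rows)
}
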