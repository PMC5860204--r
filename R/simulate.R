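# In-silico benchmark generator: signed random networks and a stochastic
# differential equation model of single-cell mRNA dynamics, sampled with
# lysis semantics (each simulated cell contributes its state at exactly
# one time point).

#' Simulation configuration
#'
#' Kinetics of the mRNA SDE benchmark model (see [drift]):
#' `dx_j = V [beta * prod_i (1 + A_ij x_i/(x_i+1)) - theta x_j] dt +
#' sigma x_j dW`. Defaults are the reference parameterization: V = 30
#' (kinetic pace scaling), beta = 1 (basal transcription), theta = 0.2
#' (degradation rate constant), sigma = 0.1 (multiplicative noise
#' scale), integrated by Euler-Maruyama from x(0) = 0 until steady state
#' at t = 3 time units, sampling 100 cells at each of 8 unevenly spaced
#' time points.
#'
#' @param V transcription scaling (> 0).
#' @param beta basal transcription rate (> 0).
#' @param theta mRNA degradation rate constant (> 0).
#' @param sigma intrinsic noise scale (>= 0).
#' @param dt Euler-Maruyama step; must not exceed a tenth of the smallest
#'   time-point spacing.
#' @param t_burn time to steady state; all sampling times must lie in
#'   (0, t_burn].
#' @param time_points strictly increasing sampling times.
#' @param cells_per_time cells (independent trajectories) per time point.
#' @param seed integer RNG seed; the dataset is a deterministic function
#'   of config + seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(V = 30, beta = 1, theta = 0.2, sigma = 0.1,
                              dt = 0.005, t_burn = 3,
                              time_points = main_design_times(),
                              cells_per_time = 100L, seed = 1L) {
  if (V <= 0 || beta <= 0 || theta <= 0 || sigma < 0 || dt <= 0 ||
      t_burn <= 0)
    snap_error("kinetic parameters must be positive (sigma >= 0)",
               "snapgrn_bad_config")
  time_points <- as.numeric(time_points)
  if (length(time_points) < 1L || any(diff(time_points) <= 0))
    snap_error("time points must be strictly increasing",
               "snapgrn_nonincreasing_times")
  if (any(time_points <= 0) || any(time_points > t_burn))
    snap_error("time points must lie in (0, t_burn]", "snapgrn_bad_config")
  min_gap <- min(diff(c(0, time_points)))
  if (dt > min_gap / 10)
    snap_error(sprintf("dt too large: must be <= %.4g (min spacing / 10)",
                       min_gap / 10), "snapgrn_bad_config")
  cells_per_time <- as.integer(cells_per_time)
  if (cells_per_time < 1L)
    snap_error("cells_per_time must be >= 1", "snapgrn_bad_config")
  structure(list(V = V, beta = beta, theta = theta, sigma = sigma, dt = dt,
                 t_burn = t_burn, time_points = time_points,
                 cells_per_time = cells_per_time, seed = as.integer(seed)),
            class = "simulation_config")
}

# The 10-point reference sampling grid; chosen past the initial transient
# so distances reflect regulation rather than the rise from x(0) = 0.
.reference_times <- c(0.51, 0.60, 0.74, 1.2, 1.3, 1.5, 1.8, 2.2, 2.6, 3)

#' @rdname simulation_config
#' @export
main_design_times <- function() .reference_times[1:8]

#' Sample a random signed network
#'
#' Uniformly samples `n_edges` distinct ordered non-self pairs; each edge
#' is activating with probability `activation_fraction`, else repressing.
#' When `n_edges >= m - 1`, a random spanning arborescence is laid down
#' first so that every gene except the root has at least one regulator
#' and is reachable from the root -- targets then actually respond to the
#' dynamics instead of sitting at their basal steady state.
#'
#' @param m number of genes.
#' @param n_edges number of edges, in `[0, m(m-1)]`.
#' @param activation_fraction probability that an edge is activating.
#' @param seed RNG seed; the network is deterministic given the seed.
#' @param gene_names optional identifiers (default `G1 ... Gm`).
#' @return A [gene_network].
#' @export
sample_random_network <- function(m, n_edges, activation_fraction = 0.5,
                                  seed = 1L, gene_names = NULL) {
  m <- as.integer(m)
  n_edges <- as.integer(n_edges)
  if (m < 2L) snap_error("need at least two genes", "snapgrn_too_few_genes")
  if (n_edges < 0L || n_edges > m * (m - 1L))
    snap_error(sprintf("n_edges must be in [0, %d]", m * (m - 1L)),
               "snapgrn_bad_config")
  if (activation_fraction < 0 || activation_fraction > 1)
    snap_error("activation_fraction must be in [0, 1]", "snapgrn_bad_config")
  if (is.null(gene_names)) gene_names <- sprintf("G%d", seq_len(m))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  edges <- matrix(integer(0), 0L, 2L)
  if (n_edges >= m - 1L && m >= 2L) {
    ord <- sample.int(m)  # ord[1] is the root
    parent <- vapply(2:m, function(k) ord[sample.int(k - 1L, 1L)], 0L)
    edges <- cbind(parent, ord[2:m])
  }
  need <- n_edges - nrow(edges)
  if (need > 0L) {
    all_pairs <- which(diag(m) == 0, arr.ind = TRUE)
    used <- paste(edges[, 1L], edges[, 2L])
    free <- which(!(paste(all_pairs[, 1L], all_pairs[, 2L]) %in% used))
    pick <- free[sample.int(length(free), need)]
    edges <- rbind(edges, all_pairs[pick, , drop = FALSE])
  }
  A <- matrix(0L, m, m)
  if (nrow(edges) > 0L)
    A[edges] <- ifelse(stats::runif(nrow(edges)) < activation_fraction,
                       1L, -1L)
  gene_network(gene_names, A)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Drift of the mRNA SDE model
#'
#' `drift_j = V * (beta * prod over regulators i of
#' (1 + A_ij * x_i / (x_i + 1)) - theta * x_j)`; an empty product is 1.
#' The saturating term `x/(x+1)` doubles production at full activation
#' and silences it at full repression. V scales the whole deterministic
#' dynamics, i.e. it sets the pace of the kinetics without changing the
#' steady states: an unregulated gene has drift `V * beta` at the origin,
#' relaxes at rate `V * theta` and settles at `beta / theta`. With the
#' default parameters (V = 30, beta = 1, theta = 0.2) the relaxation rate
#' is 6 inverse time units, so expression reaches steady state well
#' within the simulated horizon of 3 time units, and the basal rise from
#' `x(0) = 0` is essentially complete before the first reference sampling
#' time (0.51).
#'
#' @param x non-negative state vector (one entry per gene), or a cells x
#'   genes matrix to evaluate many cells at once.
#' @param network a [gene_network].
#' @param config a [simulation_config] (only V, beta, theta are used).
#' @return Drift with the same shape as `x`.
#' @export
drift <- function(x, network, config) {
  stopifnot(inherits(network, "gene_network"),
            inherits(config, "simulation_config"))
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, 1L) else as.matrix(x)
  if (any(X < 0))
    snap_error("negative state in drift evaluation", "snapgrn_negative_values")
  D <- .drift_matrix(X, network$adjacency, config)
  if (vec) drop(D) else D
}

.drift_matrix <- function(X, A, config) {
  m <- ncol(A)
  H <- X / (X + 1)
  P <- matrix(config$beta, nrow(X), m)
  reg <- which(A != 0L, arr.ind = TRUE)
  for (e in seq_len(nrow(reg))) {
    i <- reg[e, 1L]; j <- reg[e, 2L]
    P[, j] <- P[, j] * (1 + A[i, j] * H[, i])
  }
  config$V * (P - config$theta * X)
}

#' Simulate time-stamped single-cell snapshots
#'
#' For each sampling time point, `cells_per_time` independent trajectories
#' are integrated by Euler-Maruyama from `x(0) = 0` with multiplicative
#' noise `sigma * x * dW`; each trajectory contributes its state at its
#' own time point only, mimicking cell lysis (no cell is observed twice).
#' Euler steps can overshoot below zero; states are clamped at 0 after
#' each step, restoring the non-negative support of the exact process
#' (whose noise vanishes at 0).
#'
#' The integration uses one RNG substream per time point (derived from
#' the seed), so the dataset is bit-reproducible and per-time-point
#' ensembles are exchangeable.
#'
#' @param network a [gene_network].
#' @param config a [simulation_config].
#' @return A [timestamped_dataset] with `length(time_points)` snapshots of
#'   `cells_per_time` cells each.
#' @export
simulate_cells <- function(network, config = simulation_config()) {
  stopifnot(inherits(network, "gene_network"),
            inherits(config, "simulation_config"))
  m <- length(network$gene_names)
  A <- network$adjacency
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(config$seed)
  substreams <- sample.int(.Machine$integer.max - 1L,
                           length(config$time_points))
  sqdt <- sqrt(config$dt)
  snaps <- vector("list", length(config$time_points))
  for (k in seq_along(config$time_points)) {
    set.seed(substreams[k])
    n_steps <- round(config$time_points[k] / config$dt)
    X <- matrix(0, config$cells_per_time, m)
    for (s in seq_len(n_steps)) {
      D <- .drift_matrix(X, A, config)
      X <- X + D * config$dt
      if (config$sigma > 0) {
        Z <- matrix(stats::rnorm(length(X)), nrow(X), m)
        X <- X + config$sigma * X * sqdt * Z
      }
      X[X < 0] <- 0
    }
    colnames(X) <- network$gene_names
    snaps[[k]] <- X
  }
  timestamped_dataset(snaps, config$time_points,
                      gene_names = network$gene_names,
                      source_label = sprintf(
                        "sde-sim m=%d sigma=%.3g seed=%d", m, config$sigma,
                        config$seed))
}

#' Benchmark experimental designs
#'
#' Families of simulation configurations used by the in-silico benchmark:
#' * `"MAIN"`: 8 time points (the first 8 of the reference 10-point grid),
#'   100 cells per time point, sigma = 0.1;
#' * `"NOISE_SWEEP"`: the main design at sigma = 0.1, 0.2, 0.3, 0.4;
#' * `"TIMEPOINT_SWEEP"`: sigma = 0.1 with the first n = 6 ... 10 points
#'   of the reference grid.
#'
#' @param name design family name.
#' @param seed seed stored in every returned config.
#' @param cells_per_time cells per time point.
#' @return Named list of [simulation_config] objects.
#' @export
benchmark_design <- function(name = c("MAIN", "NOISE_SWEEP",
                                      "TIMEPOINT_SWEEP"),
                             seed = 1L, cells_per_time = 100L) {
  name <- match.arg(name)
  switch(name,
    MAIN = list(main = simulation_config(
      time_points = main_design_times(), cells_per_time = cells_per_time,
      seed = seed)),
    NOISE_SWEEP = setNames(lapply(c(0.1, 0.2, 0.3, 0.4), function(s)
      simulation_config(sigma = s, time_points = main_design_times(),
                        cells_per_time = cells_per_time, seed = seed)),
      paste0("sigma_", c(0.1, 0.2, 0.3, 0.4))),
    TIMEPOINT_SWEEP = setNames(lapply(6:10, function(n)
      simulation_config(time_points = .reference_times[seq_len(n)],
                        cells_per_time = cells_per_time, seed = seed)),
      paste0("n_", 6:10)))
}
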