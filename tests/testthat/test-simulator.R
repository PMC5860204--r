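test_that("random network sampler is reproducible and well-formed", {
  expect_equal(sum(sample_random_network(10, 0, seed = 1)$adjacency != 0), 0L)

  n1 <- sample_random_network(10, 15, seed = 1)
  n2 <- sample_random_network(10, 15, seed = 1)
  expect_identical(n1$adjacency, n2$adjacency)
  expect_equal(sum(n1$adjacency != 0), 15L)
  expect_true(all(diag(n1$adjacency) == 0))
  expect_false(identical(n1$adjacency,
                         sample_random_network(10, 15, seed = 2)$adjacency))

  # with n_edges >= m-1 every gene except the root has a regulator
  for (s in 1:5) {
    net <- sample_random_network(8, 10, seed = s)
    expect_lte(sum(colSums(net$adjacency != 0) == 0), 1L)
  }
  n20 <- sample_random_network(20, 30, seed = 4)
  expect_equal(length(n20$gene_names), 20L)

  expect_error(sample_random_network(5, 21, seed = 1),
               class = "snapgrn_bad_config")
  # all-activating / all-repressing extremes
  expect_true(all(sample_random_network(6, 8, 1, seed = 3)$adjacency >= 0))
  expect_true(all(sample_random_network(6, 8, 0, seed = 3)$adjacency <= 0))
})

test_that("drift follows the regulated kinetics", {
  cfg <- simulation_config(seed = 1)
  m <- 3
  A <- matrix(0, m, m); A[1, 2] <- 1; A[3, 2] <- -1
  net <- gene_network(paste0("g", 1:m), A)

  # at the origin every gene transcribes at the basal rate V * beta = 30
  expect_equal(drift(rep(0, m), net, cfg), rep(30, m))

  # unregulated fixed point: beta / theta
  xeq <- cfg$beta / cfg$theta
  expect_equal(drift(c(xeq, 0, 0), net, cfg)[1], 0)

  # repressor at saturation silences production: drift -> -V * theta * x
  x <- c(0, 2, 1e9)
  expect_equal(drift(x, net, cfg)[2], -cfg$V * cfg$theta * 2,
               tolerance = 1e-6)

  # matrix form agrees with the vector form row by row
  X <- matrix(runif(6, 0, 5), 2, m)
  D <- drift(X, net, cfg)
  expect_equal(D[1, ], drift(X[1, ], net, cfg))
  expect_error(drift(c(-1, 0, 0), net, cfg),
               class = "snapgrn_negative_values")
})

test_that("simulation configs validate timing and kinetics", {
  expect_error(simulation_config(theta = 0), class = "snapgrn_bad_config")
  expect_error(simulation_config(time_points = c(1, 0.5)),
               class = "snapgrn_nonincreasing_times")
  expect_error(simulation_config(time_points = c(1, 4)),  # beyond t_burn
               class = "snapgrn_bad_config")
  expect_error(simulation_config(dt = 0.05),  # > min spacing / 10
               class = "snapgrn_bad_config")
  expect_equal(length(main_design_times()), 8L)
})

test_that("noise-free simulation matches an independent ODE oracle", {
  skip_if_not_installed("deSolve")
  net <- sample_random_network(4, 6, seed = 2)
  cfg <- simulation_config(sigma = 0, dt = 0.001, cells_per_time = 2,
                           time_points = c(0.51, 1.2, 2.2, 3), seed = 1)
  d <- simulate_cells(net, cfg)
  # all cells of a time point are identical when sigma = 0
  for (s in d$snapshots) expect_lt(max(abs(s[1, ] - s[2, ])), 1e-9)

  sol <- deSolve::ode(
    y = rep(0, 4), times = c(0, cfg$time_points),
    func = function(t, y, p) list(drift(pmax(y, 0), net, cfg)),
    method = "lsoda", rtol = 1e-8, atol = 1e-10)
  for (k in seq_along(cfg$time_points)) {
    ref <- sol[k + 1, -1]
    # first-order Euler at dt = 0.001: sub-percent agreement, with an
    # absolute floor for strongly repressed genes near zero
    expect_lt(max(abs(d$snapshots[[k]][1, ] - ref) / pmax(abs(ref), 0.5)),
              0.01)
  }

  # an unregulated gene has settled at beta/theta by t = 3
  empty <- gene_network(c("a", "b"))
  d2 <- simulate_cells(empty, simulation_config(
    sigma = 0, dt = 0.002, cells_per_time = 2, time_points = 3, seed = 1))
  expect_equal(unname(d2$snapshots[[1]][1, ]), rep(5, 2), tolerance = 1e-3)
})

test_that("stochastic ensembles are reproducible, non-negative and unbiased", {
  net <- sample_random_network(5, 7, seed = 6)
  cfg <- simulation_config(cells_per_time = 30, seed = 123)
  d1 <- simulate_cells(net, cfg)
  d2 <- simulate_cells(net, cfg)
  for (k in seq_along(d1$snapshots))
    expect_identical(d1$snapshots[[k]], d2$snapshots[[k]])
  expect_true(all(vapply(d1$snapshots, function(s) all(s >= 0), TRUE)))
  expect_equal(n_cells(d1), rep(30L, 8))

  # weak-noise ensemble mean of an unregulated gene ~ beta/theta at t = 3
  empty <- gene_network(c("a", "b"))
  dm <- simulate_cells(empty, simulation_config(
    sigma = 0.01, cells_per_time = 1000, time_points = 3, seed = 99))
  expect_equal(mean(dm$snapshots[[1]][, 1]), 5, tolerance = 0.02 * 5)
})

test_that("benchmark designs enumerate the published sweeps", {
  main <- benchmark_design("MAIN")
  expect_length(main, 1L)
  expect_equal(main$main$time_points, main_design_times())
  expect_equal(main$main$sigma, 0.1)
  expect_equal(main$main$cells_per_time, 100L)

  ns <- benchmark_design("NOISE_SWEEP")
  expect_length(ns, 4L)
  expect_equal(vapply(ns, `[[`, 0, "sigma"), c(0.1, 0.2, 0.3, 0.4),
               ignore_attr = TRUE)

  ts <- benchmark_design("TIMEPOINT_SWEEP")
  expect_length(ts, 5L)
  expect_equal(vapply(ts, function(c) length(c$time_points), 0L),
               6:10, ignore_attr = TRUE)
  expect_equal(max(ts$n_10$time_points), 3)
  expect_error(benchmark_design("BOGUS"))
})
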