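test_that("regression problems have the lagged Granger shape", {
  set.seed(2)
  # n = 8 time points -> 7 windows -> X is 6 x m, y length 6
  p8 <- profile_from_matrix(matrix(runif(7 * 4), 7, 4))
  pr <- build_problem(p8, 2)
  expect_equal(dim(pr$X), c(6L, 4L))
  expect_length(pr$y, 6L)
  expect_equal(pr$y, p8$normalized[2:7, 2], ignore_attr = TRUE)
  expect_equal(pr$X, p8$normalized[1:6, ], ignore_attr = TRUE)

  # n = 5 -> exactly the minimal 3 equations
  p5 <- profile_from_matrix(matrix(runif(4 * 3), 4, 3))
  expect_equal(nrow(build_problem(p5, 1)$X), 3L)

  # n = 4 is rejected with the five-time-point rule
  p4 <- profile_from_matrix(matrix(runif(3 * 3), 3, 3))
  expect_error(build_problem(p4, 1), regexp = "five time points",
               class = "snapgrn_too_few_timepoints")
  # a single gene leaves no regressors
  expect_error(build_problem(profile_from_matrix(matrix(runif(5), 5, 1)), 1),
               class = "snapgrn_too_few_genes")
})

test_that("ridge path solutions match the NNLS-augmentation oracle", {
  skip_if_not_installed("pracma")
  set.seed(42)
  for (i in 1:40) {
    nr <- sample(3:6, 1); m <- sample(2:8, 1)
    prob <- structure(list(X = matrix(rexp(nr * m), nr, m),
                           y = rexp(nr),
                           target_index = sample(m, 1),
                           gene_names = sprintf("g%d", 1:m)),
                      class = "regression_problem")
    lam <- runif(1, 0.05, 5)
    fit <- nonneg_penalized_path(prob, "RIDGE", lambda_grid = lam)
    keep <- setdiff(1:m, prob$target_index)
    oracle <- nnls_ridge_oracle(prob$X[, keep, drop = FALSE], prob$y, lam)
    expect_equal(unname(fit[keep, 1]), oracle, tolerance = 1e-6)
    expect_equal(unname(fit[prob$target_index, 1]), 0)
    expect_true(all(fit >= 0))
  }
})

test_that("shrinkage limits and monotonicity hold along the path", {
  set.seed(7)
  prob <- structure(list(X = matrix(rexp(5 * 4), 5, 4), y = rexp(5),
                         target_index = 1L, gene_names = paste0("g", 1:4)),
                    class = "regression_problem")
  grid <- default_lambda_grid(prob, n_lambda = 40)
  path <- nonneg_penalized_path(prob, "RIDGE", grid)
  norms <- sqrt(colSums(path^2))
  # grid is descending, so the norm must be non-decreasing along it
  expect_true(all(diff(norms) >= -1e-10))
  # a gigantic penalty shrinks everything away
  big <- nonneg_penalized_path(prob, "RIDGE", 1e12 * max(abs(prob$X)))
  expect_lt(sqrt(sum(big^2)), 1e-6)
  # zero response gives zero coefficients at every lambda
  prob0 <- prob; prob0$y <- rep(0, 5)
  expect_true(all(nonneg_penalized_path(prob0, "RIDGE", grid) == 0))
})

test_that("lasso and elastic-net paths satisfy their KKT conditions", {
  set.seed(19)
  for (pen in c("LASSO", "ELASTICNET")) {
    prob <- structure(list(X = matrix(rexp(5 * 5), 5, 5), y = rexp(5),
                           target_index = 2L, gene_names = paste0("g", 1:5)),
                      class = "regression_problem")
    lam <- 0.7; w <- 0.4
    a <- nonneg_penalized_path(prob, pen, lam, mixing = w)[, 1]
    keep <- setdiff(1:5, 2L)
    r <- prob$y - prob$X %*% a
    grad_ls <- -2 * drop(crossprod(prob$X, r))   # d/da of ||y - Xa||^2
    l1 <- if (pen == "LASSO") lam else lam * w
    l2 <- if (pen == "LASSO") 0 else lam * (1 - w)
    for (p in keep) {
      g <- grad_ls[p] + l2 * a[p] + l1
      if (a[p] > 1e-12) expect_lt(abs(g), 1e-6) else expect_gte(g, -1e-6)
    }
  }
})

test_that("LOOCV selects lambda by mean test error with conservative ties", {
  set.seed(5)
  # exact non-negative linear system: CV error increases with lambda,
  # so the smallest grid value wins
  X <- matrix(runif(6 * 3, 1, 2), 6, 3)
  astar <- c(0.8, 0, 0.3)
  prob <- structure(list(X = cbind(X, 0), y = drop(X %*% astar),
                         target_index = 4L, gene_names = paste0("g", 1:4)),
                    class = "regression_problem")
  grid <- default_lambda_grid(prob, n_lambda = 25)
  sel <- loocv_select(prob, "RIDGE", grid)
  expect_equal(sel$lambda_opt, min(grid))
  expect_true(all(diff(sel$cv_errors$mean_error) <= 1e-9))  # descending grid
  expect_equal(nrow(sel$cv_errors), 25L)
  expect_equal(unique(sel$cv_errors$n_folds), 6L)

  # all-zero response ties every lambda; the largest (most regularized) wins
  prob0 <- prob; prob0$y <- rep(0, 6)
  sel0 <- loocv_select(prob0, "RIDGE", grid)
  expect_equal(sel0$lambda_opt, max(grid))

  # three rows -> exactly three folds
  prob3 <- structure(list(X = matrix(runif(3 * 2, 1, 2), 3, 2), y = runif(3),
                          target_index = 1L, gene_names = c("a", "b")),
                     class = "regression_problem")
  expect_equal(unique(loocv_select(prob3, "RIDGE",
                                   default_lambda_grid(prob3))$cv_errors$n_folds),
               3L)

  # identically zero regressors: every fold is degenerate
  probz <- structure(list(X = matrix(0, 4, 3), y = runif(4),
                          target_index = 1L, gene_names = paste0("g", 1:3)),
                     class = "regression_problem")
  expect_error(suppressWarnings(loocv_select(probz, "RIDGE", c(2, 1))),
               class = "snapgrn_degenerate_cv")
})

test_that("fit_target recovers a planted single regulator", {
  hits <- 0L
  for (s in 1:50) {
    set.seed(s)
    m <- 6; nw <- 7
    driver <- abs(rnorm(nw, 0, 2)) + 0.2
    noise <- matrix(abs(rnorm(nw * (m - 2), 0, 0.4)), nw, m - 2)
    target <- c(0.1, 0.9 * driver[seq_len(nw - 1)]) +
      abs(rnorm(nw, 0, 0.05))  # responds to the driver one window later
    prof <- profile_from_matrix(cbind(driver, target, noise))
    fit <- fit_target(prof, 2)
    expect_true(all(fit$alpha >= 0))
    expect_equal(unname(fit$alpha[2]), 0)
    if (which.max(fit$alpha) == 1L) hits <- hits + 1L
  }
  expect_gte(hits, 48L)  # >= 95% of 50 replicates

  # an all-zero profile yields all-zero coefficients
  p0 <- profile_from_matrix(matrix(0, 6, 3))
  expect_true(all(fit_target(p0, 1)$alpha == 0))
})
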