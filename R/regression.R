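# Per-target constrained penalized regression: the target gene's
# normalized distance profile, one window ahead, is regressed on the
# lagged profiles of all genes under a non-negativity constraint, with the
# penalty weight chosen by leave-one-out cross-validation.

#' Build the lagged regression problem for one target gene
#'
#' Predictive (Granger-style) causality: the response `y[l]` is the
#' target's normalized distance in window `l+1`, the regressors `X[l, ]`
#' are every gene's normalized distance in window `l`, for
#' `l = 1 ... n-2`. There is no intercept: a zero shift in all regulators
#' predicts a zero shift in the target.
#'
#' @param profile a `dd_profile` with at least 4 windows (i.e. at least
#'   five time points): 3 usable equations is the minimum for which
#'   leave-one-out cross-validation can report a mean and a standard
#'   deviation of the test errors.
#' @param target_index column index (or gene name) of the target.
#' @return A list of class `regression_problem` with elements `X`
#'   ((n-2) x m), `y` (length n-2), `target_index`, `gene_names`.
#' @export
build_problem <- function(profile, target_index) {
  stopifnot(inherits(profile, "dd_profile"))
  if (is.character(target_index))
    target_index <- match(target_index, profile$gene_names)
  target_index <- as.integer(target_index)
  m <- length(profile$gene_names)
  if (is.na(target_index) || target_index < 1L || target_index > m)
    snap_error("unknown target gene", "snapgrn_unknown_gene")
  if (m < 2L)
    snap_error("at least two genes are needed (no regressors otherwise)",
               "snapgrn_too_few_genes")
  nw <- nrow(profile$normalized)
  if (nw < 4L)
    snap_error("at least five time points required (minimum 3 regression equations for LOOCV)",
               "snapgrn_too_few_timepoints")
  rows <- seq_len(nw - 1L)
  structure(list(X = profile$normalized[rows, , drop = FALSE],
                 y = profile$normalized[rows + 1L, target_index],
                 target_index = target_index,
                 gene_names = profile$gene_names),
            class = "regression_problem")
}

#' Geometric penalty-weight grid for a problem
#'
#' Descending geometric grid anchored at the data scale:
#' `lambda_max = max |X' y|` over the non-target columns (falling back to 1
#' when the problem is identically zero), down to
#' `lambda_min_ratio * lambda_max`.
#'
#' @param problem a `regression_problem`.
#' @param n_lambda number of grid points.
#' @param lambda_min_ratio smallest/largest grid value, in (0, 1).
#' @return Strictly positive, descending numeric vector.
#' @export
default_lambda_grid <- function(problem, n_lambda = 100L,
                                lambda_min_ratio = 1e-4) {
  stopifnot(inherits(problem, "regression_problem"))
  xty <- abs(crossprod(problem$X, problem$y))
  xty[problem$target_index] <- 0
  lmax <- max(xty)
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = n_lambda))
}

.penalty_code <- function(penalty) {
  switch(penalty, RIDGE = 0L, LASSO = 1L, ELASTICNET = 2L,
         snap_error(sprintf("unknown penalty '%s'", penalty),
                    "snapgrn_bad_config"))
}

#' Non-negative penalized coefficient path
#'
#' Solves, for every lambda on the grid, the penalized least squares
#' problem `min ||y - X a||^2 + P(a)` subject to `a >= 0` and
#' `a[target] = 0`, where `P` is `(lambda/2)||a||^2` (ridge),
#' `lambda ||a||_1` (lasso) or the elastic-net mixture
#' `lambda ((1-w)/2 ||a||^2 + w ||a||_1)`. Solved by cyclic coordinate
#' descent with clipping at zero, warm-started along the descending grid;
#' convergence when the largest coefficient change in a sweep falls below
#' `tol`.
#'
#' @param problem a `regression_problem`.
#' @param penalty `"RIDGE"`, `"LASSO"` or `"ELASTICNET"`.
#' @param lambda_grid strictly positive, descending penalty weights.
#' @param mixing elastic-net L1 share, in (0, 1).
#' @param tol coordinate-descent convergence tolerance.
#' @param max_sweeps cap on coordinate-descent sweeps per lambda.
#' @return m x n_lambda coefficient matrix (rows = genes; target row all
#'   zero), with the lambda grid as an attribute.
#' @export
nonneg_penalized_path <- function(problem, penalty = "RIDGE", lambda_grid,
                                  mixing = 0.5, tol = 1e-10,
                                  max_sweeps = 1e5L) {
  stopifnot(inherits(problem, "regression_problem"))
  if (any(!is.finite(problem$X)) || any(!is.finite(problem$y)))
    snap_error("non-finite entries in regression data",
               "snapgrn_missing_values")
  lambda_grid <- as.numeric(lambda_grid)
  if (length(lambda_grid) < 1L || any(lambda_grid <= 0) ||
      is.unsorted(rev(lambda_grid), strictly = FALSE))
    snap_error("lambda grid must be positive and descending",
               "snapgrn_bad_config")
  keep <- setdiff(seq_len(ncol(problem$X)), problem$target_index)
  coef_sub <- nn_penalized_path_cpp(problem$X[, keep, drop = FALSE],
                                    problem$y, lambda_grid,
                                    .penalty_code(penalty), mixing,
                                    tol, as.integer(max_sweeps))
  path <- matrix(0, ncol(problem$X), length(lambda_grid),
                 dimnames = list(problem$gene_names, NULL))
  path[keep, ] <- coef_sub
  attr(path, "lambda") <- lambda_grid
  path
}

#' Leave-one-out cross-validation over the penalty grid
#'
#' Each row of the problem serves once as the test set: the path is fitted
#' on the remaining rows and the squared prediction error on the held-out
#' row is recorded per lambda. The optimal lambda minimizes the mean test
#' error; among lambdas whose mean error ties with the minimum (within
#' 1e-12 relative), the largest (most regularized) wins, which makes the
#' all-flat case deterministic.
#'
#' Folds whose training regressor matrix is identically zero cannot be
#' fitted and are skipped with a warning; if every fold is degenerate the
#' selection fails.
#'
#' @inheritParams nonneg_penalized_path
#' @return list with `lambda_opt` and `cv_errors`, a data.frame with
#'   columns `lambda`, `mean_error`, `sd_error`, `n_folds`.
#' @export
loocv_select <- function(problem, penalty = "RIDGE", lambda_grid,
                         mixing = 0.5) {
  stopifnot(inherits(problem, "regression_problem"))
  nr <- nrow(problem$X)
  if (nr < 3L)
    snap_error("LOOCV needs at least 3 rows", "snapgrn_too_few_timepoints")
  nl <- length(lambda_grid)
  errs <- matrix(NA_real_, nr, nl)
  for (r in seq_len(nr)) {
    Xtr <- problem$X[-r, , drop = FALSE]
    if (all(Xtr[, -problem$target_index] == 0)) {
      snap_warning(sprintf("LOOCV fold %d skipped: training regressors all zero", r),
                   "snapgrn_degenerate_fold")
      next
    }
    sub <- structure(list(X = Xtr, y = problem$y[-r],
                          target_index = problem$target_index,
                          gene_names = problem$gene_names),
                     class = "regression_problem")
    path <- nonneg_penalized_path(sub, penalty, lambda_grid, mixing)
    pred <- drop(problem$X[r, , drop = FALSE] %*% path)
    errs[r, ] <- (problem$y[r] - pred)^2
  }
  usable <- rowSums(is.na(errs)) == 0L
  if (!any(usable))
    snap_error("all LOOCV folds degenerate (regressors identically zero)",
               "snapgrn_degenerate_cv")
  mean_err <- colMeans(errs[usable, , drop = FALSE])
  sd_err <- apply(errs[usable, , drop = FALSE], 2L, stats::sd)
  tol <- 1e-12 * max(min(mean_err), .Machine$double.xmin)
  tied <- which(mean_err <= min(mean_err) + tol)
  lambda_opt <- max(lambda_grid[tied])  # grid is descending: earliest index
  list(lambda_opt = lambda_opt,
       cv_errors = data.frame(lambda = lambda_grid, mean_error = mean_err,
                              sd_error = sd_err, n_folds = sum(usable)))
}

#' Fit one target gene end to end
#'
#' Composes [build_problem], [loocv_select] and [nonneg_penalized_path]:
#' selects the penalty weight by LOOCV, then refits on the full data and
#' returns the coefficients at the selected lambda.
#'
#' @param profile a `dd_profile` (at least five time points).
#' @param target_index target gene index or name.
#' @param config a [run_config].
#' @return list of class `regression_result`: `alpha` (named m-vector,
#'   non-negative, target entry 0), `lambda_opt`, `cv_errors`, `path`
#'   (m x n_lambda), `target_index`.
#' @export
fit_target <- function(profile, target_index, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  problem <- build_problem(profile, target_index)
  grid <- default_lambda_grid(problem, config$n_lambda,
                              config$lambda_min_ratio)
  if (all(problem$X[, -problem$target_index] == 0)) {
    # no usable regressor signal anywhere: coefficients are identically
    # zero at every lambda; report the most-regularized grid point
    alpha <- setNames(numeric(ncol(problem$X)), problem$gene_names)
    return(structure(list(
      alpha = alpha, lambda_opt = grid[1L],
      cv_errors = data.frame(lambda = grid,
                             mean_error = mean(problem$y^2),
                             sd_error = stats::sd(problem$y^2),
                             n_folds = nrow(problem$X)),
      path = matrix(0, ncol(problem$X), length(grid),
                    dimnames = list(problem$gene_names, NULL)),
      target_index = problem$target_index),
      class = "regression_result"))
  }
  sel <- loocv_select(problem, config$penalty, grid, config$mixing)
  path <- nonneg_penalized_path(problem, config$penalty, grid, config$mixing)
  alpha <- path[, which.min(abs(grid - sel$lambda_opt))]
  structure(list(alpha = alpha, lambda_opt = sel$lambda_opt,
                 cv_errors = sel$cv_errors, path = path,
                 target_index = problem$target_index),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("regression_result: target %s, lambda_opt %.4g, %d non-zero coefficients\n",
              names(x$alpha)[x$target_index], x$lambda_opt,
              sum(x$alpha > 0)))
  invisible(x)
}
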