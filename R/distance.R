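# Two-sample distribution distances between consecutive expression
# snapshots, and the per-gene normalized distance profile that feeds the
# regression step.
#
# ECDF convention throughout: right-continuous, jump 1/s at each sample
# point; sums/suprema are evaluated at the pooled sample points, which is
# exact for step functions. Ties across the two samples are handled by
# evaluating only after all jumps at the tied value have accumulated
# (i.e. at distinct pooled values).

.check_samples <- function(a, b, min_size = 1L) {
  if (length(a) < 1L || length(b) < 1L)
    snap_error("empty sample", "snapgrn_empty_sample")
  if (length(a) < min_size || length(b) < min_size)
    snap_error(sprintf("each sample needs at least %d points", min_size),
               "snapgrn_singleton_sample")
  if (anyNA(a) || anyNA(b) || !all(is.finite(c(a, b))))
    snap_error("samples must be finite", "snapgrn_missing_values")
}

# ECDFs of both samples at the distinct pooled values, plus pooled counts.
.pooled_ecdfs <- function(a, b) {
  z <- sort(unique(c(a, b)))
  list(z = z,
       Fa = findInterval(z, sort(a)) / length(a),
       Fb = findInterval(z, sort(b)) / length(b),
       counts = tabulate(findInterval(c(a, b), z), nbins = length(z)))
}

#' Two-sample distribution distances
#'
#' Scalar distances between the empirical distributions of two samples,
#' used to quantify how much a gene's expression distribution moves
#' between consecutive time points.
#'
#' * `ks_distance()`: two-sample Kolmogorov-Smirnov statistic, the maximum
#'   absolute difference between the two ECDFs; in \[0, 1\].
#' * `mean_difference()`: absolute difference of the sample means (the
#'   only metric here that is not rank-based).
#' * `anderson_darling_distance()`: two-sample Anderson-Darling statistic
#'   in its pooled form, the variance-weighted integral of the squared
#'   ECDF difference `(na*nb/N) * int (Fa-Fb)^2 / (H(1-H)) dH` with `H`
#'   the pooled ECDF; weights changes in the distribution tails more
#'   heavily than KS.
#' * `cramer_von_mises_distance()`: two-sample Cramer-von Mises criterion
#'   `(na*nb/N^2) * sum over pooled points of (Fa-Fb)^2`.
#'
#' All four are symmetric in their arguments and zero for identical
#' samples; KS, AD and CM depend only on ranks, so they are invariant
#' under any strictly increasing transform applied to both samples.
#'
#' @param a,b numeric sample vectors (non-empty; AD requires >= 2 points
#'   per sample).
#' @return A single non-negative number.
#' @examples
#' ks_distance(c(1, 2, 3), c(2, 3, 4))  # 1/3
#' @export
ks_distance <- function(a, b) {
  .check_samples(a, b)
  e <- .pooled_ecdfs(a, b)
  max(abs(e$Fa - e$Fb))
}

#' @rdname ks_distance
#' @export
mean_difference <- function(a, b) {
  .check_samples(a, b)
  abs(mean(a) - mean(b))
}

#' @rdname ks_distance
#' @export
anderson_darling_distance <- function(a, b) {
  .check_samples(a, b, min_size = 2L)
  e <- .pooled_ecdfs(a, b)
  N <- length(a) + length(b)
  H <- cumsum(e$counts) / N
  keep <- H < 1  # last pooled value: H(1-H)=0 and Fa=Fb, a 0/0 limit of 0
  w <- e$counts[keep] / N
  (length(a) * length(b) / N) *
    sum(w * (e$Fa[keep] - e$Fb[keep])^2 / (H[keep] * (1 - H[keep])))
}

#' @rdname ks_distance
#' @export
cramer_von_mises_distance <- function(a, b) {
  .check_samples(a, b)
  e <- .pooled_ecdfs(a, b)
  N <- length(a) + length(b)
  (length(a) * length(b) / N^2) * sum(e$counts * (e$Fa - e$Fb)^2)
}

.dd_metric_fun <- function(metric) {
  switch(metric,
         KS = ks_distance,
         MEAN = mean_difference,
         AD = anderson_darling_distance,
         CM = cramer_von_mises_distance,
         snap_error(sprintf("unknown distance metric '%s'", metric),
                    "snapgrn_bad_config"))
}

#' Per-gene normalized distance profile
#'
#' For each gene j and each consecutive time window l (from t_l to
#' t_{l+1}), computes the distribution distance `DD[l, j]` between the
#' gene's expression samples at the two time points, and its normalized
#' form `DD[l, j] / (t_{l+1} - t_l)`. Normalizing by the window width
#' makes windows of unequal length comparable, which matters because
#' snapshot experiments are rarely uniformly sampled.
#'
#' @param dataset a [timestamped_dataset] with at least two time points.
#' @param metric one of `"KS"`, `"MEAN"`, `"AD"`, `"CM"` (see
#'   [ks_distance]).
#' @return An object of class `dd_profile`: list with `gene_names`,
#'   `window_starts`/`window_ends` (length n-1), `raw` and `normalized`
#'   ((n-1) x m matrices) and `metric`.
#' @export
compute_dd_profile <- function(dataset, metric = "KS") {
  stopifnot(inherits(dataset, "timestamped_dataset"))
  n <- n_timepoints(dataset)
  if (n < 2L)
    snap_error("at least two time points are needed to compute distances",
               "snapgrn_too_few_timepoints")
  if (metric != "MEAN" && any(n_cells(dataset) < 2L))
    snap_error("snapshots with a single cell support only the MEAN metric",
               "snapgrn_singleton_sample")
  fun <- .dd_metric_fun(metric)
  m <- n_genes(dataset)
  raw <- matrix(0, n - 1L, m, dimnames = list(NULL, dataset$gene_names))
  for (l in seq_len(n - 1L)) {
    s0 <- dataset$snapshots[[l]]
    s1 <- dataset$snapshots[[l + 1L]]
    for (j in seq_len(m)) raw[l, j] <- fun(s0[, j], s1[, j])
  }
  dt <- diff(dataset$times)
  structure(list(gene_names = dataset$gene_names,
                 window_starts = dataset$times[-n],
                 window_ends = dataset$times[-1L],
                 raw = raw,
                 normalized = raw / dt,
                 metric = metric),
            class = "dd_profile")
}

#' @export
print.dd_profile <- function(x, ...) {
  cat(sprintf("dd_profile: %d windows x %d genes, metric %s\n",
              nrow(x$raw), length(x$gene_names), x$metric))
  invisible(x)
}

#' Export a distance profile as TSV (windows x genes)
#'
#' @param profile a `dd_profile`.
#' @param path output path.
#' @param normalized write the width-normalized distances (default) or the
#'   raw ones.
#' @export
write_dd_profile <- function(profile, path, normalized = TRUE) {
  stopifnot(inherits(profile, "dd_profile"))
  mat <- if (normalized) profile$normalized else profile$raw
  tab <- data.frame(window_start = profile$window_starts,
                    window_end = profile$window_ends,
                    mat, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
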