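#' Time-stamped single-cell expression dataset
#'
#' Bundles a sequence of single-cell expression snapshots, one per
#' measurement time point. Each snapshot is a cells x genes matrix of
#' non-negative expression values; cells are profiled destructively, so the
#' snapshots are cross-sectional (no cell appears at two time points).
#'
#' @param snapshots list of numeric matrices, one per time point, each with
#'   cells in rows and the same genes in columns (same order).
#' @param times numeric vector of time stamps, strictly increasing, one per
#'   snapshot.
#' @param gene_names character vector of unique gene identifiers; defaults
#'   to the column names of the first snapshot.
#' @param source_label free-text provenance tag.
#'
#' @return An object of class `timestamped_dataset`: a list with elements
#'   `gene_names`, `times`, `snapshots` and `source_label`. `n_timepoints()`
#'   and `n_genes()` give n and m; `n_cells()` the per-snapshot cell counts.
#'
#' @details Expression values must be finite and non-negative (raw counts,
#'   Ct-derived expression or normalized units are all acceptable: the
#'   downstream distances are rank/CDF based, so no internal normalization
#'   is applied and none is needed). Negative or missing values are an
#'   error, never silently clamped or dropped. A snapshot with a single
#'   cell is accepted with a warning: its empirical distribution is
#'   degenerate and only the mean-difference distance remains meaningful.
#'
#' @examples
#' d <- timestamped_dataset(
#'   snapshots = list(matrix(runif(20), 10, 2), matrix(runif(20), 10, 2)),
#'   times = c(0, 1), gene_names = c("g1", "g2"))
#' n_timepoints(d)
#' @export
timestamped_dataset <- function(snapshots, times, gene_names = NULL,
                                source_label = "") {
  if (!is.list(snapshots) || length(snapshots) == 0L)
    snap_error("`snapshots` must be a non-empty list of matrices",
               "snapgrn_bad_dataset")
  snapshots <- lapply(snapshots, function(s) {
    s <- as.matrix(s)
    storage.mode(s) <- "double"
    s
  })
  if (length(times) != length(snapshots))
    snap_error("`times` must have one entry per snapshot", "snapgrn_bad_dataset")
  times <- as.numeric(times)
  if (anyNA(times) || any(!is.finite(times)))
    snap_error("time stamps must be finite", "snapgrn_bad_dataset")
  ord <- order(times)
  times <- times[ord]
  snapshots <- snapshots[ord]
  if (any(diff(times) <= 0))
    snap_error("time stamps must be strictly increasing (duplicated time point?)",
               "snapgrn_nonincreasing_times")
  m <- ncol(snapshots[[1L]])
  if (is.null(gene_names)) gene_names <- colnames(snapshots[[1L]])
  if (is.null(gene_names))
    snap_error("gene names are required (supply `gene_names` or column names)",
               "snapgrn_bad_dataset")
  gene_names <- as.character(gene_names)
  if (length(gene_names) != m)
    snap_error("`gene_names` length does not match snapshot columns",
               "snapgrn_bad_dataset")
  if (anyDuplicated(gene_names))
    snap_error(sprintf("duplicate gene names: %s",
                       paste(unique(gene_names[duplicated(gene_names)]),
                             collapse = ", ")),
               "snapgrn_duplicate_genes")
  for (k in seq_along(snapshots)) {
    s <- snapshots[[k]]
    if (ncol(s) != m)
      snap_error("all snapshots must share the same genes in the same order",
                 "snapgrn_gene_mismatch")
    if (nrow(s) < 1L)
      snap_error(sprintf("snapshot %d has no cells", k), "snapgrn_bad_dataset")
    n_missing <- sum(!is.finite(s))
    if (n_missing > 0L)
      snap_error(sprintf(
        "snapshot %d contains %d missing/non-finite values; missing data are not supported",
        k, n_missing), "snapgrn_missing_values")
    if (any(s < 0))
      snap_error(sprintf("snapshot %d contains negative expression values", k),
                 "snapgrn_negative_values")
    colnames(snapshots[[k]]) <- gene_names
  }
  if (any(vapply(snapshots, nrow, 0L) < 2L))
    snap_warning(paste("snapshot with a single cell: empirical distributions",
                       "are degenerate; only the mean-difference metric is",
                       "meaningful"),
                 "snapgrn_single_cell_snapshot")
  structure(list(gene_names = gene_names, times = times,
                 snapshots = snapshots, source_label = source_label),
            class = "timestamped_dataset")
}

#' @rdname timestamped_dataset
#' @param x a `timestamped_dataset`.
#' @export
n_timepoints <- function(x) length(x$times)

#' @rdname timestamped_dataset
#' @export
n_genes <- function(x) length(x$gene_names)

#' @rdname timestamped_dataset
#' @export
n_cells <- function(x) vapply(x$snapshots, nrow, 0L)

#' @export
print.timestamped_dataset <- function(x, ...) {
  cat(sprintf("timestamped_dataset: %d genes, %d time points (%s)\n",
              n_genes(x), n_timepoints(x),
              paste(signif(x$times, 4), collapse = ", ")))
  cat(sprintf("  cells per time point: %s\n",
              paste(n_cells(x), collapse = ", ")))
  if (nzchar(x$source_label)) cat("  source:", x$source_label, "\n")
  invisible(x)
}

#' Signed directed gene network
#'
#' An m x m signed adjacency matrix over named genes. Entry `(i, j)` is the
#' regulation of gene `j` by gene `i`: `+1` activation, `-1` repression,
#' `0` no edge. Self-regulation is not representable (diagonal must be 0).
#'
#' @param gene_names character vector of unique gene identifiers.
#' @param adjacency m x m matrix with entries in {-1, 0, +1}; defaults to
#'   the empty network.
#' @return An object of class `gene_network` with elements `gene_names` and
#'   `adjacency` (integer matrix, dimnames set to the gene names).
#' @examples
#' net <- gene_network(c("a", "b"), matrix(c(0, 0, 1, 0), 2, 2))
#' net$adjacency["a", "b"]
#' @export
gene_network <- function(gene_names, adjacency = NULL) {
  gene_names <- as.character(gene_names)
  m <- length(gene_names)
  if (m < 1L) snap_error("empty gene set", "snapgrn_bad_network")
  if (anyDuplicated(gene_names))
    snap_error("duplicate gene names in network", "snapgrn_duplicate_genes")
  if (is.null(adjacency)) adjacency <- matrix(0L, m, m)
  adjacency <- as.matrix(adjacency)
  if (!all(dim(adjacency) == c(m, m)))
    snap_error("adjacency must be m x m", "snapgrn_bad_network")
  if (anyNA(adjacency) || !all(adjacency %in% c(-1, 0, 1)))
    snap_error("adjacency entries must be in {-1, 0, +1}", "snapgrn_bad_sign")
  if (any(diag(adjacency) != 0))
    snap_error("self-loop not permitted (non-zero diagonal)",
               "snapgrn_self_loop")
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(gene_names, gene_names)
  structure(list(gene_names = gene_names, adjacency = adjacency),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  n_act <- sum(x$adjacency == 1L)
  n_rep <- sum(x$adjacency == -1L)
  cat(sprintf("gene_network: %d genes, %d edges (%d activating, %d repressing)\n",
              length(x$gene_names), n_act + n_rep, n_act, n_rep))
  invisible(x)
}

n_edges <- function(network) sum(network$adjacency != 0L)

#' Ranked candidate edge list
#'
#' The primary inference output: all m(m-1) ordered non-self gene pairs with
#' a non-negative confidence score (the regression coefficient of the
#' regulator's lagged distance profile in the target's model) and a
#' predicted regulation sign. Records are sorted by descending score; ties
#' are broken lexicographically by (regulator, target) so the ordering is
#' fully deterministic.
#'
#' @param records data.frame with columns `regulator`, `target`, `score`,
#'   `sign`, covering every ordered non-self pair exactly once.
#' @param gene_names canonical gene order; defaults to the sorted union of
#'   names appearing in `records`.
#' @return An object of class `ranked_edges`: the sorted records
#'   data.frame (with a `rank` column prepended) carrying the gene names as
#'   an attribute.
#' @export
ranked_edges <- function(records, gene_names = NULL) {
  req <- c("regulator", "target", "score", "sign")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    snap_error("records must have columns regulator, target, score, sign",
               "snapgrn_bad_ranked_edges")
  records$regulator <- as.character(records$regulator)
  records$target <- as.character(records$target)
  if (is.null(gene_names))
    gene_names <- sort(unique(c(records$regulator, records$target)))
  gene_names <- as.character(gene_names)
  m <- length(gene_names)
  if (m < 2L)
    snap_error("a ranked edge list needs at least two genes",
               "snapgrn_bad_ranked_edges")
  if (any(records$regulator == records$target))
    snap_error("self-loop not permitted in ranked edges", "snapgrn_self_loop")
  if (!all(records$regulator %in% gene_names) ||
      !all(records$target %in% gene_names))
    snap_error("records name genes absent from `gene_names`",
               "snapgrn_unknown_gene")
  if (nrow(records) != m * (m - 1L) ||
      anyDuplicated(paste(records$regulator, records$target, sep = "\r")))
    snap_error(sprintf(
      "ranked edge list must cover all %d ordered non-self pairs exactly once",
      m * (m - 1L)), "snapgrn_incomplete_ranking")
  if (anyNA(records$score) || any(records$score < 0))
    snap_error("scores must be non-negative", "snapgrn_bad_score")
  if (!all(records$sign %in% c(-1, 0, 1)))
    snap_error("signs must be in {-1, 0, +1}", "snapgrn_bad_sign")
  ord <- order(-records$score, records$regulator, records$target)
  records <- records[ord, req, drop = FALSE]
  records <- cbind(rank = seq_len(nrow(records)), records)
  rownames(records) <- NULL
  structure(records, gene_names = gene_names,
            class = c("ranked_edges", "data.frame"))
}

#' @export
print.ranked_edges <- function(x, n = 10L, ...) {
  gn <- attr(x, "gene_names")
  cat(sprintf("ranked_edges: %d candidate edges over %d genes; top %d:\n",
              nrow(x), length(gn), min(n, nrow(x))))
  print.data.frame(utils::head(as.data.frame(x), n))
  invisible(x)
}

#' Inference run configuration
#'
#' Collects the tunable choices of the inference pipeline. Defaults
#' reproduce the reference configuration: Kolmogorov-Smirnov distance,
#' ridge penalty, leave-one-out cross-validation over a 100-point
#' geometric lambda grid, and Spearman partial-correlation signs.
#'
#' @param dd_metric distribution distance: `"KS"` (Kolmogorov-Smirnov,
#'   default), `"MEAN"` (absolute mean difference), `"AD"`
#'   (Anderson-Darling) or `"CM"` (Cramer-von Mises).
#' @param penalty `"RIDGE"` (default), `"LASSO"` or `"ELASTICNET"`.
#' @param mixing elastic-net mixing weight in (0, 1); L1 share of the
#'   penalty. Ignored unless `penalty = "ELASTICNET"`.
#' @param n_lambda number of penalty weights on the geometric grid (>= 2).
#' @param lambda_min_ratio ratio of the smallest to the largest grid
#'   lambda, in (0, 1).
#' @param seed integer seed recorded with the run (inference itself is
#'   deterministic; the seed matters only for simulation helpers).
#' @param sign_method `"PARTIAL_SPEARMAN"` (default) or `"NONE"` (leave all
#'   signs 0).
#' @param rescale_per_target if `TRUE`, divide each target's coefficients
#'   by their maximum before global ranking. Off by default: the global
#'   ranking uses raw coefficients across all targets.
#' @return A list of class `run_config`.
#' @export
run_config <- function(dd_metric = c("KS", "MEAN", "AD", "CM"),
                       penalty = c("RIDGE", "LASSO", "ELASTICNET"),
                       mixing = 0.5,
                       n_lambda = 100L,
                       lambda_min_ratio = 1e-4,
                       seed = 1L,
                       sign_method = c("PARTIAL_SPEARMAN", "NONE"),
                       rescale_per_target = FALSE) {
  dd_metric <- match.arg(dd_metric)
  penalty <- match.arg(penalty)
  sign_method <- match.arg(sign_method)
  n_lambda <- as.integer(n_lambda)
  if (n_lambda < 2L) snap_error("n_lambda must be >= 2", "snapgrn_bad_config")
  if (!is.numeric(lambda_min_ratio) || lambda_min_ratio <= 0 ||
      lambda_min_ratio >= 1)
    snap_error("lambda_min_ratio must be in (0, 1)", "snapgrn_bad_config")
  if (penalty == "ELASTICNET" && (mixing <= 0 || mixing >= 1))
    snap_error("elastic-net mixing weight must be in (0, 1)",
               "snapgrn_bad_config")
  structure(list(dd_metric = dd_metric, penalty = penalty, mixing = mixing,
                 n_lambda = n_lambda, lambda_min_ratio = lambda_min_ratio,
                 seed = as.integer(seed), sign_method = sign_method,
                 rescale_per_target = isTRUE(rescale_per_target)),
            class = "run_config")
}
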