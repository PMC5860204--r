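# End-to-end inference: distance profiles -> per-target constrained ridge
# with LOOCV -> global edge ranking -> partial-correlation signs; plus the
# downstream degree-ratio gene ordering and pseudotime binning.

#' Infer a signed, ranked gene regulatory network
#'
#' Full pipeline on a time-stamped dataset: (1) per-gene normalized
#' distance profiles between consecutive time points; (2) for every
#' target gene independently, non-negative penalized regression of its
#' profile on the one-window-lagged profiles of all other genes, penalty
#' weight by leave-one-out cross-validation; (3) all m(m-1) candidate
#' edges ranked by descending coefficient, ties broken lexicographically
#' by (regulator, target); (4) edge signs from Spearman rank partial
#' correlations of the pooled expressions. Inference is deterministic:
#' two runs on the same input give bit-identical output.
#'
#' Scores are the raw regression coefficients pooled across all targets.
#' Each target selects its own penalty weight, so cross-target score
#' comparability is imperfect; `rescale_per_target = TRUE` in the config
#' divides each target's coefficients by their maximum before ranking
#' (off by default, keeping the raw-coefficient convention).
#'
#' @param dataset a [timestamped_dataset] with at least five time points
#'   and at least two genes.
#' @param config a [run_config].
#' @return A [ranked_edges] object; attributes `lambda_opt` (named per
#'   target) and `cv_errors` (list per target) record the penalty
#'   selection.
#' @examples
#' net <- sample_random_network(5, 6, seed = 1)
#' d <- simulate_cells(net, simulation_config(cells_per_time = 30, seed = 1))
#' head(infer_grn(d))
#' @export
infer_grn <- function(dataset, config = run_config()) {
  stopifnot(inherits(dataset, "timestamped_dataset"),
            inherits(config, "run_config"))
  if (n_timepoints(dataset) < 5L)
    snap_error("at least five time points are required for inference",
               "snapgrn_too_few_timepoints")
  if (n_genes(dataset) < 2L)
    snap_error("at least two genes are required", "snapgrn_too_few_genes")
  profile <- compute_dd_profile(dataset, config$dd_metric)
  m <- n_genes(dataset)
  gn <- dataset$gene_names
  scores <- matrix(0, m, m, dimnames = list(gn, gn))  # [regulator, target]
  lambda_opt <- setNames(numeric(m), gn)
  cv_list <- setNames(vector("list", m), gn)
  for (j in seq_len(m)) {
    fit <- fit_target(profile, j, config)
    alpha <- fit$alpha
    if (config$rescale_per_target && max(alpha) > 0)
      alpha <- alpha / max(alpha)
    scores[, j] <- alpha
    lambda_opt[j] <- fit$lambda_opt
    cv_list[[j]] <- fit$cv_errors
  }
  pairs <- which(diag(m) == 0, arr.ind = TRUE)
  records <- data.frame(regulator = gn[pairs[, 1L]],
                        target = gn[pairs[, 2L]],
                        score = scores[pairs],
                        sign = 0L)
  ranked <- ranked_edges(records, gene_names = gn)
  if (config$sign_method == "PARTIAL_SPEARMAN")
    ranked <- attach_signs(ranked, spearman_partial_matrix(pooled_expression(dataset)))
  attr(ranked, "lambda_opt") <- lambda_opt
  attr(ranked, "cv_errors") <- cv_list
  ranked
}

#' Threshold a ranked edge list into a network
#'
#' `rule = "NONZERO"` keeps every edge with a strictly positive score;
#' `rule = "TOP_Q"` keeps the `q` highest-ranked records (in the list's
#' deterministic order, so `TOP_Q(q)` is always nested in `TOP_Q(q+1)`).
#'
#' @param ranked a [ranked_edges] object.
#' @param rule `"NONZERO"` or `"TOP_Q"`.
#' @param q number of edges to keep under `"TOP_Q"`.
#' @return A [gene_network] with the kept edges carrying their predicted
#'   signs (sign 0 records are kept as +1-less edges only if signed;
#'   a kept record with sign 0 is stored as +1 to keep the edge present).
#' @export
threshold_edges <- function(ranked, rule = c("NONZERO", "TOP_Q"), q = NULL) {
  stopifnot(inherits(ranked, "ranked_edges"))
  rule <- match.arg(rule)
  gn <- attr(ranked, "gene_names")
  keep <- if (rule == "NONZERO") {
    which(ranked$score > 0)
  } else {
    if (is.null(q) || q < 0 || q > nrow(ranked))
      snap_error(sprintf("q must be between 0 and %d", nrow(ranked)),
                 "snapgrn_bad_config")
    seq_len(q)
  }
  A <- matrix(0L, length(gn), length(gn), dimnames = list(gn, gn))
  if (length(keep) > 0L) {
    sgn <- ranked$sign[keep]
    sgn[sgn == 0L] <- 1L  # unsigned inference: keep the edge, default +
    A[cbind(match(ranked$regulator[keep], gn),
            match(ranked$target[keep], gn))] <- sgn
  }
  gene_network(gn, A)
}

#' Order genes by out/in-degree ratio
#'
#' For each gene, out-degree = number of targets, in-degree = number of
#' regulators in the thresholded network; the ratio (with in-degree 0
#' mapping to +Inf, sorted first) orders genes from upstream drivers to
#' downstream responders. Groups follow the published cutoffs:
#' upstream ratio >= 5.5, midstream 5.5 > ratio >= 1.1, downstream
#' ratio < 1.1.
#'
#' @param network a [gene_network].
#' @return data.frame of class `degree_ratio_table` with columns `gene`,
#'   `out_degree`, `in_degree`, `ratio`, `group`, sorted by decreasing
#'   ratio (ties: larger out-degree first, then gene name).
#' @export
degree_ratio_ranking <- function(network) {
  stopifnot(inherits(network, "gene_network"))
  A <- network$adjacency != 0L
  out_deg <- rowSums(A)
  in_deg <- colSums(A)
  if (all(out_deg + in_deg == 0))
    snap_warning("empty network: degree ratios undefined, all genes downstream",
                 "snapgrn_empty_network")
  ratio <- ifelse(in_deg == 0, ifelse(out_deg == 0, 0, Inf),
                  out_deg / in_deg)
  group <- ifelse(ratio >= 5.5, "UPSTREAM",
                  ifelse(ratio >= 1.1, "MIDSTREAM", "DOWNSTREAM"))
  tab <- data.frame(gene = network$gene_names, out_degree = out_deg,
                    in_degree = in_deg, ratio = ratio, group = group,
                    row.names = NULL)
  tab <- tab[order(-tab$ratio, -tab$out_degree, tab$gene), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("degree_ratio_table", "data.frame")
  tab
}

#' Bin pseudotime-ordered cells into snapshots
#'
#' For datasets without wall-clock time stamps: cells carrying a
#' precomputed pseudotime are grouped into `n_bins` equal-width bins over
#' the pseudotime range; each non-empty bin becomes a snapshot with the
#' bin center as its time stamp. Empty bins are dropped with a warning;
#' fewer than 5 non-empty bins is an error (the downstream inference
#' needs five time points).
#'
#' @param expressions cells x genes numeric matrix (named columns).
#' @param pseudotimes finite numeric vector, one per cell.
#' @param n_bins number of bins (>= 5).
#' @return A [timestamped_dataset].
#' @export
bin_pseudotime <- function(expressions, pseudotimes, n_bins = 5L) {
  expressions <- as.matrix(expressions)
  if (length(pseudotimes) != nrow(expressions))
    snap_error("one pseudotime per cell required", "snapgrn_bad_layout")
  if (anyNA(pseudotimes) || any(!is.finite(pseudotimes)))
    snap_error("pseudotimes must be finite", "snapgrn_missing_values")
  if (n_bins < 5L)
    snap_error("at least 5 bins required", "snapgrn_too_few_timepoints")
  rng <- range(pseudotimes)
  if (diff(rng) <= 0)
    snap_error("pseudotimes are all identical: cannot bin",
               "snapgrn_degenerate_pseudotime")
  breaks <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  bin <- findInterval(pseudotimes, breaks, rightmost.closed = TRUE)
  centers <- (breaks[-1L] + breaks[-(n_bins + 1L)]) / 2
  occupied <- sort(unique(bin))
  if (length(occupied) < n_bins)
    snap_warning(sprintf("%d empty pseudotime bin(s) dropped",
                         n_bins - length(occupied)),
                 "snapgrn_empty_bins")
  if (length(occupied) < 5L)
    snap_error("fewer than 5 non-empty pseudotime bins",
               "snapgrn_too_few_timepoints")
  snaps <- lapply(occupied, function(b)
    expressions[bin == b, , drop = FALSE])
  timestamped_dataset(snaps, centers[occupied],
                      gene_names = colnames(expressions),
                      source_label = "pseudotime-binned")
}
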