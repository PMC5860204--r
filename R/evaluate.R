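# AUROC / AUPR scoring of ranked edge predictions against gold-standard
# networks, sweeping the number q of accepted top edges over the full
# m(m-1) candidate universe.

.gold_lookup <- function(ranked, gold) {
  gn <- attr(ranked, "gene_names")
  if (!setequal(gn, gold$gene_names))
    snap_error("gene sets of prediction and gold standard differ (use evaluate_restricted for subsets)",
               "snapgrn_gene_mismatch")
  gsign <- gold$adjacency[cbind(match(ranked$regulator, gold$gene_names),
                                match(ranked$target, gold$gene_names))]
  list(gold_loc = gsign != 0L, gold_sign = gsign)
}

#' Confusion counts at a cut-off q
#'
#' The prediction set is the top `q` records of the ranked list. Unsigned
#' mode scores edge existence only. Signed mode requires the predicted
#' sign to match: a predicted edge at a gold location with the wrong sign
#' counts as a false positive while the gold edge stays a false negative.
#' True negatives are the ordered non-self pairs that are neither gold
#' edges nor false-positive locations.
#'
#' @param ranked a [ranked_edges] object.
#' @param gold a [gene_network] over the same genes.
#' @param q cut-off, `1 <= q <= m(m-1)`.
#' @param signed logical.
#' @return Named vector `c(TP, FP, TN, FN)`.
#' @export
confusion_at_q <- function(ranked, gold, q, signed = TRUE) {
  stopifnot(inherits(ranked, "ranked_edges"), inherits(gold, "gene_network"))
  M <- nrow(ranked)
  if (q < 1L || q > M)
    snap_error(sprintf("q must be in [1, %d]", M), "snapgrn_bad_config")
  lk <- .gold_lookup(ranked, gold)
  top <- seq_len(q)
  hit <- if (signed) {
    lk$gold_loc[top] & (ranked$sign[top] == lk$gold_sign[top])
  } else lk$gold_loc[top]
  tp <- sum(hit)
  fp <- q - tp
  fp_nongold <- sum(!lk$gold_loc[top])
  n_gold <- sum(lk$gold_loc)
  tn <- M - n_gold - fp_nongold
  fn <- n_gold - tp
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# ROC/PR points at tie-block boundaries. Tied scores are swept as a single
# block so the arbitrary within-tie order cannot leak into the areas
# (equivalent to the rank-sum AUROC); important because all-zero
# coefficient tails are common.
.sweep_points <- function(ranked, gold, signed) {
  lk <- .gold_lookup(ranked, gold)
  M <- nrow(ranked)
  n_gold <- sum(lk$gold_loc)
  if (n_gold == 0L || n_gold == M)
    snap_error("gold standard needs at least one edge and one non-edge",
               "snapgrn_degenerate_gold")
  hit <- if (signed) lk$gold_loc & (ranked$sign == lk$gold_sign) else lk$gold_loc
  q_ends <- cumsum(rle(ranked$score)$lengths)  # records are score-sorted
  tp <- cumsum(hit)[q_ends]
  fp <- q_ends - tp
  fp_nongold <- q_ends - cumsum(lk$gold_loc)[q_ends]
  tn <- M - n_gold - fp_nongold
  fn <- n_gold - tp
  data.frame(q = q_ends, TP = tp, FP = fp, TN = tn, FN = fn,
             TPR = tp / (tp + fn), FPR = fp / (fp + tn),
             recall = tp / n_gold, precision = tp / q_ends)
}

.trapezoid <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)

#' Area under ROC and precision-recall curves
#'
#' Sweeps the cut-off q over the whole ranked list (tied-score blocks as
#' single sweep steps), plotting TPR = TP/(TP+FN) against
#' FPR = FP/(FP+TN) for the ROC curve and precision = TP/q against
#' recall = TP/(TP+FN) for the PR curve. The ROC area is trapezoidal with
#' (0, 0) prepended. The PR area anchors the left end at the first sweep
#' point's precision (a rectangle over `[0, recall_1]`; no interpolation
#' toward recall 0), then integrates trapezoidally.
#'
#' @inheritParams confusion_at_q
#' @return list of class `evaluation_result`: `auroc`, `aupr`,
#'   `roc_points`, `pr_points` (data.frames), `signed`,
#'   `restricted_gene_set` (NULL here), `universe` (m(m-1)).
#' @export
auroc_aupr <- function(ranked, gold, signed = TRUE) {
  pts <- .sweep_points(ranked, gold, signed)
  roc_x <- c(0, pts$FPR)
  roc_y <- c(0, pts$TPR)
  auroc <- .trapezoid(roc_x, roc_y)
  aupr <- pts$recall[1L] * pts$precision[1L] +
    .trapezoid(pts$recall, pts$precision)
  structure(list(auroc = auroc, aupr = aupr,
                 roc_points = data.frame(q = c(0, pts$q), FPR = roc_x,
                                         TPR = roc_y),
                 pr_points = pts[, c("q", "recall", "precision")],
                 signed = signed, restricted_gene_set = NULL,
                 universe = nrow(ranked)),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("evaluation_result (%s): AUROC %.4f, AUPR %.4f over %d candidate edges\n",
              if (x$signed) "signed" else "unsigned", x$auroc, x$aupr,
              x$universe))
  invisible(x)
}

#' Evaluate on a gene subset
#'
#' Restricts both the prediction and the gold standard to edges with BOTH
#' endpoints in `gene_subset` (preserving the relative prediction order),
#' then scores as [auroc_aupr] over the reduced |S|(|S|-1) universe. This
#' is the protocol for gold standards that cover only part of the profiled
#' genes.
#'
#' @inheritParams confusion_at_q
#' @param gene_subset character vector, a subset of both gene sets.
#' @return An `evaluation_result` with `restricted_gene_set` recorded.
#' @export
evaluate_restricted <- function(ranked, gold, gene_subset, signed = TRUE) {
  stopifnot(inherits(ranked, "ranked_edges"), inherits(gold, "gene_network"))
  gene_subset <- intersect(as.character(gene_subset),
                           intersect(attr(ranked, "gene_names"),
                                     gold$gene_names))
  if (length(gene_subset) < 2L)
    snap_error("gene subset must contain at least two genes present in both inputs",
               "snapgrn_gene_mismatch")
  keep <- ranked$regulator %in% gene_subset & ranked$target %in% gene_subset
  sub_ranked <- ranked_edges(as.data.frame(ranked)[keep,
                               c("regulator", "target", "score", "sign")],
                             gene_names = gene_subset)
  idx <- match(gene_subset, gold$gene_names)
  sub_gold <- gene_network(gene_subset,
                           gold$adjacency[idx, idx, drop = FALSE])
  res <- auroc_aupr(sub_ranked, sub_gold, signed)
  res$restricted_gene_set <- gene_subset
  res
}

#' Export ROC / PR curve points as TSV
#'
#' @param result an `evaluation_result`.
#' @param roc_path,pr_path output paths (either may be NULL to skip).
#' @export
write_curves <- function(result, roc_path = NULL, pr_path = NULL) {
  stopifnot(inherits(result, "evaluation_result"))
  if (!is.null(roc_path))
    utils::write.table(result$roc_points, roc_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (!is.null(pr_path))
    utils::write.table(result$pr_points, pr_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(result)
}
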