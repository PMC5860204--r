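# Regulation mode (activation vs. repression) from Spearman rank partial
# correlations on the expressions pooled across all time points.

#' Pool expression across all time points
#'
#' Row-concatenates the snapshots in time order, giving one
#' (sum of cells) x genes matrix on which correlations are computed.
#'
#' @param dataset a [timestamped_dataset].
#' @return Numeric matrix with `sum(n_cells(dataset))` rows.
#' @export
pooled_expression <- function(dataset) {
  stopifnot(inherits(dataset, "timestamped_dataset"))
  do.call(rbind, dataset$snapshots)
}

#' Spearman rank partial correlation sign matrix
#'
#' For every gene pair (i, j), the Spearman rank partial correlation of
#' their pooled expressions given all remaining m-2 genes. Columns are
#' rank-transformed (average ranks on ties), the rank correlation matrix
#' `C` is inverted, and `pcorr[i, j] = -P[i, j] / sqrt(P[i, i] P[j, j])`
#' with `P = C^{-1}`. With m = 2 this reduces to the plain Spearman
#' correlation. The edge sign is the sign of the partial correlation;
#' correlation is symmetric, so the sign of i -> j always equals the sign
#' of j -> i (the method cannot produce asymmetric modes).
#'
#' A gene with constant pooled expression has no defined rank correlation;
#' its correlations are set to 0 with a warning. If the rank correlation
#' matrix is ill-conditioned (condition number above `cond_max`, e.g.
#' collinear genes or fewer cells than genes), it is shrunk toward the
#' identity, `(1-g) C + g I`, with the minimal weight `g` that restores
#' the condition bound; this keeps the pipeline total and is reported with
#' a warning.
#'
#' @param pooled numeric matrix, cells x genes (see [pooled_expression]).
#' @param cond_max condition-number ceiling triggering shrinkage.
#' @param zero_tol absolute partial correlations below this map to sign 0,
#'   so numerically null correlations are not reported as modes.
#' @return list of class `sign_matrix`: `signs` (m x m in {-1, 0, +1},
#'   symmetric, zero diagonal), `pcorr` (m x m, zero diagonal),
#'   `gene_names`.
#' @export
spearman_partial_matrix <- function(pooled, cond_max = 1e10,
                                    zero_tol = 1e-12) {
  pooled <- as.matrix(pooled)
  m <- ncol(pooled)
  if (m < 2L)
    snap_error("partial correlation needs at least two genes",
               "snapgrn_too_few_genes")
  gene_names <- colnames(pooled) %||% paste0("g", seq_len(m))
  ranks <- apply(pooled, 2L, rank)  # average ranks on ties
  constant <- apply(ranks, 2L, function(r) max(r) == min(r))
  C <- diag(m)
  if (sum(!constant) >= 2L)
    C[!constant, !constant] <- stats::cor(ranks[, !constant, drop = FALSE])
  if (any(constant))
    snap_warning(sprintf("constant gene(s) %s: correlations set to 0",
                         paste(gene_names[constant], collapse = ", ")),
                 "snapgrn_constant_gene")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  lmax <- max(ev)
  lmin <- min(ev)
  if (lmin <= 0 || lmax / lmin > cond_max) {
    # minimal g with ((1-g)lmax + g) / ((1-g)lmin + g) <= cond_max
    g <- (lmax - cond_max * lmin) / (lmax + cond_max - 1 - cond_max * lmin)
    g <- min(max(g, 0), 1)
    snap_warning(sprintf(
      "rank correlation matrix ill-conditioned; shrinking toward identity (weight %.3g)",
      g), "snapgrn_shrinkage")
    C <- (1 - g) * C + g * diag(m)
  }
  P <- solve(C)
  pcorr <- -P / sqrt(outer(diag(P), diag(P)))
  pcorr <- (pcorr + t(pcorr)) / 2  # enforce exact symmetry
  diag(pcorr) <- 0
  signs <- sign(pcorr)
  signs[abs(pcorr) < zero_tol] <- 0
  dimnames(pcorr) <- dimnames(signs) <- list(gene_names, gene_names)
  structure(list(signs = signs, pcorr = pcorr, gene_names = gene_names),
            class = "sign_matrix")
}

#' @export
print.sign_matrix <- function(x, ...) {
  cat(sprintf("sign_matrix: %d genes; %d positive, %d negative pairs\n",
              length(x$gene_names), sum(x$signs[upper.tri(x$signs)] > 0),
              sum(x$signs[upper.tri(x$signs)] < 0)))
  invisible(x)
}

#' Attach partial-correlation signs to a ranked edge list
#'
#' Sets each record's sign to `signs[regulator, target]`; scores and the
#' ranking order are untouched, so the operation is idempotent.
#'
#' @param ranked a [ranked_edges] object.
#' @param signs a `sign_matrix` over the same gene set.
#' @return The ranked list with signs filled in.
#' @export
attach_signs <- function(ranked, signs) {
  stopifnot(inherits(ranked, "ranked_edges"), inherits(signs, "sign_matrix"))
  gn <- attr(ranked, "gene_names")
  if (!setequal(gn, signs$gene_names))
    snap_error("gene sets of ranked list and sign matrix differ",
               "snapgrn_gene_mismatch")
  ranked$sign <- signs$signs[cbind(match(ranked$regulator, signs$gene_names),
                                   match(ranked$target, signs$gene_names))]
  ranked
}

#' Export a partial-correlation matrix as TSV
#'
#' @param signs a `sign_matrix`.
#' @param path output path.
#' @export
write_pcorr_matrix <- function(signs, path) {
  stopifnot(inherits(signs, "sign_matrix"))
  tab <- data.frame(gene = signs$gene_names, signs$pcorr, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
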