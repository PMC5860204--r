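# Independent oracles and small fixture builders shared across tests.

# Non-negative penalized least squares by NNLS on the augmented system
# [X; sqrt(lambda/2) I], [y; 0] -- independent of the coordinate-descent
# solver under test.
nnls_ridge_oracle <- function(X, y, lambda) {
  p <- ncol(X)
  Xa <- rbind(X, sqrt(lambda / 2) * diag(p))
  ya <- c(y, rep(0, p))
  pracma::lsqnonneg(Xa, ya)$x
}

# Partial correlation of columns i, j of `ranks` given the remaining
# columns, via correlation of linear-regression residuals.
residual_pcor_oracle <- function(ranks, i, j) {
  ctrl <- ranks[, -c(i, j), drop = FALSE]
  if (ncol(ctrl) == 0) return(stats::cor(ranks[, i], ranks[, j]))
  ri <- stats::lm.fit(cbind(1, ctrl), ranks[, i])$residuals
  rj <- stats::lm.fit(cbind(1, ctrl), ranks[, j])$residuals
  stats::cor(ri, rj)
}

# AUROC/AUPR by exhaustive enumeration of every cut-off q, recomputing
# the confusion table from set logic at each q (assumes distinct scores).
exhaustive_eval_oracle <- function(ranked, gold, signed) {
  gn <- attr(ranked, "gene_names")
  gs <- gold$adjacency[cbind(match(ranked$regulator, gn),
                             match(ranked$target, gn))]
  M <- nrow(ranked)
  n_gold <- sum(gs != 0)
  tpr <- fpr <- prec <- rec <- numeric(M)
  for (q in seq_len(M)) {
    sub <- gs[seq_len(q)]
    tp <- if (signed) sum(sub != 0 & ranked$sign[seq_len(q)] == sub)
          else sum(sub != 0)
    fp <- q - tp
    fp_nongold <- sum(sub == 0)
    tn <- M - n_gold - fp_nongold
    fn <- n_gold - tp
    tpr[q] <- tp / (tp + fn)
    fpr[q] <- fp / (fp + tn)
    rec[q] <- tp / n_gold
    prec[q] <- tp / q
  }
  x <- c(0, fpr); y <- c(0, tpr)
  auroc <- sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
  aupr <- rec[1] * prec[1] +
    sum(diff(rec) * (prec[-length(prec)] + prec[-1]) / 2)
  list(auroc = auroc, aupr = aupr)
}

# Random complete ranked list over m genes with distinct scores.
random_ranked_list <- function(m, signed = TRUE, gene_names = sprintf("G%d", seq_len(m))) {
  pairs <- which(diag(m) == 0, arr.ind = TRUE)
  n <- nrow(pairs)
  ranked_edges(data.frame(
    regulator = gene_names[pairs[, 1]], target = gene_names[pairs[, 2]],
    score = sample(seq_len(n)) + stats::runif(n, 0, 0.4),
    sign = if (signed) sample(c(-1L, 1L), n, replace = TRUE) else 0L),
    gene_names = gene_names)
}

# Small dataset of Gaussian snapshots with specified per-time means.
gaussian_dataset <- function(mean_paths, times, cells = 40, sdev = 1,
                             base = 50) {
  snaps <- lapply(seq_along(times), function(k)
    sapply(seq_len(ncol(mean_paths)), function(j)
      stats::rnorm(cells, base + mean_paths[k, j], sdev)))
  timestamped_dataset(snaps, times,
                      gene_names = colnames(mean_paths) %||%
                        sprintf("g%d", seq_len(ncol(mean_paths))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A dd_profile object built directly from a normalized matrix (unit
# window widths), for regression tests that plant known structure.
profile_from_matrix <- function(normalized, gene_names = NULL) {
  m <- ncol(normalized)
  if (is.null(gene_names)) gene_names <- sprintf("g%d", seq_len(m))
  nw <- nrow(normalized)
  structure(list(gene_names = gene_names,
                 window_starts = seq_len(nw) - 1,
                 window_ends = seq_len(nw),
                 raw = normalized, normalized = normalized,
                 metric = "KS"),
            class = "dd_profile")
}
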