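make_gold3 <- function() {
  A <- matrix(0, 3, 3); A[1, 2] <- 1; A[2, 3] <- -1
  gene_network(c("g1", "g2", "g3"), A)
}

# ranked list over 3 genes with a chosen top-2 prediction
rank3 <- function(top2, signs2) {
  pairs <- which(diag(3) == 0, arr.ind = TRUE)
  gn <- c("g1", "g2", "g3")
  rec <- data.frame(regulator = gn[pairs[, 1]], target = gn[pairs[, 2]],
                    score = 0, sign = 0L)
  key <- paste(rec$regulator, rec$target)
  rec$score[match(top2, key)] <- c(2, 1.5)
  rec$sign[match(top2, key)] <- signs2
  others <- setdiff(seq_len(6), match(top2, key))
  rec$score[others] <- seq(1, 0.1, length.out = 4)
  ranked_edges(rec, gn)
}

test_that("confusion counts respect signs per the toy enumeration", {
  gold <- make_gold3()
  # prediction: (g1->g2, -), (g2->g3, -): one sign mismatch
  r <- rank3(c("g1 g2", "g2 g3"), c(-1L, -1L))
  signed <- confusion_at_q(r, gold, 2, signed = TRUE)
  expect_equal(unname(signed), c(1, 1, 4, 1))    # TP, FP, TN, FN
  unsigned <- confusion_at_q(r, gold, 2, signed = FALSE)
  expect_equal(unname(unsigned[c("TP", "FP")]), c(2, 0))

  # perfect prediction at q = |gold|
  rp <- rank3(c("g1 g2", "g2 g3"), c(1L, -1L))
  cp <- confusion_at_q(rp, gold, 2, signed = TRUE)
  expect_equal(unname(cp), c(2, 0, 4, 0))
  expect_error(confusion_at_q(rp, gold, 7, signed = TRUE),
               class = "snapgrn_bad_config")
})

test_that("a gold-first ranking attains AUROC and AUPR of 1", {
  gold <- make_gold3()
  rp <- rank3(c("g1 g2", "g2 g3"), c(1L, -1L))
  res <- auroc_aupr(rp, gold, signed = TRUE)
  expect_equal(res$auroc, 1)
  expect_equal(res$aupr, 1)
  expect_equal(res$roc_points$FPR[1], 0)
  expect_equal(res$roc_points$TPR[1], 0)
  # recall is non-decreasing along the sweep
  expect_true(all(diff(res$pr_points$recall) >= 0))
})

test_that("sweep areas match the exhaustive enumeration oracle", {
  set.seed(33)
  for (i in 1:25) {
    m <- sample(3:6, 1)
    net <- sample_random_network(m, sample(seq_len(m * (m - 1) - 1), 1),
                                 seed = i)
    r <- random_ranked_list(m, gene_names = net$gene_names)
    for (signed in c(TRUE, FALSE)) {
      got <- auroc_aupr(r, net, signed = signed)
      want <- exhaustive_eval_oracle(r, net, signed = signed)
      expect_equal(got$auroc, want$auroc, tolerance = 1e-12)
      expect_equal(got$aupr, want$aupr, tolerance = 1e-12)
    }
  }
})

test_that("score ties are swept as blocks, not in arbitrary order", {
  net <- sample_random_network(5, 8, seed = 2)
  pairs <- which(diag(5) == 0, arr.ind = TRUE)
  gn <- net$gene_names
  tied <- ranked_edges(data.frame(regulator = gn[pairs[, 1]],
                                  target = gn[pairs[, 2]],
                                  score = 1, sign = 1L), gn)
  # one tie block covering everything: the ROC is the diagonal
  expect_equal(auroc_aupr(tied, net, signed = FALSE)$auroc, 0.5)

  # AUROC is invariant under strictly monotone transforms of the scores
  set.seed(2)
  r <- random_ranked_list(5, gene_names = gn)
  r3 <- ranked_edges(within(as.data.frame(r), score <- score^3)[-1], gn)
  expect_equal(auroc_aupr(r, net, FALSE)$auroc,
               auroc_aupr(r3, net, FALSE)$auroc, tolerance = 1e-12)
})

test_that("sign mismatches can only hurt the signed evaluation", {
  set.seed(55)
  for (i in 1:10) {
    net <- sample_random_network(5, 8, seed = i)
    r <- random_ranked_list(5, gene_names = net$gene_names)
    u <- auroc_aupr(r, net, signed = FALSE)$auroc
    s <- auroc_aupr(r, net, signed = TRUE)$auroc
    expect_lte(s, u + 1e-12)
  }
  # with all predicted signs correct the two coincide
  net <- sample_random_network(4, 6, seed = 3)
  r <- random_ranked_list(4, signed = FALSE, gene_names = net$gene_names)
  df <- as.data.frame(r)
  gs <- net$adjacency[cbind(match(df$regulator, net$gene_names),
                            match(df$target, net$gene_names))]
  df$sign <- ifelse(gs != 0, gs, 1L)
  rc <- ranked_edges(df[c("regulator", "target", "score", "sign")],
                     net$gene_names)
  expect_equal(auroc_aupr(rc, net, TRUE)$auroc,
               auroc_aupr(rc, net, FALSE)$auroc)
})

test_that("restricted evaluation reduces the candidate universe", {
  set.seed(77)
  net <- sample_random_network(8, 14, seed = 5)
  r <- random_ranked_list(8, gene_names = net$gene_names)
  full <- auroc_aupr(r, net, signed = FALSE)
  same <- evaluate_restricted(r, net, net$gene_names, signed = FALSE)
  expect_equal(same$auroc, full$auroc)

  sub <- net$gene_names[1:5]
  res <- evaluate_restricted(r, net, sub, signed = FALSE)
  expect_equal(res$universe, 20L)                 # 5 * 4 ordered pairs
  expect_identical(sort(res$restricted_gene_set), sort(sub))
  expect_error(evaluate_restricted(r, net, "nope", signed = FALSE),
               class = "snapgrn_gene_mismatch")

  # degenerate gold standards are rejected
  empty <- gene_network(net$gene_names)
  expect_error(auroc_aupr(r, empty, FALSE), class = "snapgrn_degenerate_gold")
  full <- gene_network(net$gene_names,
                       matrix(1, 8, 8) - diag(8))
  expect_error(auroc_aupr(r, full, FALSE), class = "snapgrn_degenerate_gold")
})

test_that("a 45-gene prediction restricted to 20 genes scores over 380 pairs", {
  set.seed(88)
  net <- sample_random_network(45, 60, seed = 8)
  r <- random_ranked_list(45, gene_names = net$gene_names)
  sub <- net$gene_names[1:20]
  res <- evaluate_restricted(r, net, sub, signed = TRUE)
  expect_equal(res$universe, 380L)
  expect_length(res$restricted_gene_set, 20L)
})
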