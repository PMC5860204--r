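Package: snapgrn
Title: Gene Regulatory Network Inference from Time-Stamped Single-Cell
    Expression Snapshots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers directed, signed gene regulatory networks from
    time-stamped cross-sectional single-cell expression data, in which each
    cell is profiled once at one of several post-stimulation time points.
    Temporal change of each gene is summarized as the Kolmogorov-Smirnov
    (or mean-difference, Anderson-Darling, Cramer-von Mises) distance
    between its expression distributions at consecutive time points,
    normalized by the window width. Regulatory edges are recovered by
    Granger-style non-negativity-constrained ridge regression of each
    gene's distance profile on the lagged profiles of all other genes,
    with the penalty weight chosen by leave-one-out cross-validation, and
    edge signs are assigned from Spearman rank partial correlations.
    Includes a stochastic differential equation simulator of single-cell
    snapshot data from known networks and a signed/unsigned AUROC/AUPR
    evaluation harness for benchmarking against gold-standard networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
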