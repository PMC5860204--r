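# Convenience driver: simulate -> infer -> evaluate over replicate random
# networks, summarizing mean +/- sd of AUROC and AUPR per design.

#' Run the in-silico benchmark
#'
#' For each network seed, samples a random signed network, simulates
#' single-cell snapshots under every configuration of the chosen design
#' family, runs the full inference pipeline and scores it against the
#' generating network (signed by default). Simulation seeds are derived
#' deterministically from the network seeds so the whole benchmark is a
#' function of its arguments.
#'
#' @param n_genes,network_edges size of the random gold-standard networks.
#' @param design design family passed to [benchmark_design].
#' @param network_seeds one sampler seed per replicate network.
#' @param cells_per_time cells per time point.
#' @param config a [run_config] for the inference step.
#' @param signed score with edge signs (default) or existence only.
#' @param sim_seed_offset added to each network seed to seed its
#'   simulation.
#' @return list of class `benchmark_result`: `per_network` (data.frame
#'   with one row per network x configuration: seed, configuration name,
#'   auroc, aupr) and `summary` (mean and sd per configuration).
#' @export
run_benchmark <- function(n_genes = 10L, network_edges = 15L,
                          design = "MAIN", network_seeds = 1:10,
                          cells_per_time = 100L, config = run_config(),
                          signed = TRUE, sim_seed_offset = 104729L) {
  rows <- list()
  for (seed in network_seeds) {
    net <- sample_random_network(n_genes, network_edges, seed = seed)
    configs <- benchmark_design(design, seed = seed + sim_seed_offset,
                                cells_per_time = cells_per_time)
    for (cname in names(configs)) {
      dataset <- simulate_cells(net, configs[[cname]])
      ranked <- infer_grn(dataset, config)
      res <- auroc_aupr(ranked, net, signed = signed)
      rows[[length(rows) + 1L]] <- data.frame(
        network_seed = seed, configuration = cname,
        auroc = res$auroc, aupr = res$aupr)
    }
  }
  per_network <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_network, per_network$configuration),
    function(d) data.frame(configuration = d$configuration[1L],
                           n_networks = nrow(d),
                           auroc_mean = mean(d$auroc),
                           auroc_sd = stats::sd(d$auroc),
                           aupr_mean = mean(d$aupr),
                           aupr_sd = stats::sd(d$aupr))))
  # keep the design's own configuration order, not alphabetical
  summ <- summ[match(unique(per_network$configuration),
                     summ$configuration), , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(per_network = per_network, summary = summ,
                 design = design, signed = signed),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cat(sprintf("benchmark_result (%s, %s):\n", x$design,
              if (x$signed) "signed" else "unsigned"))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s AUROC %.2f +/- %.2f   AUPR %.2f +/- %.2f  (n=%d)\n",
                s$configuration[i], s$auroc_mean[i], s$auroc_sd[i],
                s$aupr_mean[i], s$aupr_sd[i], s$n_networks[i]))
  invisible(x)
}
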