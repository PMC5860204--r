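# Readers/writers for the plain-text exchange formats: expression tables
# (TSV/CSV, one row per cell), 3-column gold-standard edge lists and the
# 5-column ranked-edge output.

.read_delim_auto <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Read time-stamped single-cell expression data
#'
#' Two layouts are supported. (1) A single delimited file (TSV or CSV by
#' extension) with a header row: one column named `time` carrying each
#' cell's time stamp, the remaining columns one per gene. (2) One file per
#' time point (gene columns only), with the time stamps supplied in
#' `times`, one per file.
#'
#' Gene identity is by name: in the multi-file layout the first file's
#' header fixes the canonical gene order and later files are matched (and
#' reordered) by name, never by column position.
#'
#' @param path file path, or a vector of per-time-point file paths.
#' @param times numeric time stamps, required iff `path` has length > 1.
#' @param time_col name of the time column in the single-file layout.
#' @param source_label provenance tag stored on the result.
#' @return A [timestamped_dataset], snapshots sorted by time.
#' @export
read_timestamped_expression <- function(path, times = NULL,
                                        time_col = "time",
                                        source_label = NULL) {
  if (length(path) > 1L || !is.null(times)) {
    if (is.null(times) || length(times) != length(path))
      snap_error("multi-file layout requires one time stamp per file",
                 "snapgrn_bad_layout")
    tabs <- lapply(path, .read_delim_auto)
    genes <- names(tabs[[1L]])
    .check_gene_cols(genes, path[[1L]])
    snaps <- vector("list", length(tabs))
    for (k in seq_along(tabs)) {
      tk <- tabs[[k]]
      if (!setequal(names(tk), genes))
        snap_error(sprintf("gene set in '%s' does not match '%s'",
                           path[[k]], path[[1L]]), "snapgrn_gene_mismatch")
      snaps[[k]] <- .as_expression_matrix(tk[genes], path[[k]])
    }
    return(timestamped_dataset(snaps, times, gene_names = genes,
                               source_label = source_label %||%
                                 paste(path, collapse = ";")))
  }
  tab <- .read_delim_auto(path)
  if (!time_col %in% names(tab))
    snap_error(sprintf("column '%s' not found in '%s'", time_col, path),
               "snapgrn_bad_layout")
  tvals <- tab[[time_col]]
  if (!is.numeric(tvals))
    snap_error("time column must be numeric", "snapgrn_bad_layout")
  genes <- names(tab)[names(tab) != time_col]
  .check_gene_cols(genes, path)
  bad <- !vapply(tab[genes], is.numeric, TRUE)
  if (any(bad))
    snap_error(sprintf("non-numeric expression column(s) in '%s': %s", path,
                       paste(genes[bad], collapse = ", ")),
               "snapgrn_non_numeric")
  ut <- sort(unique(tvals))
  if (length(ut) < 2L)
    snap_error("fewer than 2 time points in expression file",
               "snapgrn_too_few_timepoints")
  snaps <- lapply(ut, function(t)
    .as_expression_matrix(tab[tvals == t, genes, drop = FALSE], path))
  timestamped_dataset(snaps, ut, gene_names = genes,
                      source_label = source_label %||% path)
}

.check_gene_cols <- function(genes, path) {
  if (length(genes) == 0L)
    snap_error(sprintf("no gene columns in '%s'", path), "snapgrn_bad_layout")
  if (anyDuplicated(genes))
    snap_error(sprintf("duplicate gene names in '%s': %s", path,
                       paste(unique(genes[duplicated(genes)]), collapse = ", ")),
               "snapgrn_duplicate_genes")
  invisible(genes)
}

.as_expression_matrix <- function(df, path) {
  bad <- !vapply(df, is.numeric, TRUE)
  if (any(bad))
    snap_error(sprintf("non-numeric expression column(s) in '%s': %s", path,
                       paste(names(df)[bad], collapse = ", ")),
               "snapgrn_non_numeric")
  m <- as.matrix(df)
  dimnames(m) <- list(NULL, names(df))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dataset in the single-file expression layout
#'
#' @param dataset a [timestamped_dataset].
#' @param path output path (TSV; a `time` column plus one column per gene).
#' @export
write_timestamped_expression <- function(dataset, path) {
  stopifnot(inherits(dataset, "timestamped_dataset"))
  rows <- do.call(rbind, dataset$snapshots)
  tab <- data.frame(time = rep(dataset$times, n_cells(dataset)),
                    check.names = FALSE)
  tab <- cbind(tab, as.data.frame(rows, check.names = FALSE))
  utils::write.table(format(tab, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gold-standard network edge list
#'
#' Reads a headerless 3-column tab-delimited edge list (regulator, target,
#' value), the layout used by GeneNetWeaver gold-standard exports. Values
#' may be signed ({-1, +1}) or use the unsigned dialect ({0, 1}), where 1
#' maps to +1 and 0 means "no edge" (the row is dropped).
#'
#' @param path edge-list file.
#' @param gene_names the full gene universe; rows naming other genes are an
#'   error. Required because genes without edges would otherwise vanish.
#' @return A [gene_network].
#' @export
read_network_edgelist <- function(path, gene_names) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("regulator", "target", "value"))
  net <- gene_network(gene_names)
  if (nrow(tab) == 0L) return(net)
  unknown <- setdiff(unique(c(tab$regulator, tab$target)), gene_names)
  if (length(unknown) > 0L)
    snap_error(sprintf("unknown gene(s) in edge list: %s",
                       paste(unknown, collapse = ", ")),
               "snapgrn_unknown_gene")
  if (any(tab$regulator == tab$target))
    snap_error("self-loop not permitted in edge list", "snapgrn_self_loop")
  if (!is.numeric(tab$value) || !all(tab$value %in% c(-1, 0, 1)))
    snap_error("edge values must be in {-1, 0, 1}", "snapgrn_bad_sign")
  tab$value[tab$value == 0] <- NA  # unsigned dialect: 0 = absent edge
  tab <- tab[!is.na(tab$value), , drop = FALSE]
  A <- net$adjacency
  A[cbind(match(tab$regulator, gene_names),
          match(tab$target, gene_names))] <- as.integer(tab$value)
  gene_network(gene_names, A)
}

#' Write a network as a 3-column signed edge list
#'
#' @param network a [gene_network].
#' @param path output TSV path (regulator TAB target TAB sign, no header).
#' @export
write_network_edgelist <- function(network, path) {
  stopifnot(inherits(network, "gene_network"))
  idx <- which(network$adjacency != 0L, arr.ind = TRUE)
  tab <- data.frame(regulator = network$gene_names[idx[, 1L]],
                    target = network$gene_names[idx[, 2L]],
                    sign = network$adjacency[idx])
  tab <- tab[order(tab$regulator, tab$target), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write / read a ranked edge list
#'
#' The output is a 5-column TSV (rank, regulator, target, score, sign),
#' one row per candidate edge in descending score order. Scores are
#' printed with 15 significant digits so that a write/read round trip
#' reproduces the list exactly at that precision.
#'
#' @param ranked a [ranked_edges] object.
#' @param path output path.
#' @export
write_ranked_edges <- function(ranked, path) {
  stopifnot(inherits(ranked, "ranked_edges"))
  tab <- as.data.frame(ranked)
  tab$score <- formatC(tab$score, digits = 15, format = "g")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_edges
#' @param gene_names optional canonical gene order; defaults to the sorted
#'   union of genes in the file.
#' @export
read_ranked_edges <- function(path, gene_names = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("regulator", "target", "score", "sign")
  if (!all(req %in% names(tab)))
    snap_error("ranked-edge file must have columns rank, regulator, target, score, sign",
               "snapgrn_bad_ranked_edges")
  ranked_edges(tab[req], gene_names = gene_names)
}
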