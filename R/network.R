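#' Sample Pearson correlation of two vectors
#'
#' Thin wrapper around [stats::cor()] that enforces the preconditions of
#' network construction: equal lengths of at least 3 and non-constant
#' vectors. A constant vector has undefined correlation; `NA` is returned
#' with a warning (the network builder treats it as no edge).
#'
#' @param x,y Numeric vectors.
#' @return The sample Pearson correlation in [-1, 1], or `NA`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have the same length")
  if (length(x) < 3L) stop("need >= 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

# Inclusive threshold comparison with a tiny guard for double rounding
# (e.g. r = 4/5 computed by cor() must pass a literal 0.8 threshold).
meets_threshold <- function(r, threshold, mode) {
  v <- if (mode == "absolute") abs(r) else r
  !is.na(v) & v >= threshold - 1e-12
}

#' Build a thresholded bipartite lncRNA-mRNA co-expression network
#'
#' Computes the sample Pearson correlation for every (lncRNA, mRNA) feature
#' pair across samples and keeps pairs meeting the threshold: `|r| >=
#' threshold` in `"absolute"` mode (default) or `r >= threshold` in
#' `"signed"` mode. The boundary is inclusive — an r exactly equal to the
#' threshold yields an edge. Only across-biotype pairs are tested, so the
#' resulting graph is bipartite by construction. Constant features
#' (undefined correlation) contribute no edges, with a warning.
#'
#' @param x An [expr_matrix] containing both biotypes.
#' @param threshold Correlation threshold in (0, 1] (default 0.8).
#' @param mode `"absolute"` or `"signed"`.
#' @return An object of class `coexpression_network`: list with `edges`
#'   (data.frame `lnc_id`, `mrna_id`, `r`), `nodes` (data.frame `id`,
#'   `biotype` — all candidate features), `threshold`, `mode`.
#' @examples
#' sim <- generate_expression(synthetic_config(n_case = 15, n_control = 15,
#'                                             n_noise = 100, seed = 1))
#' net <- build_network(sim$matrix, threshold = 0.8)
#' net
#' @export
build_network <- function(x, threshold = 0.8,
                          mode = c("absolute", "signed")) {
  stopifnot(inherits(x, "expr_matrix"))
  mode <- match.arg(mode)
  if (threshold <= 0 || threshold > 1) stop("'threshold' must be in (0, 1]")
  bt <- biotypes(x)
  lnc <- names(bt)[bt == "lncRNA"]
  mrna <- names(bt)[bt == "mRNA"]
  if (!length(lnc) || !length(mrna))
    stop("network needs both lncRNA and mRNA features")
  v <- exprs(x)
  const <- apply(v, 1L, stats::sd) == 0
  if (any(const))
    warning(sum(const), " constant feature(s) have undefined correlation ",
            "and form no edges")
  r <- suppressWarnings(stats::cor(t(v[lnc, , drop = FALSE]),
                                   t(v[mrna, , drop = FALSE])))
  hit <- which(meets_threshold(r, threshold, mode), arr.ind = TRUE)
  edges <- data.frame(lnc_id = lnc[hit[, 1L]], mrna_id = mrna[hit[, 2L]],
                      r = r[hit])
  edges <- edges[order(edges$lnc_id, edges$mrna_id), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges,
                 nodes = data.frame(id = c(lnc, mrna),
                                    biotype = rep(c("lncRNA", "mRNA"),
                                                  c(length(lnc),
                                                    length(mrna)))),
                 threshold = threshold, mode = mode),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  deg <- degree_summary(x)
  cat(sprintf(paste0("coexpression_network: %d edges over %d lncRNA / %d ",
                     "mRNA candidates (%s |r| >= %g)\n"),
              nrow(x$edges), sum(x$nodes$biotype == "lncRNA"),
              sum(x$nodes$biotype == "mRNA"), x$mode, x$threshold))
  cat(sprintf("connected: %d lncRNA, %d mRNA\n",
              deg$n_connected_lnc, deg$n_connected_mrna))
  invisible(x)
}

#' Degree summary of a co-expression network
#'
#' Exact per-node degree tallies and per-partition summaries, in the
#' reporting convention "one lncRNA correlates with a to b mRNAs". Degrees
#' of connected nodes only enter the min/max/mean; the handshake identity
#' (lncRNA-side degree sum = mRNA-side degree sum = edge count) always
#' holds.
#'
#' @param network A `coexpression_network`.
#' @return A list with `degree` (named vector over all nodes), `n_edges`,
#'   `n_nodes`, `n_connected_lnc`, `n_connected_mrna`, and per-partition
#'   `lnc`/`mrna` lists of `min`, `max`, `mean` degree among connected
#'   nodes (all `NA` for an empty network).
#' @export
degree_summary <- function(network) {
  stopifnot(inherits(network, "coexpression_network"))
  deg <- stats::setNames(integer(nrow(network$nodes)), network$nodes$id)
  if (nrow(network$edges)) {
    t1 <- table(network$edges$lnc_id)
    t2 <- table(network$edges$mrna_id)
    deg[names(t1)] <- as.integer(t1)
    deg[names(t2)] <- as.integer(t2)
  }
  part <- function(bt) {
    d <- deg[network$nodes$id[network$nodes$biotype == bt]]
    d <- d[d > 0L]
    if (!length(d)) return(list(min = NA, max = NA, mean = NA))
    list(min = min(d), max = max(d), mean = mean(d))
  }
  list(degree = deg, n_edges = nrow(network$edges),
       n_nodes = nrow(network$nodes),
       n_connected_lnc = sum(deg > 0L &
                               network$nodes$biotype == "lncRNA"),
       n_connected_mrna = sum(deg > 0L & network$nodes$biotype == "mRNA"),
       lnc = part("lncRNA"), mrna = part("mRNA"))
}

#' Extract the pathway subnetwork around a gene set
#'
#' Restricts a network to the mRNA nodes belonging to a pathway gene set,
#' their incident edges, and the lncRNA endpoints of those edges — the
#' "pathway plus its co-expressed lncRNAs" view.
#'
#' @param network A `coexpression_network`.
#' @param gene_set Non-empty character vector of mRNA feature ids.
#' @return A `coexpression_network`; empty (with a warning) when the gene
#'   set does not intersect the network's mRNAs.
#' @export
pathway_subnetwork <- function(network, gene_set) {
  stopifnot(inherits(network, "coexpression_network"))
  gene_set <- unique(as.character(gene_set))
  if (!length(gene_set)) stop("empty gene set")
  mrna_keep <- intersect(
    network$nodes$id[network$nodes$biotype == "mRNA"], gene_set)
  edges <- network$edges[network$edges$mrna_id %in% mrna_keep, ,
                         drop = FALSE]
  if (!nrow(edges))
    warning("gene set does not intersect the network's connected mRNAs")
  rownames(edges) <- NULL
  lnc_keep <- unique(edges$lnc_id)
  nodes <- network$nodes[network$nodes$id %in% c(lnc_keep, mrna_keep), ,
                         drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(edges = edges, nodes = nodes,
                 threshold = network$threshold, mode = network$mode),
            class = "coexpression_network")
}

#' Export a co-expression network for Cytoscape
#'
#' `"sif"` writes simple-interaction-format lines
#' `lnc_id<TAB>coexp<TAB>mrna_id`; `"graphml"` writes GraphML through
#' igraph with a `biotype` node attribute and an `r` edge attribute;
#' `"edge-tsv"` writes a three-column table (`lnc_id`, `mrna_id`, `r`)
#' whose write/read round trip through [read_edge_tsv()] is lossless to 6
#' decimals.
#'
#' @param network A `coexpression_network`.
#' @param path Output path.
#' @param format `"sif"`, `"graphml"` or `"edge-tsv"`.
#' @return Invisibly, `path`.
#' @export
export_graph <- function(network, path,
                         format = c("sif", "graphml", "edge-tsv")) {
  stopifnot(inherits(network, "coexpression_network"))
  format <- match.arg(format)
  e <- network$edges
  if (format == "sif") {
    writeLines(if (nrow(e)) paste(e$lnc_id, "coexp", e$mrna_id, sep = "\t")
               else character(0), path)
  } else if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      e[, c("lnc_id", "mrna_id", "r")], directed = FALSE,
      vertices = network$nodes)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    df <- e
    df$r <- sprintf("%.10g", df$r)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a co-expression network back from an edge TSV
#'
#' @param path Path written by [export_graph(format = "edge-tsv")].
#' @param nodes Optional node table (`id`, `biotype`); defaults to the
#'   nodes present in the edges.
#' @param threshold,mode Metadata to attach (defaults: the minimum edge
#'   |r| and `"absolute"`).
#' @return A `coexpression_network`.
#' @export
read_edge_tsv <- function(path, nodes = NULL, threshold = NULL,
                          mode = "absolute") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "character",
                                         "numeric"))
  names(df) <- c("lnc_id", "mrna_id", "r")
  if (is.null(nodes))
    nodes <- data.frame(id = c(unique(df$lnc_id), unique(df$mrna_id)),
                        biotype = rep(c("lncRNA", "mRNA"),
                                      c(length(unique(df$lnc_id)),
                                        length(unique(df$mrna_id)))))
  if (is.null(threshold))
    threshold <- if (nrow(df)) min(abs(df$r)) else 1
  structure(list(edges = df, nodes = nodes, threshold = threshold,
                 mode = mode),
            class = "coexpression_network")
}
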