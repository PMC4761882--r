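#' Per-feature two-group fold changes
#'
#' Summarizes each feature by its group means on the log2 scale, the log2
#' fold change (case mean minus control mean), the linear fold
#' `2^|log2FC|`, and a direction call: `up` when `log2FC >= lfc_cutoff`,
#' `down` when `log2FC <= -lfc_cutoff`, `flat` otherwise. The default
#' cutoff of 1 (two-fold) is a reporting convention, not a significance
#' test.
#'
#' @param x An [expr_matrix] of log2 intensities.
#' @param labels Class labels from [class_labels()].
#' @param lfc_cutoff Absolute log2-fold-change threshold for the
#'   `up`/`down` call (default 1).
#' @return A data.frame with columns `feature_id`, `biotype`, `mean_case`,
#'   `mean_control`, `log2_fold_change`, `linear_fold`, `direction`.
#' @export
fold_change <- function(x, labels, lfc_cutoff = 1) {
  stopifnot(inherits(x, "expr_matrix"), lfc_cutoff >= 0)
  lab <- check_labels(labels, samples(x))
  v <- exprs(x)
  case_lv <- levels(lab)[2L]
  mean_case <- rowMeans(v[, lab == case_lv, drop = FALSE])
  mean_control <- rowMeans(v[, lab != case_lv, drop = FALSE])
  lfc <- mean_case - mean_control
  data.frame(feature_id = features(x), biotype = unname(biotypes(x)),
             mean_case = mean_case, mean_control = mean_control,
             log2_fold_change = lfc, linear_fold = 2^abs(lfc),
             direction = ifelse(lfc >= lfc_cutoff, "up",
                                ifelse(lfc <= -lfc_cutoff, "down", "flat")),
             row.names = NULL)
}

#' Hierarchical clustering for heatmap ordering
#'
#' Agglomerative clustering of features or samples with the microarray
#' convention of correlation distance (`1 - Pearson r`) and average
#' linkage, as used to order two-group expression heatmaps. A constant
#' vector has undefined correlation; it is placed at distance 1 from
#' everything, with a warning.
#'
#' @param x An [expr_matrix].
#' @param axis `"features"` (rows) or `"samples"` (columns); the chosen
#'   axis must have >= 2 items.
#' @return A list of class `dendro` with `merge`, `height`, `order`
#'   (leaf positions), `labels`, `leaf_order` (labels in dendrogram
#'   order), and the underlying [stats::hclust] object as `hclust`.
#' @export
hierarchical_cluster <- function(x, axis = c("features", "samples")) {
  stopifnot(inherits(x, "expr_matrix"))
  axis <- match.arg(axis)
  m <- if (axis == "features") exprs(x) else t(exprs(x))
  if (nrow(m) < 2L) stop("need >= 2 ", axis, " to cluster")
  r <- suppressWarnings(stats::cor(t(m)))
  if (anyNA(r)) {
    warning("constant vector(s) with undefined correlation; using distance 1")
    r[is.na(r)] <- 0
  }
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "average")
  structure(list(merge = hc$merge, height = hc$height, order = hc$order,
                 labels = hc$labels, leaf_order = hc$labels[hc$order],
                 hclust = hc, axis = axis),
            class = "dendro")
}

#' @export
print.dendro <- function(x, ...) {
  cat(sprintf("dendro: %d %s, average linkage on 1 - Pearson r\n",
              length(x$labels), x$axis))
  invisible(x)
}

#' Export a dendrogram as a JSON merge list or Newick tree
#'
#' JSON serializes the merge table (`(node, node, height)` triples in
#' [stats::hclust] convention: negative entries are leaves) together with
#' labels and leaf order; Newick goes through [ape::as.phylo()].
#'
#' @param dendro A `dendro` from [hierarchical_cluster()].
#' @param path Output path.
#' @param format `"json"` or `"newick"`.
#' @return Invisibly, `path`.
#' @export
export_dendrogram <- function(dendro, path, format = c("json", "newick")) {
  stopifnot(inherits(dendro, "dendro"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      list(merge = dendro$merge, height = dendro$height,
           labels = dendro$labels, leaf_order = dendro$leaf_order),
      path, digits = NA, auto_unbox = FALSE)
  } else {
    ape::write.tree(ape::as.phylo(dendro$hclust), file = path)
  }
  invisible(path)
}

#' Relative qPCR quantification by the 2^-ddCt method
#'
#' For each target gene: per-sample delta-Ct is the target Ct minus the
#' reference-gene Ct in the same sample; delta-delta-Ct is the case-group
#' mean delta-Ct minus the control-group mean (unpaired design); the
#' relative fold change is `2^(-ddCt)`. Values above 1 mean higher
#' expression in cases; `fold_magnitude` reports the fold in the
#' "x-fold higher / x-fold lower" convention (the reciprocal for folds
#' below 1).
#'
#' @param ct A `ct_table` (see [generate_ct_table()]) or a list with
#'   elements `ct` (gene x sample Ct matrix including the reference row),
#'   `reference` (reference gene id) and `labels` ([class_labels()]).
#' @return A data.frame with columns `gene`, `delta_delta_ct`,
#'   `fold_change`, `fold_magnitude`, `direction`.
#' @examples
#' tab <- generate_ct_table(planted_fold_changes = c(8.1, 0.5), seed = 3)
#' ddct_fold_change(tab)
#' @export
ddct_fold_change <- function(ct) {
  m <- ct$ct
  if (!is.matrix(m) || !is.numeric(m)) stop("'ct$ct' must be a numeric matrix")
  if (any(!is.finite(m)) || any(m <= 0)) stop("Ct values must be finite and > 0")
  if (!ct$reference %in% rownames(m))
    stop("reference gene '", ct$reference, "' not measured")
  lab <- check_labels(ct$labels, colnames(m))
  case_lv <- levels(lab)[2L]
  dct <- sweep(m, 2L, m[ct$reference, ])
  targets <- setdiff(rownames(m), ct$reference)
  ddct <- rowMeans(dct[targets, lab == case_lv, drop = FALSE]) -
    rowMeans(dct[targets, lab != case_lv, drop = FALSE])
  fold <- 2^(-ddct)
  data.frame(gene = targets, delta_delta_ct = ddct, fold_change = fold,
             fold_magnitude = ifelse(fold >= 1, fold, 1 / fold),
             direction = ifelse(fold >= 1, "up", "down"),
             row.names = NULL)
}
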