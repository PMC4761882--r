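#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution of
#' log2 intensities: each column's values are replaced by the mean of the
#' column-wise sorted vectors at the corresponding rank, with ties averaged.
#' The heavy lifting is delegated to [limma::normalizeQuantiles()], the
#' standard microarray implementation. The operation preserves within-sample
#' ranks and is idempotent.
#'
#' @param x An [expr_matrix] with at least two samples.
#' @return A quantile-normalized [expr_matrix].
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  if (ncol(exprs(x)) < 2L)
    stop("quantile normalization needs >= 2 samples")
  v <- limma::normalizeQuantiles(exprs(x), ties = TRUE)
  dimnames(v) <- dimnames(exprs(x))
  expr_matrix(v, biotypes(x))
}

#' Variance-filter features
#'
#' Keeps features with sample variance at or above `min_variance`, then the
#' `max_features` highest-variance features, ordered by descending variance
#' (ties keep input order). Samples are never reordered. This is the
#' parameterized stand-in for the candidate pre-selection that precedes
#' mRMR ranking; no published cutoff is assumed.
#'
#' @param x An [expr_matrix].
#' @param min_variance Minimum per-feature variance (default 0).
#' @param max_features Maximum number of features retained (default all).
#' @return A filtered [expr_matrix]; an error if nothing survives.
#' @export
filter_features <- function(x, min_variance = 0, max_features = Inf) {
  stopifnot(inherits(x, "expr_matrix"), min_variance >= 0, max_features >= 1)
  v <- apply(exprs(x), 1L, stats::var)
  keep <- which(v >= min_variance)
  if (!length(keep)) stop("all features removed by the variance filter")
  ord <- keep[order(-v[keep])]          # radix sort: stable in input order
  if (length(ord) > max_features) ord <- ord[seq_len(max_features)]
  x[ord, ]
}
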