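#' Discretize an expression matrix into three states
#'
#' Mutual information on continuous intensities requires discretization.
#' Each feature is binned around its own mean: with per-feature mean `mu`
#' and standard deviation `sigma`, a value below `mu - t*sigma` becomes
#' state -1, above `mu + t*sigma` becomes +1, and 0 otherwise. A constant
#' feature (`sigma = 0`) maps entirely to state 0. The default `t = 0.5`
#' follows the convention of the mRMR literature on microarray data.
#'
#' @param x An [expr_matrix].
#' @param t Threshold multiplier (> 0) in units of per-feature standard
#'   deviations.
#' @return An object of class `disc_matrix`: list with `states` (integer
#'   matrix in \{-1, 0, +1\}), `bin_edges` (feature x 2 matrix of low/high
#'   thresholds) and `biotype`.
#' @export
discretize <- function(x, t = 0.5) {
  stopifnot(inherits(x, "expr_matrix"), is.numeric(t), length(t) == 1L, t > 0)
  v <- exprs(x)
  mu <- rowMeans(v)
  sigma <- apply(v, 1L, stats::sd)
  lo <- mu - t * sigma
  hi <- mu + t * sigma
  states <- matrix(0L, nrow(v), ncol(v), dimnames = dimnames(v))
  states[v < lo] <- -1L
  states[v > hi] <- 1L
  states[sigma == 0, ] <- 0L   # degenerate features carry no information
  structure(list(states = states,
                 bin_edges = cbind(low = lo, high = hi),
                 biotype = biotypes(x)),
            class = "disc_matrix")
}

#' @export
print.disc_matrix <- function(x, ...) {
  cat(sprintf("disc_matrix: %d features x %d samples, states {-1, 0, +1}\n",
              nrow(x$states), ncol(x$states)))
  invisible(x)
}

# Plug-in MI (bits) from a joint count table. 0*log0 := 0; tiny negative
# rounding residue is clamped to zero so MI is always >= 0.
mi_from_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0L) return(0)
  nz <- counts > 0
  r <- rowSums(counts)[row(counts)[nz]]
  cc <- colSums(counts)[col(counts)[nz]]
  cij <- counts[nz]
  i <- sum(cij / n * log2(cij * n / (r * cc)))
  max(i, 0)
}

#' Plug-in mutual information between two discrete vectors
#'
#' Empirical (frequency plug-in) mutual information
#' `I(x;y) = sum p(x,y) log2( p(x,y) / (p(x) p(y)) )` over observed state
#' pairs, with `0 log 0 = 0` and probabilities estimated by relative
#' frequency. Reported in bits (log base 2); only rankings matter
#' downstream so the base is a convention. Symmetric and non-negative;
#' `mutual_information(x, x)` equals the empirical entropy of `x`.
#'
#' @param x,y Discrete vectors of equal length (integer states, factors or
#'   character labels).
#' @return Mutual information in bits (a single non-negative number).
#' @examples
#' mutual_information(c(-1, -1, 1, 1), c(-1, -1, 1, 1)) # 1 bit
#' mutual_information(c(-1, -1, 1, 1), c(-1, 1, -1, 1)) # 0
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have the same length")
  if (!length(x)) stop("empty vectors")
  mi_from_counts(table(as.character(x), as.character(y)))
}

# Vectorized MI of every row of an integer state matrix (values in
# {-1,0,1}) against one state vector y. Joint counts for all rows at once
# via indicator cross-products; this is the hot path of mrmr_select.
mi_profile <- function(states, y) {
  n <- ncol(states)
  cy <- vapply(c(-1L, 0L, 1L), function(b) as.numeric(y == b), numeric(n))
  acc <- numeric(nrow(states))
  rmarg <- vapply(c(-1L, 0L, 1L), function(a) rowSums(states == a),
                  numeric(nrow(states)))
  cmarg <- colSums(cy)
  for (ai in 1:3) {
    A <- (states == c(-1L, 0L, 1L)[ai]) + 0
    cnt <- A %*% cy                      # N x 3 joint counts for x-state ai
    for (bi in 1:3) {
      cab <- cnt[, bi]
      nz <- cab > 0
      if (any(nz))
        acc[nz] <- acc[nz] + cab[nz] / n *
          log2(cab[nz] * n / (rmarg[nz, ai] * cmarg[bi]))
    }
  }
  pmax(acc, 0)
}

# Encode two-level class labels as states aligned to given sample ids.
label_states <- function(labels, sample_ids) {
  lab <- check_labels(labels, sample_ids)
  ifelse(as.integer(lab) == 2L, 1L, -1L)
}

#' Relevance of a feature to the class
#'
#' The relevance `D` of a discretized feature is its mutual information
#' with the case/control class vector, using the same plug-in estimator as
#' [mutual_information()].
#'
#' @param feature Discrete state vector, named by sample id or aligned to
#'   `names(labels)`.
#' @param labels Class labels from [class_labels()].
#' @return `D` in bits.
#' @export
relevance <- function(feature, labels) {
  ids <- if (!is.null(names(feature))) names(feature) else names(labels)
  mutual_information(feature, label_states(labels, ids))
}

#' Redundancy of a candidate feature against a selected set
#'
#' The redundancy `R` of a candidate is the mean mutual information between
#' the candidate and each already-selected feature; by convention `R = 0`
#' for an empty selected set (the first selection round).
#'
#' @param candidate Discrete state vector.
#' @param selected_set List of discrete state vectors (possibly empty).
#' @return `R` in bits.
#' @export
redundancy <- function(candidate, selected_set) {
  if (!length(selected_set)) return(0)
  mean(vapply(selected_set,
              function(s) mutual_information(candidate, s), numeric(1L)))
}

#' Greedy mRMR feature selection
#'
#' Iteratively selects `k` features balancing maximum relevance to the
#' class against minimum redundancy with the already-selected set. Round 1
#' picks the feature with maximal relevance `D`; each later round picks,
#' among the not-yet-selected features, the maximizer of `D - R` (scheme
#' `"MID"`, the default mutual-information difference) or
#' `D / (R + 1e-12)` (scheme `"MIQ"`, the quotient variant). Ties are
#' broken by input order, so the selection is deterministic.
#'
#' @param x A `disc_matrix` from [discretize()].
#' @param labels Class labels from [class_labels()].
#' @param k Number of features to select, `1 <= k <=` number of features.
#' @param scheme `"MID"` or `"MIQ"`.
#' @return An object of class `mrmr_selection`: list with `selected` (a
#'   data.frame with columns `h` (selection round), `feature_id`,
#'   `biotype`, `D`, `R`, `score`), `scheme`, `total_features`,
#'   `selected_count`, `remaining` (ids not selected).
#' @examples
#' cfg <- synthetic_config(n_informative = 5, n_redundant = 2, n_noise = 20,
#'                         seed = 1)
#' sim <- generate_expression(cfg)
#' sel <- mrmr_select(discretize(sim$matrix), sim$labels, k = 5)
#' sel$selected
#' @export
mrmr_select <- function(x, labels, k, scheme = c("MID", "MIQ")) {
  stopifnot(inherits(x, "disc_matrix"))
  scheme <- match.arg(scheme)
  states <- x$states
  N <- nrow(states)
  if (k < 1L || k > N) stop("'k' must be between 1 and ", N)
  cls <- label_states(labels, colnames(states))
  D <- mi_profile(states, cls)
  eps <- 1e-12
  sum_mi <- numeric(N)        # running sum of MI with selected features
  picked <- integer(0L)
  rec <- vector("list", k)
  for (h in seq_len(k)) {
    m <- h - 1L
    R <- if (m == 0L) numeric(N) else sum_mi / m
    score <- if (scheme == "MID") D - R else D / (R + eps)
    score[picked] <- -Inf
    # earliest input index within a relative hair of the maximum wins, so
    # mathematically tied candidates resolve by input order regardless of
    # float summation order
    mx <- max(score)
    j <- which(score >= mx - 1e-9 * max(1, abs(mx)))[1L]
    rec[[h]] <- data.frame(h = h, feature_id = rownames(states)[j],
                           biotype = unname(x$biotype[rownames(states)[j]]),
                           D = D[j], R = R[j], score = score[j])
    picked <- c(picked, j)
    if (h < k) sum_mi <- sum_mi + mi_profile(states, states[j, ])
  }
  structure(list(selected = do.call(rbind, rec),
                 scheme = scheme,
                 total_features = N,
                 selected_count = k,
                 remaining = rownames(states)[-picked]),
            class = "mrmr_selection")
}

#' @export
print.mrmr_selection <- function(x, ...) {
  cat(sprintf("mrmr_selection (%s): %d of %d features\n",
              x$scheme, x$selected_count, x$total_features))
  print(utils::head(x$selected, 10L))
  if (x$selected_count > 10L) cat("...\n")
  invisible(x)
}

#' Maximum-relevance (MaxRel) feature table
#'
#' Ranks every candidate feature purely by its relevance `D` to the class,
#' in descending order with ties kept in input order — the companion table
#' to the redundancy-penalized [mrmr_select()] ranking.
#'
#' @inheritParams mrmr_select
#' @return A data.frame with columns `rank`, `feature_id`, `biotype`, `D`.
#' @export
maxrel_table <- function(x, labels) {
  stopifnot(inherits(x, "disc_matrix"))
  states <- x$states
  D <- mi_profile(states, label_states(labels, colnames(states)))
  ord <- order(-D)            # radix: stable, preserves input order on ties
  data.frame(rank = seq_len(nrow(states)),
             feature_id = rownames(states)[ord],
             biotype = unname(x$biotype[rownames(states)[ord]]),
             D = D[ord])
}

#' Write an mRMR or MaxRel table as TSV
#'
#' @param x An `mrmr_selection` or the data.frame from [maxrel_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(x, path) {
  df <- if (inherits(x, "mrmr_selection")) x$selected else x
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
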