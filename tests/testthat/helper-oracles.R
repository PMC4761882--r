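# Independent oracles, deliberately written along different code paths than
# the package implementation.

# MI via the entropy decomposition H(x) + H(y) - H(x,y), using table().
mi_entropy <- function(x, y) {
  ent <- function(tab) {
    p <- as.numeric(tab) / sum(tab)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  ent(table(x)) + ent(table(y)) - ent(table(paste(x, y)))
}

# Exact-arithmetic MI from a joint count table with small integer counts:
# n * I = sum_ij n_ij * [log2(n_ij * n) - log2(r_i * c_j)].  Every integer
# involved is <= 64, so prime exponents (2, 3, 5, 7) of the full product
# are accumulated exactly in integer arithmetic; the only floating step is
# one log2 per prime at the very end.
mi_exact_counts <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  primes <- c(2L, 3L, 5L, 7L)
  pexp <- function(m) {       # prime exponent vector of integer m >= 1
    e <- integer(4L)
    for (i in seq_along(primes)) {
      while (m %% primes[i] == 0L) { e[i] <- e[i] + 1L; m <- m %/% primes[i] }
    }
    stopifnot(m == 1L)
    e
  }
  acc <- integer(4L)
  r <- rowSums(counts); cc <- colSums(counts)
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    cij <- counts[i, j]
    if (cij > 0)
      acc <- acc + cij * (pexp(cij) + pexp(n) - pexp(r[i]) - pexp(cc[j]))
  }
  sum(acc * log2(primes)) / n
}

# Brute-force greedy mRMR: rescans every remaining candidate each round,
# recomputing relevance and redundancy from scratch with mi_entropy.
greedy_oracle <- function(states, cls, k, scheme = "MID", eps = 1e-12) {
  N <- nrow(states)
  remaining <- seq_len(N)
  selected <- integer(0L)
  D <- vapply(seq_len(N), function(i) mi_entropy(states[i, ], cls),
              numeric(1L))
  for (h in seq_len(k)) {
    sc <- vapply(remaining, function(i) {
      R <- if (!length(selected)) 0 else
        mean(vapply(selected,
                    function(s) mi_entropy(states[i, ], states[s, ]),
                    numeric(1L)))
      if (scheme == "MID") D[i] - R else D[i] / (R + eps)
    }, numeric(1L))
    # earliest index within a relative hair of the maximum (same tie rule
    # as the implementation, reached by an independent computation)
    mx <- max(sc)
    best <- remaining[which(sc >= mx - 1e-9 * max(1, abs(mx)))[1L]]
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
  }
  selected
}

# Exhaustive hypergeometric upper tail: enumerate every possible draw of
# list_size items from the universe and count draws with >= overlap
# category members.
enum_hypergeom <- function(overlap, list_size, category_size,
                           universe_size) {
  draws <- utils::combn(universe_size, list_size)
  in_cat <- colSums(draws <= category_size)  # category = items 1..cat_size
  sum(in_cat >= overlap) / ncol(draws)
}

# Brute-force thresholded bipartite edge list via a double loop.
brute_edges <- function(x, threshold, mode = "absolute") {
  bt <- biotypes(x)
  v <- exprs(x)
  out <- list()
  for (l in names(bt)[bt == "lncRNA"]) for (m in names(bt)[bt == "mRNA"]) {
    if (sd(v[l, ]) == 0 || sd(v[m, ]) == 0) next
    r <- cor(v[l, ], v[m, ])
    keep <- if (mode == "absolute") abs(r) >= threshold - 1e-12
            else r >= threshold - 1e-12
    if (keep) out[[length(out) + 1L]] <- data.frame(lnc_id = l, mrna_id = m,
                                                    r = r)
  }
  if (!length(out))
    return(data.frame(lnc_id = character(0), mrna_id = character(0),
                      r = numeric(0)))
  df <- do.call(rbind, out)
  df <- df[order(df$lnc_id, df$mrna_id), ]
  rownames(df) <- NULL
  df
}
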