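#' Hypergeometric / EASE over-representation p-value
#'
#' Upper-tail probability `P(X >= overlap)` that a random draw of
#' `list_size` features from a universe of `universe_size`, of which
#' `category_size` belong to the category, contains at least `overlap`
#' category members. `mode = "EASE"` applies DAVID's conservative variant,
#' substituting `overlap - 1` (floored at 0) before taking the tail.
#'
#' @param overlap Observed list-category intersection size.
#' @param list_size Size of the (mapped) gene list.
#' @param category_size Category size in the universe.
#' @param universe_size Universe size.
#' @param mode `"hypergeometric"` (default) or `"EASE"`.
#' @return A p-value in (0, 1].
#' @examples
#' hypergeom_p(4, 4, 5, 10)        # 5 / 210
#' hypergeom_p(4, 4, 5, 10, mode = "EASE")
#' @export
hypergeom_p <- function(overlap, list_size, category_size, universe_size,
                        mode = c("hypergeometric", "EASE")) {
  mode <- match.arg(mode)
  stopifnot(overlap >= 0, list_size >= 0, category_size >= 0,
            universe_size >= 1)
  if (category_size > universe_size)
    stop("category size exceeds universe size")
  if (list_size > universe_size)
    stop("list size exceeds universe size")
  if (overlap > min(list_size, category_size))
    stop("overlap exceeds list or category size")
  k <- if (mode == "EASE") max(overlap - 1L, 0L) else overlap
  # P(X >= k) via the survival function of the hypergeometric law
  stats::phyper(k - 1L, category_size, universe_size - category_size,
                list_size, lower.tail = FALSE)
}

#' Category over-representation analysis of a gene list
#'
#' Tests every category of an annotation collection for over-representation
#' of a gene list, producing the count / percent / p / -lg P / FDR table
#' used to rank GO terms and pathways. List genes outside the universe are
#' dropped first (a message reports how many); `percent` is
#' `100 * count / mapped-list-size`, the DAVID-style denominator.
#' Benjamini-Hochberg FDR is computed across all tested categories (those
#' with `count >= 1`) before any filtering; results are then sorted by
#' `neg_lg_p` (`-log10 p`) descending, filtered to `neg_lg_p > cutoff`, and
#' truncated to `top_k`.
#'
#' @param gene_list Character vector of feature ids (non-empty).
#' @param annotations An [annotation_collection].
#' @param neg_lg_p_cutoff Keep categories with `-log10(p)` strictly above
#'   this value (default 0, i.e. `p < 1`... effectively no filter at 0 only
#'   for p = 1 categories; use 2.5 for the conventional stringent cut).
#' @param top_k Maximum rows returned (default all).
#' @param mode Test variant, see [hypergeom_p()].
#' @return A data.frame with columns `category_id`, `description`,
#'   `count`, `percent`, `p_value`, `neg_lg_p`, `fdr`, sorted by
#'   `neg_lg_p` descending (ties in input category order). Attribute
#'   `mapped_list_size` records the denominator.
#' @export
enrich <- function(gene_list, annotations, neg_lg_p_cutoff = 0,
                   top_k = Inf, mode = c("hypergeometric", "EASE")) {
  stopifnot(inherits(annotations, "annotation_collection"))
  mode <- match.arg(mode)
  gene_list <- unique(as.character(gene_list))
  if (!length(gene_list)) stop("empty gene list")
  mapped <- intersect(gene_list, annotations$universe)
  dropped <- length(gene_list) - length(mapped)
  if (dropped > 0L)
    message(dropped, " list gene(s) outside the universe were dropped")
  if (!length(mapped)) stop("no list gene maps to the annotation universe")
  nu <- length(annotations$universe)
  nl <- length(mapped)
  counts <- vapply(annotations$categories,
                   function(m) length(intersect(m, mapped)), integer(1L))
  tested <- which(counts >= 1L)
  if (!length(tested)) {
    out <- data.frame(category_id = character(0), description = character(0),
                      count = integer(0), percent = numeric(0),
                      p_value = numeric(0), neg_lg_p = numeric(0),
                      fdr = numeric(0))
    attr(out, "mapped_list_size") <- nl
    return(out)
  }
  p <- vapply(tested, function(i) {
    hypergeom_p(counts[i], nl, length(annotations$categories[[i]]), nu,
                mode = mode)
  }, numeric(1L))
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(
    category_id = names(annotations$categories)[tested],
    description = unname(annotations$descriptions[tested]),
    count = unname(counts[tested]),
    percent = 100 * unname(counts[tested]) / nl,
    p_value = p, neg_lg_p = -log10(p), fdr = fdr, row.names = NULL)
  out <- out[order(-out$neg_lg_p), , drop = FALSE]   # stable: ties keep order
  out <- out[out$neg_lg_p > neg_lg_p_cutoff, , drop = FALSE]
  if (nrow(out) > top_k) out <- out[seq_len(top_k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mapped_list_size") <- nl
  out
}

#' Write an enrichment table as TSV
#'
#' @param x Data.frame from [enrich()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
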