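#' Expression matrix with feature biotypes
#'
#' Lightweight container for a log2 feature-by-sample expression matrix in
#' which every feature carries a biotype tag (`"mRNA"` or `"lncRNA"`), the
#' two partitions of the co-expression network downstream.
#'
#' @param values Numeric matrix, features in rows and samples in columns.
#'   Both dimensions must be named with unique identifiers and all values
#'   must be finite.
#' @param biotype Character vector of `"mRNA"`/`"lncRNA"` tags, either named
#'   by feature id or in row order of `values`.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   (the numeric matrix) and `biotype` (named character vector aligned to
#'   the rows).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("LNC_0001", "MRNA_0001", "MRNA_0002"),
#'                             paste0("S", 1:4)))
#' em <- expr_matrix(m, c("lncRNA", "mRNA", "mRNA"))
#' dim(em)
#' @export
expr_matrix <- function(values, biotype) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature (row) and sample (column) names")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicate sample id(s): ", paste(unique(dup), collapse = ", "))
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at feature '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  biotype <- stats::setNames(as.character(biotype), names(biotype))
  if (is.null(names(biotype))) {
    if (length(biotype) != nrow(values))
      stop("'biotype' must have one entry per feature")
    names(biotype) <- rownames(values)
  }
  missing <- setdiff(rownames(values), names(biotype))
  if (length(missing))
    stop("missing biotype for feature(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  biotype <- biotype[rownames(values)]
  bad <- setdiff(unique(biotype), c("mRNA", "lncRNA"))
  if (length(bad))
    stop("biotype must be 'mRNA' or 'lncRNA'; got: ",
         paste(bad, collapse = ", "))
  structure(list(values = values, biotype = biotype), class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (%d lncRNA, %d mRNA)\n",
              nrow(x$values), ncol(x$values),
              sum(x$biotype == "lncRNA"), sum(x$biotype == "mRNA")))
  invisible(x)
}

#' Accessors for `expr_matrix` components
#'
#' @param x An [expr_matrix].
#' @return `exprs()` the numeric matrix; `features()`/`samples()` the row and
#'   column ids; `biotypes()` the named biotype vector.
#' @rdname exprs
#' @export
exprs <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  x$values
}

#' @rdname exprs
#' @export
features <- function(x) rownames(exprs(x))

#' @rdname exprs
#' @export
samples <- function(x) colnames(exprs(x))

#' @rdname exprs
#' @export
biotypes <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  x$biotype
}

#' Subset an expression matrix by feature and/or sample ids
#'
#' @param x An [expr_matrix].
#' @param i,j Feature / sample indices or ids (as for `[`); missing keeps all.
#' @param ... Ignored.
#' @param drop Ignored; the result is always an `expr_matrix`.
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  v <- x$values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  expr_matrix(v, x$biotype[rownames(v)])
}

#' Two-group sample class labels
#'
#' Builds the sample-to-class map used as the target variable of mRMR
#' relevance and of all two-group summaries. Stored as a named factor whose
#' first level is the control (reference) class and second level the case
#' class, so that fold changes are case minus control.
#'
#' @param sample_ids Character vector of sample identifiers (unique).
#' @param class Character vector of class assignments, parallel to
#'   `sample_ids` (or named by them). Exactly two distinct values.
#' @param case Which class value is the case group. Defaults to `"case"`
#'   when present, otherwise must be given.
#'
#' @return A named factor of class assignments with levels
#'   `c(control, case)`.
#' @examples
#' class_labels(paste0("S", 1:4), c("case", "case", "control", "control"))
#' @export
class_labels <- function(sample_ids, class, case = NULL) {
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample id(s) in labels")
  class <- as.character(class)
  if (!is.null(names(class))) class <- class[sample_ids]
  if (length(class) != length(sample_ids) || anyNA(class))
    stop("every sample must have exactly one class label")
  lev <- unique(class)
  if (length(lev) != 2L)
    stop("labels must contain exactly two classes; found: ",
         paste(lev, collapse = ", "))
  if (is.null(case)) {
    if (!"case" %in% lev)
      stop("no class named 'case'; specify `case=` explicitly")
    case <- "case"
  }
  if (!case %in% lev) stop("case class '", case, "' not present in labels")
  control <- setdiff(lev, case)
  structure(factor(class, levels = c(control, case)),
            names = sample_ids, case = case)
}

# Validate labels against a sample-id vector; returns labels reordered to ids.
check_labels <- function(labels, sample_ids) {
  if (!is.factor(labels) || nlevels(labels) != 2L || is.null(names(labels)))
    stop("labels must be a two-level named factor from class_labels()")
  missing <- setdiff(sample_ids, names(labels))
  if (length(missing))
    stop("no class label for sample(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  out <- labels[sample_ids]
  if (any(table(out) == 0L)) stop("both classes must be non-empty")
  out
}

#' Gene-set annotation collection
#'
#' Categories (GO-term- or pathway-like gene sets) over a feature universe,
#' the input to over-representation analysis.
#'
#' @param categories Named list of character vectors; each element is the
#'   member feature-id set of one category. No empty categories.
#' @param descriptions Optional named character vector of human-readable
#'   term descriptions (defaults to the category ids).
#' @param universe Character vector of all feature ids the annotation covers.
#'   Every category member must be in the universe.
#'
#' @return An object of class `annotation_collection`.
#' @export
annotation_collection <- function(categories, descriptions = NULL,
                                  universe = NULL) {
  if (!is.list(categories) || is.null(names(categories)) ||
      anyDuplicated(names(categories)))
    stop("'categories' must be a uniquely named list of member-id vectors")
  categories <- lapply(categories, function(x) unique(as.character(x)))
  if (any(lengths(categories) == 0L))
    stop("empty categories are not allowed")
  if (is.null(universe)) universe <- unique(unlist(categories))
  universe <- unique(as.character(universe))
  stray <- setdiff(unlist(categories), universe)
  if (length(stray))
    stop("category member(s) outside the universe: ",
         paste(utils::head(stray, 5L), collapse = ", "))
  if (is.null(descriptions))
    descriptions <- stats::setNames(names(categories), names(categories))
  descriptions <- as.character(descriptions)
  names(descriptions) <- names(categories)
  structure(list(categories = categories, descriptions = descriptions,
                 universe = universe),
            class = "annotation_collection")
}

#' @export
print.annotation_collection <- function(x, ...) {
  cat(sprintf("annotation_collection: %d categories over %d universe features\n",
              length(x$categories), length(x$universe)))
  invisible(x)
}
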