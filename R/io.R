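#' Read an expression matrix with its biotype table
#'
#' Reads a tab-separated expression file (first column feature ids, header
#' row of sample ids, `.` decimal separator) together with a two-column
#' biotype file (`feature_id<TAB>biotype`) and returns a validated
#' [expr_matrix]. Row and column order are preserved from the file.
#'
#' Validation is strict: duplicate feature or sample ids, a feature without
#' a biotype, and any non-numeric or non-finite cell are hard errors naming
#' the offending id or cell.
#'
#' @param path Path to the matrix TSV.
#' @param biotype_path Path to the biotype TSV.
#' @return An [expr_matrix].
#' @seealso [write_matrix()]
#' @export
read_matrix <- function(path, biotype_path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  if (ncol(raw) < 2L) stop("matrix file needs a feature-id column and >= 1 sample")
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate feature id(s) in ", path, ": ", paste(dup, collapse = ", "))
  sample_ids <- colnames(raw)[-1L]
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric cell '%s' at feature '%s', sample '%s'",
                 vals[bad[1L], bad[2L]], ids[bad[1L]], sample_ids[bad[2L]]))
  }
  dimnames(num) <- list(ids, sample_ids)
  expr_matrix(num, read_biotypes(biotype_path))
}

#' Write an expression matrix and its biotype table as TSV
#'
#' Inverse of [read_matrix()]; the round trip is lossless to at least six
#' decimal places (values are written with 10 significant digits).
#'
#' @param x An [expr_matrix].
#' @param path Output path for the matrix TSV.
#' @param biotype_path Optional output path for the biotype TSV.
#' @param digits Significant digits written (default 10).
#' @return Invisibly, `path`.
#' @export
write_matrix <- function(x, path, biotype_path = NULL, digits = 10L) {
  stopifnot(inherits(x, "expr_matrix"))
  df <- data.frame(feature_id = features(x),
                   signif(exprs(x), digits),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(biotype_path)) write_biotypes(biotypes(x), biotype_path)
  invisible(path)
}

#' Read / write feature biotype tables
#'
#' Two-column TSV with header `feature_id<TAB>biotype`.
#'
#' @param path File path.
#' @return `read_biotypes()` a named character vector of biotypes.
#' @rdname biotype-io
#' @export
read_biotypes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) < 2L) stop("biotype file must have two columns")
  stats::setNames(df[[2L]], df[[1L]])
}

#' @param biotype Named character vector of biotypes.
#' @rdname biotype-io
#' @export
write_biotypes <- function(biotype, path) {
  utils::write.table(
    data.frame(feature_id = names(biotype), biotype = unname(biotype)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write two-column sample label tables
#'
#' TSV with header `sample_id<TAB>class`.
#'
#' @param path File path.
#' @param case Case class value, passed to [class_labels()].
#' @return `read_labels()` a named two-level factor.
#' @rdname label-io
#' @export
read_labels <- function(path, case = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  if (ncol(df) < 2L) stop("label file must have two columns")
  class_labels(df[[1L]], df[[2L]], case = case)
}

#' @param labels A named factor from [class_labels()].
#' @rdname label-io
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    data.frame(sample_id = names(labels), class = as.character(labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write annotation collections in GMT format
#'
#' One tab-separated line per category: id, description, then member ids.
#'
#' @param path File path.
#' @param universe Optional universe for [annotation_collection()]; defaults
#'   to the union of all members.
#' @return `read_gmt()` an [annotation_collection].
#' @rdname gmt-io
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short))
    stop("GMT line(s) with no members: ", paste(which(short), collapse = ", "))
  ids <- vapply(parts, `[[`, "", 1L)
  annotation_collection(
    categories = stats::setNames(lapply(parts, function(p) p[-(1:2)]), ids),
    descriptions = stats::setNames(vapply(parts, `[[`, "", 2L), ids),
    universe = universe)
}

#' @param annotations An [annotation_collection].
#' @rdname gmt-io
#' @export
write_gmt <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_collection"))
  lines <- vapply(names(annotations$categories), function(id) {
    paste(c(id, annotations$descriptions[[id]],
            annotations$categories[[id]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
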