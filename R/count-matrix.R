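#' Construct a tagged count matrix
#'
#' The central container of the package: a plain numeric feature-by-sample
#' matrix (features in rows, samples in columns) carrying feature/sample
#' identifiers in its dimnames, an optional sample-to-group mapping, and a
#' layer tag recording where in the workflow the matrix sits
#' (`"ground_truth"`, `"raw"` or `"processed"`).
#'
#' Using a lightly-attributed base matrix (rather than a heavier container)
#' keeps every numeric operation in the package directly expressible with
#' ordinary matrix algebra.
#'
#' @param x numeric matrix, features in rows, samples in columns. Must be
#'   nonnegative and free of missing values.
#' @param layer one of `"ground_truth"`, `"raw"`, `"processed"`.
#' @param groups optional character vector of group (condition) labels, one
#'   per sample, named by sample id or in column order.
#' @return a `count_matrix`: the input matrix with class, `layer` and
#'   `groups` attributes and guaranteed dimnames.
#' @export
count_matrix <- function(x, layer = c("raw", "ground_truth", "processed"),
                         groups = NULL) {
  layer <- match.arg(layer)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("count matrix contains missing values")
  if (any(x < 0)) stop("count matrix contains negative values")
  if (is.null(rownames(x))) rownames(x) <- sprintf("F%04d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("S%03d", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicated feature ids")
  if (anyDuplicated(colnames(x))) stop("duplicated sample ids")
  if (!is.null(groups)) {
    groups <- as.character(groups)
    if (length(groups) != ncol(x))
      stop("`groups` must have one label per sample")
    names(groups) <- colnames(x)
  }
  structure(x, class = c("count_matrix", "matrix", "array"),
            layer = layer, groups = groups)
}

#' Layer tag of a count matrix
#' @param x a `count_matrix` (or plain matrix, in which case `NULL`).
#' @return the layer string or `NULL`.
#' @export
cm_layer <- function(x) attr(x, "layer", exact = TRUE)

#' Sample group labels of a count matrix
#' @param x a `count_matrix`.
#' @return named character vector of group labels, or `NULL`.
#' @export
cm_groups <- function(x) attr(x, "groups", exact = TRUE)

# Re-tag a matrix while preserving dimnames/groups; internal.
retag <- function(x, template, layer) {
  count_matrix(x, layer = layer, groups = cm_groups(template))
}

#' @method print count_matrix
#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d features x %d samples, sparsity %.2f%%\n",
              cm_layer(x) %||% "untagged", nrow(x), ncol(x),
              100 * mean(x == 0)))
  g <- cm_groups(x)
  if (!is.null(g))
    cat("groups:", paste(sprintf("%s(%d)", names(table(g)), table(g)),
                         collapse = " "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
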