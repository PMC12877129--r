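#' Expression matrix container
#'
#' Light container for a cells-or-samples x genes expression matrix. Rows are
#' observation units (cells or bulk samples), columns are genes. The `kind`
#' flag distinguishes raw counts (non-negative integers) from normalized
#' values (e.g. log-CPM); several pipeline steps require one kind or the
#' other and refuse the wrong one.
#'
#' @param values numeric matrix or sparse `Matrix`, rows = cells/samples,
#'   columns = genes, all entries non-negative.
#' @param row_ids character vector of unique cell/sample identifiers;
#'   defaults to `rownames(values)`.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `colnames(values)`.
#' @param kind `"counts"` (integer-valued) or `"normalized"`.
#' @return An `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, row_ids = rownames(values),
                              gene_ids = colnames(values),
                              kind = c("counts", "normalized")) {
  kind <- match.arg(kind)
  if (is.null(row_ids) || is.null(gene_ids)) {
    stop_("row_ids and gene_ids are required (or set dimnames on 'values')")
  }
  row_ids <- as.character(row_ids)
  gene_ids <- as.character(gene_ids)
  if (length(row_ids) != nrow(values)) {
    stop_("length(row_ids) does not match nrow(values)")
  }
  if (length(gene_ids) != ncol(values)) {
    stop_("length(gene_ids) does not match ncol(values)")
  }
  if (anyDuplicated(row_ids)) stop_("duplicate row (cell/sample) identifiers")
  if (anyDuplicated(gene_ids)) stop_("duplicate gene identifiers")
  vals <- if (inherits(values, "Matrix")) values else as.matrix(values)
  xs <- if (inherits(vals, "sparseMatrix")) vals@x else as.numeric(vals)
  if (length(xs)) {
    if (min(xs) < 0) stop_("expression values must be non-negative")
    if (kind == "counts" && any(abs(xs - round(xs)) > 1e-8)) {
      stop_("kind = 'counts' requires integer-valued entries")
    }
  }
  dimnames(vals) <- list(row_ids, gene_ids)
  structure(
    list(values = vals, row_ids = row_ids, gene_ids = gene_ids, kind = kind),
    class = "ExpressionMatrix"
  )
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @method print ExpressionMatrix
#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix [%s]: %d %s x %d genes\n", x$kind,
              nrow(x$values),
              if (x$kind == "counts") "cells" else "rows",
              ncol(x$values)))
  invisible(x)
}

#' Subset an ExpressionMatrix by row and/or gene
#'
#' @param x an `ExpressionMatrix`.
#' @param i,j row and column indices (any form `[` accepts).
#' @param ... ignored.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  vals <- x$values
  if (missing(i)) i <- seq_len(nrow(vals))
  if (missing(j)) j <- seq_len(ncol(vals))
  expression_matrix(vals[i, j, drop = FALSE], kind = x$kind)
}

as_dense <- function(em) as.matrix(em$values)

check_kind <- function(em, kind, fun) {
  if (!inherits(em, "ExpressionMatrix")) {
    stop_(sprintf("%s() expects an ExpressionMatrix", fun))
  }
  if (em$kind != kind) {
    stop_(sprintf("%s() requires a matrix of kind '%s' (got '%s')",
                  fun, kind, em$kind))
  }
  invisible(em)
}
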