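#' Expression matrix with unit metadata
#'
#' Lightweight container for a genes x units matrix (bulk samples, single
#' cells, or spatial spots) together with per-unit metadata and the
#' transformation layer the values live on.
#'
#' @param values numeric matrix (genes x units) or sparse `Matrix`; must have
#'   row and column names.
#' @param layer one of `"counts"`, `"TPM"`, `"VST"`, `"normalized"`.
#' @param meta `data.frame` with one row per unit; must contain a `unit`
#'   column matching `colnames(values)`.
#' @param gene_lengths optional named numeric vector of gene lengths (bp),
#'   required by [compute_tpm()].
#'
#' @return An object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, layer = c("counts", "TPM", "VST", "normalized"),
                        meta = NULL, gene_lengths = NULL) {
  layer <- match.arg(layer)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("expression values must carry gene (row) and unit (column) names")
  if (anyDuplicated(rownames(values))) .stopf("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) .stopf("duplicate unit identifiers")
  if (layer == "counts") {
    v <- if (inherits(values, "Matrix")) values@x else values
    if (any(v < 0) || any(v != round(v)))
      .stopf("counts layer requires nonnegative integers")
  }
  if (layer == "TPM") {
    cs <- Matrix::colSums(values)
    if (any(abs(cs - 1e6) > 1))
      .stopf("TPM columns must sum to 1e6")
  }
  if (is.null(meta)) meta <- data.frame(unit = colnames(values))
  if (!"unit" %in% names(meta)) .stopf("meta requires a 'unit' column")
  if (!identical(as.character(meta$unit), colnames(values)))
    .stopf("meta$unit must match the column names of the values")
  if (!is.null(gene_lengths)) {
    gene_lengths <- gene_lengths[rownames(values)]
    if (anyNA(gene_lengths) || any(gene_lengths <= 0))
      .stopf("gene_lengths must be positive and cover every gene")
  }
  structure(list(values = values, layer = layer, meta = meta,
                 gene_lengths = gene_lengths),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d units, layer=%s\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' Subset an expression matrix by genes and/or units
#'
#' @param x an `expr_matrix`.
#' @param genes character vector of gene ids (NULL keeps all).
#' @param units character vector of unit ids (NULL keeps all).
#' @return an `expr_matrix` with metadata kept in step.
#' @export
subset_expr <- function(x, genes = NULL, units = NULL) {
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(units)) v <- v[, units, drop = FALSE]
  meta <- x$meta[match(colnames(v), x$meta$unit), , drop = FALSE]
  rownames(meta) <- NULL
  expr_matrix(v, layer = x$layer, meta = meta,
              gene_lengths = if (is.null(x$gene_lengths)) NULL else
                x$gene_lengths[rownames(v)])
}
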