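#' Construct a gene-by-cell expression matrix
#'
#' The central container of the package: a dense genes x cells numeric
#' matrix tagged with the species it came from and the transformation
#' layer its values live on.
#'
#' @param values Numeric matrix, genes as rows and cells as columns.
#'   Row names are gene symbols, column names are cell ids; both are
#'   required and must be unique.
#' @param species Character scalar naming the species (free-form label,
#'   e.g. `"mouse"`).
#' @param layer One of `"counts"` (non-negative raw counts),
#'   `"normcounts"` (depth-normalized, linear scale, see
#'   [normalize_counts()]), `"lognorm"` (log-normalized, see
#'   [log_normalize()]) or `"standardized"`.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `species`, `layer`.
#' @export
#' @examples
#' m <- expression_matrix(
#'   matrix(0:5, nrow = 3, dimnames = list(paste0("g", 1:3), c("c1", "c2"))),
#'   species = "mouse", layer = "counts"
#' )
#' dim(m)
expression_matrix <- function(values, species, layer = c("counts", "normcounts", "lognorm", "standardized")) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix (genes x cells)", call. = FALSE)
  }
  gene_ids <- rownames(values)
  cell_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("`values` must carry gene symbols as rownames and cell ids as colnames",
      call. = FALSE
    )
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids in expression matrix", call. = FALSE)
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids in expression matrix", call. = FALSE)
  if (!is.character(species) || length(species) != 1L || is.na(species)) {
    stop("`species` must be a single string", call. = FALSE)
  }
  if (layer %in% c("counts", "normcounts") && any(values < 0)) {
    stop(layer, " layer must be non-negative", call. = FALSE)
  }
  if (layer == "lognorm" && any(!is.finite(values))) {
    stop("lognorm layer must be finite", call. = FALSE)
  }
  structure(
    list(values = values, species = species, layer = layer),
    class = "ExpressionMatrix"
  )
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' Gene symbols of an expression matrix
#' @param m An `ExpressionMatrix`.
#' @return Character vector of gene symbols (row order).
#' @export
genes <- function(m) rownames(m$values)

#' Cell ids of an expression matrix
#' @param m An `ExpressionMatrix`.
#' @return Character vector of cell ids (column order).
#' @export
cells <- function(m) colnames(m$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix [%s, %s]: %d genes x %d cells\n",
    x$species, x$layer, nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' Subset an expression matrix by gene symbols and/or cell ids
#'
#' @param m An `ExpressionMatrix`.
#' @param genes,cells Character vectors of symbols / cell ids to keep
#'   (in the given order), or `NULL` to keep all.
#' @return An `ExpressionMatrix` restricted to the requested rows/columns.
#' @export
subset_matrix <- function(m, genes = NULL, cells = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- m$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing) > 0L) {
      stop(
        "genes not present in matrix: ", paste(utils::head(missing, 5L), collapse = ", "),
        call. = FALSE
      )
    }
    v <- v[genes, , drop = FALSE]
  }
  if (!is.null(cells)) {
    missing <- setdiff(cells, colnames(v))
    if (length(missing) > 0L) {
      stop(
        "cells not present in matrix: ", paste(utils::head(missing, 5L), collapse = ", "),
        call. = FALSE
      )
    }
    v <- v[, cells, drop = FALSE]
  }
  expression_matrix(v, species = m$species, layer = m$layer)
}

#' Depth-normalize a count matrix on the linear scale
#'
#' Scales every cell to a common total (`scale * x / total`) without a
#' log transform. This is the layer on which per-group median profiles
#' are taken before the log-and-center step of
#' [center_log_profiles()].
#'
#' @inheritParams log_normalize
#' @return An `ExpressionMatrix` on the `normcounts` layer.
#' @export
normalize_counts <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stop("normalize_counts expects the counts layer", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    stop("`scale` must be a single positive number", call. = FALSE)
  }
  totals <- colSums(m$values)
  empty <- totals == 0
  if (any(empty)) {
    warning(sum(empty), " cell(s) with zero total counts produce all-zero columns")
  }
  denom <- ifelse(empty, 1, totals)
  v <- sweep(m$values, 2L, scale / denom, "*")
  expression_matrix(v, species = m$species, layer = "normcounts")
}

#' Log-normalize a count matrix
#'
#' Per-cell library-size normalization followed by a natural-log
#' transform: each count is scaled to `scale * x / total` of its cell and
#' mapped through `ln(1 + .)`. Cells with zero total counts yield
#' all-zero columns (with a warning) rather than NaNs.
#'
#' @param m An `ExpressionMatrix` on the `counts` layer.
#' @param scale Positive scale factor applied to per-cell proportions
#'   (default 10,000, the usual convention for droplet data).
#' @return An `ExpressionMatrix` on the `lognorm` layer with the same
#'   dimensions. For every cell with nonzero total, the column of
#'   `exp(v) - 1` sums to `scale`.
#' @export
#' @examples
#' m <- expression_matrix(
#'   matrix(c(1, 1), nrow = 2, dimnames = list(c("g1", "g2"), "c1")),
#'   species = "s", layer = "counts"
#' )
#' log_normalize(m, scale = 2)$values # both entries ln(2)
log_normalize <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stop("log_normalize expects the counts layer", call. = FALSE)
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0) {
    stop("`scale` must be a single positive number", call. = FALSE)
  }
  totals <- colSums(m$values)
  empty <- totals == 0
  if (any(empty)) {
    warning(sum(empty), " cell(s) with zero total counts produce all-zero columns")
  }
  denom <- ifelse(empty, 1, totals)
  v <- log1p(sweep(m$values, 2L, scale / denom, "*"))
  v[, empty] <- 0
  expression_matrix(v, species = m$species, layer = "lognorm")
}
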