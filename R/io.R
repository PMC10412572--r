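#' Read a 10x-convention Matrix-Market count matrix
#'
#' Reads a Matrix-Market triplet file together with the usual
#' `features.tsv` / `barcodes.tsv` sidecars (optionally gzipped) and
#' returns a counts-layer [expression_matrix()]. The features file may
#' have one column (symbol) or the 10x three-column layout
#' (id, symbol, type); the symbol column is used. Duplicate symbols are
#' made unique by suffixing `.1`, `.2`, ... in order of appearance.
#'
#' @param matrix_path Path to the `.mtx` triplet file (1-based indices).
#' @param features_path Path to the features/genes TSV (no header).
#' @param barcodes_path Path to the barcodes file, one cell id per line.
#' @param species Species label attached to the result.
#' @return An `ExpressionMatrix` on the `counts` layer.
#' @export
read_counts_10x <- function(matrix_path, features_path, barcodes_path, species) {
  mm <- Matrix::readMM(matrix_path)
  feats <- utils::read.delim(features_path,
    header = FALSE, colClasses = "character",
    stringsAsFactors = FALSE
  )
  barcodes <- readLines(barcodes_path)
  # 10x layout is (id, symbol, type); a bare symbol list is also accepted
  sym_col <- if (ncol(feats) >= 2L) 2L else 1L
  symbols <- feats[[sym_col]]
  if (length(symbols) != nrow(mm)) {
    stop(sprintf(
      "features file has %d rows but matrix has %d rows",
      length(symbols), nrow(mm)
    ), call. = FALSE)
  }
  if (length(barcodes) != ncol(mm)) {
    stop(sprintf(
      "barcodes file has %d rows but matrix has %d columns",
      length(barcodes), ncol(mm)
    ), call. = FALSE)
  }
  v <- as.matrix(mm)
  if (any(v < 0)) stop("negative entries in count matrix", call. = FALSE)
  rownames(v) <- make_unique_symbols(symbols)
  colnames(v) <- barcodes
  expression_matrix(v, species = species, layer = "counts")
}

#' Write a count matrix in the 10x Matrix-Market convention
#'
#' Inverse of [read_counts_10x()]: writes `matrix.mtx`, `features.tsv`
#' (single symbol column) and `barcodes.tsv` into `dir`.
#'
#' @param m An `ExpressionMatrix` on the `counts` layer.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths of the three files written.
#' @export
write_counts_10x <- function(m, dir) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stop("write_counts_10x expects the counts layer", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(methods::as(Matrix::Matrix(m$values, sparse = TRUE), "generalMatrix"), paths[1L])
  writeLines(rownames(m$values), paths[2L])
  writeLines(colnames(m$values), paths[3L])
  invisible(paths)
}

#' Read a dense genes-by-cells TSV matrix
#'
#' Expects genes as rows, a header line of cell ids, and the gene symbol
#' in the first column.
#'
#' @param path Path to the TSV file.
#' @param species Species label attached to the result.
#' @param layer Layer tag of the stored values (default `"counts"`).
#' @return An `ExpressionMatrix`.
#' @export
read_matrix_tsv <- function(path, species, layer = "counts") {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1L, drop = FALSE])
  mode(v) <- "numeric"
  rownames(v) <- make_unique_symbols(as.character(df[[1L]]))
  expression_matrix(v, species = species, layer = layer)
}

#' Write a dense genes-by-cells TSV matrix
#' @param m An `ExpressionMatrix`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(gene = rownames(m$values), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a typed TSV table with a required-column schema
#'
#' Thin wrapper over `read.delim` that checks required columns up front
#' and preserves extra columns and row order.
#'
#' @param path Path to a TSV file with a header.
#' @param required Character vector of column names that must be present.
#' @return A `data.frame` with at least the required columns.
#' @export
read_table <- function(path, required = character()) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(
      "missing required column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  df
}

#' Write a TSV table
#' @param df A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell annotation table
#'
#' Requires columns `cell_id` and `label`; an optional `pseudotime`
#' column is validated to be finite and non-negative where present.
#'
#' @param path Path to the annotation TSV.
#' @return A data.frame with columns `cell_id`, `label` and, if present,
#'   `pseudotime`.
#' @export
read_annotation <- function(path) {
  df <- read_table(path, required = c("cell_id", "label"))
  validate_annotation(df)
}

#' Validate a cell annotation data frame
#' @param df Data frame with `cell_id`, `label`, optional `pseudotime`.
#' @return The validated data frame (invisibly unchanged).
#' @export
validate_annotation <- function(df) {
  if (anyDuplicated(df$cell_id)) stop("duplicate cell_id in annotation", call. = FALSE)
  if ("pseudotime" %in% names(df)) {
    pt <- df$pseudotime
    if (any(!is.na(pt) & (!is.finite(pt) | pt < 0))) {
      stop("pseudotime must be finite and non-negative", call. = FALSE)
    }
  }
  df
}

#' Read an Ensembl-style ortholog table
#'
#' @param path Path to a TSV with the four annotation columns.
#' @param cols Named character vector remapping the expected column
#'   names (`gene_a`, `gene_b`, `homology_type`, `confidence`) onto the
#'   file's actual ones.
#' @return A data.frame with the four canonical columns (extra columns
#'   preserved).
#' @export
read_orthologs <- function(path,
                           cols = c(
                             gene_a = "gene_a", gene_b = "gene_b",
                             homology_type = "homology_type",
                             confidence = "confidence"
                           )) {
  canonical <- c("gene_a", "gene_b", "homology_type", "confidence")
  stopifnot(all(canonical %in% names(cols)))
  df <- read_table(path, required = unname(cols[canonical]))
  for (nm in canonical) names(df)[names(df) == cols[[nm]]] <- nm
  df$confidence <- as.integer(df$confidence)
  df
}

#' Read a two-column gene alias table
#' @param path Path to a TSV with columns `alias`, `official`.
#' @return A data.frame with columns `alias`, `official`.
#' @export
read_aliases <- function(path) {
  df <- read_table(path, required = c("alias", "official"))
  if (anyDuplicated(df$alias)) stop("alias table maps an alias to several official symbols", call. = FALSE)
  df
}

#' Read a transcription-factor symbol list
#' @param path Plain-text file, one symbol per line.
#' @return Character vector of unique symbols (order preserved).
#' @export
read_tf_list <- function(path) {
  lines <- trimws(readLines(path))
  unique(lines[nzchar(lines)])
}

# ".k" suffix uniquification, first occurrence keeps the bare symbol
make_unique_symbols <- function(x) {
  if (!anyDuplicated(x)) {
    return(x)
  }
  out <- x
  counts <- new.env(parent = emptyenv())
  for (i in seq_along(x)) {
    s <- x[[i]]
    k <- if (is.null(counts[[s]])) 0L else counts[[s]]
    if (k > 0L) out[[i]] <- paste0(s, ".", k)
    counts[[s]] <- k + 1L
  }
  # collisions of a suffixed name with a pre-existing literal are not handled;
  # symbols of the form "X.1" alongside duplicate "X" would need another pass
  out
}
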