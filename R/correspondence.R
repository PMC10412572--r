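#' Per-group median expression profiles
#'
#' Builds a genes x groups matrix whose entry (g, k) is the median of
#' gene g over the cells labeled k. Median profiles are robust to the
#' heavy right tail of single-cell counts and are the standard summary
#' for cross-dataset correlation.
#'
#' @param m An `ExpressionMatrix` (any layer).
#' @param ann Annotation data.frame with columns `cell_id`, `label`
#'   covering every cell of `m`.
#' @return A `GroupProfileMatrix`: list with `values` (genes x groups
#'   matrix, group columns in first-appearance order), `species`, and
#'   `centered = FALSE`.
#' @export
group_median_profiles <- function(m, ann) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  idx <- match(cells(m), ann$cell_id)
  if (any(is.na(idx))) {
    stop("annotation is missing ", sum(is.na(idx)), " cell(s) of the matrix", call. = FALSE)
  }
  labels <- ann$label[idx]
  groups <- unique(labels)
  sizes <- table(factor(labels, levels = groups))
  if (any(sizes == 1L)) {
    warning("group(s) of size 1: ", paste(names(sizes)[sizes == 1L], collapse = ", "))
  }
  prof <- matrix(0, nrow(m$values), length(groups),
    dimnames = list(genes(m), groups)
  )
  for (k in groups) {
    prof[, k] <- apply(m$values[, labels == k, drop = FALSE], 1L, stats::median)
  }
  structure(
    list(values = prof, species = m$species, centered = FALSE),
    class = "GroupProfileMatrix"
  )
}

#' @export
print.GroupProfileMatrix <- function(x, ...) {
  cat(sprintf(
    "GroupProfileMatrix [%s%s]: %d genes x %d groups\n",
    x$species, if (x$centered) ", centered" else "",
    nrow(x$values), ncol(x$values)
  ))
  invisible(x)
}

#' Center log-transformed median profiles gene-wise
#'
#' Applies `ln(1 + x)` and removes each gene's mean across groups, so
#' every gene row has mean zero and correlations between group columns
#' reflect relative, not absolute, expression.
#'
#' @param p An uncentered `GroupProfileMatrix` with non-negative values.
#' @return The centered `GroupProfileMatrix` (`centered = TRUE`).
#' @export
#' @examples
#' p <- structure(
#'   list(
#'     values = matrix(c(0, exp(2) - 1), 1, 2,
#'       dimnames = list("g1", c("k1", "k2"))
#'     ),
#'     species = "s", centered = FALSE
#'   ),
#'   class = "GroupProfileMatrix"
#' )
#' center_log_profiles(p)$values # -1, 1
center_log_profiles <- function(p) {
  stopifnot(inherits(p, "GroupProfileMatrix"))
  if (isTRUE(p$centered)) stop("profiles are already centered", call. = FALSE)
  if (any(p$values < 0)) stop("profile values must be non-negative", call. = FALSE)
  lg <- log1p(p$values)
  v <- lg - rowMeans(lg)
  p$values <- v
  p$centered <- TRUE
  p
}

#' Cross-species correlation of group profiles over homologous gene pairs
#'
#' Pearson correlation between every group column of species A and every
#' group column of species B, computed over the shared homologous gene
#' pairs only, with genes aligned through the ortholog bijection.
#'
#' @param p_a,p_b Centered `GroupProfileMatrix` objects for the two
#'   species.
#' @param pairs Data.frame of shared gene pairs (`gene_a`, `gene_b`),
#'   at least 3 rows; see [intersect_homologous_hvgs()].
#' @return A groups_A x groups_B matrix of Pearson r with attribute
#'   `n_genes` (number of pairs used). Columns that are constant over
#'   the pair genes yield `NaN` entries and a warning.
#' @export
cross_species_correlation <- function(p_a, p_b, pairs) {
  stopifnot(inherits(p_a, "GroupProfileMatrix"), inherits(p_b, "GroupProfileMatrix"))
  if (!isTRUE(p_a$centered) || !isTRUE(p_b$centered)) {
    stop("profiles must be centered first (center_log_profiles)", call. = FALSE)
  }
  if (nrow(pairs) < 3L) stop("need at least 3 shared gene pairs", call. = FALSE)
  missing_a <- setdiff(pairs$gene_a, rownames(p_a$values))
  missing_b <- setdiff(pairs$gene_b, rownames(p_b$values))
  if (length(missing_a) + length(missing_b) > 0L) {
    stop("gene pair members absent from profiles", call. = FALSE)
  }
  va <- p_a$values[pairs$gene_a, , drop = FALSE]
  vb <- p_b$values[pairs$gene_b, , drop = FALSE]
  const_a <- apply(va, 2L, stats::sd) == 0
  const_b <- apply(vb, 2L, stats::sd) == 0
  if (any(const_a) || any(const_b)) {
    warning("constant profile column(s) produce NaN correlations")
  }
  r <- suppressWarnings(stats::cor(va, vb))
  r[const_a, ] <- NaN
  r[, const_b] <- NaN
  attr(r, "n_genes") <- nrow(pairs)
  r
}

#' Score query cells against reference group centroids
#'
#' A deterministic, correlation-based label-transfer score: each query
#' cell is correlated with every reference group profile over the shared
#' homologous gene pairs; negative correlations are rectified to zero
#' and the rest renormalized to sum to one. Cells uncorrelated with all
#' references (all r <= 0), and constant cells, get a uniform row.
#'
#' @param query An `ExpressionMatrix` on the `lognorm` layer (query
#'   species).
#' @param ref_profiles A centered `GroupProfileMatrix` (reference
#'   species).
#' @param pairs Shared gene-pair data.frame; the column named by
#'   `query_side` holds query-species symbols, the other side
#'   reference-species symbols.
#' @param query_side `"gene_a"` or `"gene_b"`.
#' @return A `LabelScoreMatrix`: list with `scores` (cells x labels,
#'   rows summing to 1) and `predicted` (named character vector,
#'   row-wise argmax, earliest label on ties).
#' @export
score_labels <- function(query, ref_profiles, pairs, query_side = c("gene_a", "gene_b")) {
  query_side <- match.arg(query_side)
  stopifnot(inherits(query, "ExpressionMatrix"), inherits(ref_profiles, "GroupProfileMatrix"))
  if (query$layer != "lognorm") stop("query must be log-normalized", call. = FALSE)
  if (!isTRUE(ref_profiles$centered)) stop("reference profiles must be centered", call. = FALSE)
  if (nrow(pairs) < 3L) stop("need at least 3 shared gene pairs", call. = FALSE)
  ref_side <- setdiff(c("gene_a", "gene_b"), query_side)
  qv <- query$values[pairs[[query_side]], , drop = FALSE]
  rv <- ref_profiles$values[pairs[[ref_side]], , drop = FALSE]
  const_q <- apply(qv, 2L, stats::sd) == 0
  if (any(const_q)) {
    warning(sum(const_q), " constant query cell(s) get uniform scores")
  }
  r <- suppressWarnings(stats::cor(qv, rv)) # cells x labels
  r[const_q, ] <- 0
  scores <- pmax(r, 0)
  rs <- rowSums(scores)
  flat <- rs == 0 | !is.finite(rs)
  scores[flat, ] <- 1 / ncol(scores)
  scores[!flat, ] <- scores[!flat, , drop = FALSE] / rs[!flat]
  predicted <- colnames(scores)[apply(scores, 1L, which.max)]
  names(predicted) <- rownames(scores)
  structure(
    list(scores = scores, predicted = predicted),
    class = "LabelScoreMatrix"
  )
}
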