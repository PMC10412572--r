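#' Gene-set module score with expression-matched binned controls
#'
#' For each cell, the mean log-normalized expression of the gene set
#' minus the mean over a pool of control genes drawn to match the set's
#' expression level: all genes are ranked by their dataset-average
#' expression into `n_bins` equal-frequency bins, and each set gene
#' contributes `n_ctrl` control genes sampled from its own bin (with
#' replacement when the bin holds fewer than `n_ctrl` genes). The
#' control pool makes the score robust to library-size and
#' expression-level artifacts: on structureless data it is centered at
#' zero.
#'
#' @param m An `ExpressionMatrix` on the `lognorm` layer.
#' @param gene_set Non-empty character vector of genes, all present in
#'   `m`.
#' @param n_bins Number of equal-frequency expression bins (default 24).
#' @param n_ctrl Control genes drawn per set gene (default 100).
#' @param seed Integer seed for the control draw (mandatory: the score
#'   is otherwise not reproducible).
#' @return Numeric vector of per-cell scores (named by cell id), with
#'   the parameters recorded in attribute `params`.
#' @export
module_score <- function(m, gene_set, n_bins = 24L, n_ctrl = 100L, seed) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "lognorm") stop("module_score expects the lognorm layer", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (length(gene_set) == 0L) stop("empty gene set", call. = FALSE)
  missing_genes <- setdiff(gene_set, genes(m))
  if (length(missing_genes) > 0L) {
    stop(
      "gene(s) absent from matrix: ", paste(utils::head(missing_genes, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  v <- m$values
  data_avg <- rowMeans(v)
  n_genes <- nrow(v)
  n_bins <- min(n_bins, n_genes)
  # equal-frequency bins over the average-expression ranking; averages
  # are rounded so that float noise (e.g. from a global shift) cannot
  # reorder genuinely tied genes
  bin <- ceiling(n_bins * rank(signif(data_avg, 9), ties.method = "first") / n_genes)
  names(bin) <- rownames(v)
  ctrl <- with_local_seed(seed, {
    unlist(lapply(gene_set, function(g) {
      members <- names(bin)[bin == bin[[g]]]
      sample(members, n_ctrl, replace = length(members) < n_ctrl)
    }), use.names = FALSE)
  })
  set_mean <- colMeans(v[gene_set, , drop = FALSE])
  ctrl_mean <- colMeans(v[ctrl, , drop = FALSE]) # duplicates kept: pooled multiset
  score <- set_mean - ctrl_mean
  attr(score, "params") <- list(n_bins = n_bins, n_ctrl = n_ctrl, seed = seed)
  score
}

#' Smooth a per-cell signal along pseudotime
#'
#' Orders cells by pseudotime and applies a sliding-window mean whose
#' width is a fixed fraction of the number of cells. The windowed mean
#' preserves monotonicity of the input; `method = "loess"` is available
#' behind the same interface for smoother curves.
#'
#' @param values Numeric vector, one value per cell.
#' @param pseudotime Numeric vector of finite pseudotimes, aligned with
#'   `values`.
#' @param window_frac Window width as a fraction of the cell count
#'   (default 0.2).
#' @param method `"window"` (default) or `"loess"`.
#' @return A data.frame with columns `pseudotime` (sorted) and `fitted`.
#' @export
trend_along_pseudotime <- function(values, pseudotime, window_frac = 0.2,
                                   method = c("window", "loess")) {
  method <- match.arg(method)
  n <- length(values)
  if (length(pseudotime) != n) stop("values and pseudotime must be aligned", call. = FALSE)
  if (n < 5L) stop("need at least 5 cells", call. = FALSE)
  if (any(!is.finite(pseudotime))) stop("pseudotime must be finite", call. = FALSE)
  ord <- order(pseudotime, values) # value-tie-break keeps the curve permutation-invariant
  pt <- pseudotime[ord]
  x <- values[ord]
  if (method == "loess") {
    fit <- stats::loess(x ~ pt, span = window_frac, degree = 2)
    return(data.frame(pseudotime = pt, fitted = stats::fitted(fit)))
  }
  w <- ceiling(window_frac * n)
  if (w %% 2L == 0L) w <- w + 1L # odd width: symmetric, unbiased in the interior
  h_lo <- (w - 1L) %/% 2L
  h_hi <- w - 1L - h_lo
  cs <- cumsum(c(0, x))
  lo <- pmax(1L, seq_len(n) - h_lo)
  hi <- pmin(n, seq_len(n) + h_hi)
  fitted <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  data.frame(pseudotime = pt, fitted = fitted)
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Per-gene two-sided Wilcoxon rank-sum tests of group A against group
#' B on the log-normalized layer. P values are exact (null CDF of the
#' rank-sum statistic) when both groups have at most `exact_max` cells
#' and the gene has no tied values; otherwise the normal approximation
#' with tie correction and continuity correction is used. Fold changes
#' are computed on the de-logged scale with a pseudocount of 1:
#' `log_fc = ln((mean(expm1(v_A)) + 1) / (mean(expm1(v_B)) + 1))`.
#' P values are Benjamini-Hochberg adjusted across all tested genes and
#' genes with `p_adj < alpha` are flagged significant.
#'
#' @param m An `ExpressionMatrix` on the `lognorm` layer.
#' @param cells_a,cells_b Disjoint non-empty cell-id vectors (>= 3 cells
#'   each).
#' @param alpha Adjusted-p significance threshold (default 1e-4).
#' @param exact_max Largest group size for which the exact null is used
#'   (default 10).
#' @return A `DEGTable` data.frame with columns `gene`, `log_fc`, `p`,
#'   `p_adj`, `significant`, `direction` (`"up"`/`"down"` in group A).
#' @export
#' @examples
#' # a single gene with A = {1,2,3}, B = {4,5,6} has exact p = 0.1
wilcoxon_de <- function(m, cells_a, cells_b, alpha = 1e-4, exact_max = 10L) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "lognorm") stop("wilcoxon_de expects the lognorm layer", call. = FALSE)
  if (length(intersect(cells_a, cells_b)) > 0L) stop("cell groups overlap", call. = FALSE)
  if (length(cells_a) < 3L || length(cells_b) < 3L) {
    stop("each group needs at least 3 cells", call. = FALSE)
  }
  va <- m$values[, cells_a, drop = FALSE]
  vb <- m$values[, cells_b, drop = FALSE]
  na <- length(cells_a)
  nb <- length(cells_b)
  p <- vapply(seq_len(nrow(va)), function(g) {
    wilcox_p(va[g, ], vb[g, ], exact_max = exact_max)
  }, numeric(1L))
  log_fc <- log((rowMeans(expm1(va)) + 1) / (rowMeans(expm1(vb)) + 1))
  p_adj <- stats::p.adjust(p, method = "BH")
  data.frame(
    gene = genes(m), log_fc = log_fc, p = p, p_adj = p_adj,
    significant = p_adj < alpha,
    direction = ifelse(log_fc > 0, "up", "down"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# two-sided rank-sum p value for one gene
wilcox_p <- function(xa, xb, exact_max = 10L) {
  na <- length(xa)
  nb <- length(xb)
  r <- rank(c(xa, xb))
  w <- sum(r[seq_len(na)]) - na * (na + 1) / 2 # Mann-Whitney U of group A
  ties <- table(r)
  has_ties <- any(ties > 1L)
  if (!has_ties && na <= exact_max && nb <= exact_max) {
    p <- if (w > na * nb / 2) {
      stats::pwilcox(w - 1, na, nb, lower.tail = FALSE)
    } else {
      stats::pwilcox(w, na, nb)
    }
    return(min(2 * p, 1))
  }
  mu <- na * nb / 2
  n <- na + nb
  sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) {
    return(1) # all values identical
  }
  z <- w - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2) # continuity correction
  min(2 * stats::pnorm(-abs(z)), 1)
}

#' Top-k upregulated marker signature from a DEG table
#'
#' Among significant, upregulated genes, returns the `k` genes with the
#' largest fold change, in descending fold-change order. Ties are broken
#' by smaller adjusted p, then by symbol.
#'
#' @param deg A `DEGTable` from [wilcoxon_de()].
#' @param k Signature size (default 20).
#' @return Character vector of at most `k` genes; a warning is emitted
#'   when fewer than `k` qualify.
#' @export
marker_signature <- function(deg, k = 20L) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  up <- deg[deg$significant & deg$direction == "up", , drop = FALSE]
  up <- up[order(-up$log_fc, up$p_adj, up$gene), , drop = FALSE]
  if (nrow(up) < k) {
    warning(sprintf("only %d significant upregulated gene(s) available (k = %d)", nrow(up), k))
  }
  utils::head(up$gene, k)
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
with_local_seed <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
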