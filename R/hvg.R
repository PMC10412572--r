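#' Per-gene standardized-variance dispersion statistic
#'
#' Computes, for every gene of a raw count matrix, the mean, the raw
#' variance, and a standardized variance: the variance of the counts
#' after standardizing each gene by its mean and by the standard
#' deviation *expected* at that mean under the global mean-variance
#' trend. The trend is a local regression of `log10(variance)` on
#' `log10(mean)` fitted over all genes with positive variance
#' (loess, span 0.3, degree 2). Standardized values are clipped above at
#' `sqrt(N)` (N = number of cells) so a single outlier cell cannot
#' dominate. Genes sitting on the trend (e.g. Poisson-like noise) score
#' close to 1; genuinely variable genes score above it.
#'
#' @param m An `ExpressionMatrix` on the `counts` layer with at least
#'   two cells.
#' @param span,degree Loess parameters of the mean-variance trend.
#' @return A data.frame with one row per gene (in matrix order) and
#'   columns `gene`, `mean`, `var`, `var_std`. Genes with zero variance
#'   get `var_std = 0`.
#' @export
compute_gene_dispersion <- function(m, span = 0.3, degree = 2) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "counts") stop("dispersion is computed on the counts layer", call. = FALSE)
  n <- ncol(m$values)
  if (n < 2L) stop("at least 2 cells are required", call. = FALSE)
  v <- m$values
  mu <- rowMeans(v)
  s2 <- rowSums((v - mu)^2) / (n - 1L)
  var_std <- numeric(nrow(v))
  usable <- s2 > 0 & mu > 0
  if (any(usable)) {
    fit <- stats::loess(log10(s2[usable]) ~ log10(mu[usable]),
      span = span, degree = degree
    )
    sd_hat <- sqrt(10^stats::fitted(fit))
    clip <- sqrt(n)
    z <- (v[usable, , drop = FALSE] - mu[usable]) / sd_hat
    z <- pmin(z, clip)
    var_std[usable] <- rowSums(z^2) / (n - 1L)
  }
  data.frame(
    gene = rownames(v), mean = mu, var = s2, var_std = var_std,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Select highly variable genes with the mean-of-variances cutoff
#'
#' Given dispersion statistics restricted to a candidate gene set
#' (normally the genes retained by [filter_one_to_one()] and present in
#' the matrix), flags as highly variable exactly the genes whose
#' standardized variance lies strictly above the arithmetic mean of the
#' standardized variances over the candidates. The mean is the cutoff;
#' no gene count has to be chosen by hand.
#'
#' @param stats A data.frame as returned by [compute_gene_dispersion()],
#'   already restricted to the candidate genes.
#' @return The input with two additions: a logical `selected` column and
#'   a `cutoff` attribute (also repeated in a `cutoff` column for easy
#'   serialization).
#' @export
#' @examples
#' st <- data.frame(
#'   gene = paste0("g", 1:4), mean = 1, var = 1,
#'   var_std = c(1, 2, 3, 4)
#' )
#' select_hvgs_mean_cutoff(st) # cutoff 2.5, selects g3 and g4
select_hvgs_mean_cutoff <- function(stats) {
  if (!is.data.frame(stats) || !all(c("gene", "var_std") %in% names(stats))) {
    stop("`stats` must be a dispersion table with columns gene, var_std", call. = FALSE)
  }
  if (nrow(stats) == 0L) stop("empty candidate gene set", call. = FALSE)
  cutoff <- mean(stats$var_std)
  out <- stats
  out$selected <- out$var_std > cutoff
  out$cutoff <- cutoff
  attr(out, "cutoff") <- cutoff
  out
}

#' Intersect per-species HVG selections through the ortholog bijection
#'
#' The cross-species step: a homologous gene pair is retained when its
#' member is selected as highly variable in *both* species. The result
#' is symmetric in species order.
#'
#' @param hvg_a,hvg_b HVG tables (see [select_hvgs_mean_cutoff()]) for
#'   species A and B.
#' @param t A bijective ortholog table (`gene_a`, `gene_b`).
#' @return A data.frame with columns `gene_a`, `gene_b`: the shared
#'   homologous HVG pairs, in the order of `t`. A warning is emitted if
#'   the intersection is empty.
#' @export
intersect_homologous_hvgs <- function(hvg_a, hvg_b, t) {
  if (anyDuplicated(t$gene_a) || anyDuplicated(t$gene_b)) {
    stop("ortholog table is not bijective; run filter_one_to_one first", call. = FALSE)
  }
  sel_a <- hvg_a$gene[hvg_a$selected]
  sel_b <- hvg_b$gene[hvg_b$selected]
  keep <- t$gene_a %in% sel_a & t$gene_b %in% sel_b
  out <- t[keep, c("gene_a", "gene_b"), drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no homologous HVG pairs shared between species")
  out
}
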