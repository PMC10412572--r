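#' Restrict selected HVGs to transcription factors
#'
#' @param hvg An HVG table with `gene` and `selected` columns.
#' @param tf_list Character vector of TF symbols.
#' @return Character vector: the selected HVGs that are TFs, in HVG
#'   table order. Empty (with a warning) if the sets are disjoint.
#' @export
select_tfs <- function(hvg, tf_list) {
  if (length(tf_list) == 0L) stop("TF list is empty", call. = FALSE)
  out <- hvg$gene[hvg$selected & hvg$gene %in% tf_list]
  if (length(out) == 0L) warning("no selected HVG is in the TF list")
  out
}

#' Pearson correlation distance between transcription factors
#'
#' Computes pairwise Pearson correlations r between TF expression
#' vectors across cells (ordered by pseudotime when given, which does
#' not change r but makes exported matrices easier to read) and maps
#' them to the distance `d = sqrt((1 - r) / 2)`, so r = 1, 0, -1 give
#' d = 0, sqrt(1/2), 1. Constant TFs get r defined as 0 against every
#' other TF (d = sqrt(1/2)) with a warning, keeping the matrix usable
#' for clustering.
#'
#' @param m An `ExpressionMatrix` containing all `tfs` (any layer; the
#'   log-normalized layer is the usual choice), with at least 3 cells.
#' @param tfs Character vector of TF symbols present in `m`.
#' @param pseudotime Optional numeric vector (one value per cell of `m`)
#'   used only to order cells in the returned attribute.
#' @return A symmetric TF x TF matrix of distances in `[0, 1]` with zero
#'   diagonal, carrying the correlation matrix as attribute `r`.
#' @export
tf_distance_matrix <- function(m, tfs, pseudotime = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (ncol(m$values) < 3L) stop("need at least 3 cells", call. = FALSE)
  missing <- setdiff(tfs, genes(m))
  if (length(missing) > 0L) {
    stop("TF(s) absent from matrix: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- t(m$values[tfs, , drop = FALSE]) # cells x TFs
  if (!is.null(pseudotime)) {
    if (length(pseudotime) != nrow(v)) stop("pseudotime length must match cell count", call. = FALSE)
    v <- v[order(pseudotime), , drop = FALSE]
  }
  const <- apply(v, 2L, stats::sd) == 0
  if (any(const)) {
    warning(
      "constant TF(s) assigned r = 0: ",
      paste(tfs[const], collapse = ", ")
    )
  }
  r <- suppressWarnings(stats::cor(v))
  r[const, ] <- 0
  r[, const] <- 0
  diag(r) <- 1
  d <- sqrt(pmax(1 - r, 0) / 2)
  diag(d) <- 0
  attr(d, "r") <- r
  d
}

#' UPGMA hierarchical clustering of a distance matrix
#'
#' Classic unweighted pair group method with arithmetic mean: the two
#' closest clusters are merged at a height equal to their distance, and
#' the merged cluster's distance to any other cluster is the
#' size-weighted average of its members' distances. Ties are broken by
#' the lowest (row, column) index pair of the current distance matrix,
#' which makes the tree deterministic. Heights are non-decreasing
#' (ultrametric).
#'
#' @param d Symmetric numeric distance matrix (n >= 2, zero diagonal,
#'   no NaN), with labels as dimnames.
#' @return A `MergeTree`: list with `merge` (hclust-style (n-1) x 2
#'   integer matrix, negatives = leaves), `height`, `size` (cluster size
#'   after each merge) and `labels`. Convertible with
#'   [as_hclust()].
#' @export
upgma_cluster <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("`d` must be a square matrix", call. = FALSE)
  n <- nrow(d)
  if (n < 2L) stop("need at least 2 leaves", call. = FALSE)
  if (any(is.na(d))) stop("NaN/NA in distance matrix", call. = FALSE)
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero", call. = FALSE)
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("L", seq_len(n))
  work <- d
  active_id <- -seq_len(n) # hclust convention: negative = leaf
  sizes <- rep(1L, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  msize <- integer(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active_id)
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq.int(i + 1L, k)) {
        if (work[i, j] < best_d) {
          best_d <- work[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]
    j <- best[2L]
    ni <- sizes[i]
    nj <- sizes[j]
    merge[step, ] <- c(active_id[i], active_id[j])
    height[step] <- best_d
    msize[step] <- ni + nj
    # size-weighted average linkage; merged cluster takes slot i
    new_d <- (ni * work[i, ] + nj * work[j, ]) / (ni + nj)
    work[i, ] <- new_d
    work[, i] <- new_d
    work[i, i] <- 0
    work <- work[-j, -j, drop = FALSE]
    active_id[i] <- step
    sizes[i] <- ni + nj
    active_id <- active_id[-j]
    sizes <- sizes[-j]
  }
  structure(
    list(merge = merge, height = height, size = msize, labels = labels),
    class = "MergeTree"
  )
}

#' Convert a MergeTree to a stats::hclust object
#' @param tree A `MergeTree` from [upgma_cluster()].
#' @return An object of class `hclust` (for plotting or `cutree`).
#' @export
as_hclust <- function(tree) {
  stopifnot(inherits(tree, "MergeTree"))
  h <- list(
    merge = tree$merge, height = tree$height,
    order = tree_leaf_order(tree), labels = tree$labels,
    method = "upgma", call = NULL, dist.method = "pearson"
  )
  class(h) <- "hclust"
  h
}

tree_leaf_order <- function(tree) {
  expand <- function(node) {
    if (node < 0L) {
      return(-node)
    }
    c(expand(tree$merge[node, 1L]), expand(tree$merge[node, 2L]))
  }
  expand(nrow(tree$merge))
}

#' Cut a merge tree at a height with a minimum module size
#'
#' A static cut: all merges at height <= `height` are applied and the
#' resulting branches become candidate modules. Branches with at least
#' `min_size` leaves get module ids 1..M ordered by decreasing size
#' (ties by smallest leaf index); smaller branches are left unassigned
#' (id 0). With `height = "auto"` the n-1 merge heights are scanned and
#' the chosen cut is the one assigning the most leaves to modules of
#' size >= `min_size`; ties are broken toward the cut sitting under the
#' largest gap to the next merge height (the most separated boundary),
#' then toward the lower height. Maximizing assigned leaves keeps
#' well-separated branches intact (a cut slicing a clean branch strands
#' leaves in fragments below `min_size`), and the gap rule places the
#' boundary where the tree is most clearly split instead of at the top
#' merge.
#'
#' @param tree A `MergeTree`.
#' @param height Numeric cut height, or `"auto"`.
#' @param min_size Minimum number of leaves for a branch to become a
#'   module (>= 1).
#' @return A `ModuleAssignment`: list with `assignment` (named integer
#'   vector, leaf -> module id, 0 = unassigned), `height` (the cut
#'   used), `min_size`, `n_modules`.
#' @export
cut_tree_min_size <- function(tree, height = "auto", min_size = 5L) {
  stopifnot(inherits(tree, "MergeTree"))
  n <- length(tree$labels)
  if (min_size < 1L) stop("min_size must be >= 1", call. = FALSE)
  if (min_size > n) {
    warning("min_size exceeds leaf count; nothing assigned")
    assignment <- stats::setNames(integer(n), tree$labels)
    return(structure(
      list(
        assignment = assignment, height = NA_real_,
        min_size = min_size, n_modules = 0L
      ),
      class = "ModuleAssignment"
    ))
  }
  if (identical(height, "auto")) {
    candidates <- sort(unique(tree$height))
    assigned <- vapply(candidates, function(h) {
      tab <- table(cut_branches(tree, h))
      sum(tab[tab >= min_size])
    }, numeric(1L))
    gap <- c(diff(candidates), 0) # distance to the next merge above the cut
    ord <- order(-assigned, -gap, candidates)
    height <- candidates[ord[1L]]
  } else {
    if (!is.numeric(height) || length(height) != 1L) {
      stop("`height` must be a single number or \"auto\"", call. = FALSE)
    }
    if (height < 0 || height > max(tree$height)) {
      stop("cut height outside [0, max merge height]", call. = FALSE)
    }
  }
  branch <- cut_branches(tree, height)
  tab <- table(branch)
  big <- names(tab)[tab >= min_size]
  # order modules by decreasing size, then by first leaf index
  first_leaf <- vapply(big, function(b) min(which(branch == b)), integer(1L))
  ord <- order(-as.integer(tab[big]), first_leaf)
  ids <- stats::setNames(seq_along(big), big[ord])
  assignment <- ifelse(branch %in% names(ids), ids[as.character(branch)], 0L)
  assignment <- stats::setNames(as.integer(assignment), tree$labels)
  structure(
    list(
      assignment = assignment, height = height,
      min_size = min_size, n_modules = length(big)
    ),
    class = "ModuleAssignment"
  )
}

# component label per leaf after applying merges with height <= h
cut_branches <- function(tree, h) {
  n <- length(tree$labels)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  node_leaf <- integer(nrow(tree$merge)) # representative leaf per merge node
  for (s in seq_len(nrow(tree$merge))) {
    reps <- vapply(tree$merge[s, ], function(ch) {
      if (ch < 0L) -ch else node_leaf[ch]
    }, integer(1L))
    node_leaf[s] <- reps[1L]
    if (tree$height[s] <= h) {
      ra <- find(reps[1L])
      rb <- find(reps[2L])
      if (ra != rb) parent[rb] <- ra
    }
  }
  vapply(seq_len(n), find, integer(1L))
}

#' @export
print.ModuleAssignment <- function(x, ...) {
  cat(sprintf(
    "ModuleAssignment: %d module(s) (min size %d, cut height %.4g); %d of %d leaves assigned\n",
    x$n_modules, x$min_size, x$height,
    sum(x$assignment > 0L), length(x$assignment)
  ))
  invisible(x)
}
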