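#' Configuration for the synthetic two-species generator
#'
#' Returns the frozen default configuration (`default-v1`) with any
#' field overridden by name. The defaults emulate a modest droplet-style
#' experiment in each of two species sharing cell-type structure through
#' a one-to-one ortholog bijection: 5 cell types x 100 cells, 2000
#' ortholog gene pairs, 300 planted type-variable ortholog pairs at a
#' 2-fold effect, two anticorrelated 30-gene TF modules ramping along a
#' latent pseudotime, and 50 planted DE genes at 2-fold.
#'
#' @param ... Named overrides of the default fields (see Details).
#' @details Fields: `n_types`, `cells_per_type`, `n_genes`,
#'   `n_planted_hvg`, `effect_size` (fold multiplier >= 1 on the high
#'   type), `nb_size` (negative-binomial inverse dispersion),
#'   `libsize_sigma` (log-normal sd of per-cell depth factors),
#'   `ortholog_noise` (sd of the cross-species jitter on log effects),
#'   `n_decoy_one2many`, `n_lowconf` (extra non-usable ortholog rows),
#'   `tf_module_sizes` (integer vector), `tf_lo_mean`, `tf_fold`
#'   (per-cell mean ramps from `tf_lo_mean` to `tf_lo_mean * tf_fold`
#'   along pseudotime), `de_n_genes`, `de_fold`, `seed`.
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    n_types = 5L,
    cells_per_type = 100L,
    n_genes = 2000L,
    n_planted_hvg = 300L,
    effect_size = 2.0,
    nb_size = 2.0,
    libsize_sigma = 0.3,
    ortholog_noise = 0.1,
    n_decoy_one2many = 50L,
    n_lowconf = 50L,
    tf_module_sizes = c(30L, 30L),
    tf_lo_mean = 0.02,
    tf_fold = 1000,
    de_n_genes = 50L,
    de_fold = 2.0,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "SyntheticConfig")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$n_types >= 1L, cfg$cells_per_type >= 1L, cfg$n_genes >= 1L,
    cfg$n_planted_hvg >= 0L, cfg$n_planted_hvg <= cfg$n_genes,
    cfg$effect_size >= 1, cfg$nb_size > 0, cfg$libsize_sigma >= 0,
    cfg$ortholog_noise >= 0, cfg$de_n_genes >= 0, cfg$de_fold >= 1,
    cfg$tf_lo_mean > 0, cfg$tf_fold >= 1,
    sum(cfg$tf_module_sizes) + cfg$n_planted_hvg + cfg$de_n_genes <= cfg$n_genes
  )
  invisible(cfg)
}

#' Generate a paired two-species synthetic dataset with ground truth
#'
#' Simulates gene-by-cell negative-binomial count matrices for two
#' species ("mouse"-like species A, "human"-like species B) that share
#' biological structure through a one-to-one ortholog bijection:
#'
#' * every gene pair shares a baseline log mean drawn from
#'   Normal(ln 0.5, 1);
#' * planted variable ortholog pairs are drawn from the expressed half
#'   of the genes and get a multiplicative `effect_size` bump in one
#'   randomly chosen "high" cell type, shared across species (same type
#'   through the type pairing) up to a small log-scale jitter;
#' * TF-module genes ramp log-linearly from `tf_lo_mean` to
#'   `tf_lo_mean * tf_fold` along a per-cell latent pseudotime uniform
#'   on (0, 1) — the first module increases, the second decreases, which
#'   makes the two modules anticorrelated;
#' * planted DE genes (also drawn from expressed genes) are upregulated
#'   `de_fold`-fold in the first cell type;
#' * per-cell depth factors are log-normal, and counts are
#'   NB(mean x depth, size = `nb_size`).
#'
#' The emitted ortholog table is the true bijection plus
#' `n_decoy_one2many` one-to-many rows and `n_lowconf` low-confidence
#' rows, so that [filter_one_to_one()] recovers exactly the truth.
#' The same seed reproduces the dataset exactly.
#'
#' @param cfg A `SyntheticConfig` from [synthetic_config()].
#' @return A list with `matrix_a`, `matrix_b` (counts
#'   `ExpressionMatrix`), `annotation_a`, `annotation_b` (data.frames
#'   with `cell_id`, `label`, `pseudotime`), `orthologs` (the emitted
#'   table), and `truth` (a `GroundTruth` list: `planted_hvg` pairs with
#'   their high type, `type_pairing`, `tf_modules` per species,
#'   `de_genes`, `bijection`, the config).
#' @export
generate_species_pair <- function(cfg = synthetic_config()) {
  validate_config(cfg)
  with_local_seed(cfg$seed, generate_species_pair_impl(cfg))
}

generate_species_pair_impl <- function(cfg) {
  n_genes <- cfg$n_genes
  n_cells <- cfg$n_types * cfg$cells_per_type
  genes_a <- sprintf("gA%04d", seq_len(n_genes))
  genes_b <- sprintf("GB%04d", seq_len(n_genes))
  types_a <- paste0("mT", seq_len(cfg$n_types))
  types_b <- paste0("hT", seq_len(cfg$n_types))

  base_log_mean <- stats::rnorm(n_genes, mean = log(0.5), sd = 1)

  # gene roles: TF modules, then planted HVGs and DE genes from the
  # expressed (above-median baseline) remainder
  idx_all <- seq_len(n_genes)
  n_tf <- sum(cfg$tf_module_sizes)
  tf_idx <- if (n_tf > 0L) sample(idx_all, n_tf) else integer(0)
  rest <- setdiff(idx_all, tf_idx)
  expressed <- rest[base_log_mean[rest] >= stats::median(base_log_mean)]
  if (length(expressed) < cfg$n_planted_hvg + cfg$de_n_genes) {
    stop("not enough expressed genes to plant HVG and DE effects", call. = FALSE)
  }
  planted_idx <- if (cfg$n_planted_hvg > 0L) sample(expressed, cfg$n_planted_hvg) else integer(0)
  de_idx <- if (cfg$de_n_genes > 0L) sample(setdiff(expressed, planted_idx), cfg$de_n_genes) else integer(0)

  high_type <- sample.int(cfg$n_types, cfg$n_planted_hvg, replace = TRUE)
  tf_module <- rep(seq_along(cfg$tf_module_sizes), cfg$tf_module_sizes)
  tf_sign <- c(1, -1)[((tf_module - 1L) %% 2L) + 1L] # alternate up/down ramps

  jitter_b <- stats::rnorm(cfg$n_planted_hvg, 0, cfg$ortholog_noise)

  simulate_species <- function(gene_names, cell_prefix, type_names, effect_jitter) {
    type <- rep(type_names, each = cfg$cells_per_type)
    pseudotime <- stats::runif(n_cells)
    libsize <- exp(stats::rnorm(n_cells, 0, cfg$libsize_sigma))
    log_mu <- matrix(base_log_mean, n_genes, n_cells)
    # planted type effects
    if (cfg$n_planted_hvg > 0L) {
      for (k in seq_len(cfg$n_planted_hvg)) {
        hit <- type == type_names[high_type[k]]
        log_mu[planted_idx[k], hit] <- log_mu[planted_idx[k], hit] +
          log(cfg$effect_size) + effect_jitter[k]
      }
    }
    # TF ramps overwrite the baseline with a pseudotime-dependent mean
    if (n_tf > 0L) {
      span <- log(cfg$tf_fold)
      for (k in seq_len(n_tf)) {
        t_eff <- if (tf_sign[k] > 0) pseudotime else 1 - pseudotime
        log_mu[tf_idx[k], ] <- log(cfg$tf_lo_mean) + span * t_eff
      }
    }
    # DE genes up in the first type
    if (cfg$de_n_genes > 0L) {
      hit <- type == type_names[1L]
      log_mu[de_idx, hit] <- log_mu[de_idx, hit] + log(cfg$de_fold)
    }
    mu <- exp(log_mu) * rep(libsize, each = n_genes)
    counts <- matrix(
      stats::rnbinom(n_genes * n_cells, size = cfg$nb_size, mu = mu),
      n_genes, n_cells
    )
    storage.mode(counts) <- "double"
    cell_ids <- sprintf("%s%04d", cell_prefix, seq_len(n_cells))
    dimnames(counts) <- list(gene_names, cell_ids)
    list(
      counts = counts,
      annotation = data.frame(
        cell_id = cell_ids, label = type, pseudotime = pseudotime,
        stringsAsFactors = FALSE
      )
    )
  }

  sp_a <- simulate_species(genes_a, "cA", types_a, rep(0, cfg$n_planted_hvg))
  sp_b <- simulate_species(genes_b, "cB", types_b, jitter_b)

  bijection <- data.frame(
    gene_a = genes_a, gene_b = genes_b,
    homology_type = "one2one", confidence = 1L,
    stringsAsFactors = FALSE
  )
  decoys <- if (cfg$n_decoy_one2many > 0L) {
    src <- sample(idx_all, cfg$n_decoy_one2many)
    data.frame(
      gene_a = genes_a[src],
      gene_b = sprintf("GBdup%04d", seq_len(cfg$n_decoy_one2many)),
      homology_type = "one2many", confidence = 1L,
      stringsAsFactors = FALSE
    )
  } else {
    NULL
  }
  lowconf <- if (cfg$n_lowconf > 0L) {
    data.frame(
      gene_a = sprintf("gAlc%04d", seq_len(cfg$n_lowconf)),
      gene_b = sprintf("GBlc%04d", seq_len(cfg$n_lowconf)),
      homology_type = "one2one", confidence = 0L,
      stringsAsFactors = FALSE
    )
  } else {
    NULL
  }
  orthologs <- rbind(bijection, decoys, lowconf)
  # interleave rows deterministically so the decoys are not all trailing
  orthologs <- orthologs[order(sample.int(nrow(orthologs))), , drop = FALSE]
  rownames(orthologs) <- NULL

  truth <- list(
    planted_hvg = data.frame(
      gene_a = genes_a[planted_idx], gene_b = genes_b[planted_idx],
      high_type_a = types_a[high_type], high_type_b = types_b[high_type],
      stringsAsFactors = FALSE
    ),
    type_pairing = stats::setNames(types_b, types_a),
    tf_modules = data.frame(
      gene_a = genes_a[tf_idx], gene_b = genes_b[tf_idx],
      module = tf_module, stringsAsFactors = FALSE
    ),
    de_genes = data.frame(
      gene_a = genes_a[de_idx], gene_b = genes_b[de_idx],
      up_in = rep(types_a[1L], length(de_idx)), stringsAsFactors = FALSE
    ),
    bijection = bijection,
    config = cfg
  )

  list(
    matrix_a = expression_matrix(sp_a$counts, species = "species_a", layer = "counts"),
    matrix_b = expression_matrix(sp_b$counts, species = "species_b", layer = "counts"),
    annotation_a = sp_a$annotation,
    annotation_b = sp_b$annotation,
    orthologs = orthologs,
    truth = truth
  )
}

#' Recovery metrics against planted ground truth
#'
#' @param predicted Character vector of predicted items (e.g. recovered
#'   gene pairs encoded as `"a|b"`, or plain gene symbols).
#' @param truth Character vector of planted items in the same encoding.
#' @param universe Optional character vector restricting the evaluation:
#'   predictions outside it are ignored (used to exclude genes that are
#'   planted with a different kind of signal from the false-positive
#'   count).
#' @return A list with `sensitivity`, `precision` (NaN when nothing was
#'   predicted), `tp`, `fp`, `fn`.
#' @export
recovery_metrics <- function(predicted, truth, universe = NULL) {
  if (!is.null(universe)) {
    predicted <- intersect(predicted, universe)
    truth <- intersect(truth, universe)
  }
  tp <- length(intersect(predicted, truth))
  fp <- length(setdiff(predicted, truth))
  fn <- length(setdiff(truth, predicted))
  list(
    sensitivity = if (tp + fn == 0L) NaN else tp / (tp + fn),
    precision = if (tp + fp == 0L) NaN else tp / (tp + fp),
    tp = tp, fp = fp, fn = fn
  )
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Vectors of cluster labels over the same items.
#' @return The adjusted Rand index (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings cover different item sets", call. = FALSE)
  mclust::adjustedRandIndex(a, b)
}
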