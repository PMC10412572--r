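#' Run the full cross-species comparison workflow
#'
#' Orchestrates the whole comparison from raw inputs to a directory of
#' result tables: read both species' counts and annotations, filter the
#' ortholog table to a bijection, compute dispersion statistics and
#' select homologous HVGs per species, intersect them, build centered
#' median profiles and the cross-species correspondence matrix, and
#' optionally detect TF modules and run a differential-expression
#' contrast. Every output is a TSV; a `manifest.json` records the
#' config, input digests, seed, and per-stage outputs with row counts
#' and digests. Reruns with identical inputs and seed reproduce every
#' output byte for byte.
#'
#' @param config A named list or the path of a YAML file. Required keys:
#'   `species_a` / `species_b` (each with `name`, a counts source —
#'   either `counts_tsv` or `counts_10x` (a directory with
#'   `matrix.mtx`, `features.tsv`, `barcodes.tsv`) — and `annotation`),
#'   and `orthologs`. Optional: `tf_list` (path), `deg` (list with
#'   `species` = `"a"`/`"b"`, `group_a`, `group_b`), `seed` (default 1),
#'   `params` (`scale`, `min_module_size`, `cut_height`, `marker_k`).
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the manifest list. On a stage failure the stage
#'   name is reported and outputs already written are renamed with a
#'   `.partial` suffix.
#' @export
run_full_comparison <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  for (key in c("species_a", "species_b", "orthologs")) {
    if (is.null(config[[key]])) stop("config lacks required key: ", key, call. = FALSE)
  }
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  params <- utils::modifyList(
    list(scale = 1e4, min_module_size = 5L, cut_height = "auto", marker_k = 20L),
    if (is.null(config$params)) list() else config$params
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  written <- character(0)
  stage <- "load"
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_table(df, path)
    written <<- c(written, path)
    path
  }
  on_failure <- function(e) {
    for (f in written) file.rename(f, paste0(f, ".partial"))
    stop(sprintf("pipeline aborted at stage '%s': %s", stage, conditionMessage(e)),
      call. = FALSE
    )
  }

  manifest <- tryCatch(
    {
      input_paths <- c(
        unlist(config$species_a[c("counts_tsv", "counts_10x", "annotation")]),
        unlist(config$species_b[c("counts_tsv", "counts_10x", "annotation")]),
        orthologs = config$orthologs, tf_list = config$tf_list
      )
      load_species <- function(sp) {
        m <- if (!is.null(sp$counts_tsv)) {
          read_matrix_tsv(sp$counts_tsv, species = sp$name)
        } else if (!is.null(sp$counts_10x)) {
          read_counts_10x(
            file.path(sp$counts_10x, "matrix.mtx"),
            file.path(sp$counts_10x, "features.tsv"),
            file.path(sp$counts_10x, "barcodes.tsv"),
            species = sp$name
          )
        } else {
          stop("species entry needs counts_tsv or counts_10x")
        }
        list(m = m, ann = read_annotation(sp$annotation))
      }
      a <- load_species(config$species_a)
      b <- load_species(config$species_b)
      orth_raw <- read_orthologs(config$orthologs)

      stage <- "orthology"
      orth <- filter_one_to_one(orth_raw)
      emit(orth, "orthologs_one2one.tsv")

      stage <- "normalize"
      ln_a <- log_normalize(a$m, scale = params$scale)
      ln_b <- log_normalize(b$m, scale = params$scale)

      stage <- "hvg"
      cand <- orth[orth$gene_a %in% genes(a$m) & orth$gene_b %in% genes(b$m), , drop = FALSE]
      disp_a <- compute_gene_dispersion(a$m)
      disp_b <- compute_gene_dispersion(b$m)
      hvg_a <- select_hvgs_mean_cutoff(disp_a[match(cand$gene_a, disp_a$gene), , drop = FALSE])
      hvg_b <- select_hvgs_mean_cutoff(disp_b[match(cand$gene_b, disp_b$gene), , drop = FALSE])
      emit(hvg_a, "hvg_a.tsv")
      emit(hvg_b, "hvg_b.tsv")

      stage <- "intersect"
      shared <- intersect_homologous_hvgs(hvg_a, hvg_b, cand)
      emit(shared, "shared_hvg_pairs.tsv")

      stage <- "correspondence"
      # medians are taken on the depth-normalized linear scale; the log
      # lives in the centering step
      nc_a <- normalize_counts(a$m, scale = params$scale)
      nc_b <- normalize_counts(b$m, scale = params$scale)
      prof_a <- center_log_profiles(group_median_profiles(nc_a, a$ann))
      prof_b <- center_log_profiles(group_median_profiles(nc_b, b$ann))
      corr <- cross_species_correlation(prof_a, prof_b, shared)
      emit(
        data.frame(group_a = rownames(corr), corr, check.names = FALSE),
        "correspondence.tsv"
      )

      tf_path <- NULL
      if (!is.null(config$tf_list)) {
        stage <- "tf_modules"
        tfs <- select_tfs(hvg_a, read_tf_list(config$tf_list))
        if (length(tfs) >= 2L) {
          pt <- a$ann$pseudotime[match(cells(ln_a), a$ann$cell_id)]
          d <- tf_distance_matrix(ln_a, tfs, pseudotime = pt)
          modules <- cut_tree_min_size(upgma_cluster(d),
            height = params$cut_height, min_size = params$min_module_size
          )
          tf_path <- emit(
            data.frame(tf = names(modules$assignment), module = modules$assignment),
            "tf_modules.tsv"
          )
        } else {
          warning("fewer than 2 HVG TFs; TF module stage skipped")
        }
      }

      deg_path <- NULL
      if (!is.null(config$deg)) {
        stage <- "deg"
        side <- match.arg(config$deg$species, c("a", "b"))
        ln <- if (side == "a") ln_a else ln_b
        ann <- if (side == "a") a$ann else b$ann
        deg <- wilcoxon_de(
          ln,
          ann$cell_id[ann$label == config$deg$group_a],
          ann$cell_id[ann$label == config$deg$group_b]
        )
        deg_path <- emit(deg, "deg.tsv")
        sig <- marker_signature(deg, k = params$marker_k)
        markers_file <- file.path(out_dir, "markers.txt")
        writeLines(sig, markers_file)
        written <- c(written, markers_file)
      }

      stage <- "manifest"
      existing <- input_paths[!vapply(input_paths, is.null, logical(1L))]
      manifest <- list(
        package = "crossortho",
        version = as.character(utils::packageVersion("crossortho")),
        seed = seed,
        config = config,
        params = params,
        inputs = lapply(existing, function(p) {
          list(path = p, md5 = digest_path(p))
        }),
        outputs = lapply(written, function(p) {
          list(
            path = p,
            rows = length(readLines(p)) - 1L,
            md5 = unname(tools::md5sum(p))
          )
        })
      )
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA
      )
      manifest
    },
    error = on_failure
  )
  invisible(manifest)
}

# md5 of a file, or of the concatenated files of a directory
digest_path <- function(p) {
  if (dir.exists(p)) {
    files <- sort(list.files(p, full.names = TRUE))
    return(unname(tools::md5sum(files)))
  }
  unname(tools::md5sum(p))
}
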