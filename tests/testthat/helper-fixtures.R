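# small in-code fixtures shared across test files

make_em <- function(values, species = "mouse", layer = "counts",
                    genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(values)))
  if (is.null(cells)) cells <- sprintf("c%03d", seq_len(ncol(values)))
  dimnames(values) <- list(genes, cells)
  expression_matrix(values, species = species, layer = layer)
}

random_counts_em <- function(n_genes, n_cells, seed, lambda = 2, ...) {
  set.seed(seed)
  make_em(matrix(rpois(n_genes * n_cells, lambda) + 0, n_genes, n_cells), ...)
}

# uncentered group profile object built directly from a values matrix
make_profile <- function(values, species = "s", centered = FALSE) {
  structure(
    list(values = values, species = species, centered = centered),
    class = "GroupProfileMatrix"
  )
}

ortholog_table <- function(gene_a, gene_b,
                           homology_type = "one2one", confidence = 1L) {
  data.frame(
    gene_a = gene_a, gene_b = gene_b,
    homology_type = homology_type, confidence = confidence,
    stringsAsFactors = FALSE
  )
}

# tiny two-species simulation for fast end-to-end tests
small_sim <- function(seed = 1) {
  generate_species_pair(synthetic_config(
    seed = seed, n_types = 3L, cells_per_type = 30L, n_genes = 300L,
    n_planted_hvg = 40L, tf_module_sizes = c(8L, 8L), de_n_genes = 10L,
    n_decoy_one2many = 10L, n_lowconf = 10L
  ))
}
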