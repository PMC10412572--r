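Package: crossortho
Title: Cross-Species Single-Cell Comparison via Homologous Highly Variable Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing single-cell RNA-seq datasets across two
    species through one-to-one orthologs. Filters Ensembl-style ortholog
    tables to a high-confidence bijection, selects highly variable genes
    with a standardized-variance statistic and a mean-of-variances cutoff,
    intersects the per-species selections into a shared homologous gene
    set, and uses that set for downstream comparison: cell-type
    correspondence by Pearson correlation of centered median expression
    profiles, transcription-factor co-expression module discovery by UPGMA
    clustering of a Pearson correlation distance, binned-control gene-set
    module scores, and Wilcoxon rank-sum differential expression with
    marker-signature extraction. Includes a deterministic two-species
    synthetic data generator with planted ground truth for benchmarking,
    a single-call pipeline driver, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    mclust
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
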