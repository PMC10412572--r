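#' crossortho: cross-species single-cell comparison via homologous HVGs
#'
#' Compare single-cell transcriptomes of two species through their
#' one-to-one orthologs: select highly variable genes per species with a
#' standardized-variance statistic and a mean-of-variances cutoff,
#' intersect them into a shared homologous gene set, and use that set
#' for cell-type correspondence, TF co-expression modules, module
#' scores and differential expression. See the package vignette for the
#' methods.
#'
#' @keywords internal
"_PACKAGE"

#' @importFrom stats median loess fitted cor sd rnorm runif rnbinom pwilcox pnorm p.adjust setNames
#' @importFrom utils head read.delim write.table modifyList packageVersion
NULL
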