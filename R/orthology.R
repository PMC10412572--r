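#' Filter an ortholog table to a high-confidence one-to-one bijection
#'
#' Keeps only rows annotated `one2one` with confidence 1, then enforces
#' a strict bijection: any gene (on either side) still involved in more
#' than one retained row is dropped entirely, on the grounds that
#' residual ambiguity after one-to-one annotation is a data error and
#' arbitrarily keeping one row would bias downstream intersections.
#' The operation is idempotent.
#'
#' @param t Ortholog data.frame with columns `gene_a`, `gene_b`,
#'   `homology_type` (values among `one2one`, `one2many`, `many2many`)
#'   and `confidence` (0/1).
#' @return The filtered data.frame; every `gene_a` and every `gene_b`
#'   appears exactly once. A warning is emitted if the result is empty,
#'   and a message reports how many ambiguous rows were dropped.
#' @export
#' @examples
#' t <- data.frame(
#'   gene_a = c("a1", "a2", "a3"), gene_b = c("b1", "b2", "b3"),
#'   homology_type = c("one2one", "one2many", "one2one"),
#'   confidence = c(1, 1, 0)
#' )
#' filter_one_to_one(t) # keeps only (a1, b1)
filter_one_to_one <- function(t) {
  required <- c("gene_a", "gene_b", "homology_type", "confidence")
  missing <- setdiff(required, names(t))
  if (length(missing) > 0L) {
    stop("ortholog table lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  keep <- t$homology_type == "one2one" & t$confidence == 1
  out <- t[keep, , drop = FALSE]
  dup_a <- out$gene_a %in% out$gene_a[duplicated(out$gene_a)]
  dup_b <- out$gene_b %in% out$gene_b[duplicated(out$gene_b)]
  ambiguous <- dup_a | dup_b
  if (any(ambiguous)) {
    message(sum(ambiguous), " ambiguous one2one row(s) dropped to enforce a bijection")
    out <- out[!ambiguous, , drop = FALSE]
  }
  if (nrow(out) == 0L) warning("no orthologs remain after one-to-one filtering")
  rownames(out) <- NULL
  out
}

#' Replace gene aliases by official symbols
#'
#' Unknown symbols pass through unchanged. If two input symbols collapse
#' onto the same official symbol, the first occurrence is kept and later
#' ones are dropped with a message.
#'
#' @param genes Character vector of gene symbols.
#' @param aliases Data.frame with columns `alias`, `official`.
#' @return Character vector of official symbols, order preserved,
#'   collisions removed.
#' @export
#' @examples
#' al <- data.frame(alias = "Cd31", official = "Pecam1")
#' normalize_symbols(c("Cd31", "Gm1234"), al)
normalize_symbols <- function(genes, aliases) {
  stopifnot(all(c("alias", "official") %in% names(aliases)))
  idx <- match(genes, aliases$alias)
  out <- ifelse(is.na(idx), genes, aliases$official[idx])
  dup <- duplicated(out)
  if (any(dup)) {
    message(
      sum(dup), " symbol(s) collapsed onto an already-present official symbol and were dropped: ",
      paste(utils::head(unique(out[dup]), 5L), collapse = ", ")
    )
    out <- out[!dup]
  }
  out
}

#' Translate gene symbols across species through an ortholog bijection
#'
#' @param genes Character vector of symbols in the source species.
#' @param t A bijective ortholog table (see [filter_one_to_one()]).
#' @param direction `"a_to_b"` if `genes` are species-A symbols,
#'   `"b_to_a"` otherwise.
#' @return A list with elements `mapped` (data.frame `from`, `to`, in
#'   input order, restricted to genes present in `t`) and `unmapped`
#'   (character vector of symbols absent from `t`).
#' @export
translate <- function(genes, t, direction = c("a_to_b", "b_to_a")) {
  direction <- match.arg(direction)
  if (anyDuplicated(t$gene_a) || anyDuplicated(t$gene_b)) {
    stop("ortholog table is not bijective; run filter_one_to_one first", call. = FALSE)
  }
  from_col <- if (direction == "a_to_b") "gene_a" else "gene_b"
  to_col <- if (direction == "a_to_b") "gene_b" else "gene_a"
  idx <- match(genes, t[[from_col]])
  hit <- !is.na(idx)
  list(
    mapped = data.frame(
      from = genes[hit], to = t[[to_col]][idx[hit]],
      stringsAsFactors = FALSE
    ),
    unmapped = genes[!hit]
  )
}
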