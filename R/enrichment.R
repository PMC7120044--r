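#' Hypergeometric gene-set over-representation analysis
#'
#' Tests each gene set for over-representation in a query gene list using
#' the same upper-tail hypergeometric kernel as the shared-target ceRNA
#' test ([shared_target_pvalue()]): with a background universe of `N`
#' genes, a set of size `K`, a query of size `M` and an overlap of `x`,
#' `p = P(X >= x)`. P-values are Benjamini--Hochberg adjusted across all
#' tested sets.
#'
#' Query genes outside the universe are dropped with a warning; each set
#' is intersected with the universe before testing. The default universe
#' is the union of all collection genes (the background of an unspecified
#' annotation tool).
#'
#' @param query Character vector of gene ids.
#' @param collection A `"gene_sets"` collection (see [read_gmt()]).
#' @param universe Optional character vector of background gene ids.
#' @return A data frame of class `"enrichment"`, sorted by `p_raw` then set
#'   id, with columns `set_id`, `description`, `overlap_count`, `set_size`,
#'   `query_size`, `universe_size`, `p_raw`, `p_adj` and
#'   `overlapping_genes` (comma-joined).
#' @export
enrich <- function(query, collection, universe = NULL) {
  stopifnot(inherits(collection, "gene_sets"))
  query <- unique(as.character(query))
  if (is.null(universe))
    universe <- sort(unique(unlist(collection$sets, use.names = FALSE)))
  else universe <- unique(as.character(universe))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("dropping %d query genes outside the universe",
                    length(outside)))
    query <- intersect(query, universe)
  }
  if (!length(query)) stop("empty query after universe filtering")
  N <- length(universe); M <- length(query)
  sets <- lapply(collection$sets, intersect, universe)
  keep <- lengths(sets) > 0L
  sets <- sets[keep]
  if (!length(sets)) stop("no gene sets overlap the universe")
  ov <- lapply(sets, intersect, query)
  K <- lengths(sets); x <- lengths(ov)
  p <- hyper_tail(x, N, K, M)
  res <- data.frame(
    set_id = names(sets),
    description = unname(collection$descriptions[names(sets)]),
    overlap_count = as.integer(x), set_size = as.integer(K),
    query_size = M, universe_size = N,
    p_raw = p, p_adj = p.adjust(p, "BH"),
    overlapping_genes = vapply(ov, function(g)
      paste(sort(g), collapse = ","), character(1L)),
    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(res$p_raw, res$set_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment", "data.frame")
  res
}

#' Filter enrichment results by FDR (and an optional display p cutoff)
#'
#' Retains sets with `p_adj < fdr_cut`; when `p_cut_display` is given the
#' raw p-value must additionally fall below it (the stricter rule used for
#' plotting only the strongest categories).
#'
#' @param results An `"enrichment"` table from [enrich()].
#' @param fdr_cut BH FDR cutoff (strict `<`), default 0.05.
#' @param p_cut_display Optional raw-p display cutoff (strict `<`), e.g.
#'   0.01.
#' @return The filtered table.
#' @export
filter_enrichment <- function(results, fdr_cut = 0.05,
                              p_cut_display = NULL) {
  keep <- results$p_adj < fdr_cut
  if (!is.null(p_cut_display)) keep <- keep & results$p_raw < p_cut_display
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.enrichment <- function(x, ...) {
  cat(sprintf("gene-set over-representation: %d sets tested, query of %d",
              nrow(x), if (nrow(x)) x$query_size[1L] else 0L))
  cat(sprintf(" against universe of %d\n",
              if (nrow(x)) x$universe_size[1L] else 0L))
  if (nrow(x))
    print.data.frame(head(as.data.frame(
      x[, c("set_id", "overlap_count", "set_size", "p_raw", "p_adj")]), 10L))
  invisible(x)
}
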