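# Upper-tail hypergeometric probability of drawing >= x white balls:
# P = 1 - F(x-1; N, K, M) = sum_{t=x}^{min(K,M)} C(K,t) C(N-K, M-t) / C(N,M).
# phyper works in log space internally, so small tails are exact to double
# precision. The roles of K and M are exchangeable; evaluating with the
# smaller set first makes the symmetry exact in floating point, not just
# mathematically.
hyper_tail <- function(x, N, K, M) {
  k <- pmin(K, M)
  m <- pmax(K, M)
  phyper(x - 1, k, N - k, m, lower.tail = FALSE)
}

#' Shared-miRNA-target hypergeometric test for one RNA pair
#'
#' Tests whether two RNAs share more predicted miRNA regulators than
#' expected by chance, the statistical core of ceRNA pair calling. With a
#' universe of `N` miRNAs, target sets of sizes `K` and `M`, and `x` shared
#' miRNAs, the p-value is the upper hypergeometric tail
#' `P(X >= x) = 1 - F(x - 1; N, K, M)`; pairs with `p < 0.05` are candidate
#' ceRNA pairs.
#'
#' @param targets_a,targets_b Character vectors of miRNA ids (both subsets
#'   of `universe`, both non-empty).
#' @param universe Character vector: the miRNA universe.
#' @return An object of class `"shared_target_stat"`: list with `N`, `K`,
#'   `M`, `x`, `p_value` and `shared_mirnas`.
#' @examples
#' u <- paste0("m", 1:10)
#' shared_target_pvalue(u[1:4], u[2:6], u)  # N=10, K=4, M=5, x=3 -> 66/252
#' @export
shared_target_pvalue <- function(targets_a, targets_b, universe) {
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty miRNA universe")
  targets_a <- unique(as.character(targets_a))
  targets_b <- unique(as.character(targets_b))
  if (!length(targets_a) || !length(targets_b))
    stop("both target sets must be non-empty")
  out_a <- setdiff(targets_a, universe)
  out_b <- setdiff(targets_b, universe)
  if (length(out_a) || length(out_b))
    stop("target sets must be subsets of the universe; outside ids: ",
         paste(head(c(out_a, out_b), 5L), collapse = ", "))
  shared <- sort(intersect(targets_a, targets_b))
  N <- length(universe); K <- length(targets_a); M <- length(targets_b)
  x <- length(shared)
  structure(list(N = N, K = K, M = M, x = x,
                 p_value = hyper_tail(x, N, K, M),
                 shared_mirnas = shared),
            class = "shared_target_stat")
}

#' @export
print.shared_target_stat <- function(x, ...) {
  cat(sprintf(
    "shared-target test: x = %d shared of K = %d, M = %d (universe N = %d)\n",
    x$x, x$K, x$M, x$N))
  cat(sprintf("  P(X >= x) = %.4g\n", x$p_value))
  invisible(x)
}

#' Pearson correlation between two expression profiles
#'
#' Thin, validated wrapper around the sample Pearson correlation used by
#' the co-expression filter. Constant vectors have no defined correlation;
#' `NA` is returned with a warning so callers can skip the pair.
#'
#' @param a,b Numeric vectors of equal length >= 3.
#' @return The correlation coefficient, or `NA` for a constant input.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (length(a) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant expression vector; correlation undefined, pair skipped")
    return(NA_real_)
  }
  cor(a, b)
}

#' Infer ceRNA pairs by shared-target test plus co-expression filter
#'
#' Evaluates every unordered pair of RNAs present in both the expression
#' matrix and the target map that shares at least one predicted miRNA
#' (candidates are generated through an inverted miRNA-to-RNA index, so
#' disjoint pairs are never enumerated). A pair is called a ceRNA pair when
#' its shared-target hypergeometric p-value is below `p_cut` and its
#' Pearson expression correlation exceeds `r_cut` (both strict; the filter
#' uses signed positive r under the ceRNA co-expression hypothesis, or
#' `|r|` with `use_abs_r = TRUE`).
#'
#' @param em An [expression_matrix()] of lncRNA/mRNA expression.
#' @param targets A [target_map()].
#' @param p_cut Hypergeometric p-value cutoff (strict `<`), default 0.05.
#' @param r_cut Pearson correlation cutoff (strict `>`), default 0.7.
#' @param use_abs_r Filter on `|r|` instead of signed r.
#' @param adjust `"none"` (default; raw pair p-values) or `"bh"` to filter
#'   on BH-adjusted pair p-values instead.
#' @param rna_types Optional named character vector typing each RNA
#'   (`"lncRNA"`, `"mRNA"`, ...); used only by `pair_types`.
#' @param pair_types Optional character vector of admissible unordered type
#'   combinations such as `"lncRNA-mRNA"`; default keeps all RNA--RNA pairs.
#' @return A data frame of class `"cerna_pairs"` with columns `rna_a`,
#'   `rna_b` (lexicographic within pair), `N`, `K`, `M`, `x`, `p_value`,
#'   `r` and `shared_mirnas` (comma-joined), sorted by `p_value` then by
#'   decreasing `r`. Attributes record the thresholds and the number of
#'   candidate pairs evaluated.
#' @export
infer_cerna_pairs <- function(em, targets, p_cut = 0.05, r_cut = 0.7,
                              use_abs_r = FALSE,
                              adjust = c("none", "bh"),
                              rna_types = NULL, pair_types = NULL) {
  adjust <- match.arg(adjust)
  stopifnot(inherits(em, "expr_matrix"), inherits(targets, "target_map"))
  common <- intersect(rownames(em$values), names(targets$targets))
  if (!length(common))
    stop("no RNA ids shared between expression matrix and target map")
  common <- sort(common)
  universe <- targets$universe
  N <- length(universe)
  tsets <- targets$targets[common]

  # inverted index as a sparse membership matrix; tcrossprod counts the
  # shared miRNAs of every pair in one pass
  mir_idx <- match(unlist(tsets, use.names = FALSE), universe)
  rna_idx <- rep.int(seq_along(tsets), lengths(tsets))
  memb <- sparseMatrix(i = rna_idx, j = mir_idx, x = 1,
                       dims = c(length(tsets), N))
  shared_counts <- as(as(tcrossprod(memb), "generalMatrix"),
                      "TsparseMatrix")
  K <- Matrix::rowSums(memb)
  sel <- shared_counts@i < shared_counts@j & shared_counts@x > 0
  ia <- shared_counts@i[sel] + 1L
  ib <- shared_counts@j[sel] + 1L
  x <- shared_counts@x[sel]
  if (!length(ia)) {
    warning("no RNA pairs share any miRNA target; empty result")
    return(empty_cerna_pairs(N, p_cut, r_cut, 0L))
  }
  n_cand <- length(ia)
  p <- hyper_tail(x, N, K[ia], K[ib])
  p_filter <- if (adjust == "bh") p.adjust(p, "BH") else p

  # correlations across all samples; constant features are skipped
  sds <- apply(em$values[common, , drop = FALSE], 1L, stats::sd)
  if (any(sds == 0))
    warning(sprintf("skipping %d constant features in correlation filter",
                    sum(sds == 0)))
  cmat <- suppressWarnings(cor(t(em$values[common, , drop = FALSE])))
  r <- cmat[cbind(ia, ib)]
  r_ok <- !is.na(r) & (if (use_abs_r) abs(r) else r) > r_cut
  keep <- p_filter < p_cut & r_ok

  if (!is.null(pair_types)) {
    if (is.null(rna_types))
      stop("`pair_types` requires `rna_types`")
    ta <- unname(rna_types[common[ia]]); tb <- unname(rna_types[common[ib]])
    ta[is.na(ta)] <- "other"; tb[is.na(tb)] <- "other"
    combo <- paste(pmin(ta, tb), pmax(ta, tb), sep = "-")
    pair_types <- vapply(strsplit(pair_types, "-", fixed = TRUE),
                         function(p) paste(sort(p), collapse = "-"),
                         character(1L))
    keep <- keep & combo %in% pair_types
  }

  if (!any(keep)) {
    warning("no pairs pass the hypergeometric and correlation thresholds")
    return(empty_cerna_pairs(N, p_cut, r_cut, n_cand))
  }
  ia <- ia[keep]; ib <- ib[keep]
  shared <- mapply(function(a, b) paste(sort(intersect(tsets[[a]],
                                                       tsets[[b]])),
                                        collapse = ","),
                   ia, ib)
  res <- data.frame(rna_a = common[ia], rna_b = common[ib],
                    N = N, K = as.integer(K[ia]), M = as.integer(K[ib]),
                    x = as.integer(x[keep]), p_value = p[keep],
                    r = r[keep], shared_mirnas = shared,
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[order(res$p_value, -res$r, res$rna_a, res$rna_b), ,
             drop = FALSE]
  rownames(res) <- NULL
  attr(res, "universe_size") <- N
  attr(res, "p_cut") <- p_cut
  attr(res, "r_cut") <- r_cut
  attr(res, "n_candidates") <- n_cand
  class(res) <- c("cerna_pairs", "data.frame")
  res
}

empty_cerna_pairs <- function(N, p_cut, r_cut, n_candidates) {
  res <- data.frame(rna_a = character(), rna_b = character(),
                    N = integer(), K = integer(), M = integer(),
                    x = integer(), p_value = numeric(), r = numeric(),
                    shared_mirnas = character(), stringsAsFactors = FALSE)
  attr(res, "universe_size") <- N
  attr(res, "p_cut") <- p_cut
  attr(res, "r_cut") <- r_cut
  attr(res, "n_candidates") <- n_candidates
  class(res) <- c("cerna_pairs", "data.frame")
  res
}

#' @export
print.cerna_pairs <- function(x, ...) {
  cat(sprintf(
    "ceRNA pairs: %d retained of %d candidates (p < %g, r > %g, N = %d)\n",
    nrow(x), attr(x, "n_candidates"), attr(x, "p_cut"), attr(x, "r_cut"),
    attr(x, "universe_size")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... and %d more pairs\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
summary.cerna_pairs <- function(object, ...) {
  cat(sprintf("ceRNA pair inference (universe N = %d miRNAs)\n",
              attr(object, "universe_size")))
  cat(sprintf("  candidates with >= 1 shared miRNA: %d\n",
              attr(object, "n_candidates")))
  cat(sprintf("  retained at p < %g and r > %g: %d\n",
              attr(object, "p_cut"), attr(object, "r_cut"), nrow(object)))
  if (nrow(object)) {
    cat(sprintf("  shared targets per pair: median %d (range %d-%d)\n",
                as.integer(median(object$x)), min(object$x), max(object$x)))
    cat(sprintf("  correlation: median %.3f (range %.3f-%.3f)\n",
                median(object$r), min(object$r), max(object$r)))
  }
  invisible(object)
}

#' Assemble the typed ceRNA network
#'
#' Builds the lncRNA--miRNA--mRNA network from called ceRNA pairs. Each pair
#' contributes one `cerna` edge; with `include_mirna_edges = TRUE` each
#' shared miRNA becomes a node connected to both pair members by `targets`
#' edges. Node degree is recomputed from the assembled edge set (in the
#' usual rendering, node size is proportional to degree).
#'
#' @param pairs A `"cerna_pairs"` table (non-empty).
#' @param rna_types Named character vector mapping RNA ids to
#'   `"lncRNA"`/`"mRNA"`; unmapped ids become `"other"`.
#' @param include_mirna_edges Add shared-miRNA nodes and RNA--miRNA edges.
#' @return An object of class `"cerna_network"`: list with `graph` (igraph),
#'   `pairs` (the input table).
#' @export
build_network <- function(pairs, rna_types = NULL,
                          include_mirna_edges = FALSE) {
  if (nrow(pairs) == 0L) stop("cannot build a network from zero pairs")
  edges <- data.frame(source = pairs$rna_a, interaction = "cerna",
                      target = pairs$rna_b, stringsAsFactors = FALSE)
  if (include_mirna_edges) {
    sh <- strsplit(pairs$shared_mirnas, ",", fixed = TRUE)
    n_sh <- lengths(sh)
    mir_edges <- data.frame(
      source = rep(c(pairs$rna_a, pairs$rna_b), c(n_sh, n_sh)),
      interaction = "targets",
      target = unlist(c(sh, sh), use.names = FALSE),
      stringsAsFactors = FALSE)
    edges <- rbind(edges, unique(mir_edges))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("source", "target", "interaction")], directed = FALSE)
  ids <- igraph::V(g)$name
  type <- rep("other", length(ids))
  if (!is.null(rna_types)) {
    known <- ids %in% names(rna_types)
    type[known] <- unname(rna_types[ids[known]])
  }
  if (include_mirna_edges) {
    mirna_ids <- unique(unlist(strsplit(pairs$shared_mirnas, ",",
                                        fixed = TRUE)))
    type[ids %in% mirna_ids] <- "miRNA"
  }
  igraph::V(g)$type <- type
  structure(list(graph = g, pairs = pairs), class = "cerna_network")
}

#' Node table of a ceRNA network
#' @param network A `"cerna_network"`.
#' @return Data frame with `node`, `type`, `degree`.
#' @export
network_nodes <- function(network) {
  g <- network$graph
  data.frame(node = igraph::V(g)$name, type = igraph::V(g)$type,
             degree = as.integer(igraph::degree(g)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Edge table of a ceRNA network
#' @param network A `"cerna_network"`.
#' @return Data frame with `source`, `interaction`, `target`.
#' @export
network_edges <- function(network) {
  g <- network$graph
  el <- igraph::as_edgelist(g)
  data.frame(source = el[, 1L],
             interaction = igraph::E(g)$interaction,
             target = el[, 2L],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.cerna_network <- function(x, ...) {
  nodes <- network_nodes(x)
  cat(sprintf("ceRNA network: %d nodes, %d edges\n",
              nrow(nodes), igraph::ecount(x$graph)))
  print(table(nodes$type))
  invisible(x)
}

#' Plot a ceRNA network with degree-scaled nodes
#'
#' Node size is proportional to degree and color encodes node type
#' (lncRNA, mRNA, miRNA, other), the conventional rendering of ceRNA
#' networks.
#'
#' @param x A `"cerna_network"`.
#' @param ... Passed to `plot.igraph`.
#' @export
plot.cerna_network <- function(x, ...) {
  g <- x$graph
  pal <- c(lncRNA = "#D55E00", mRNA = "#009E73", miRNA = "#0072B2",
           other = "#999999")
  col <- pal[igraph::V(g)$type]
  col[is.na(col)] <- pal[["other"]]
  deg <- igraph::degree(g)
  plot(g, vertex.color = col,
       vertex.size = 4 + 10 * deg / max(1, max(deg)),
       vertex.label.cex = 0.6, ...)
  legend("topleft", legend = names(pal), pt.bg = pal, pch = 21, bty = "n")
  invisible(x)
}

#' Overlay differential-methylation calls on a ceRNA network
#'
#' Intersects the network's lncRNA and mRNA node sets with the
#' methylation-differential features, and additionally reports the subset
#' of methylation-differential mRNAs that form a ceRNA pair with at least
#' one lncRNA (the gene list typically sent to enrichment analysis).
#'
#' @param network A `"cerna_network"` with typed nodes.
#' @param dm A `"diff_table"` of methylation calls, or a character vector
#'   of methylation-differential feature ids.
#' @return An object of class `"meth_overlay"`: list with sorted character
#'   vectors `lncrna_meth`, `mrna_meth` and `mrna_paired_with_lncrna`.
#' @export
overlay_methylation <- function(network, dm) {
  meth <- if (inherits(dm, "data.frame"))
    dm$feature_id[dm$call != "none"] else as.character(dm)
  nodes <- network_nodes(network)
  lnc <- nodes$node[nodes$type == "lncRNA"]
  mrna <- nodes$node[nodes$type == "mRNA"]
  lnc_meth <- sort(intersect(lnc, meth))
  mrna_meth <- sort(intersect(mrna, meth))
  pr <- network$pairs
  type_of <- setNames(nodes$type, nodes$node)
  with_lnc <- c(pr$rna_b[type_of[pr$rna_a] == "lncRNA"],
                pr$rna_a[type_of[pr$rna_b] == "lncRNA"])
  paired <- sort(intersect(mrna_meth, with_lnc))
  structure(list(lncrna_meth = lnc_meth, mrna_meth = mrna_meth,
                 mrna_paired_with_lncrna = paired),
            class = "meth_overlay")
}

#' @export
print.meth_overlay <- function(x, ...) {
  cat(sprintf(paste0(
    "methylation overlay: %d lncRNAs and %d mRNAs in the network are\n",
    "methylation-differential; %d of those mRNAs form a ceRNA pair with a\n",
    "lncRNA\n"),
    length(x$lncrna_meth), length(x$mrna_meth),
    length(x$mrna_paired_with_lncrna)))
  invisible(x)
}

#' Candidate lncRNAs: methylation-differential network lncRNAs that are
#' also differentially expressed
#'
#' Plain set intersection of the network lncRNAs carrying a methylation
#' difference with the differentially expressed lncRNAs, yielding the
#' candidates screened for prognosis.
#'
#' @param meth_lncrnas Character vector (e.g. `lncrna_meth` from
#'   [overlay_methylation()]).
#' @param de_lncrnas Character vector of differentially expressed lncRNAs.
#' @return Sorted character vector.
#' @export
candidate_lncrnas <- function(meth_lncrnas, de_lncrnas) {
  sort(intersect(as.character(meth_lncrnas), as.character(de_lncrnas)))
}

#' Extract the subnetwork around a set of focus nodes
#'
#' Returns the induced subgraph on the focus nodes plus their first
#' neighbors, with degrees recomputed within the subgraph. Focus ids absent
#' from the network are ignored with a warning.
#'
#' @param network A `"cerna_network"`.
#' @param focus_nodes Character vector of node ids.
#' @return A `"cerna_network"` on the closed neighborhood of the focus set.
#' @export
extract_subnetwork <- function(network, focus_nodes) {
  g <- network$graph
  focus_nodes <- unique(as.character(focus_nodes))
  missing <- setdiff(focus_nodes, igraph::V(g)$name)
  if (length(missing))
    warning("focus nodes not in network (ignored): ",
            paste(missing, collapse = ", "))
  focus_nodes <- setdiff(focus_nodes, missing)
  if (!length(focus_nodes)) {
    sub <- igraph::induced_subgraph(g, integer(0))
    pairs <- network$pairs[0, , drop = FALSE]
    return(structure(list(graph = sub, pairs = pairs),
                     class = "cerna_network"))
  }
  nb <- unique(unlist(lapply(
    igraph::ego(g, order = 1, nodes = focus_nodes), names)))
  sub <- igraph::induced_subgraph(g, nb)
  keep_ids <- igraph::V(sub)$name
  pr <- network$pairs
  pairs <- pr[pr$rna_a %in% keep_ids & pr$rna_b %in% keep_ids, ,
              drop = FALSE]
  structure(list(graph = sub, pairs = pairs), class = "cerna_network")
}
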