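#' Construct an expression matrix with tumor/normal group labels
#'
#' The central expression container: a numeric features x samples matrix on
#' the log2 scale together with a per-sample group label (`"tumor"` or
#' `"normal"`). Feature ids must be unique and every sample must carry a
#' label.
#'
#' @param values Numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). Values are assumed
#'   log2-scale unless `log2_transform = TRUE`.
#' @param groups Character vector of group labels, either named by sample id
#'   or in column order; values must be `"tumor"` or `"normal"`.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to raw-scale values.
#' @return An object of class `"expr_matrix"`: a list with elements `values`
#'   (the matrix) and `groups` (named character vector).
#' @examples
#' m <- matrix(rnorm(12, 8), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expression_matrix(m, c("tumor", "tumor", "normal", "normal"))
#' em
#' @export
expression_matrix <- function(values, groups, log2_transform = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  groups <- as.character(groups) |> setNames(names(groups))
  if (is.null(names(groups))) {
    if (length(groups) != ncol(values))
      stop("`groups` length does not match number of samples")
    names(groups) <- colnames(values)
  }
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "))
  groups <- groups[colnames(values)]
  bad <- setdiff(unique(groups), c("tumor", "normal"))
  if (length(bad))
    stop("group labels must be 'tumor' or 'normal'; found: ",
         paste(bad, collapse = ", "))
  if (log2_transform) values <- log2(values + 1)
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d features x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$groups == "tumor"), sum(x$groups == "normal")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read a tab-delimited expression matrix
#'
#' Expects a header row of sample ids and a first column of feature ids;
#' remaining cells must be numeric. Duplicate feature-id rows are collapsed
#' to their per-sample arithmetic mean (the standard probe-to-gene rule; see
#' [collapse_features()]).
#'
#' @param path Path to a TSV file.
#' @param groups Group labels covering all samples: a named character vector,
#'   or a path to a two-column TSV (`sample`, `group`).
#' @param log2_transform Apply `log2(x + 1)` on read (for raw-scale input).
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path, groups, log2_transform = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty or malformed expression file: ", path)
  ids <- as.character(df[[1L]])
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample columns in ", path, ": ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!vapply(df[-1L], is.numeric, logical(1L)))
    for (j in bad) {
      col <- df[[j + 1L]]
      i <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))[1L]
      stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                   col[i], ids[i], sample_ids[j]))
    }
  }
  rownames(vals) <- make.unique(ids)  # temporary; duplicates collapsed below
  if (is.character(groups) && length(groups) == 1L && file.exists(groups))
    groups <- read_group_file(groups)
  if (!is.null(names(groups))) {
    missing <- setdiff(sample_ids, names(groups))
    if (length(missing))
      stop("group labels missing for samples: ",
           paste(missing, collapse = ", "))
    groups <- groups[sample_ids]
  }
  em <- expression_matrix(vals, groups, log2_transform = log2_transform)
  if (anyDuplicated(ids)) {
    message(sprintf("collapsing %d duplicate feature rows by mean",
                    sum(duplicated(ids))))
    em <- collapse_features(em, setNames(ids, rownames(em$values)))
  }
  em
}

read_group_file <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Write an expression matrix (and its group labels) to TSV
#'
#' @param em An [expression_matrix()].
#' @param path Output TSV path; first column `feature_id`.
#' @param groups_path Optional path for a two-column `sample`/`group` TSV.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(em, path, groups_path = NULL) {
  df <- data.frame(feature_id = rownames(em$values), em$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(groups_path))
    write.table(data.frame(sample = names(em$groups), group = em$groups),
                groups_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to gene-level rows by mean
#'
#' When several probes map to one gene the gene's expression is the
#' arithmetic mean of its probes, computed per sample; probes without a gene
#' symbol in the mapping are removed.
#'
#' @param em An [expression_matrix()] whose rows are probes.
#' @param probe_to_gene Named character vector (names = probe ids, values =
#'   gene ids) or a two-column data frame (probe, gene).
#' @return An [expression_matrix()] with one row per mapped gene, in order of
#'   first appearance among the probes.
#' @examples
#' m <- matrix(c(2, 4, 4, 6), 2, 2, byrow = TRUE,
#'             dimnames = list(c("p1", "p2"), c("s1", "s2")))
#' em <- expression_matrix(m, c("tumor", "normal"))
#' collapse_features(em, c(p1 = "G", p2 = "G"))$values
#' @export
collapse_features <- function(em, probe_to_gene) {
  if (is.data.frame(probe_to_gene))
    probe_to_gene <- setNames(as.character(probe_to_gene[[2L]]),
                              as.character(probe_to_gene[[1L]]))
  if (length(probe_to_gene) == 0L) stop("empty probe-to-gene mapping")
  probes <- intersect(rownames(em$values), names(probe_to_gene))
  dropped <- nrow(em$values) - length(probes)
  if (dropped > 0L)
    message(sprintf("dropping %d probes without a gene symbol", dropped))
  if (length(probes) == 0L) stop("no probes match the mapping")
  genes <- probe_to_gene[probes]
  sub <- em$values[probes, , drop = FALSE]
  sums <- rowsum(sub, group = genes, reorder = FALSE)
  counts <- as.vector(table(factor(genes, levels = rownames(sums))))
  expression_matrix(sums / counts, em$groups)
}

#' Construct or read a target map (RNA to miRNA target sets)
#'
#' A target map records, for each RNA, the set of miRNAs predicted to bind
#' it, together with the miRNA universe the hypergeometric test is computed
#' against. Unless supplied, the universe is the union of all target sets.
#'
#' @param targets Named list of character vectors (RNA id -> miRNA ids).
#' @param universe Optional character vector of miRNA ids; must contain every
#'   target set.
#' @return An object of class `"target_map"`.
#' @export
target_map <- function(targets, universe = NULL) {
  if (!length(targets) || is.null(names(targets)))
    stop("`targets` must be a non-empty named list")
  targets <- lapply(targets, function(x) sort(unique(as.character(x))))
  empty <- names(targets)[lengths(targets) == 0L]
  if (length(empty)) {
    warning("dropping RNAs with empty target sets: ",
            paste(empty, collapse = ", "))
    targets <- targets[lengths(targets) > 0L]
  }
  if (!length(targets)) stop("no RNAs with non-empty target sets")
  targets <- targets[order(names(targets))]
  all_mirnas <- sort(unique(unlist(targets, use.names = FALSE)))
  if (is.null(universe)) universe <- all_mirnas
  else {
    universe <- sort(unique(as.character(universe)))
    out <- setdiff(all_mirnas, universe)
    if (length(out))
      stop("universe does not contain target miRNAs: ",
           paste(head(out, 5L), collapse = ", "))
  }
  structure(list(targets = targets, universe = universe),
            class = "target_map")
}

#' @export
print.target_map <- function(x, ...) {
  cat(sprintf("target_map: %d RNAs, universe of %d miRNAs, %s targets/RNA\n",
              length(x$targets), length(x$universe),
              format(mean(lengths(x$targets)), digits = 3)))
  invisible(x)
}

#' Read a target map from a two-column TSV or a GMT file
#'
#' The TSV form has one (RNA, miRNA) pair per row (header optional,
#' detected); the GMT form has one RNA per line: id, description, then its
#' miRNAs. Duplicate pairs are collapsed (set semantics); RNAs with no
#' miRNAs are dropped with a warning.
#'
#' @param path Input file; format chosen by extension (`.gmt` = GMT) unless
#'   `format` is given.
#' @param universe Optional explicit miRNA universe (character vector or a
#'   one-column file of ids).
#' @param format `"auto"`, `"tsv"` or `"gmt"`.
#' @return A [target_map()].
#' @export
read_target_map <- function(path, universe = NULL,
                            format = c("auto", "tsv", "gmt")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.gmt$", path, ignore.case = TRUE)) "gmt" else "tsv"
  if (is.character(universe) && length(universe) == 1L &&
      file.exists(universe))
    universe <- readLines(universe)
  if (format == "gmt") {
    gs <- read_gmt(path)
    return(target_map(gs$sets, universe))
  }
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("target TSV needs two columns: RNA, miRNA")
  if (identical(tolower(as.character(df[1L, 1L])), "rna") ||
      identical(tolower(as.character(df[1L, 2L])), "mirna"))
    df <- df[-1L, , drop = FALSE]
  targets <- split(as.character(df[[2L]]), as.character(df[[1L]]))
  target_map(targets, universe)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `id`, `description`,
#' member genes. Empty sets are dropped with a warning; duplicate set ids
#' are an error.
#'
#' @param path GMT file path.
#' @return An object of class `"gene_sets"`: list with `sets` (named list of
#'   character vectors) and `descriptions` (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop("duplicate gene-set ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  desc <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else "",
                 character(1L))
  sets <- lapply(parts, function(p)
    sort(unique(p[-(1:2)][nzchar(p[-(1:2)])])))
  names(sets) <- ids
  names(desc) <- ids
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping empty gene sets: ", paste(ids[empty], collapse = ", "))
    sets <- sets[!empty]
    desc <- desc[!empty]
  }
  structure(list(sets = sets, descriptions = desc), class = "gene_sets")
}

#' Write a gene-set collection to GMT
#' @param gs A `"gene_sets"` object (see [read_gmt()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(gs, path) {
  lines <- vapply(names(gs$sets), function(id)
    paste(c(id, gs$descriptions[[id]], gs$sets[[id]]), collapse = "\t"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical follow-up table
#'
#' Expects columns `sample_id` (or `sample`), `time` (days, > 0) and `event`
#' (1 = death observed, 0 = censored).
#'
#' @param path TSV path.
#' @return A validated data frame of class `"clinical_table"`.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df)[names(df) == "sample"] <- "sample_id"
  clinical_table(df)
}

#' Validate a clinical table
#' @param df Data frame with `sample_id`, `time`, `event` columns.
#' @return The validated data frame, classed `"clinical_table"`.
#' @export
clinical_table <- function(df) {
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids")
  if (any(!is.finite(df$time)) || any(df$time <= 0))
    stop("follow-up times must be positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
  class(df) <- c("clinical_table", "data.frame")
  df
}

#' Write a network as an edge list plus node-attribute table
#'
#' The edge file is a headered SIF-style TSV (`source`, `interaction`,
#' `target`); the node file lists `node`, `type` and `degree`. Both are
#' sorted lexicographically so output is deterministic and directly
#' importable by Cytoscape.
#'
#' @param network A `"cerna_network"` (see [build_network()]).
#' @param edge_path Output path for the edge table.
#' @param node_path Output path for the node-attribute table.
#' @return Invisibly, `edge_path`.
#' @export
write_edge_list <- function(network, edge_path, node_path) {
  edges <- network_edges(network)
  if (nrow(edges) == 0L) stop("network has no edges")
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  write.table(edges, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  nodes <- network_nodes(network)
  nodes <- nodes[order(nodes$node), , drop = FALSE]
  write.table(nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(edge_path)
}

#' Read an edge list written by [write_edge_list()]
#' @param edge_path Edge-table path.
#' @return Data frame with `source`, `interaction`, `target`.
#' @export
read_edge_list <- function(edge_path) {
  read.delim(edge_path, stringsAsFactors = FALSE)
}
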