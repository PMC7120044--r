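#' Two-group differential expression screen
#'
#' Per-feature two-sample test of tumor versus normal on log2-scale values.
#' The effect size is `log2fc = mean(tumor) - mean(normal)`; p-values come
#' from a Welch (default) or pooled-variance Student t-test, and are
#' Benjamini--Hochberg adjusted across features. The expression call uses
#' the raw p-value (`p_raw < p_cut` and `|log2fc| > effect_cut`); the
#' methylation variant ([differential_methylation()]) uses the adjusted
#' p-value instead.
#'
#' Features with any missing value are dropped with a message. A feature
#' with zero variance in both groups gets `p_raw = 1` when the group means
#' are equal (no evidence either way) and `p_raw = 0` when they differ
#' deterministically.
#'
#' @param em An [expression_matrix()] with both groups of size >= 2.
#' @param p_cut Significance cutoff (strict `<`), default 0.05.
#' @param effect_cut Effect-size cutoff (strict `>` on `|log2fc|`), default 1.
#' @param p_col Which p-value feeds the call: `"raw"` (expression
#'   convention) or `"adj"` (methylation convention).
#' @param test `"welch"` (unequal variances, default) or `"student"`.
#' @return A data frame of class `"diff_table"` with columns `feature_id`,
#'   `log2fc`, `p_raw`, `p_adj` and `call` (`"up"`, `"down"`, `"none"`),
#'   one row per tested feature in input order.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(200, 8), 20, 10,
#'             dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:10)))
#' m[1, 1:5] <- m[1, 1:5] + 3  # strong tumor shift
#' em <- expression_matrix(m, rep(c("tumor", "normal"), each = 5))
#' head(differential_expression(em))
#' @export
differential_expression <- function(em, p_cut = 0.05, effect_cut = 1,
                                    p_col = c("raw", "adj"),
                                    test = c("welch", "student")) {
  p_col <- match.arg(p_col)
  test <- match.arg(test)
  stopifnot(inherits(em, "expr_matrix"))
  is_t <- em$groups == "tumor"
  n1 <- sum(is_t); n2 <- sum(!is_t)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 samples (tumor=", n1,
         ", normal=", n2, ")")
  vals <- em$values
  ok <- rowSums(is.na(vals)) == 0L
  if (any(!ok)) {
    message(sprintf("dropping %d features with missing values", sum(!ok)))
    vals <- vals[ok, , drop = FALSE]
  }
  if (nrow(vals) == 0L) stop("no complete features to test")
  x1 <- vals[, is_t, drop = FALSE]
  x2 <- vals[, !is_t, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1L)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1L)
  fc <- m1 - m2
  if (test == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  } else {
    sp2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / (n1 + n2 - 2L)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep.int(n1 + n2 - 2L, length(fc))
  }
  tstat <- fc / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate] <- ifelse(fc[degenerate] == 0, 1, 0)
  tab <- data.frame(feature_id = rownames(vals), log2fc = fc,
                    p_raw = pmin(p, 1), p_adj = p.adjust(pmin(p, 1), "BH"),
                    call = "none", row.names = NULL,
                    stringsAsFactors = FALSE)
  differential_calls(tab, p_col = p_col, p_cut = p_cut,
                     effect_cut = effect_cut)
}

#' Apply (or re-apply) up/down/none calls to a differential table
#'
#' The screening rule is `p < p_cut` (strict) on the chosen p-value column
#' and `|effect| > effect_cut` (strict); the direction of the effect gives
#' `"up"` or `"down"`.
#'
#' @param tab Data frame with `feature_id`, `log2fc`, `p_raw` and
#'   optionally `p_adj` (computed by BH if absent).
#' @inheritParams differential_expression
#' @return The table with an updated `call` column, classed `"diff_table"`.
#' @export
differential_calls <- function(tab, p_col = c("raw", "adj"), p_cut = 0.05,
                               effect_cut = 1) {
  p_col <- match.arg(p_col)
  need <- c("feature_id", "log2fc", "p_raw")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("differential table missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(tab$p_adj)) tab$p_adj <- p.adjust(tab$p_raw, "BH")
  p <- if (p_col == "raw") tab$p_raw else tab$p_adj
  sig <- p < p_cut & abs(tab$log2fc) > effect_cut
  tab$call <- ifelse(sig & tab$log2fc > 0, "up",
                     ifelse(sig & tab$log2fc < 0, "down", "none"))
  attr(tab, "p_col") <- p_col
  attr(tab, "p_cut") <- p_cut
  attr(tab, "effect_cut") <- effect_cut
  class(tab) <- unique(c("diff_table", class(tab)))
  tab
}

#' Two-group differential methylation screen
#'
#' Same machinery as [differential_expression()], but following the
#' methylation convention: the call uses the BH-adjusted p-value
#' (`p_adj < p_cut`) and the effect (`log2fc` column, here the tumor-minus-
#' normal delta on the supplied value scale, e.g. M-values) must exceed
#' `effect_cut` in magnitude. Accepts either a methylation
#' [expression_matrix()] or a precomputed table with `feature_id`,
#' `log2fc`/`delta` and `p_raw` (and optionally `p_adj`) columns.
#'
#' @param x An [expression_matrix()] of methylation values, or a
#'   precomputed data frame.
#' @inheritParams differential_expression
#' @return A `"diff_table"` (see [differential_expression()]).
#' @export
differential_methylation <- function(x, p_cut = 0.05, effect_cut = 1,
                                     p_col = c("adj", "raw"),
                                     test = c("welch", "student")) {
  p_col <- match.arg(p_col)
  if (inherits(x, "expr_matrix")) {
    tab <- differential_expression(x, test = match.arg(test))
  } else {
    tab <- as.data.frame(x, stringsAsFactors = FALSE)
    if (is.null(tab$log2fc) && !is.null(tab$delta)) tab$log2fc <- tab$delta
    if (is.null(tab$p_raw) && !is.null(tab$p)) tab$p_raw <- tab$p
  }
  differential_calls(tab, p_col = p_col, p_cut = p_cut,
                     effect_cut = effect_cut)
}

#' Consensus signature across differential tables
#'
#' Intersects the up-regulated calls of all tables, and separately the
#' down-regulated calls, mirroring the Venn-diagram consensus step across
#' independent datasets.
#'
#' @param tables A list of two or more `"diff_table"` objects.
#' @return A list with sorted character vectors `up` and `down`.
#' @examples
#' t1 <- data.frame(feature_id = c("a", "b", "c"), log2fc = 2,
#'                  p_raw = 0.01)
#' t2 <- data.frame(feature_id = c("b", "c", "d"), log2fc = 2,
#'                  p_raw = 0.01)
#' consensus_signature(list(differential_calls(t1), differential_calls(t2)))
#' @export
consensus_signature <- function(tables) {
  if (length(tables) < 2L) stop("consensus requires at least two tables")
  ups <- lapply(tables, function(t) t$feature_id[t$call == "up"])
  downs <- lapply(tables, function(t) t$feature_id[t$call == "down"])
  list(up = sort(Reduce(intersect, ups)),
       down = sort(Reduce(intersect, downs)))
}
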