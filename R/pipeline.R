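#' Assemble a validated pipeline configuration
#'
#' One flat configuration object holding every input path and every
#' threshold of the pipeline, so a run is fully described by a single
#' value. File existence is checked at run time, stage by stage.
#'
#' @param mirna Character vector of >= 1 miRNA expression TSV paths.
#' @param mirna_groups Group-file paths matching `mirna`.
#' @param rna RNA (lncRNA+mRNA) expression TSV path.
#' @param rna_groups Group-file path for `rna`.
#' @param targets Target-map path (two-column TSV or GMT).
#' @param methylation Methylation matrix TSV (with `methylation_groups`) or
#'   a precomputed differential table TSV (`feature_id`, `log2fc`/`delta`,
#'   `p_raw`; set `methylation_groups = NULL`).
#' @param methylation_groups Group-file path for the methylation matrix, or
#'   `NULL` when `methylation` is a precomputed table.
#' @param gene_sets GMT path for enrichment.
#' @param clinical Clinical TSV path (`sample_id`, `time`, `event`).
#' @param rna_types Two-column TSV (id, type) typing RNAs as
#'   `lncRNA`/`mRNA`.
#' @param outdir Output directory.
#' @param expr_p,expr_effect Expression call thresholds (raw p, |log2FC|).
#' @param meth_p,meth_effect Methylation call thresholds (adjusted p,
#'   |delta|).
#' @param pair_p,pair_r ceRNA pair thresholds (hypergeometric p, Pearson r).
#' @param enrich_fdr,enrich_display_p Enrichment FDR and display cutoffs.
#' @param screen_p Log-rank screening threshold (`p <= screen_p`).
#' @param horizon ROC horizon in days (3 years = 1095).
#' @param seed Integer seed echoed into the manifest.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(mirna, mirna_groups, rna, rna_groups, targets,
                            methylation, methylation_groups = NULL,
                            gene_sets, clinical, rna_types, outdir,
                            expr_p = 0.05, expr_effect = 1,
                            meth_p = 0.05, meth_effect = 1,
                            pair_p = 0.05, pair_r = 0.7,
                            enrich_fdr = 0.05, enrich_display_p = 0.01,
                            screen_p = 0.05, horizon = 1095, seed = 1L) {
  cfg <- as.list(environment())
  if (length(cfg$mirna) < 1L) stop("at least one miRNA dataset is required")
  if (length(cfg$mirna_groups) != length(cfg$mirna))
    stop("mirna_groups must match mirna datasets")
  for (nm in c("expr_p", "meth_p", "pair_p", "enrich_fdr",
               "enrich_display_p", "screen_p")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || v <= 0 || v > 1)
      stop(nm, " must be a probability in (0, 1]")
  }
  if (cfg$pair_r < -1 || cfg$pair_r > 1) stop("pair_r must be in [-1, 1]")
  if (cfg$horizon <= 0) stop("horizon must be positive")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

require_file <- function(path, stage) {
  if (!file.exists(path))
    stop(sprintf("[%s] input file not found: %s", stage, path))
  path
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full ceRNA + methylation + prognosis pipeline
#'
#' Executes, in order: per-dataset differential miRNA screening and the
#' cross-dataset consensus; differential RNA screening; ceRNA pair
#' inference (hypergeometric shared-target test + Pearson filter) and
#' network assembly; differential methylation and its overlay on the
#' network; candidate-lncRNA intersection; gene-set over-representation of
#' the methylation-differential mRNAs paired with lncRNAs; the per-lncRNA
#' median-split log-rank screen; and, when any candidate passes the
#' screen, a multivariable Cox risk model with fixed-horizon AUC. Every
#' stage's table is written to `outdir` and a deterministic JSON manifest
#' records input hashes, the configuration, and per-stage row counts, so
#' a rerun on identical inputs is bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly, as a named list (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "setup"
  run <- function(name, expr) {
    stage <<- name
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, ...)

  inputs <- c(config$mirna, config$mirna_groups, config$rna,
              config$rna_groups, config$targets, config$methylation,
              config$methylation_groups, config$gene_sets, config$clinical,
              config$rna_types)
  for (f in inputs) require_file(f, "setup")

  mirna_tabs <- run("differential_mirna", {
    lapply(seq_along(config$mirna), function(i) {
      em <- read_expression_matrix(config$mirna[i],
                                   config$mirna_groups[i])
      tab <- differential_expression(em, p_cut = config$expr_p,
                                     effect_cut = config$expr_effect)
      write_tsv(tab, out(sprintf("mirna_de_%d.tsv", i)))
      tab
    })
  })
  consensus <- run("consensus", {
    cs <- if (length(mirna_tabs) >= 2L) consensus_signature(mirna_tabs)
          else list(up = sort(mirna_tabs[[1]]$feature_id[
                      mirna_tabs[[1]]$call == "up"]),
                    down = sort(mirna_tabs[[1]]$feature_id[
                      mirna_tabs[[1]]$call == "down"]))
    write_tsv(data.frame(
      mirna = c(cs$up, cs$down),
      direction = rep(c("up", "down"), c(length(cs$up), length(cs$down)))),
      out("consensus_mirnas.tsv"))
    cs
  })

  rna_em <- run("read_rna", read_expression_matrix(config$rna,
                                                   config$rna_groups))
  types <- run("read_rna_types", {
    df <- read.delim(config$rna_types, stringsAsFactors = FALSE)
    setNames(as.character(df[[2L]]), as.character(df[[1L]]))
  })
  rna_de <- run("differential_rna", {
    tab <- differential_expression(rna_em, p_cut = config$expr_p,
                                   effect_cut = config$expr_effect)
    write_tsv(tab, out("rna_de.tsv"))
    tab
  })
  lnc_ids <- names(types)[types == "lncRNA"]
  de_lnc <- rna_de$feature_id[rna_de$call != "none" &
                              rna_de$feature_id %in% lnc_ids]

  pairs <- run("cerna_pairs", {
    tm <- read_target_map(config$targets)
    pr <- infer_cerna_pairs(rna_em, tm, p_cut = config$pair_p,
                            r_cut = config$pair_r)
    write_tsv(as.data.frame(pr), out("cerna_pairs.tsv"))
    pr
  })
  network <- run("network", {
    net <- build_network(pairs, rna_types = types,
                         include_mirna_edges = FALSE)
    write_edge_list(net, out("network_edges.tsv"), out("network_nodes.tsv"))
    net
  })

  meth_de <- run("differential_methylation", {
    tab <- if (is.null(config$methylation_groups)) {
      differential_methylation(read.delim(config$methylation,
                                          stringsAsFactors = FALSE),
                               p_cut = config$meth_p,
                               effect_cut = config$meth_effect)
    } else {
      differential_methylation(
        read_expression_matrix(config$methylation,
                               config$methylation_groups),
        p_cut = config$meth_p, effect_cut = config$meth_effect)
    }
    write_tsv(tab, out("methylation_de.tsv"))
    tab
  })
  overlay <- run("overlay", {
    ov <- overlay_methylation(network, meth_de)
    write_tsv(data.frame(
      gene = c(ov$lncrna_meth, ov$mrna_meth, ov$mrna_paired_with_lncrna),
      category = rep(c("lncrna_meth", "mrna_meth",
                       "mrna_paired_with_lncrna"),
                     c(length(ov$lncrna_meth), length(ov$mrna_meth),
                       length(ov$mrna_paired_with_lncrna)))),
      out("methylation_overlay.tsv"))
    ov
  })
  candidates <- run("candidates", {
    cand <- candidate_lncrnas(overlay$lncrna_meth, de_lnc)
    writeLines(cand, out("candidate_lncrnas.txt"))
    cand
  })

  enrichment <- run("enrichment", {
    query <- overlay$mrna_paired_with_lncrna
    if (length(query)) {
      gs <- read_gmt(config$gene_sets)
      res <- enrich(query, gs,
                    universe = sort(names(types)[types == "mRNA"]))
      write_tsv(as.data.frame(res), out("enrichment.tsv"))
      write_tsv(as.data.frame(
        filter_enrichment(res, fdr_cut = config$enrich_fdr)),
        out("enrichment_significant.tsv"))
      res
    } else {
      message("no methylation-differential paired mRNAs; skipping enrichment")
      NULL
    }
  })

  clinical <- run("read_clinical", read_clinical_table(config$clinical))
  screen <- run("survival_screen", {
    feats <- intersect(candidates, rownames(rna_em$values))
    if (length(feats)) {
      sc <- survival_screen(rna_em, clinical, feats)
      write_tsv(sc, out("survival_screen.tsv"))
      sc
    } else {
      message("no candidate lncRNAs to screen")
      NULL
    }
  })
  prognostic <- if (!is.null(screen))
    screen$feature_id[screen$logrank_p <= config$screen_p] else character(0)

  model <- run("cox_model", {
    if (length(prognostic)) {
      m <- suppressWarnings(cox_fit(rna_em, clinical,
                                    features = prognostic))
      write_tsv(data.frame(feature_id = names(coef(m)),
                           coefficient = unname(coef(m))),
                out("risk_coefficients.tsv"))
      write_tsv(data.frame(sample_id = names(m$risk_score),
                           risk_score = unname(m$risk_score)),
                out("risk_scores.tsv"))
      m
    } else {
      message("no lncRNA passed the survival screen; skipping Cox model")
      NULL
    }
  })
  auc <- run("horizon_auc", {
    if (!is.null(model))
      tryCatch(as.numeric(auc_at_horizon(model, clinical,
                                         horizon = config$horizon)),
               error = function(e) {
                 message("horizon AUC unavailable: ", conditionMessage(e))
                 NA_real_
               })
    else NA_real_
  })

  manifest <- list(
    package_version = as.character(packageVersion("cernet")),
    config = lapply(unclass(config), function(x)
      if (is.numeric(x)) x else as.character(x)),
    input_md5 = as.list(tools::md5sum(inputs)),
    counts = list(
      mirna_de = vapply(mirna_tabs, function(t)
        sum(t$call != "none"), integer(1L)),
      consensus_up = length(consensus$up),
      consensus_down = length(consensus$down),
      rna_de = sum(rna_de$call != "none"),
      de_lncrnas = length(de_lnc),
      cerna_pairs = nrow(pairs),
      network_nodes = nrow(network_nodes(network)),
      network_edges = nrow(network_edges(network)),
      methylation_de = sum(meth_de$call != "none"),
      overlay_lncrna = length(overlay$lncrna_meth),
      overlay_mrna = length(overlay$mrna_meth),
      overlay_mrna_paired = length(overlay$mrna_paired_with_lncrna),
      candidate_lncrnas = length(candidates),
      enriched_sets = if (is.null(enrichment)) 0L else
        nrow(filter_enrichment(enrichment, fdr_cut = config$enrich_fdr)),
      screened_lncrnas = if (is.null(screen)) 0L else nrow(screen),
      prognostic_lncrnas = length(prognostic)),
    horizon_auc = auc)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
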