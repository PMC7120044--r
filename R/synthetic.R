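#' Configuration for the synthetic cohort generator
#'
#' Collects every knob of the generative model in one validated object.
#' Defaults describe the reference study conditions used throughout the
#' package's tests: 25 tumor + 25 normal samples, a universe of 100 miRNAs
#' with 10 predicted targets per RNA, 20 planted lncRNA--mRNA ceRNA pairs
#' sharing 8 of their 10 miRNAs, a log2 differential shift of 2 against
#' residual noise of 0.5, a shared latent factor with loading 1.5 driving
#' pair co-expression, 30% of genes planted as methylation-differential,
#' and exponential survival whose log-hazard rises by `hazard_beta` per
#' standard deviation of each planted prognostic lncRNA.
#'
#' @param n_tumor,n_normal Samples per group (each expression dataset).
#' @param n_mirna Number of miRNAs; also the target universe size.
#' @param n_lncrna,n_mrna Number of lncRNA and mRNA features.
#' @param n_planted_pairs Planted ceRNA pairs (lncRNA_i -- mRNA_i).
#' @param shared_targets_planted Shared miRNA count per planted pair; must
#'   not exceed `targets_per_rna`.
#' @param targets_per_rna Baseline predicted-target-set size per RNA.
#' @param de_shift Log2 shift applied to planted differential features in
#'   tumor samples.
#' @param noise_sd Residual (per-sample) standard deviation on the log2
#'   scale.
#' @param factor_loading Loading of the per-sample latent factor shared by
#'   the two members of each planted pair.
#' @param n_de_mirna Planted differential miRNAs (half up, half down),
#'   shared by both generated miRNA datasets.
#' @param n_de_lncrna Planted differential lncRNAs, drawn from the planted
#'   pair lncRNAs; each one's partner mRNA is shifted in the same
#'   direction (ceRNA partners co-vary). Must be `<= n_planted_pairs`.
#' @param meth_frac Fraction of lncRNA+mRNA features planted as
#'   methylation-differential (always including the prognostic lncRNAs).
#' @param n_prognostic Planted prognostic lncRNAs (first
#'   `n_prognostic` planted differential lncRNAs); `<= n_de_lncrna`.
#' @param hazard_beta Log-hazard increase per standard deviation of each
#'   planted prognostic lncRNA's expression.
#' @param censor_frac Target fraction of censored follow-ups.
#' @param baseline_hazard Exponential baseline hazard per day (default:
#'   median survival of two years).
#' @param n_gene_sets,gene_set_size Toy GMT collection: number of random
#'   mRNA sets and their size; one additional planted set contains the
#'   paired mRNAs.
#' @param seed Integer master seed; one derived stream per generator
#'   component.
#' @return A validated list of class `"sim_config"`.
#' @export
simulation_config <- function(n_tumor = 25, n_normal = 25,
                              n_mirna = 100, n_lncrna = 60, n_mrna = 150,
                              n_planted_pairs = 20,
                              shared_targets_planted = 8,
                              targets_per_rna = 10,
                              de_shift = 2, noise_sd = 0.5,
                              factor_loading = 1.5,
                              n_de_mirna = 20, n_de_lncrna = 12,
                              meth_frac = 0.3, n_prognostic = 4,
                              hazard_beta = 0.8, censor_frac = 0.3,
                              baseline_hazard = log(2) / 730,
                              n_gene_sets = 10, gene_set_size = 15,
                              seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_tumor", "n_normal", "n_mirna", "n_lncrna", "n_mrna",
              "targets_per_rna")
  for (nm in counts)
    if (cfg[[nm]] < 1) stop(nm, " must be >= 1")
  if (cfg$shared_targets_planted > cfg$targets_per_rna)
    stop("infeasible overlap: shared_targets_planted (",
         cfg$shared_targets_planted, ") exceeds targets_per_rna (",
         cfg$targets_per_rna, ")")
  if (cfg$n_mirna < 2 * cfg$targets_per_rna - cfg$shared_targets_planted)
    stop("universe too small for the requested planted overlap")
  if (cfg$n_planted_pairs > min(cfg$n_lncrna, cfg$n_mrna))
    stop("more planted pairs than available lncRNAs or mRNAs")
  if (cfg$n_de_lncrna > cfg$n_planted_pairs)
    stop("n_de_lncrna must not exceed n_planted_pairs")
  if (cfg$n_prognostic > cfg$n_de_lncrna)
    stop("n_prognostic must not exceed n_de_lncrna")
  if (cfg$n_de_mirna > cfg$n_mirna)
    stop("n_de_mirna must not exceed n_mirna")
  if (cfg$meth_frac < 0 || cfg$meth_frac > 1)
    stop("meth_frac must be in [0, 1]")
  if (cfg$censor_frac < 0 || cfg$censor_frac > 1)
    stop("censor_frac must be in [0, 1]")
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("synthetic cohort configuration:\n")
  cat(sprintf("  samples: %d tumor + %d normal; seed %d\n",
              x$n_tumor, x$n_normal, x$seed))
  cat(sprintf("  features: %d miRNA, %d lncRNA, %d mRNA\n",
              x$n_mirna, x$n_lncrna, x$n_mrna))
  cat(sprintf("  planted: %d pairs (%d/%d shared targets), %d DE miRNAs,",
              x$n_planted_pairs, x$shared_targets_planted,
              x$targets_per_rna, x$n_de_mirna))
  cat(sprintf(" %d DE lncRNAs,\n    meth_frac %.2f, %d prognostic (beta %.2f)\n",
              x$n_de_lncrna, x$meth_frac, x$n_prognostic, x$hazard_beta))
  invisible(x)
}

# Named per-component seeds derived from the master seed. Components draw
# from their own stream, so adding a component does not perturb the others.
component_seeds <- function(seed) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, 8L),
           c("mirna1", "mirna2", "rna", "targets", "methylation",
             "survival", "gene_sets", "reserve"))
}

# baseline log2 expression: per-feature mean ~ N(center, 1), residual
# noise ~ N(0, noise_sd); planted features shifted by shift * direction in
# tumor columns
simulate_matrix <- function(features, samples, groups, noise_sd,
                            shift = NULL, center = 8) {
  mu <- rnorm(length(features), center, 1)
  vals <- matrix(rnorm(length(features) * length(samples), 0, noise_sd),
                 length(features), length(samples),
                 dimnames = list(features, samples)) + mu
  if (!is.null(shift) && length(shift)) {
    idx <- match(names(shift), features)
    vals[idx, groups == "tumor"] <-
      vals[idx, groups == "tumor"] + unname(shift)
  }
  vals
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Produces every input the pipeline consumes -- two miRNA expression
#' matrices (independent noise, same planted differential miRNAs,
#' mimicking two array datasets), an lncRNA+mRNA expression matrix, a
#' target map, a methylation matrix, a clinical table, a toy gene-set
#' collection -- plus the ground-truth record of everything planted.
#'
#' The generative model: baseline log2 expression per feature is
#' `N(8, 1)` with residual noise `N(0, noise_sd)`; planted differential
#' features are shifted by `de_shift` (sign per feature) in tumor samples;
#' the two members of a planted ceRNA pair additionally share a per-sample
#' latent factor `N(0, 1)` scaled by `factor_loading`, which drives their
#' Pearson correlation; target sets are uniform draws of
#' `targets_per_rna` miRNAs, overridden for planted pairs to share exactly
#' `shared_targets_planted`; methylation values are `N(0, 1)` baselines
#' with planted genes shifted by `de_shift` on the M-value-like scale;
#' survival times for tumor samples are exponential with rate
#' `baseline_hazard * exp(hazard_beta * sum(z))` over the standardized
#' expression `z` of each planted prognostic lncRNA, censored uniformly on
#' `(0, c_max)` with `c_max` solved to hit `censor_frac` on average.
#' Identical seeds give bit-identical cohorts.
#'
#' @param config A [simulation_config()].
#' @return A list of class `"cerna_cohort"`: `mirna` (list of two
#'   [expression_matrix()]), `rna`, `methylation` (expression matrices),
#'   `targets` ([target_map()]), `clinical` ([clinical_table()]),
#'   `gene_sets`, `rna_types` (named character), `truth` (see below) and
#'   `config`. The `truth` element records `planted_pairs` (data frame),
#'   `de_mirna_up`/`de_mirna_down`, `de_lncrna_up`/`de_lncrna_down`,
#'   `de_mrna_up`/`de_mrna_down`, `meth_genes` and `prognostic_lncrnas`
#'   (named numeric of true hazard signs).
#' @export
generate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- component_seeds(config$seed)
  mirna_ids <- sprintf("MIR%04d", seq_len(config$n_mirna))
  lnc_ids <- sprintf("LNC%04d", seq_len(config$n_lncrna))
  mrna_ids <- sprintf("MRNA%04d", seq_len(config$n_mrna))
  rna_ids <- c(lnc_ids, mrna_ids)
  rna_types <- setNames(rep(c("lncRNA", "mRNA"),
                            c(config$n_lncrna, config$n_mrna)), rna_ids)

  # ---- planted structure (deterministic given ids) ----
  n_pp <- config$n_planted_pairs
  planted_pairs <- data.frame(lncrna = lnc_ids[seq_len(n_pp)],
                              mrna = mrna_ids[seq_len(n_pp)],
                              stringsAsFactors = FALSE)
  de_lnc <- lnc_ids[seq_len(config$n_de_lncrna)]
  de_lnc_dir <- setNames(rep_len(c(1, -1), config$n_de_lncrna), de_lnc)
  de_mrna <- mrna_ids[seq_len(config$n_de_lncrna)]  # same-pair partners
  de_mrna_dir <- setNames(unname(de_lnc_dir), de_mrna)
  prog <- de_lnc[seq_len(config$n_prognostic)]
  prog_sign <- setNames(rep(1, config$n_prognostic), prog)

  de_mir <- mirna_ids[seq_len(config$n_de_mirna)]
  de_mir_dir <- setNames(rep_len(c(1, -1), config$n_de_mirna), de_mir)

  groups <- rep(c("tumor", "normal"), c(config$n_tumor, config$n_normal))

  # ---- miRNA datasets ----
  mirna <- lapply(1:2, function(d) {
    set.seed(seeds[[paste0("mirna", d)]])
    samples <- sprintf("M%dS%03d", d, seq_along(groups))
    vals <- simulate_matrix(mirna_ids, samples, groups, config$noise_sd,
                            shift = de_mir_dir * config$de_shift)
    expression_matrix(vals, setNames(groups, samples))
  })

  # ---- RNA matrix with latent pair factors ----
  set.seed(seeds[["rna"]])
  rna_samples <- sprintf("RS%03d", seq_along(groups))
  rna_shift <- c(de_lnc_dir, de_mrna_dir) * config$de_shift
  rna_vals <- simulate_matrix(rna_ids, rna_samples, groups,
                              config$noise_sd, shift = rna_shift)
  if (n_pp > 0 && config$factor_loading != 0) {
    fac <- matrix(rnorm(n_pp * length(groups)), n_pp, length(groups))
    load <- config$factor_loading
    rna_vals[planted_pairs$lncrna, ] <-
      rna_vals[planted_pairs$lncrna, , drop = FALSE] + load * fac
    rna_vals[planted_pairs$mrna, ] <-
      rna_vals[planted_pairs$mrna, , drop = FALSE] + load * fac
  }
  rna <- expression_matrix(rna_vals, setNames(groups, rna_samples))

  # ---- target map ----
  set.seed(seeds[["targets"]])
  tsets <- lapply(setNames(rna_ids, rna_ids), function(id)
    sample(mirna_ids, config$targets_per_rna))
  s <- config$shared_targets_planted
  for (i in seq_len(n_pp)) {
    pool <- sample(mirna_ids)
    extra <- config$targets_per_rna - s
    tsets[[planted_pairs$lncrna[i]]] <- c(pool[seq_len(s)],
                                          pool[s + seq_len(extra)])
    tsets[[planted_pairs$mrna[i]]] <- c(pool[seq_len(s)],
                                        pool[s + extra + seq_len(extra)])
  }
  targets <- target_map(tsets, universe = mirna_ids)

  # ---- methylation matrix ----
  set.seed(seeds[["methylation"]])
  n_meth <- round(config$meth_frac * length(rna_ids))
  meth_genes <- character(0)
  if (n_meth > 0) {
    meth_genes <- unique(c(prog, sample(rna_ids, n_meth)))
    meth_genes <- c(prog, setdiff(meth_genes, prog)[
      seq_len(max(0, n_meth - length(prog)))])
    meth_genes <- sort(meth_genes)
  }
  meth_dir <- setNames(rep_len(c(1, -1), length(meth_genes)), meth_genes)
  meth_samples <- sprintf("MS%03d", seq_along(groups))
  meth_vals <- simulate_matrix(rna_ids, meth_samples, groups,
                               config$noise_sd,
                               shift = meth_dir * config$de_shift,
                               center = 0)
  methylation <- expression_matrix(meth_vals, setNames(groups, meth_samples))

  # ---- survival for the tumor samples of the RNA cohort ----
  set.seed(seeds[["survival"]])
  tumor_samples <- rna_samples[groups == "tumor"]
  lp <- rep(0, length(tumor_samples))
  if (length(prog)) {
    z <- scale(t(rna_vals[prog, groups == "tumor", drop = FALSE]))
    lp <- as.vector(z %*% (config$hazard_beta * prog_sign))
  }
  rate <- config$baseline_hazard * exp(lp)
  t_event <- rexp(length(rate), rate)
  if (config$censor_frac > 0) {
    cmax <- uniroot(function(cm)
      mean((1 - exp(-rate * cm)) / (rate * cm)) - config$censor_frac,
      interval = c(1e-6, 1e8), tol = 1e-8)$root
    t_cens <- runif(length(rate), 0, cmax)
  } else t_cens <- rep(Inf, length(rate))
  clinical <- clinical_table(data.frame(
    sample_id = tumor_samples,
    time = pmax(pmin(t_event, t_cens), 1e-3),
    event = as.integer(t_event <= t_cens),
    stringsAsFactors = FALSE))

  # ---- toy gene-set collection over mRNAs ----
  set.seed(seeds[["gene_sets"]])
  sets <- lapply(seq_len(config$n_gene_sets), function(i)
    sort(sample(mrna_ids, min(config$gene_set_size, length(mrna_ids)))))
  names(sets) <- sprintf("RANDOM_SET_%02d", seq_along(sets))
  if (n_pp > 0) sets$PLANTED_PAIRED_MRNAS <- sort(planted_pairs$mrna)
  desc <- setNames(c(rep("random background set", config$n_gene_sets),
                     if (n_pp > 0) "mRNAs planted as ceRNA pair partners"),
                   names(sets))
  gene_sets <- structure(list(sets = sets, descriptions = desc),
                         class = "gene_sets")

  truth <- list(
    planted_pairs = planted_pairs,
    de_mirna_up = sort(names(de_mir_dir)[de_mir_dir > 0]),
    de_mirna_down = sort(names(de_mir_dir)[de_mir_dir < 0]),
    de_lncrna_up = sort(names(de_lnc_dir)[de_lnc_dir > 0]),
    de_lncrna_down = sort(names(de_lnc_dir)[de_lnc_dir < 0]),
    de_mrna_up = sort(names(de_mrna_dir)[de_mrna_dir > 0]),
    de_mrna_down = sort(names(de_mrna_dir)[de_mrna_dir < 0]),
    meth_genes = meth_genes,
    prognostic_lncrnas = prog_sign)

  structure(list(mirna = mirna, rna = rna, methylation = methylation,
                 targets = targets, clinical = clinical,
                 gene_sets = gene_sets, rna_types = rna_types,
                 truth = truth, config = config),
            class = "cerna_cohort")
}

#' @export
print.cerna_cohort <- function(x, ...) {
  cat("synthetic ceRNA cohort\n")
  cat(sprintf("  miRNA datasets: 2 x (%d x %d); RNA: %d x %d\n",
              nrow(x$mirna[[1]]$values), ncol(x$mirna[[1]]$values),
              nrow(x$rna$values), ncol(x$rna$values)))
  cat(sprintf("  planted pairs: %d; meth genes: %d; prognostic lncRNAs: %d\n",
              nrow(x$truth$planted_pairs), length(x$truth$meth_genes),
              length(x$truth$prognostic_lncrnas)))
  invisible(x)
}

#' Closed-form expected shared-target p-value
#'
#' For planted pairs: the hypergeometric tail probability at the planted
#' overlap `x = shared_targets_planted` with `K = M = targets_per_rna` and
#' `N = n_mirna`. For background pairs (uniform random target sets): the
#' expectation of the tail p-value over the overlap distribution,
#' `E[P(X >= x_obs)] = sum_x P(X = x) P(X >= x)`.
#'
#' @param config A [simulation_config()].
#' @param pair_kind `"planted"` or `"background"`.
#' @return A probability.
#' @export
expected_shared_pvalue <- function(config,
                                   pair_kind = c("planted", "background")) {
  pair_kind <- match.arg(pair_kind)
  stopifnot(inherits(config, "sim_config"))
  N <- config$n_mirna; K <- config$targets_per_rna
  if (pair_kind == "planted")
    return(hyper_tail(config$shared_targets_planted, N, K, K))
  xs <- 0:min(K, K)
  pmf <- dhyper(xs, K, N - K, K)
  sum(pmf * hyper_tail(xs, N, K, K))
}

#' Write a synthetic cohort bundle to disk
#'
#' Serializes every component in the same plain-text formats the readers
#' consume: TSV expression matrices with group files, a two-column target
#' TSV, a GMT collection, a clinical TSV, an `rna_types.tsv`, a flat
#' key=value `truth.txt` and a `config.txt` echo.
#'
#' @param cohort A `"cerna_cohort"` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cerna_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, paste0(...))
  paths <- c(mirna1 = p("mirna1.tsv"), mirna1_groups = p("mirna1_groups.tsv"),
             mirna2 = p("mirna2.tsv"), mirna2_groups = p("mirna2_groups.tsv"),
             rna = p("rna.tsv"), rna_groups = p("rna_groups.tsv"),
             methylation = p("methylation.tsv"),
             methylation_groups = p("methylation_groups.tsv"),
             targets = p("targets.tsv"), gene_sets = p("gene_sets.gmt"),
             clinical = p("clinical.tsv"), rna_types = p("rna_types.tsv"),
             truth = p("truth.txt"), config = p("config.txt"))
  write_expression_matrix(cohort$mirna[[1]], paths["mirna1"],
                          paths["mirna1_groups"])
  write_expression_matrix(cohort$mirna[[2]], paths["mirna2"],
                          paths["mirna2_groups"])
  write_expression_matrix(cohort$rna, paths["rna"], paths["rna_groups"])
  write_expression_matrix(cohort$methylation, paths["methylation"],
                          paths["methylation_groups"])
  tg <- cohort$targets$targets
  write.table(data.frame(rna = rep(names(tg), lengths(tg)),
                         mirna = unlist(tg, use.names = FALSE)),
              paths["targets"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write_gmt(cohort$gene_sets, paths["gene_sets"])
  write.table(as.data.frame(cohort$clinical), paths["clinical"],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(rna = names(cohort$rna_types),
                         type = unname(cohort$rna_types)),
              paths["rna_types"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeLines(serialize_flat(truth_to_flat(cohort$truth)), paths["truth"])
  cfg <- unclass(cohort$config)
  writeLines(serialize_flat(lapply(cfg, format, digits = 15)),
             paths["config"])
  invisible(paths)
}

truth_to_flat <- function(truth) {
  list(
    planted_pairs = paste(truth$planted_pairs$lncrna,
                          truth$planted_pairs$mrna,
                          sep = ":", collapse = ","),
    de_mirna_up = paste(truth$de_mirna_up, collapse = ","),
    de_mirna_down = paste(truth$de_mirna_down, collapse = ","),
    de_lncrna_up = paste(truth$de_lncrna_up, collapse = ","),
    de_lncrna_down = paste(truth$de_lncrna_down, collapse = ","),
    de_mrna_up = paste(truth$de_mrna_up, collapse = ","),
    de_mrna_down = paste(truth$de_mrna_down, collapse = ","),
    meth_genes = paste(truth$meth_genes, collapse = ","),
    prognostic_lncrnas = paste(names(truth$prognostic_lncrnas),
                               truth$prognostic_lncrnas,
                               sep = ":", collapse = ","))
}

serialize_flat <- function(x) {
  paste0(names(x), " = ", vapply(x, paste, character(1L), collapse = ","))
}

#' Generate and write a synthetic cohort in one call
#' @param config A [simulation_config()].
#' @param dir Output directory.
#' @return The generated `"cerna_cohort"`, invisibly; files are written to
#'   `dir`.
#' @export
simulate_cohort <- function(config = simulation_config(), dir) {
  cohort <- generate_cohort(config)
  write_cohort(cohort, dir)
  invisible(cohort)
}
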