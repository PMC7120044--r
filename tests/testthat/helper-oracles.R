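# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force tail sums, textbook formulas and
# hand arithmetic.

# exhaustive hypergeometric upper tail: sum of C(K,t) C(N-K,M-t) / C(N,M)
hyper_tail_oracle <- function(x, N, K, M) {
  if (x > min(K, M)) return(0)
  ts <- seq.int(x, min(K, M))
  sum(choose(K, ts) * choose(N - K, M - ts)) / choose(N, M)
}

# textbook sample Pearson correlation
pearson_oracle <- function(a, b) {
  da <- a - mean(a); db <- b - mean(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# two-sample log-rank chi-square from first principles: at each event time,
# observed minus expected events in group 1 with the hypergeometric variance
logrank_oracle <- function(time, event, group) {
  g1 <- sort(unique(as.character(group)))[1L]
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# small expression matrix builder
tiny_expr <- function(values, groups, features = NULL, samples = NULL) {
  if (is.null(features)) features <- sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(features, samples)
  expression_matrix(values, groups)
}

# a small simulation configuration for survival-focused tests: few
# features, one planted prognostic lncRNA
surv_config <- function(n_tumor, hazard_beta, censor_frac = 0.3, seed = 1) {
  simulation_config(n_tumor = n_tumor, n_normal = 2,
                    n_mirna = 5, n_lncrna = 2, n_mrna = 2,
                    n_planted_pairs = 1, shared_targets_planted = 1,
                    targets_per_rna = 2, n_de_mirna = 0, n_de_lncrna = 1,
                    n_prognostic = 1, hazard_beta = hazard_beta,
                    censor_frac = censor_frac, meth_frac = 0.5,
                    n_gene_sets = 2, gene_set_size = 2, seed = seed)
}

# pipeline_config pointing at a written cohort bundle
bundle_config <- function(dir, outdir, ...) {
  pipeline_config(
    mirna = file.path(dir, c("mirna1.tsv", "mirna2.tsv")),
    mirna_groups = file.path(dir, c("mirna1_groups.tsv",
                                    "mirna2_groups.tsv")),
    rna = file.path(dir, "rna.tsv"),
    rna_groups = file.path(dir, "rna_groups.tsv"),
    targets = file.path(dir, "targets.tsv"),
    methylation = file.path(dir, "methylation.tsv"),
    methylation_groups = file.path(dir, "methylation_groups.tsv"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    clinical = file.path(dir, "clinical.tsv"),
    rna_types = file.path(dir, "rna_types.tsv"),
    outdir = outdir, ...)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

truth_pair_keys <- function(cohort)
  pair_key(cohort$truth$planted_pairs$lncrna,
           cohort$truth$planted_pairs$mrna)
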