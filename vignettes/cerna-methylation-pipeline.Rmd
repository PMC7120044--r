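---
title: "ceRNA network inference with methylation overlay and prognostic screening: methods"
author: "cernet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ceRNA network inference: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernet)
```

## The model

Competing endogenous RNA (ceRNA) regulation rests on two observable
signatures. First, two transcripts regulated by a common pool of miRNAs
share more predicted miRNA binders than chance allows. With a universe of
$N$ miRNAs, target sets of sizes $K$ and $M$, and an observed overlap of
$x$, the probability of an overlap at least as large under random draws is
the upper hypergeometric tail

$$P \;=\; 1 - F(x-1;\,N,K,M) \;=\; \sum_{t=x}^{\min(K,M)}
\frac{\binom{K}{t}\binom{N-K}{M-t}}{\binom{N}{M}}.$$

Second, genuine ceRNA partners are positively co-expressed, because
releasing shared miRNA pressure raises both transcripts together. The
pair call therefore requires both $P < p_{\text{cut}}$ (default 0.05,
strict) and sample Pearson correlation $r > r_{\text{cut}}$ (default 0.7,
strict, signed positive). The same hypergeometric kernel, applied to gene
sets instead of target sets, performs the over-representation analysis;
the package guarantees (and tests) that both routes produce identical
p-values for identical $(N, K, M, x)$.

`phyper()` evaluates the tail in log space, so extreme tails retain full
double precision; the kernel orders its two set sizes canonically so the
pair test is exactly symmetric in floating point, not only mathematically.
The test is undefined for an RNA with an empty target set; callers must
pre-filter, and the constructors drop such RNAs with a warning.

## Thresholds and their defaults

| parameter | default | applies to | note |
|---|---|---|---|
| expression p (raw) | 0.05 | differential miRNA/RNA screen | raw p by convention of the screening literature |
| expression effect | 1.0 | \|log2FC\| | log2 scale |
| methylation p (BH) | 0.05 | differential methylation | *adjusted* p, unlike expression |
| methylation effect | 1.0 | \|Δ\| | on the supplied value scale (see below) |
| pair p | 0.05 | hypergeometric tail | raw; `adjust = "bh"` optional |
| pair r | 0.7 | Pearson correlation | signed; `use_abs_r` optional |
| enrichment FDR | 0.05 | BH across sets | plus optional display filter p < 0.01 |
| screen p | 0.05 | median-split log-rank | `p <= 0.05` |
| horizon | 1095 d | ROC AUC | 3 years, TCGA day convention |

Two asymmetries are deliberate. The expression rule uses the raw p-value
while the methylation rule uses the BH-adjusted one — both conventions are
honored literally and independently configurable. And the methylation
effect threshold of 1 cannot refer to beta-values (bounded by 1); the
package interprets Δ on whatever scale the matrix supplies (M-values or
expression-style intensities), with the threshold exposed for other
scales.

## The test statistic for differential screening

Per-feature screening uses the Welch two-sample $t$ on log2 values
(`test = "student"` switches to the pooled-variance form). This is a
deliberate, documented choice of a self-contained test over an
empirical-Bayes moderated $t$: moderation matters most below ~5 samples
per group, while the package's reference conditions use 25 per group,
where the two agree closely. Degenerate features (zero variance in both
groups) get $p = 1$ when group means are equal and $p = 0$ otherwise,
keeping the table total and the BH adjustment well defined. Features with
missing values in a tested contrast are dropped with a logged count —
the simplest defensible rule, applied uniformly.

Multi-dataset consensus intersects the up-calls of all datasets, and
separately the down-calls, mirroring the familiar Venn-diagram step.

## Candidate generation at scale

All unordered RNA pairs with at least one shared miRNA are enumerated via
an inverted index: a sparse RNA × miRNA membership matrix whose
cross-product counts every pair's overlap in one pass. Pairs sharing no
miRNA are never materialized. The test suite verifies output equality
with naive all-pairs enumeration, and invariance to input row order.
Correlations come from one `cor()` call over the RNAs present in both
inputs; constant features have no defined correlation and their pairs are
skipped with a warning.

## Survival methods

Kaplan–Meier estimation, the log-rank test and Cox partial-likelihood
maximization (Breslow tie handling, Newton iterations at a tightened
tolerance of 1e−9, capped at 100) are provided through the `survival`
package behind the package's validated surfaces; the test suite pins
their behavior to closed forms and hand arithmetic (product-limit on
three events, observed-minus-expected log-rank on a six-sample table).
The median split sends ties to the low group, so splits are reproducible;
a split that empties a group (constant expression) is an error rather
than a silent degenerate test.

The fixed-horizon AUC treats samples with an event at or before the
horizon as cases and samples observed beyond it as controls; samples
censored before the horizon are excluded, and the AUC is the Mann–Whitney
probability (ties one half) that a case's risk score exceeds a control's.
Exclusion was chosen over inverse-probability-of-censoring weighting
because it is assumption-free and transparent; it is slightly
conservative under heavy early censoring, and the estimator's name is
recorded in the result's metadata. The AUC is invariant under monotone
transforms of the risk score, which the tests exercise.

## What the synthetic generator emulates

`generate_cohort()` produces the statistical structure the analysis
assumes, plus the ground truth needed to score recovery:

* baseline log2 expression per feature $\sim \mathcal N(8, 1)$, residual
  noise $\mathcal N(0, \sigma)$ with $\sigma = 0.5$;
* planted differential features shifted by $\pm 2$ in tumor samples;
  the two miRNA datasets share the planted miRNA signature but have
  independent noise, emulating two independent array studies;
* each planted lncRNA–mRNA pair shares a per-sample latent factor with
  loading 1.5, giving a population correlation of about 0.9 against the
  residual noise — a phenomenological stand-in for miRNA-mediated
  coupling (the pipeline only consumes correlations, so mechanistic
  titration kinetics are out of scope). When a planted pair member is
  also differential, its partner is shifted in the same direction:
  opposite shifts would contradict the co-expression the pair is planted
  to show;
* target sets are uniform draws of 10 miRNAs from a universe of 100,
  overridden so planted pairs share exactly 8 — a planted tail
  probability of about $10^{-8}$, while a random pair needs an overlap of
  4+ (probability < 2%) to reach $p < 0.05$ and essentially never passes
  $r > 0.7$ at 50 samples;
* 30% of genes are planted as methylation-differential on an
  M-value-like scale (baseline $\mathcal N(0,1)$, shift $\pm 2$);
* survival for the tumor samples is exponential with rate
  $\lambda_0 \exp(\beta \sum_j z_j)$ over the standardized expression
  $z_j$ of each planted prognostic lncRNA ($\lambda_0 = \log 2 / 730$,
  i.e. two-year median survival; $\beta = 0.8$ per SD by default), with
  uniform censoring on $(0, c_{\max})$ where $c_{\max}$ is solved
  numerically so the expected censoring fraction matches the
  configuration. Because the hazard acts per SD, recovering $\beta$ from
  a per-unit Cox coefficient requires rescaling by the covariate's SD,
  which the recovery tests and the acceptance script do.

Reference conditions — 25 + 25 samples, 100 miRNAs, 60 lncRNAs, 150
mRNAs, 20 planted pairs, 20 planted differential miRNAs, 12 differential
lncRNAs of which 4 prognostic — are the `simulation_config()` defaults.
Survival-focused checks use the same generator with one prognostic
lncRNA and larger cohorts (n = 100–500), which keeps each replicate
inexpensive enough to run hundreds of them in the test suite.

One master seed drives a named sub-seed per component (each miRNA
dataset, RNA, targets, methylation, survival, gene sets), so adding a
component does not perturb the streams of the others, and identical
seeds give bit-identical cohorts and bundles.

What the generator does *not* emulate: array background/normalization
artifacts, batch effects, correlated miRNA families, alias/probe
annotation noise, beta-value compression, competing risks, or
non-proportional hazards. Passing the recovery tests therefore shows the
statistical machinery is correct under its stated model, not that real
GEO/TCGA cohorts — with their platform harmonization and annotation
issues — will yield comparable precision.

## Numerical and design choices

* **Universe** $N$ defaults to the union of miRNAs in the target map; an
  explicit universe can be supplied. With external target predictions the
  choice of $N$ shifts every pair p-value, so it is echoed in outputs.
* **Strict inequalities** at every gate; ties at a threshold are not
  calls.
* **No multiple-testing correction on pair p-values by default**
  (the screening convention); `adjust = "bh"` is available and documented
  because tens of thousands of candidate pairs are tested.
* **All RNA–RNA pair types** are evaluated (lncRNA–lncRNA ceRNA
  regulation is real and visible in such networks); typing is annotation,
  and `pair_types` can restrict to, say, lncRNA–mRNA only.
* **Probe collapse** averages probes mapped to a gene, dropping
  unannotated probes; identifier matching is exact and case-sensitive —
  alias resolution is input preparation, not method.
* **Determinism**: outputs are sorted lexicographically (pairs by
  p-value, then r, then ids), the manifest carries input MD5 hashes and
  the full configuration, and reruns on identical inputs are
  hash-identical. Logging goes through R's condition system rather than
  a timestamped file so that reruns stay bit-identical.
* **Pipeline orchestration** is exposed as R functions
  (`run_pipeline()`, `simulate_cohort()`); each stage failure aborts with
  the stage named.

## Known limitations

* Pearson correlation on mixed tumor+normal cohorts conflates
  within-group co-expression with shared differential shifts; the
  generator plants same-direction shifts for exactly this reason, and
  users of real data may prefer within-group correlation (compute on a
  subsetted `expression_matrix`).
* The hypergeometric test treats target predictions as fixed truth;
  database choice (union vs intersection of predictors) changes $K$, $M$
  and $N$ and is the analyst's responsibility.
* The log-rank screen at 25 samples has low power; the package reports
  what passes rather than guaranteeing the planted prognostic features
  survive the screen at small n (at n = 100 the planted effect is
  detected in well over 80% of replicates, which the tests verify).
* Enrichment results depend entirely on the supplied GMT; no annotation
  snapshot ships with the package.
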