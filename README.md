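# cernet

Competing endogenous RNA (ceRNA) network inference with DNA-methylation
overlay and prognostic lncRNA screening, for tumor/normal expression
cohorts.

## The problem

Long non-coding RNAs (lncRNAs) and mRNAs that are bound by the same
microRNAs can regulate each other indirectly: when one transcript soaks up
a shared miRNA pool, the other is de-repressed. Candidate ceRNA partners
therefore (i) share unexpectedly many predicted miRNA regulators and
(ii) are positively co-expressed. `cernet` implements this screen and the
downstream analyses typically layered on it — differential methylation
overlay, gene-set over-representation, and survival modelling — as one
tested R pipeline, for bioinformaticians analysing tumor/normal expression
studies (arrays or RNA-seq summaries) together with miRNA target
predictions, methylation data and clinical follow-up.

## The statistics at the core

For a pair of RNAs with target sets of sizes *K* and *M* inside a universe
of *N* miRNAs, sharing *x* miRNAs, the shared-target p-value is the upper
hypergeometric tail

P = 1 − F(x − 1; N, K, M) = Σ<sub>t=x</sub><sup>min(K,M)</sup>
C(K,t)·C(N−K,M−t) / C(N,M)

A pair is called a ceRNA pair when **P < 0.05** and its Pearson
co-expression **r > 0.7** (both strict; the same convention as the
screening literature). Around this kernel the package provides:

* **Differential screening** — Welch two-sample *t* per feature on log2
  values, BH adjustment; expression calls use raw p < 0.05 and
  |log2FC| > 1, methylation calls use adjusted p < 0.05 and |Δ| > 1;
  multi-dataset consensus by per-direction intersection.
* **Network assembly** — typed lncRNA/miRNA/mRNA graph, degree-annotated,
  exported as Cytoscape-ready edge/node tables; methylation overlay and
  candidate-lncRNA intersection.
* **Enrichment** — hypergeometric over-representation against GMT
  collections, sharing the exact same kernel as the pair test, with FDR
  and display-p filters.
* **Prognosis** — Kaplan–Meier curves, median-split log-rank screening,
  multivariable Cox risk scores (Breslow ties) and a fixed-horizon
  (3-year) Mann–Whitney AUC that excludes early-censored samples.
* **Synthetic cohorts** — `generate_cohort()` plants ceRNA pairs,
  differential features, methylation differences and expression-driven
  hazards, and returns the ground truth, so the entire pipeline is
  testable without external downloads.

## Worked example

```r
library(cernet)
cohort <- generate_cohort(simulation_config(seed = 1))
pairs  <- infer_cerna_pairs(cohort$rna, cohort$targets)
summary(pairs)
#> ceRNA pair inference (universe N = 100 miRNAs)
#>   candidates with >= 1 shared miRNA: 14829
#>   retained at p < 0.05 and r > 0.7: 20
#>   shared targets per pair: median 8 (range 8-8)
#>   correlation: median 0.926 (range 0.841-0.966)
head(as.data.frame(pairs)[, c("rna_a", "rna_b", "x", "p_value", "r")], 3)
#>     rna_a    rna_b x      p_value         r
#> 1 LNC0005 MRNA0005 8 1.046348e-08 0.9658557
#> 2 LNC0001 MRNA0001 8 1.046348e-08 0.9605808
#> 3 LNC0008 MRNA0008 8 1.046348e-08 0.9593617
```

The 20 retained pairs are exactly the 20 planted pairs: each shares 8 of
its 10 predicted miRNAs (tail probability ≈ 1e−8 in a universe of 100) and
co-expresses with r ≈ 0.93. Overlaying methylation calls and intersecting
with the differentially expressed lncRNAs yields the prognostic
candidates; a two-lncRNA Cox model on the screened candidates then gives

```r
model <- cox_fit(cohort$rna, cohort$clinical, c("LNC0009", "LNC0003"))
model
#> Cox risk model on 2 feature(s):
#> LNC0009 LNC0003
#>  0.2671  0.2615
round(as.numeric(auc_at_horizon(model, cohort$clinical)), 3)
#> [1] 0.742
```

i.e. both candidates carry positive log-hazard per unit expression, and
the risk score separates 3-year deaths from 3-year survivors with
AUC 0.74 on this small (n = 25) simulated cohort.

`run_pipeline(pipeline_config(...))` executes the whole chain from TSV/GMT
inputs to output tables plus a deterministic JSON manifest; see
`?run_pipeline` and the methods vignette (`vignettes/cerna-methylation-pipeline.Rmd`).

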