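# sestrat

Non-genetic stratification of tumor cohorts from **super-enhancer RNA
(seRNA) activity**, for computational biologists studying regulatory
heterogeneity in cancer.

Super-enhancers (SEs) are broad enhancer clusters whose transcription
(seRNA) tracks their activity, so a tumor's seRNA profile is an epigenetic
fingerprint independent of its mutations. `sestrat` turns that idea into a
complete, tested pipeline:

- **Cluster discovery** — resampled K-means consensus clustering of the
  seRNA matrix. The consensus entry for samples *i, j* is
  *C(i,j) = #\{resamples clustering i,j together\} / #\{resamples containing
  both\}*; the cluster number k minimizes PAC = F(0.9) − F(0.1), the mass of
  the consensus CDF in the ambiguous band.
- **SE–gene linkage** — a gene is an *SE-regulated potential gene* (SPG)
  when its TSS lies within 500 kb of an SE and Spearman's ρ(seRNA, mRNA)
  ≥ 0.3 at BH q ≤ 0.05 across samples.
- **SE-regulated genes** — SPGs ∩ cluster DEGs (Wilcoxon rank-sum on
  log2(x+1), BH, |log2FC| ≥ 1), the overlap tested by a one-sided Fisher
  exact test.
- **Core TFs and the multi-TF index** — promoter PWM enrichment
  (log2-odds scanning, both strands) nominates candidate TFs; per-cluster
  one-vs-rest LASSO logistic regression (coordinate descent, 10-fold CV,
  1-SE rule) selects one core TF per cluster, and the worst-prognosis
  cluster's linear predictor
  *index(s) = Σ\_j w\_j · z\_j(s)* on standardized log2 TF expression is the
  per-sample prognostic index.
- **Validation** — Kaplan–Meier curves, k-group log-rank tests (labels and
  median-split index), and mean-z signature scoring.
- **Synthetic cohort** — `generate_cohort()` plants clusters, active SEs,
  SE→gene links, driver-TF motifs, survival hazards and a glycolysis-like
  signature, with full machine-readable ground truth, so the whole pipeline
  runs and is tested without any download.

## Worked example

```r
library(sestrat)

cohort <- generate_cohort(cohort_config(seed = 1))
cohort
#> <synthetic_cohort> 150 samples in 3 clusters
#>   seRNA: 500 SEs | mRNA: 642 features | 20 PWMs | censoring ~30%

report <- run_pipeline(cohort, pipeline_options(n_resamples = 250), seed = 1)
report
#> <run_report> seed 1 | chosen k = 3 | clusters: 1=50, 2=50, 3=50
#>   core TFs: 1->TF01, 2->TF02, 3->TF03
#>   log-rank by cluster: p = 4.2e-14 | by index split: p = 8.97e-06

report$k_metrics
#> # A tibble: 5 × 4
#>       k    pac cdf_area delta_area
#>   <int>  <dbl>    <dbl>      <dbl>
#> 1     2 0.671     0.444     0.444
#> 2     3 0.0512    0.632     0.423
#> 3     4 0.277     0.699     0.105
#> 4     5 0.329     0.739     0.0578
#> 5     6 0.329     0.771     0.0433

glance(report$model)
#> # A tibble: 3 × 4
#>   cluster lambda n_nonzero core_tf
#>   <chr>    <dbl>     <dbl> <chr>
#> 1 1       0.0451         3 TF01
#> 2 2       0.0376         3 TF02
#> 3 3       0.0403         3 TF03
```

Reading the output: PAC dips sharply at k = 3 (0.051 against 0.67 at k = 2),
so three clusters are called; the per-cluster LASSO models each nominate the
planted driver (TF01–TF03) as core TF; and the three clusters separate in
survival (log-rank p = 4.2e-14) — cluster 3 carries the planted 4× hazard —
as does the median split of the 3-TF index on its own (p = 9.0e-06). The
planted 22-gene signature scores highest in cluster 3
(`report$signature_summary`: mean z ≈ 0.64 vs ≈ −0.3 elsewhere).

Result objects are tibble-native: `tidy()` / `glance()` methods for
consensus fits, overlap tests, log-rank results and the TF index model, and
`autoplot()` for consensus heatmaps, KM curves and LASSO weights. A thin
command-line front end covering each stage
(`simulate`, `cluster`, `link`, `de`, `enrich`, `index`, `survival`,
`score`, `run-all`) ships in `inst/scripts/sestrat-cli.R`.

See `vignettes/serna-stratification.Rmd` for the full methods account:
estimators, defaults and their rationale, the generative model behind the
synthetic cohort, and known limitations.

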