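---
title: "Stratifying tumors by super-enhancer RNA activity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratifying tumors by super-enhancer RNA activity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Super-enhancers (SEs) are broad clusters of enhancers with unusually strong
regulatory activity. Because SE loci are themselves transcribed, the
expression of super-enhancer RNA (seRNA) is a usable per-sample proxy for SE
activity, and tumors can be stratified by their seRNA profiles without any
reference to somatic mutations — a *non-genetic* stratification. `sestrat`
implements that analysis as a tested, reusable pipeline:

1. **Cluster discovery.** Resampled K-means consensus clustering of the
   seRNA matrix, with the number of clusters chosen by PAC (proportion of
   ambiguous clustering).
2. **Cluster-specific SEs.** One-vs-rest differential activity on the seRNA
   matrix.
3. **SE–gene linkage.** Candidate genes are those whose transcription start
   site (TSS) lies within a window (default 500 kb) of an SE; a link is
   called when seRNA and mRNA expression correlate across samples. Genes
   with at least one passing link are *SE-regulated potential genes* (SPGs).
4. **SE-regulated genes.** SPGs intersected with the cluster's
   differentially expressed genes, the overlap tested by Fisher's exact
   test.
5. **Core transcription factors.** Promoter motif enrichment of the
   SE-regulated genes nominates candidate TFs; per-cluster one-vs-rest
   LASSO-penalized logistic regression on TF expression picks one core TF
   per cluster (largest absolute standardized weight among nonzero
   coefficients).
6. **Multi-TF index.** The worst-prognosis cluster's intercept-free linear
   predictor on standardized log2 TF expression gives a per-sample scalar
   index used for prognosis and cluster prediction.
7. **Validation.** Kaplan–Meier curves with k-group log-rank tests for
   cluster labels and for the median-split index, plus single-sample
   signature scoring (a glycolysis-signature analogue).

Everything runs on a built-in synthetic cohort with machine-readable ground
truth, so every stage is testable offline.

```{r}
library(sestrat)
cohort <- generate_cohort(cohort_config(seed = 1))
report <- run_pipeline(cohort, pipeline_options(n_resamples = 250), seed = 1)
report
```

# Models and estimators

## Consensus clustering and PAC

For each candidate k, `consensus_cluster()` draws `n_resamples` subsamples
of 80% of the samples without replacement, clusters each with K-means
(k-means++ seeding, Lloyd iterations), and records for every sample pair the
fraction of co-sampled resamples in which the pair co-clustered. Features
are prepared once: log2(x+1), the top 2,000 features by median absolute
deviation, z-scored. Final labels come from average-linkage hierarchical
clustering of one minus the consensus matrix — a deterministic consolidation
rather than one more K-means run.

PAC is the mass of the consensus CDF between 0.1 and 0.9: crisp clusterings
put nearly all pairwise consensus values at 0 or 1, so lower PAC means a
cleaner partition. `select_k()` minimizes PAC with ties broken toward
smaller k; when the PAC profile is flat to within 0.02 the data carry no
evidence of structure and the smallest k is returned with a warning. The
area under the consensus CDF and its increments (delta-area) are reported
alongside for transparency.

## Linkage geometry and correlation

All coordinates are BED-style 0-based half-open. The distance from a TSS to
an SE interval is 0 inside the interval and the distance to the nearer
boundary outside; the window test is inclusive at exactly `window_bp`.
Correlation is Spearman by default (robust to the log-normal marginals of
expression data; Pearson available), with exact permutation p-values at
n ≤ 9 (tie-free) and the t approximation otherwise. Benjamini–Hochberg
correction is applied jointly across all candidate pairs of a run — one
family, one FDR. SPGs require a positive correlation of at least 0.3 at
q ≤ 0.05 by default; all three gates are configurable.

## Differential expression

Per feature, a two-sided Wilcoxon rank-sum test of cluster vs rest on
log2(x+1), exact when both groups have ≤ 8 samples without ties, otherwise
the normal approximation with tie-corrected variance and continuity
correction. The effect size is the difference of group means on log2(x+1).
Gates default to q ≤ 0.05 and |log2FC| ≥ 1. A rank test was chosen over a
count-model fit because the pipeline's inputs are generic expression
matrices with no library-size or dispersion structure to exploit; the test
is fully specified, exact at small n, and its calibration is verified in the
test suite (type-I error within [0.03, 0.07] at α = 0.05 over 5,000 null
features). Note that at the 8+8 boundary the exact and approximate branches
can differ by up to 0.011 in p — that is a property of the textbook
continuity-corrected approximation, not of this implementation.

## Motif enrichment

Known-PWM scanning replaces de novo motif discovery: the question the
pipeline asks — which TFs' motifs mark a cluster's SE-regulated promoters —
is answered by scoring a user-supplied PWM library. Scores are log2-odds
against a uniform background on both strands (N bases contribute 0, the
background odds); a promoter is a hit when any offset reaches 80% of the
PWM's maximum achievable score. Per motif, a one-sided Fisher test compares
foreground hit frequency against the background promoters, BH-corrected
across motifs. PWMs are normalized per position with a 0.01 pseudocount.

## Penalized TF selection

`lasso_logistic()` minimizes the average logistic negative log-likelihood
plus an L1 penalty (intercept unpenalized) by IRLS with cyclic coordinate
descent and soft thresholding; a step-halving safeguard keeps the penalized
objective monotone, convergence requires no coefficient to move more than
1e-7, and KKT residuals are asserted in the test suite after every fit
(including exact zeros at and above `lambda_max`). The penalty is chosen by
10-fold stratified cross-validation over a 50-point log-spaced grid from
`lambda_max` down to 0.001·`lambda_max`, taking the largest lambda within
one standard error of the minimum held-out deviance (the 1-SE rule). The fit
is cross-checked against an independent reference implementation (glmnet)
in the tests, which plays no role in the fitting itself.

Multiclass structure is handled one-vs-rest, which yields exactly one core
TF per cluster — the reported quantity — rather than a grouped multinomial
penalty. The scalar index uses the worst-prognosis cluster's weights because
every downstream use (prognostic stratification, glycolysis ranking) asks
"how much does this sample resemble the aggressive cluster?". When survival
data are present the pipeline identifies that cluster by crude hazard
(events per unit follow-up); otherwise it defaults to the highest-numbered
cluster. Survival dichotomization of the index uses the cohort median.

## Survival and signature scoring

Kaplan–Meier estimation and the k-group log-rank test are delegated to the
`survival` package, with ties between censored and event times resolved by
the standard convention (censoring after events). The test suite recomputes
the log-rank statistic from the textbook observed-minus-expected /
hypergeometric-variance formula as an independent oracle and requires
agreement to 1e-10. Signature scores are the mean of per-gene z-scores on
log2 scale — the simplest defensible single-sample score; zero-variance
genes are dropped and excluded from `n_genes_used`.

# The synthetic cohort

`generate_cohort()` plants every effect the pipeline is meant to recover,
and records all of it in `truth`:

| parameter | default | meaning |
|---|---|---|
| `n_samples`, `n_clusters` | 150, 3 | cohort size and latent clusters |
| `n_se`, `n_active_se_per_cluster` | 500, 40 | SE loci; cluster-specific active sets |
| `se_activation_effect` | 2.0 | log2 shift of active SEs (and driver TFs) in SD units |
| `n_linked_genes_per_cluster` | 30 | genes tracking a cluster-active seRNA |
| `n_bystander_genes_per_cluster` | 30 | in-window but independent genes (linkage negative controls) |
| `link_noise_sd`, `link_slope` | 0.5, 1.0 | mRNA = slope·seRNA + N(0, sd) on log2 scale |
| `n_candidate_tfs`, `n_driver_tfs_per_cluster` | 20, 1 | TF panel; planted drivers |
| `window_bp` | 500,000 | linkage window |
| `promoter_len`, `motif_len`, `motif_plant_rate` | 600, 8, 0.9 | promoters and consensus planting |
| `baseline_hazard` | (0.02, 0.02, 0.08) | per-cluster exponential event rates |
| `censor_rate` | 0.3 | expected censored fraction |
| `n_signature_genes`, `signature_effect` | 22, 1.0 | glycolysis-like signature in the worst cluster |

Raw expression is log-normal (`2^L`, `L` Gaussian with mean 6, SD 1 on log2
scale) so that raw values are positive and all planted effects are additive
on the log2 scale the pipeline analyzes. The genomic layout is
deterministic: one synthetic chromosome per cluster, each active SE in a
slot wide enough that its linked and bystander genes fall inside its window
only, with decoy genes placed 10 kb beyond the window — window-boundary
behaviour is therefore unambiguous. PWM columns concentrate 0.85 on the
consensus base; at the 0.8·max scan threshold this admits no mismatches, so
background hit rates are near zero and planted consensus occurrences
dominate enrichment. Censoring is uniform on [0, T_max] with T_max solved
numerically (by `uniroot`) so the expected censored fraction equals
`censor_rate`. One global seed expands into named substreams per component,
so adding a component never perturbs earlier draws.

What the generator does **not** emulate: library-size or batch artifacts,
copy-number structure, correlated gene–gene backgrounds, non-exponential
hazards, informative censoring, promoter GC composition, or the ~200k-locus
scale of real seRNA atlases. Passing tests therefore demonstrate that the
estimators recover the effects they target under a clean generative model
at realistic effect sizes — not that they are robust to every artifact of
real tumor data.

# Numerical choices and edge cases

- Never-co-sampled pairs get consensus 0 with a warning (vanishingly rare at
  default resampling); the consensus diagonal is 1 wherever defined.
- Zero-variance features: skipped with a warning in correlation and
  signature scoring; dropped before standardization in the TF fit.
- Tie-breaks: `select_k` prefers smaller k; `predict_clusters` prefers the
  lower cluster number; the 1-SE rule prefers the larger (sparser) lambda.
- Coefficients smaller than 1e-12 after convergence are snapped to exact
  zero: the soft threshold can leave O(machine-epsilon) dust exactly at the
  KKT boundary.
- Cluster prediction from three 2-SD-shifted driver TFs has a Bayes-optimal
  accuracy of about 0.87 under the generator's own model (the classes
  overlap); the index AUC for the worst cluster is far higher because it is
  a one-vs-rest question. The tests assert accuracy ≥ 0.8 and AUC ≥ 0.95.
- The per-cluster direction of the SPG/DEG intersection (`deg_direction =
  "auto"`) picks whichever direction gives the more significant Fisher
  overlap, mirroring programs that activate genes in some clusters and
  repress them in others; it can be forced to `"up"` or `"down"`.

# Problem sizes in the test suite

The suite exercises recovery at n = 150 (clustering, k selection) and
n = 300 (linkage, DE, drivers, survival separation) with 250 consensus
resamples and 5 seeds for the recovery claims, 5,000 null features and 1,000
null replicates for the calibration claims, and exhaustive enumeration up to
universe size 30 for the Fisher oracle. These sizes were chosen so the full
statistical story — recovery, calibration, and oracle equivalence — runs
comfortably on a laptop.

# Limitations

- The pipeline consumes a precomputed seRNA matrix; quantifying seRNA from
  sequencing data, and calling SEs from histone marks, are upstream of it.
- No Cox modeling, hazard-ratio confidence intervals, or competing risks;
  validation is nonparametric (KM + log-rank).
- No de novo motif discovery; enrichment is only as good as the supplied
  PWM library.
- The DE stand-in ignores count dispersion; with raw counts and a real
  design, a dedicated count model is the better tool.
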