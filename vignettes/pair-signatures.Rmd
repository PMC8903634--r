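---
title: "Rank-based immune lncRNA pair signatures: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based immune lncRNA pair signatures: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irlncPairs)
```

## The problem and the model

Prognostic expression signatures usually score patients with a weighted sum
of absolute expression values, which makes them fragile across platforms,
normalization pipelines and cohorts. The approach implemented here sidesteps
that fragility by building features from *within-sample comparisons*: for a
pair of long non-coding RNAs (lncRNAs) $(a, b)$, the feature is

$$x_{ab}(s) \;=\; \mathbf{1}\{\,e_a(s) > e_b(s)\,\}$$

for each sample $s$ — 1 when $a$ is expressed above $b$ in that sample,
0 otherwise (ties fall to 0). Any strictly increasing per-sample transform of
the expression values leaves every feature unchanged, so the signature
depends only on the relative ordering of the two genes, never on their
absolute levels. This rank invariance is the package's central robustness
property and is enforced by test.

The candidate genes are chosen in two screening steps over a merged
normal/tumor cohort on the log2 scale:

1. **Immune relatedness.** A lncRNA is *immune-related* (irlncRNA) when some
   curated immune gene correlates with it at Pearson $r > 0.4$ and
   $p < 0.001$ (both strict, signed by default, no multiplicity correction —
   the screen is intentionally permissive and the later stages do the
   pruning). A flag switches to $|r| > 0.4$ for users who prefer the
   absolute-correlation variant.
2. **Differential expression.** Among irlncRNAs, genes with
   $|\log_2 \mathrm{FC}| > 2$ and Benjamini–Hochberg FDR $< 0.05$ between
   tumor and normal are retained. The fold-change filter is two-sided:
   down-regulated candidates are as admissible as up-regulated ones. The
   group test is the Wilcoxon rank-sum test (exact enumeration when both
   groups have at most 12 tie-free samples, otherwise the normal
   approximation with tie and continuity corrections) — an assumption-light
   choice over moderated-variance statistics, which are out of scope here.

All pairs of the retained genes form the binary feature matrix; a pair is a
*valid match* only when its ones-fraction across the modelling cohort lies
in $[0.20, 0.80]$ (inclusive). A pair that is nearly constant across
patients cannot discriminate outcomes, so these bounds remove degenerate
features. Validity is computed on the tumor samples with survival data,
because the filter's purpose is prognostic informativeness.

The survival model is a Cox proportional-hazards model on the binary pair
features. Pairs are first screened individually (univariate Cox, Wald
$p < 0.05$, Breslow tie handling), then jointly shrunk with an L1 (lasso)
penalty; the penalty weight $\lambda$ is chosen by 10-fold cross-validated
partial-likelihood deviance with folds stratified by event status and
seeded. The minimum-deviance rule is the default; the one-standard-error
rule is available by flag. The fitted signature defines the risk score

$$\mathrm{risk}(s) \;=\; \sum_k \beta_k\, x_k(s),$$

the linear predictor over the selected pairs.

Patients are stratified by the score: time-dependent ROC curves
(cumulative-case / dynamic-control definition, with Kaplan–Meier-based
inverse-probability-of-censoring weights for cases) are computed at 1, 3 and
5 years (365/1095/1825 days); the horizon with maximal AUC wins, ties going
to the longest horizon; the cutoff maximizes the Youden index
$J = \text{sensitivity} + \text{specificity} - 1$ over observed score
values, ties going to the lower threshold (larger high-risk group); a score
strictly above the cutoff is high risk. With no censoring the ROC estimator
reduces exactly to the empirical Mann–Whitney ROC of the by-horizon status
indicator, which is how it is validated.

Downstream, the package provides Kaplan–Meier curves and the two-group
log-rank test, a multivariate Cox fit to ask whether the score is prognostic
independently of clinical covariates, Wilcoxon contrasts of clinical
factors, drug-sensitivity scores (IC50-like, lower = more sensitive) and
single-sample gene-set enrichment (ssGSEA-style rank-weighted running sums,
$\alpha = 0.25$) between the risk groups, annotated with the usual star
convention (`***` $p<0.001$, `**` $p<0.01$, `*` $p<0.05$, all strict).

## The synthetic cohort

Real inputs of this kind come from public tumor and normal expression
compendia plus a curated immune gene list; the package instead ships a
seeded generator so that every stage is testable from first principles.
`sim_config()` defaults define the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_normal`, `n_tumor` | 60, 300 | cohort sizes |
| `n_mrna`, `n_immune` | 500, 100 | mRNAs, of which immune genes |
| `n_lnc`, `n_irlnc`, `n_de` | 300, 40, 20 | lncRNAs / planted immune-related / planted DE |
| `de_shift` | 3 | tumor shift on DE genes, log2 units |
| `n_planted_pairs`, `pair_betas` | 5, 0.8 | prognostic pairs and their log-hazards |
| `baseline_hazard` | 1e-4 /day | exponential baseline |
| `censor_max` | 3650 days | uniform censoring bound |
| `batch_shifts` | 0 / +0.6 | additive offsets of two interleaved batches |
| `noise_sd` | 0.5 | residual SD, log2 units |

A single per-sample latent immune factor $f \sim N(0,1)$ loads with unit
weight on every immune gene and planted irlncRNA, giving a population
correlation of $1/(1 + \sigma^2) = 0.8$ at the default noise level — well
above the 0.4 screen, while non-planted lncRNAs are independent noise and
essentially never pass at $p < 0.001$. DE genes receive `de_shift` in tumor
samples only. Genes paired in the hazard model share a baseline mean so
their binary comparison is close to 50/50 — inside the valid-match band and
maximally informative. Survival is exponential with rate
$h_0 \exp(\sum_k \beta_k x_k)$ and uniform censoring: the simplest
generative model consistent with proportional hazards, chosen deliberately
over more realistic (e.g. Weibull, overdispersed-count) mechanisms. With
the defaults, roughly 60% of tumor samples have observed events and median
survival at mean risk sits between the 1- and 5-year horizons, so all three
ROC horizons are informative.

The two batches are interleaved *within* each cohort. The real analyses this
mirrors merge tumor and normal data from different sources, where batch and
cohort coincide; the location–scale batch adjustment implemented here
(center and rescale per gene and batch, then restore the gene's grand mean
and pooled SD) cannot distinguish batch from biology in that fully
confounded design, so it warns whenever a batch is >95% one cohort and the
generator deliberately avoids creating that situation. The adjustment
removes constant per-batch offsets exactly and is a documented
simplification relative to empirical-Bayes batch models.

What the generator does **not** emulate: RNA-seq count overdispersion and
mean–variance coupling, correlated lncRNA blocks beyond the single immune
factor, informative censoring, and non-proportional hazards. Passing tests
therefore demonstrate correctness of the estimators and the recovery
machinery under a clean proportional-hazards world, not robustness to every
artifact of real sequencing data.

## Numerical and design choices

- **Strictness conventions.** All screening inequalities are strict
  ($r > 0.4$, $p < 0.001$, $|\mathrm{log_2FC}| > 2$, FDR $< 0.05$,
  $p < 0.05$); the valid-match bounds are inclusive; expression ties
  binarize to 0; a score equal to the stratification cutoff is low risk.
- **FDR default.** The DE stage defaults to FDR < 0.05. Published variants
  of this workflow sometimes print a 0.5 threshold; both are reachable
  through `select_de_irlnc(fdr_max = )` and `pipeline_config(fdr = )`, and
  0.05 is the default because an FDR of 0.5 accepts half-false discovery
  lists.
- **Pair canonicalization.** Only unordered pairs with lexicographically
  ordered names are materialized; the reversed orientation is the exact
  complement on tie-free data, so ordered duplicates carry no information.
- **Cox conventions.** Breslow tie handling everywhere; Wald intervals and
  p-values; fits with monotone likelihood (|beta| > 15) or constant
  covariates raise rather than returning divergent estimates. The lasso
  stage uses coordinate descent over a descending lambda path
  (convergence threshold 1e-12 when a fixed lambda is requested) and pads
  single-feature designs with a zero dummy column internally.
- **Clinical covariate coding** in the independence model: age continuous;
  grade G1–G3 and stage I–IV as ordinal integers; residual disease as a 0/1
  indicator (R1 = 1); listwise deletion of missing covariates; collinear
  design matrices are rejected naming the offending columns.
- **ROC numerics.** Censoring weights use the left-continuous Kaplan–Meier
  estimate of the censoring survivor function, floored at 1e-12; curves
  include $\pm\infty$ sentinel thresholds so they span (0,0)–(1,1); the AUC
  is the exact trapezoid. The Youden maximizer restricts to finite observed
  thresholds; degenerate flat curves fall back to the median score with a
  warning.
- **Seeding.** One top-level seed drives everything: the expression draw
  uses it directly, survival uses seed+1, drug scores seed+2 and the CV
  fold assignment seed+3. Reruns of `run_pipeline()` with the same
  configuration produce byte-identical manifests; the manifest records a
  hash of the configuration (output directory excluded) alongside per-stage
  counts.

## Problem sizes and what the checks compute

The test suite and the acceptance script run entirely on generated data at
the default scale above (360 samples, 800 genes; heavier calibration checks
use 20 replicate seeds of smaller null cohorts — e.g. 150 genes by 60
samples for the DE null, 50 null features by 100 subjects for the screen
calibration). At this scale the planted-structure checks assert: at least
90% recall of planted irlncRNAs with at most 5% decoy contamination, at
least 90% DE recall, at least 3 of 5 planted pairs in the fitted signature,
a chosen-horizon AUC above 0.7, log-rank $p < 0.01$ between risk groups,
and in at least 90% of 20 replicates a multivariate risk-score confidence
interval excluding hazard ratio 1 while a noise covariate's contains it.

## Known limitations

- The location–scale batch adjustment cannot recover signal from designs
  where batch and cohort coincide, and no surrogate-variable machinery is
  provided.
- Drug-sensitivity modelling is an input contract (per-sample IC50-like
  scores), not a trained expression-to-response model; only the group
  contrasts are computed here.
- Immune infiltration uses a generic single-sample enrichment score with
  user-supplied gene sets, not a deconvolution method; scores are
  comparable within a set across samples, not across sets.
- The univariate screen's p-threshold and the lasso's λ rule are
  conventions (0.05, minimum CV deviance); on real cohorts the selected
  signature size is sensitive to both, which is why both are configurable
  and recorded in the model's CV metadata.
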