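# irlncPairs

Rank-based prognostic signatures from immune-related lncRNA pairs.

Expression-based survival signatures built from absolute expression values
rarely transfer across platforms and normalization pipelines. `irlncPairs`
implements a workflow whose features are *within-sample comparisons*: for
two lncRNAs $(a, b)$ the feature is $x_{ab}(s) = \mathbf{1}\{e_a(s) >
e_b(s)\}$ — 1 when $a$ is expressed above $b$ in sample $s$. Such features
are invariant to any strictly increasing per-sample transform of
expression, so the resulting risk score depends only on gene orderings
within each patient.

The pipeline, aimed at analysts working with tumor/normal bulk expression
and survival data:

1. **Screen immune-related lncRNAs** — keep lncRNAs correlated with a
   curated immune gene at Pearson r > 0.4 and p < 0.001.
2. **Differential expression** — Wilcoxon rank-sum tumor-vs-normal test,
   keep |log2FC| > 2 at Benjamini–Hochberg FDR < 0.05 (two-sided).
3. **Pair features** — all C(k, 2) binary pair columns, filtered to *valid
   matches* whose ones-fraction lies in [20%, 80%].
4. **Signature** — univariate Cox screen (Wald p < 0.05, Breslow ties),
   then lasso-penalized Cox with seeded, event-stratified 10-fold
   cross-validation; risk score = Σ βₖ·xₖ.
5. **Stratification** — time-dependent ROC (cumulative/dynamic, KM
   censoring weights) at 1/3/5 years, horizon of maximal AUC, Youden-index
   cutoff, high/low risk groups.
6. **Evaluation** — Kaplan–Meier + log-rank, multivariate Cox independence
   analysis, Wilcoxon contrasts of clinical factors, drug IC50-like scores
   and ssGSEA-style immune enrichment between risk groups.

A seeded synthetic-cohort generator (`sim_config()`,
`simulate_expression()`, `simulate_survival()`,
`generate_fixture_bundle()`) plants known co-expression, differential
expression and proportional-hazards structure so the whole pipeline is
testable offline; see the methods vignette
(`vignettes/pair-signatures.Rmd`) for the generative model and design
notes.

## Worked example

```r
library(irlncPairs)

cfg <- pipeline_config(out_dir = "run1", seed = 7)
res <- run_pipeline(cfg)
#> 20 DE gene(s): 20 up, 0 down
#> risk groups: 168 high / 132 low

length(res$irlnc$irlnc_ids)   # lncRNAs passing the immune co-expression screen
#> [1] 40
glance(res$model)
#> # A tibble: 1 × 4
#>   n_pairs lambda cv_folds cv_rule
#>     <int>  <dbl>    <dbl> <chr>
#> 1      12 0.0101       10 min
res$horizon$roc
#> <time_roc> horizon = 1825 days, AUC = 0.864
res$logrank
#> # A tibble: 1 × 6
#>   statistic        p n_low n_high events_low events_high
#>       <dbl>    <dbl> <int>  <int>      <int>       <int>
#> 1      88.0 6.60e-21   132    168         51         130
```

On this simulated cohort the screen recovers all 40 planted immune-related
lncRNAs, the signature keeps 12 valid pairs (all 5 planted prognostic pairs
among them), the 5-year ROC is chosen with AUC 0.86, and the high-risk
group has markedly shorter survival (log-rank p ≈ 7e-21). The multivariate
fit in `res$cox` shows the risk score remains prognostic (HR ≈ 3.1, CI
excluding 1) while age/grade/stage/residual covariates — pure noise in the
generator — stay null.

Every fitted object has tidy accessors (`tidy()`, `glance()`) and plots
(`autoplot()` for ROC curves, `plot_km_groups()` for survival curves).
Real data enter through the readers: `read_expression_matrix()`,
`read_gtf_annotation()`, `read_gene_list()`, `read_clinical_table()`,
`read_gmt()`, `read_drug_scores()`, and
`pipeline_config(simulate = FALSE, inputs = list(...))`.

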