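# stepfeats

Correlation-based feature (marker gene) selection for clustering
single-cell data.

Clustering pipelines for scRNA-seq — and near-binary data such as
scATAC-seq peak matrices — depend on choosing a feature set that contains
the cell-type-specific (differentially expressed, DE) genes and rejects
technically noisy ones. The usual mean–variance ("highly variable gene")
methods score genes one at a time. `stepfeats` instead uses the structure
of the gene–gene Pearson correlation (GGC) matrix, where markers of the
same cell type form correlated blocks:

1. **Correlation range.** For gene *i* with GGC column *G<sub>i</sub>*,
   score *c<sub>i</sub>* = max₃(*G<sub>i</sub>*) − 0.75·min(*G<sub>i</sub>*)
   (third-largest value, diagonal included, i.e. the second-largest
   non-self correlation). Scores are z-standardized within equal-frequency
   mean-expression bins; genes with *z* ≤ 0.7 are dropped.
2. **Stepwise regression.** On the column-centered GGC matrix *G*, the gene
   explaining the most variance is regressed out at each step
   (*G* = *g* **w**ᵀ + ε, **w**ᵀ = *g*ᵀ*G*/(*g*ᵀ*g*); all per-gene
   variances come from the single product *G*ᵀ*G* via
   *V* = **x·x**/(*g*ᵀ*g*)). The elbow of the variance-explained scree
   fixes a minimally redundant **seed** gene set.
3. **Guilt-by-association.** Candidates are appended one at a time by their
   strongest correlation to any current member, propagating through the
   correlation network into a full feature ordering.
4. **Density Index.** Each prefix size is scored by
   DI = √(2/N)·‖M‖_F / k_m — RMS pairwise cell distance over mean
   k-nearest-neighbor distance in the top-*D* PC embedding — and the
   DI-maximizing size is selected. DI is a label-free proxy for cluster
   separation (silhouette index).

A negative-binomial synthetic-data generator with planted cell types, plus
silhouette and AUROC evaluation utilities, make every stage testable
without external data.

## Worked example

```r
library(stepfeats)

ds <- simulate_counts(seed = 1)   # 4 planted types, 25 markers each
ds
#> <synthetic_dataset> 1000 genes x 1000 cells, 4 types, 100 DE genes (log2FC 2.0), seed 1

fit <- select_features(ds$counts)
fit
#> <feature_selection> 110 features selected (11 seeds, 140 candidates, 956 genes scored)
#>   DI-optimal size: 110 (DI = 1.811)

glance(fit)
#> # A tibble: 1 x 7
#>   n_genes_scored n_candidates n_seeds elbow_index optimal_size max_di n_selected
#> 1            956          140      11          11          110   1.81        110

head(tidy(fit), 5)
#> # A tibble: 5 x 6
#>    rank gene     is_seed association_score selected zscore
#> 1     1 gene0369 TRUE                   NA TRUE       2.61
#> 2     2 gene0520 TRUE                   NA TRUE       2.32
#> 3     3 gene0663 TRUE                   NA TRUE       2.99
#> 4     4 gene0966 TRUE                   NA TRUE       3.67
#> 5     5 gene0394 TRUE                   NA TRUE       2.67
```

Of the 956 genes surviving the 5% detection filter, 140 exceed the
correlation-range z-score threshold; stepwise regression reduces them to 11
seed genes (the scree elbow), and guilt-by-association plus DI optimization
settle on a 110-gene feature set — which here contains 97 of the 98
detectable planted markers. `autoplot(fit, "di")`, `autoplot(fit, "scree")`
and `autoplot(fit, "zscore")` visualize the three stages;
`de_recovery_auroc()` and `silhouette_index()` quantify marker recovery and
cluster separation.

File-based workflows (10x `mtx` directories, CSV/TSV) run through
`run_pipeline()` or the command-line wrapper:

```sh
Rscript inst/scripts/stepfeats.R --input counts_dir --format mtx_dir --outdir out
```

which writes `features.tsv`, `di_profile.tsv`, `scree.tsv`,
`gene_scores.tsv` and the effective configuration.

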