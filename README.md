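# mapkl

Hybrid feature selection for two-class gene-expression data: instead of
keeping the *N* top-ranked genes of a differential-expression ranking — which
are typically highly correlated with one another — `mapkl` keeps one
**exemplar** gene per cluster of top-ranked genes, producing short,
non-redundant signatures for diagnostic classification. It is aimed at
transcriptomics analysts who need compact gene panels that work for both
small (a dozen samples) and large cohorts, independently of the downstream
classifier.

## The method

Given a training set of expression profiles from a *normal* and a *disease*
class, the pipeline runs four steps:

1. **Ranking.** Every gene gets a two-group statistic (standardized Wilcoxon
   rank-sum by default, Welch *t* optionally) and a family-wise
   permutation-adjusted p-value by the Westfall–Young **maxT** procedure:
   for *B* = 1,000 label shuffles the maximum |statistic| across genes is
   recorded, and each gene's adjusted p is the proportion of permutation
   maxima at or above its observed value (step-down variant by default,
   with enforced monotonicity and +1/(B+1) smoothing).
2. **Filtering.** The top *N* genes (default *N* = 200) are kept.
3. **Cluster counting.** The number of gene clusters *k* among the top-*N*
   genes is chosen by the **Krzanowski–Lai** index on the disease-class
   training samples only: with `W_k` the within-cluster sum of squares of a
   Ward *k*-partition and *p* the number of samples,

       DIFF_k = (k-1)^(2/p) W_{k-1} - k^(2/p) W_k,     KL(k) = |DIFF_k / DIFF_{k+1}|,

   and *k* maximizes KL(k).
4. **Exemplar selection.** **Affinity propagation** clusters the top-*N*
   genes (similarity = negative squared Euclidean distance between
   expression profiles), with the shared preference tuned by bisection so
   that exactly *k* exemplars emerge. The *k* exemplars are the signature.

The package also ships the evaluation protocol around the method (stratified
5-fold CV, hold-out validation, ACC/AUC/TNR/TPR, a random-subset baseline,
and SVM/KNN/random-forest plugins) and a cluster-structured simulation
generator with known differentially expressed genes (DEGs) for validating
cluster recovery.

## Worked example

Simulate a two-class dataset with 5 planted clusters of 10 correlated DEGs
among 2,000 genes, select a signature, and validate on held-out samples:

```r
library(mapkl)

spec <- simulation_spec(n_clusters = 5, genes_per_cluster = 10,
                        n_genes = 2000, samples_per_class = 300,
                        train_per_class = 100, seed = 42)
sim <- simulate_clusters_dataset(spec)
sim$train
#> mapkl_dataset: 2000 genes x 200 samples (100 normal, 100 disease)

sig <- mapkl_select(sim$train, N = 50, B = 200, k_max = 30, seed = 42)
sig
#> mapkl signature: 5 exemplar genes (k = 5)
#>   g01935, g01372, g01170, g00481, g00321

recovery_report(sig, sim$truth)
#> $n_degs_in_signature
#> [1] 5
#> $clusters_represented
#> [1] 5

res <- hold_out_evaluate(sim$train, sim$test, sig, classifier_svm_linear(),
                         seed = 42)
unlist(res[c("ACC", "AUC", "TNR", "TPR")])
#>     ACC     AUC     TNR     TPR
#> 0.98500 0.99895 0.99500 0.97500
```

The Krzanowski–Lai index found exactly the 5 planted clusters, affinity
propagation returned one exemplar per cluster (5/5 true DEGs, all 5 clusters
represented), and the 5-gene signature classifies the 400 held-out samples
almost perfectly.

Real datasets are read with
`read_expression_csv("train.csv", "class_labels.csv", label_map = c(normal = "ctrl", disease = "tumor"))`,
with `log_transform()` and `quantile_normalize()` available for raw
intensities. A command-line front end with `simulate` / `rank` / `run` /
`evaluate` subcommands is installed at `inst/cli/mapkl.R`.

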