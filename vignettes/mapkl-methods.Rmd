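---
title: "Exemplar-based gene signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exemplar-based gene signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapkl)
```

## The problem and the idea

Univariate differential-expression rankings of microarray or RNA-seq data
put strongly co-regulated genes — members of the same pathway — next to each
other at the top of the list. A classifier built on the top *N* genes
therefore pays for many nearly redundant features, and choosing *N* itself
is arbitrary. `mapkl` replaces "keep the top *N*" with "keep one
representative per cluster of the top *N*": the data decide how many
clusters of co-expressed discriminative genes exist, and affinity
propagation picks the single most central gene of each cluster. The output
is a short signature whose length is driven by the correlation structure of
the top-ranked genes, not by a user-set constant.

## The pipeline, step by step

**1. maxT ranking.** For each gene a two-group statistic is computed —
by default the standardized Wilcoxon rank-sum
$z = (W - \mathbb{E}W)/\mathrm{sd}(W)$ with mid-ranks and tie-corrected
variance, optionally the Welch $t$. Family-wise adjustment uses the
permutation distribution of the maximum $|T|$ across genes: for $B$ uniform
shuffles of the label vector (group sizes are preserved automatically),

$$\tilde p_g = \frac{1 + \#\{b : \max_{g'} |T^*_{b,g'}| \ge |T_g|\}}{B + 1}.$$

The default *step-down* variant takes successive maxima over the
not-yet-removed genes in decreasing-$|T|$ order and enforces monotonicity of
$\tilde p$ down that order; the *single-step* variant compares every gene to
the overall maximum. Testing is two-sided via $|T|$, because disease
signatures contain both up- and down-regulated genes. The $+1/(B+1)$
smoothing avoids exactly-zero p-values, and permutation counting uses
$\ge$ (a tie with the observed statistic counts against significance — the
conservative choice). Ranks break ties by (adjusted p ascending,
$|T|$ descending, input row order), so the ranking is total and
reproducible.

**2. Top-N filter.** The default $N = 200$ is a moderate pool: large enough
to contain whole clusters of co-expressed genes, small enough that the
clustering below is well conditioned. $N$ interacts with the true number of
differentially expressed genes (DEGs): when $N$ is far above it, null genes
dilute the cluster structure; when far below, clusters are truncated. The
simulation module exists precisely to study this interaction.

**3. Krzanowski–Lai cluster count.** With $W_k$ the within-cluster sum of
squared errors of a $k$-partition of the top-$N$ genes (points = genes,
dimensions = samples) and $p$ the number of dimensions,

$$\mathrm{DIFF}_k = (k-1)^{2/p} W_{k-1} - k^{2/p} W_k,
  \qquad \mathrm{KL}(k) = \left|\frac{\mathrm{DIFF}_k}{\mathrm{DIFF}_{k+1}}\right|,$$

and the chosen $k$ maximizes $\mathrm{KL}(k)$ over $k = 2, \dots, k_{\max}-1$.
Three genuinely open choices had to be fixed here:

* *Auxiliary clustering.* The index needs a $k$-partition for every
  candidate $k$. We use agglomerative hierarchical clustering with Ward
  linkage on Euclidean distances, cut at $k$: it is deterministic, its
  partitions are nested, and consequently $W_k$ is monotone non-increasing
  in $k$ — properties a ratio-of-differences index benefits from. A
  partitioning method (e.g. k-means) would introduce seed dependence into
  the most decision-critical quantity of the pipeline.
* *Samples used.* The index is computed on the disease-class training
  samples only (the cluster structure of interest is the co-regulation of
  disease-affected genes); `kl_samples = "all"` is available for
  sensitivity analysis.
* *Absolute value.* KL is used with absolute values, per the original index
  definition; the signed ratio is exposed in the profile for audit.
  $k_{\max}$ defaults to 30, comfortably above the largest cluster counts
  the simulations plant (25); ties in the argmax break toward smaller $k$,
  and candidates whose denominator $\mathrm{DIFF}_{k+1}$ is exactly zero
  (possible only for degenerate point sets) are skipped, falling back to
  $k_{\min}$ with a warning if all are.

**4. Affinity propagation with a target count.** Genes are clustered by
affinity propagation on similarities
$s(i,j) = -\lVert x_i - x_j \rVert^2$ (all training samples by default —
the similarity should reflect the profiles the classifier will see; a
disease-only option exists), with the standard responsibility/availability
messages, damping $\lambda = 0.9$, at most 1,000 iterations, and
convergence declared when the exemplar set is stable for 100 iterations.
A seeded symmetric jitter of relative magnitude $10^{-12}$ breaks
degeneracies (e.g. duplicated profiles). After convergence, a
within-cluster refinement pass — as in the method's reference
implementations — moves each exemplar to the cluster member maximizing the
summed intra-cluster similarity, run to a fixed point. Because the number
of exemplars grows monotonically with the shared preference (the diagonal
of $s$), a bisection between the minimum off-diagonal similarity (minus a
margin) and 0 finds the preference yielding exactly the $k$ chosen in step
3; if the exact count is unreachable within 30 evaluations the closest run
is returned flagged `off_target`, never silently.

Preprocessing is deliberately *not* part of `mapkl_select()`: raw-intensity
datasets need `log_transform()` (with optional floor/ceiling clamping) and
`quantile_normalize()` first, but some public datasets arrive already
normalized, and silently re-transforming them would corrupt the analysis.

## Evaluation protocol

`cross_validate()` performs stratified 5-fold CV in which the signature is
selected **once on the full training set** — this mirrors the original
evaluation design and is mildly optimistic, since the held-out folds
contributed to gene selection; the `reselect = TRUE` option re-runs
selection inside every fold for an unbiased (nested) estimate.
`hold_out_evaluate()` fits on the full training set and scores a disjoint
test set. Metrics: ACC, specificity (TNR), sensitivity (TPR; the disease
class is positive), and rank-based AUC
$\Pr(\text{score}_{\text{disease}} > \text{score}_{\text{normal}}) +
\tfrac12 \Pr(\text{tie})$. Rates with empty denominators are reported as
`NA`, not 0. When a plugged classifier yields no continuous score the AUC
falls back to $(\mathrm{TPR}+\mathrm{TNR})/2$, documented as a one-point ROC
approximation. `random_subset_baseline()` draws 10 random 20-gene subsets
from the top-200 ranked pool and reports mean metrics — the reference point
any structured selector must beat for its extra machinery to be worthwhile.
The SVM (linear kernel), KNN and random-forest plugins wrap `e1071`,
`class` and `randomForest`; they satisfy a minimal contract (fit / predict /
score) and any user classifier can be plugged in the same way.

## The simulation generator

`simulate_clusters_dataset()` emulates a two-class study in which disease
samples carry $c$ clusters of $g$ co-regulated DEGs among otherwise null
genes: non-DEGs are i.i.d. $\mathcal N(0, 0.5)$ in both classes; in the
disease class the genes of cluster $j$ are

$$x = \delta_j + \sqrt{\rho\,\sigma^2}\, Z_{j,s} + \varepsilon, \qquad
  Z_{j,s} \sim \mathcal N(0,1),\;
  \varepsilon \sim \mathcal N(0, (1-\rho)\sigma^2),$$

with $\sigma^2 = 0.5$ the null variance, so each DEG keeps marginal variance
$\sigma^2$, genes within a cluster correlate at $\rho$, and clusters differ
by their shift $\delta_j$ and their independent factors. Defaults:
$\delta_j$ equally spaced in $[1, 2]$ and $\rho = 0.8$ — strong enough that
clusters are statistically distinguishable, weak enough that individual DEGs
overlap the null tail. (A "factor loading of 0.8" reading of $\rho$ is
impossible here: a loading of $0.8$ alone contributes variance $0.64 >
0.5$; $\rho$ is therefore defined as the within-cluster *correlation*.)
DEG positions are uniform without replacement; the first 100 samples per
class form the training set and the remaining samples the test set. Default
dimensions are 10,000 genes and 1,200 samples per class.

What the generator does *not* emulate: heavy-tailed intensity noise,
array/batch effects, correlation among null genes, unequal cluster sizes,
and DEGs that are down-regulated or disease-heterogeneous. Perfect recovery
on these simulations therefore demonstrates that the pipeline's machinery
(ranking, cluster counting, exemplar selection) works as designed — not that
real tissue data will yield one exemplar per pathway.

Two consequences of the default effect sizes are worth stating explicitly.
First, with $N$ equal to the true DEG count the pipeline recovers the
planted cluster count exactly in essentially every replicate (the
acceptance checks require ≥ 90% of 20 seeds). Second, a $k$-gene signature
at these shifts leaves an irreducible per-sample error of roughly 1%, so
hold-out accuracy sits near 99%, not exactly 100%: each selected gene
overlaps the null tail by design, and 5 such genes cannot separate the
classes perfectly.

## Numerical and testing choices

* The permutation engine computes all $B$ statistics with one
  genes × permutations matrix product (rank-sum and group-sum statistics
  are linear in the 0/1 group indicator), so $B = 1{,}000$ over 10,000
  genes takes seconds; the affinity-propagation message loop is compiled
  (Rcpp) because the preference bisection multiplies its cost.
* A Welch $t$ with zero variance in both groups returns 0 for equal means
  and a signed sentinel of $10^9$ otherwise, keeping permutation maxima
  finite and comparable.
* Quantile normalization follows the "ties share the mean of the quantile
  values they span" dialect. Note a subtlety: with ties present, this
  policy is irreconcilable with "all sorted columns identical" and with
  exact idempotence — tied entries are averaged away from the reference
  distribution. Both properties hold exactly (and are tested) for tie-free
  columns, the generic case for continuous expression values.
* Affinity propagation is a message-passing heuristic: on small random
  instances it attains the exhaustive exemplar-subset optimum in the large
  majority of cases but carries no per-instance optimality guarantee; the
  test suite quantifies this against a brute-force oracle.
* The test suite runs the pipeline checks on reduced problem sizes (e.g.
  2,000 genes, $B = 200$, 20 seeds) chosen so the whole suite completes in
  about a minute; `scripts/acceptance.R` runs the protocol at its full
  gene count (10,000) and $B = 1{,}000$.
* Every stochastic component (permutations, simulation, jitter, folds,
  subset draws) is seeded through one RNG-restoring helper, so identical
  seeds give byte-identical results end to end.

## Known limitations

Binary classification only; no missing-value support (rejection, not
imputation); no probe-to-gene annotation mapping; the cluster-count index
assumes the top-$N$ genes contain some cluster structure — on structureless
top lists the KL argmax is weakly determined and small $k$ values are
returned; and the selection-outside-CV default inherits the optimism of the
original protocol (use `reselect = TRUE` when an unbiased CV estimate
matters).
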