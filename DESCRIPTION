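Package: mapkl
Title: Hybrid Feature Selection for Two-Class Expression Data via maxT
    Ranking and Affinity Propagation Exemplars
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Selects small, non-redundant gene signatures from two-class
    gene-expression matrices by combining Westfall-Young step-down maxT
    permutation-adjusted ranking, Krzanowski-Lai estimation of the number
    of gene clusters among the top-ranked genes, and affinity propagation
    clustering tuned to yield exactly that many exemplar genes. Includes
    expression-matrix input/output with log transformation and quantile
    normalization, a cluster-structured simulation generator with known
    differentially expressed genes, and evaluation utilities (stratified
    cross-validation, hold-out validation, accuracy, AUC, sensitivity,
    specificity, and a random-subset baseline) with pluggable classifiers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    data.table,
    limma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    randomForest,
    class,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
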