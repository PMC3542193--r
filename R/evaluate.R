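# Evaluation protocol: confusion metrics, rank-based AUC, stratified 5-fold
# cross-validation on the training set, hold-out validation on a separate
# test set, and the random-subset baseline drawn from the ranked list.

#' Confusion counts and derived rates
#'
#' The disease class (label 1) is the positive class. Rates with an empty
#' denominator (e.g. TPR with no positives in the truth) are reported as
#' `NA`, not 0.
#'
#' @param truth,predicted Integer 0/1 vectors of the same length.
#' @return A list with `TP`, `TN`, `FP`, `FN`, `ACC`, `TNR` (specificity),
#'   `TPR` (sensitivity).
#' @export
confusion_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  TP <- sum(truth == 1L & predicted == 1L)
  TN <- sum(truth == 0L & predicted == 0L)
  FP <- sum(truth == 0L & predicted == 1L)
  FN <- sum(truth == 1L & predicted == 0L)
  list(TP = TP, TN = TN, FP = FP, FN = FN,
       ACC = (TP + TN) / length(truth),
       TNR = if (TN + FP > 0) TN / (TN + FP) else NA_real_,
       TPR = if (TP + FN > 0) TP / (TP + FN) else NA_real_)
}

#' Rank-based AUC
#'
#' The probability that a random disease sample scores above a random normal
#' sample, counting ties as one half (normalized Mann-Whitney U, equivalent
#' to the trapezoidal area under the ROC curve).
#'
#' @param truth Integer 0/1 vector.
#' @param scores Numeric scores, higher = more disease-like.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(truth, scores) {
  truth <- as.integer(truth)
  n1 <- sum(truth == 1L); n0 <- sum(truth == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)  # mid-ranks handle ties with the 1/2 convention
  (sum(r[truth == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Full metric set for one evaluation: confusion rates plus AUC; when the
# classifier yields no scores the AUC falls back to (TPR + TNR)/2 (balanced
# accuracy), an approximation of a one-point ROC.
.evaluate_one <- function(truth, predicted, scores = NULL) {
  cm <- confusion_metrics(truth, predicted)
  cm$AUC <- if (!is.null(scores)) auc_score(truth, scores)
            else (cm$TPR + cm$TNR) / 2
  cm
}

.metric_names <- c("ACC", "AUC", "TNR", "TPR")

.summarize_folds <- function(per_fold) {
  m <- sapply(per_fold, function(x) unlist(x[.metric_names]))
  list(per_fold = as.data.frame(t(m)),
       mean = rowMeans(m, na.rm = TRUE),
       sd = apply(m, 1, sd, na.rm = TRUE))
}

# Stratified fold labels: within each class samples are shuffled and dealt
# round-robin to the folds.
.stratified_folds <- function(labels, folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- sample(which(labels == cls))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of a signature
#'
#' The signature is applied once to the full training set (selection is not
#' repeated inside the folds, mirroring the original evaluation design; see
#' `reselect` for the honest nested variant), then the classifier is fitted
#' on k-1 folds and evaluated on the held-out fold.
#'
#' @param ds Training [mapkl_dataset()].
#' @param sig A `mapkl_signature`, or `NULL` to use all genes of `ds`.
#' @param clf A `mapkl_classifier`.
#' @param folds Number of folds (default 5).
#' @param repeats Number of repeated CV runs with different fold seeds.
#' @param seed Seed controlling fold assignment and the learner.
#' @param reselect If `TRUE`, feature selection is re-run inside every
#'   training fold with `reselect_args` passed to [mapkl_select()] (nested
#'   CV; slower but unbiased). Default `FALSE`.
#' @param reselect_args List of arguments for [mapkl_select()] when
#'   `reselect = TRUE`.
#' @return A list with `per_fold` (data.frame of ACC/AUC/TNR/TPR), `mean`,
#'   `sd`, `folds`, `repeats`.
#' @export
cross_validate <- function(ds, sig, clf, folds = 5, repeats = 1, seed = 1,
                           reselect = FALSE, reselect_args = list()) {
  tab <- table(factor(ds$labels, levels = c(0, 1)))
  if (any(tab < folds))
    stop("each class needs at least `folds` samples (have ",
         paste(tab, collapse = "/"), ")")
  reduced <- if (is.null(sig) || reselect) ds else apply_signature(ds, sig)
  results <- list()
  for (r in seq_len(repeats)) {
    fold <- .stratified_folds(ds$labels, folds, seed + 1000L * (r - 1L))
    for (f in seq_len(folds)) {
      tr_idx <- which(fold != f)
      te_idx <- which(fold == f)
      if (reselect) {
        sub <- subset_samples(ds, tr_idx)
        fsig <- do.call(mapkl_select,
                        c(list(train = sub, seed = seed), reselect_args))
        tr <- apply_signature(sub, fsig)
        te <- apply_signature(subset_samples(ds, te_idx), fsig)
      } else {
        tr <- subset_samples(reduced, tr_idx)
        te <- subset_samples(reduced, te_idx)
      }
      fitted <- fit_classifier(clf, tr, seed = seed)
      results[[length(results) + 1L]] <-
        .evaluate_one(te$labels, predict_labels(fitted, te),
                      predict_scores(fitted, te))
    }
  }
  out <- .summarize_folds(results)
  out$folds <- folds
  out$repeats <- repeats
  out
}

#' Hold-out validation of a signature
#'
#' Fits the classifier on the full training set restricted to the signature
#' genes and evaluates on a disjoint test set.
#'
#' @param train,test [mapkl_dataset()]s sharing the signature genes.
#' @param sig A `mapkl_signature`, or `NULL` to use all genes.
#' @param clf A `mapkl_classifier`.
#' @param seed Seed forwarded to the learner.
#' @return A list with the confusion counts, `ACC`, `TNR`, `TPR`, `AUC`.
#' @export
hold_out_evaluate <- function(train, test, sig, clf, seed = 1) {
  if (!is.null(sig)) {
    train <- apply_signature(train, sig)
    test <- apply_signature(test, sig)
  }
  fitted <- fit_classifier(clf, train, seed = seed)
  .evaluate_one(test$labels, predict_labels(fitted, test),
                predict_scores(fitted, test))
}

#' Random-subset baseline from the ranked list
#'
#' Draws `n_subsets` random subsets of `subset_size` genes (without
#' replacement within a subset) from the top-`pool_size` ranked genes, runs
#' hold-out classification with each, and reports the mean (and sd) of the
#' metrics — the "Rnd" reference against which structured selection is
#' judged.
#'
#' @param rl A `mapkl_ranking`.
#' @param ds_train,ds_test Training and test [mapkl_dataset()]s.
#' @param clf A `mapkl_classifier`.
#' @param subset_size Genes per subset (default 20).
#' @param n_subsets Number of subsets (default 10).
#' @param pool_size Ranked pool to draw from (default 200, capped at the
#'   number of ranked genes).
#' @param seed Seed for the draws and the learner.
#' @return A list with `per_subset`, `mean`, `sd`.
#' @export
random_subset_baseline <- function(rl, ds_train, ds_test, clf,
                                   subset_size = 20, n_subsets = 10,
                                   pool_size = 200, seed = 1) {
  pool <- head(rl$gene_id, min(pool_size, nrow(rl)))
  if (subset_size > length(pool))
    stop("subset_size exceeds the ranked pool (", length(pool), " genes)")
  draws <- with_seed(seed, replicate(n_subsets, sample(pool, subset_size),
                                     simplify = FALSE))
  results <- lapply(draws, function(genes) {
    tr <- subset_genes(ds_train, genes)
    te <- subset_genes(ds_test, genes)
    fitted <- fit_classifier(clf, tr, seed = seed)
    .evaluate_one(te$labels, predict_labels(fitted, te),
                  predict_scores(fitted, te))
  })
  out <- .summarize_folds(results)
  names(out)[names(out) == "per_fold"] <- "per_subset"
  out
}
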