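# A cheap deterministic plugin for protocol tests: nearest-centroid with the
# signed distance difference as score.
centroid_classifier <- function() {
  new_classifier("centroid", function(X, labels, seed) {
    c1 <- rowMeans(X[, labels == 1L, drop = FALSE])
    c0 <- rowMeans(X[, labels == 0L, drop = FALSE])
    score <- function(m)
      sqrt(colSums((m - c0)^2)) - sqrt(colSums((m - c1)^2))
    list(predict = function(m) as.integer(score(m) > 0), score = score)
  })
}

test_that("confusion metrics count correctly and report undefined rates as NA", {
  all_right <- confusion_metrics(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(all_right[c("ACC", "TNR", "TPR")], list(ACC = 1, TNR = 1, TPR = 1))
  r <- confusion_metrics(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(r$TNR, 0.5)
  expect_equal(r$TPR, 1)
  expect_equal(r$ACC, 0.75)
  expect_equal(r[c("TP", "TN", "FP", "FN")], list(TP = 2, TN = 1, FP = 1, FN = 0))
  expect_true(is.na(confusion_metrics(c(0, 0), c(0, 1))$TPR))
})

test_that("AUC equals the concordance probability with half-credit ties", {
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auc_score(c(1, 1, 0, 0), rep(0.5, 4)), 0.5)
  expect_equal(auc_score(c(1, 1, 0, 0), c(0.9, 0.4, 0.5, 0.1)), 0.75)
  expect_error(auc_score(c(1, 1), c(0.3, 0.4)), "both classes")
})

test_that("AUC invariances: monotone transforms and class-swap symmetry", {
  truth <- rep(c(0L, 1L), 10)
  scores <- with_seed(2, rnorm(20))
  a <- auc_score(truth, scores)
  expect_equal(auc_score(truth, exp(scores)), a)
  expect_equal(auc_score(truth, 3 * scores + 7), a)
  expect_equal(auc_score(1L - truth, -scores), a)
  expect_equal(auc_score(1L - truth, scores), 1 - a)
  # swapping the positive convention swaps TNR and TPR
  pred <- as.integer(scores > 0)
  r <- confusion_metrics(truth, pred)
  rs <- confusion_metrics(1L - truth, 1L - pred)
  expect_equal(rs$TNR, r$TPR)
  expect_equal(rs$TPR, r$TNR)
})

test_that("cross-validation is stratified, seeded and reports fold spread", {
  ds <- make_dataset(G = 30, n1 = 15, n0 = 15, seed = 21, shift_rows = 1:5,
                     shift = 3)
  cv1 <- cross_validate(ds, NULL, centroid_classifier(), folds = 5, seed = 4)
  cv2 <- cross_validate(ds, NULL, centroid_classifier(), folds = 5, seed = 4)
  expect_identical(cv1, cv2)
  expect_equal(nrow(cv1$per_fold), 5)
  expect_named(cv1$mean, c("ACC", "AUC", "TNR", "TPR"))
  expect_true(all(cv1$per_fold$ACC >= 0 & cv1$per_fold$ACC <= 1))
  expect_error(cross_validate(make_dataset(G = 5, n1 = 3, n0 = 8), NULL,
                              centroid_classifier(), folds = 5),
               "at least")
})

test_that("under label noise the mean CV AUC centres on one half", {
  aucs <- numeric(100)
  for (s in seq_len(100)) {
    ds <- with_seed(s, {
      m <- matrix(rnorm(20 * 20), 20,
                  dimnames = list(sprintf("g%02d", 1:20),
                                  sprintf("s%02d", 1:20)))
      mapkl_dataset(m, sample(rep(c(0L, 1L), each = 10)))
    })
    aucs[s] <- cross_validate(ds, NULL, centroid_classifier(), folds = 5,
                              seed = s)$mean[["AUC"]]
  }
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se + 1e-12)
})

test_that("hold-out evaluation interpolates on resubstitution", {
  ds <- make_dataset(G = 20, n1 = 8, n0 = 8, seed = 31, shift_rows = 1:4,
                     shift = 4)
  r <- hold_out_evaluate(ds, ds, NULL, centroid_classifier())
  expect_equal(r$ACC, 1)
  expect_named(r, c("TP", "TN", "FP", "FN", "ACC", "TNR", "TPR", "AUC"),
               ignore.order = TRUE)
})

test_that("random-subset baseline draws from the ranked pool reproducibly", {
  ds <- make_dataset(G = 40, n1 = 10, n0 = 10, seed = 41, shift_rows = 1:6,
                     shift = 3)
  rl <- maxt_adjust(ds, B = 100, seed = 1)
  b1 <- random_subset_baseline(rl, ds, ds, centroid_classifier(),
                               subset_size = 5, n_subsets = 4, pool_size = 20,
                               seed = 2)
  b2 <- random_subset_baseline(rl, ds, ds, centroid_classifier(),
                               subset_size = 5, n_subsets = 4, pool_size = 20,
                               seed = 2)
  expect_identical(b1, b2)
  expect_equal(nrow(b1$per_subset), 4)
  # subset_size == pool: all subsets identical, zero spread
  b3 <- random_subset_baseline(rl, ds, ds, centroid_classifier(),
                               subset_size = 10, n_subsets = 3, pool_size = 10,
                               seed = 3)
  expect_equal(unname(b3$sd), rep(0, 4))
  expect_error(random_subset_baseline(rl, ds, ds, centroid_classifier(),
                                      subset_size = 30, pool_size = 20),
               "pool")
})

test_that("AUC falls back to balanced accuracy when a learner has no scores", {
  hard <- new_classifier("hard", function(X, labels, seed) {
    c1 <- rowMeans(X[, labels == 1L, drop = FALSE])
    c0 <- rowMeans(X[, labels == 0L, drop = FALSE])
    list(predict = function(m)
      as.integer(colSums((m - c1)^2) < colSums((m - c0)^2)))
  })
  ds <- make_dataset(G = 10, n1 = 6, n0 = 6, seed = 51, shift_rows = 1:3,
                     shift = 3)
  r <- hold_out_evaluate(ds, ds, NULL, hard)
  expect_equal(r$AUC, (r$TPR + r$TNR) / 2)
})
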