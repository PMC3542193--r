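# Pluggable classifier contract. A classifier is a constructor object; fitting
# it on a labeled training set yields a fitted model exposing predict()
# (0/1 labels) and score() (higher = more disease-like, or NULL if the
# learner yields no continuous score). The three reference plugins wrap
# standard learners; their internals are not part of the method.

#' Construct a classifier plugin
#'
#' @param name Display name.
#' @param fit Function `(train_matrix, labels, seed)` (samples in columns of
#'   `train_matrix`) returning a list with functions `predict(m)` -> 0/1
#'   labels and optionally `score(m)` -> numeric scores (higher = disease).
#' @return An object of class `mapkl_classifier`.
#' @export
new_classifier <- function(name, fit) {
  structure(list(name = name, fit = fit), class = "mapkl_classifier")
}

#' Fit a classifier plugin on a labeled dataset
#'
#' @param clf A `mapkl_classifier`.
#' @param train A [mapkl_dataset()].
#' @param seed Seed forwarded to the learner (for stochastic learners).
#' @return A fitted model (class `mapkl_fitted`) with `$predict(m)` and
#'   `$score(m)` taking a genes-by-samples matrix with the training genes.
#' @export
fit_classifier <- function(clf, train, seed = 1) {
  stopifnot(inherits(clf, "mapkl_classifier"))
  fitted <- clf$fit(train$matrix, train$labels, seed)
  fitted$name <- clf$name
  fitted$genes <- rownames(train$matrix)
  class(fitted) <- "mapkl_fitted"
  fitted
}

.check_genes <- function(fitted, m) {
  missing <- setdiff(fitted$genes, rownames(m))
  if (length(missing))
    stop("gene(s) absent from matrix: ", paste(missing, collapse = ", "))
  m[fitted$genes, , drop = FALSE]
}

#' Predict 0/1 labels with a fitted classifier
#' @param fitted A `mapkl_fitted` from [fit_classifier()].
#' @param m Genes-by-samples matrix (or `mapkl_dataset`).
#' @return Integer 0/1 labels, one per sample.
#' @export
predict_labels <- function(fitted, m) {
  if (inherits(m, "mapkl_dataset")) m <- m$matrix
  fitted$predict(.check_genes(fitted, m))
}

#' Continuous disease scores from a fitted classifier
#' @inheritParams predict_labels
#' @return Numeric scores (higher = more disease-like), or `NULL` if the
#'   learner yields none.
#' @export
predict_scores <- function(fitted, m) {
  if (inherits(m, "mapkl_dataset")) m <- m$matrix
  if (is.null(fitted$score)) return(NULL)
  fitted$score(.check_genes(fitted, m))
}

#' Reference classifier plugins
#'
#' Linear-kernel support vector machine, k-nearest neighbours, and random
#' forest, wrapping \pkg{e1071}, \pkg{class} and \pkg{randomForest}. Scores
#' are oriented so that larger means more disease-like (SVM: signed decision
#' value; KNN: vote fraction for the disease class; RF: disease class
#' probability).
#'
#' @param cost SVM soft-margin cost.
#' @param k Number of neighbours for KNN.
#' @param ntree Number of random-forest trees.
#' @return A `mapkl_classifier`.
#' @export
classifier_svm_linear <- function(cost = 1) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("classifier_svm_linear requires the e1071 package")
  new_classifier("svm-linear", function(X, labels, seed) {
    y <- factor(labels, levels = c(0, 1))
    model <- with_seed(seed,
      e1071::svm(x = t(X), y = y, kernel = "linear", cost = cost, scale = FALSE))
    # decision values are oriented toward the first class in the colname "a/b"
    flip <- identical(colnames(model$decision.values)[1], "0/1")
    list(
      predict = function(m) as.integer(as.character(
        predict(model, newdata = t(m)))),
      score = function(m) {
        dv <- attr(predict(model, newdata = t(m), decision.values = TRUE),
                   "decision.values")[, 1]
        if (flip) -dv else dv
      })
  })
}

#' @rdname classifier_svm_linear
#' @export
classifier_knn <- function(k = 3) {
  if (!requireNamespace("class", quietly = TRUE))
    stop("classifier_knn requires the class package")
  new_classifier("knn", function(X, labels, seed) {
    cl <- factor(labels, levels = c(0, 1))
    run <- function(m) with_seed(seed,
      class::knn(train = t(X), test = t(m), cl = cl, k = k, prob = TRUE))
    list(
      predict = function(m) as.integer(as.character(run(m))),
      score = function(m) {
        p <- run(m)
        votes <- attr(p, "prob")  # vote share of the WINNING class
        ifelse(p == "1", votes, 1 - votes)
      })
  })
}

#' @rdname classifier_svm_linear
#' @export
classifier_rf <- function(ntree = 500) {
  if (!requireNamespace("randomForest", quietly = TRUE))
    stop("classifier_rf requires the randomForest package")
  new_classifier("rf", function(X, labels, seed) {
    y <- factor(labels, levels = c(0, 1))
    model <- with_seed(seed,
      randomForest::randomForest(x = t(X), y = y, ntree = ntree))
    list(
      predict = function(m) as.integer(as.character(
        predict(model, newdata = t(m), type = "response"))),
      score = function(m)
        predict(model, newdata = t(m), type = "prob")[, "1"])
  })
}
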