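# Krzanowski-Lai estimation of the number of gene clusters.
#
# Genes are the points, samples the dimensions (by default only the
# disease-class training samples). The auxiliary clustering producing the
# within-cluster sum of squares W_k is Ward-linkage agglomerative clustering
# on Euclidean distances: deterministic and nested, so W_k is monotone in k.

#' Within-cluster sum of squared errors
#'
#' @param points Numeric matrix, items in rows, dimensions in columns.
#' @param assignment Integer/factor vector assigning each item to a cluster;
#'   every cluster must be non-empty (guaranteed when it comes from `cutree`).
#' @return Sum over clusters of squared Euclidean distances to the cluster
#'   centroid.
#' @export
within_cluster_ss <- function(points, assignment) {
  points <- as.matrix(points)
  if (length(assignment) != nrow(points))
    stop("one assignment per item is required")
  total <- 0
  for (cl in unique(assignment)) {
    idx <- which(assignment == cl)
    if (!length(idx)) stop("empty cluster: ", cl)
    x <- points[idx, , drop = FALSE]
    ctr <- colMeans(x)
    total <- total + sum(sweep(x, 2, ctr)^2)
  }
  total
}

#' Partition items into k clusters (Ward hierarchical clustering)
#'
#' @param points Numeric matrix, items in rows.
#' @param k Number of clusters, `1 <= k <= nrow(points)`.
#' @param tree Optionally a precomputed `hclust` tree for `points` (used to
#'   avoid recomputing it across k).
#' @return Integer assignment vector of length `nrow(points)`.
#' @export
cluster_for_k <- function(points, k, tree = NULL) {
  n <- nrow(points)
  if (k < 1 || k > n) stop("k must be between 1 and the number of items")
  if (is.null(tree)) tree <- hclust(dist(points), method = "ward.D2")
  cutree(tree, k = k)
}

#' Choose the number of clusters by the Krzanowski-Lai index
#'
#' For each candidate k the within-cluster sum of squares W_k of a Ward
#' k-partition is computed; with p the number of dimensions,
#' `DIFF_k = (k-1)^(2/p) W_{k-1} - k^(2/p) W_k` and
#' `KL(k) = |DIFF_k / DIFF_{k+1}|`. The chosen k maximizes KL(k) over
#' `k_min .. k_max - 1` (ties broken toward smaller k). Candidates with
#' `DIFF_{k+1} == 0` are skipped; if every candidate is degenerate, `k_min`
#' is returned with a warning.
#'
#' @param points Numeric matrix, items (genes) in rows, dimensions (samples)
#'   in columns.
#' @param k_min Smallest candidate k (default 2).
#' @param k_max Largest k for which W_k is computed; must satisfy
#'   `k_max <= nrow(points) - 1`.
#' @return An object of class `mapkl_kl`: list with `k` (chosen), `profile`
#'   (data.frame k, W, DIFF, KL, the KL ratio also unsigned), `p`, `k_min`,
#'   `k_max`.
#' @export
kl_select_k <- function(points, k_min = 2, k_max = 30) {
  points <- as.matrix(points)
  n <- nrow(points)
  p <- ncol(points)
  if (p < 1) stop("points must have at least one dimension")
  if (k_max > n - 1) stop("k_max must be <= number of items - 1 (items = ", n, ")")
  if (k_min < 2) stop("k_min must be >= 2")
  if (k_max < k_min + 1) stop("k_max must be >= k_min + 1")

  tree <- hclust(dist(points), method = "ward.D2")
  W <- vapply(seq_len(k_max), function(k)
    within_cluster_ss(points, cluster_for_k(points, k, tree = tree)),
    numeric(1))

  e <- 2 / p
  ks <- 2:k_max
  DIFF <- (ks - 1)^e * W[ks - 1] - ks^e * W[ks]
  names(DIFF) <- ks

  cand <- k_min:(k_max - 1)
  KL <- abs(DIFF[as.character(cand)] / DIFF[as.character(cand + 1)])
  ok <- DIFF[as.character(cand + 1)] != 0
  if (!any(ok)) {
    warning("all KL denominators are zero; falling back to k_min = ", k_min)
    chosen <- k_min
  } else {
    kl_ok <- KL[ok]
    chosen <- cand[ok][which.max(kl_ok)]  # which.max -> first = smallest k on ties
  }

  profile <- data.frame(
    k = ks,
    W = W[ks],
    DIFF = unname(DIFF),
    KL = unname(ifelse(ks %in% cand, KL[as.character(ks)], NA_real_)),
    row.names = NULL)

  structure(list(k = as.integer(chosen), profile = profile, W1 = W[1],
                 p = p, k_min = k_min, k_max = k_max),
            class = "mapkl_kl")
}

#' @export
print.mapkl_kl <- function(x, ...) {
  cat("Krzanowski-Lai profile over k =", x$k_min, "..", x$k_max,
      "(p =", x$p, "dimensions): chosen k =", x$k, "\n")
  invisible(x)
}
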