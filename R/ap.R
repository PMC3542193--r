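# Affinity propagation over gene expression profiles, plus a bisection mode
# that tunes the shared preference until exactly k exemplars emerge.

#' Build a similarity matrix for affinity propagation
#'
#' Off-diagonal entries are negative squared Euclidean distances between
#' items (rows of `points`); the diagonal holds the preference values, whose
#' magnitude governs how many exemplars emerge.
#'
#' @param points Numeric matrix, items in rows.
#' @param preference A single number, a vector of length `nrow(points)`, or
#'   `"median"` (the median of the off-diagonal similarities, the usual
#'   moderate-cluster-count default).
#' @return An items-by-items similarity matrix.
#' @export
similarity_matrix <- function(points, preference = "median") {
  points <- as.matrix(points)
  if (!all(is.finite(points))) stop("points must be finite")
  n <- nrow(points)
  if (n < 2) stop("need at least 2 items")
  d2 <- as.matrix(dist(points))^2
  S <- -d2
  off <- S[row(S) != col(S)]
  pref <- if (identical(preference, "median")) median(off) else preference
  if (!length(pref) %in% c(1L, n)) stop("preference must be scalar or length n")
  diag(S) <- pref
  dimnames(S) <- list(rownames(points), rownames(points))
  S
}

# One-exemplar-per-cluster refinement (as in the reference AP
# implementations): within each converged cluster, move the exemplar to the
# member that maximizes the summed intra-cluster similarity (the diagonal
# contributes the candidate's preference). Net similarity is non-decreasing
# and the exemplar count is preserved.
.ap_refine <- function(S, exemplars) {
  for (pass in 1:100) {
    assignment <- .ap_assign(S, exemplars)
    new_ex <- vapply(exemplars, function(e) {
      members <- which(assignment == e)
      members[which.max(colSums(S[members, members, drop = FALSE]))]
    }, integer(1))
    new_ex <- sort(new_ex)
    if (identical(new_ex, sort(exemplars))) break
    exemplars <- new_ex
  }
  sort(exemplars)
}

.ap_assign <- function(S, exemplars) {
  n <- nrow(S)
  Scols <- S[, exemplars, drop = FALSE]
  pick <- max.col(Scols, ties.method = "first")
  assignment <- exemplars[pick]
  assignment[exemplars] <- exemplars  # exemplars represent themselves
  assignment
}

.ap_net_similarity <- function(S, exemplars, assignment) {
  # diagonal entries are preferences, so self-assigned exemplars contribute
  # their preference and every other point its similarity to its exemplar
  sum(S[cbind(seq_len(nrow(S)), assignment)])
}

#' Run affinity propagation clustering
#'
#' Standard damped message passing on a dense similarity matrix. A tiny
#' seeded symmetric jitter (relative scale 1e-12) is added to the
#' similarities to break degeneracies. Exemplar candidates are the points
#' whose self-responsibility plus self-availability is positive; a final
#' within-cluster refinement pass (as in the reference implementations) moves
#' each exemplar to the member of its cluster maximizing the intra-cluster
#' similarity sum, and every point is assigned to the exemplar it is most
#' similar to.
#'
#' @param S Similarity matrix from [similarity_matrix()] (diagonal =
#'   preferences).
#' @param damping Message damping factor lambda in `[0.5, 1)`.
#' @param max_iter Maximum number of message-passing iterations.
#' @param conv_window Iterations the exemplar set must stay unchanged to
#'   declare convergence.
#' @param seed Seed for the degeneracy-breaking jitter.
#' @return An object of class `mapkl_ap`: list with `exemplars` (item
#'   indices), `assignment` (item -> exemplar index), `iterations`,
#'   `converged`, `net_similarity`, and `preference` (the diagonal used).
#' @export
ap_run <- function(S, damping = 0.9, max_iter = 1000, conv_window = 100,
                   seed = 1) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n != ncol(S)) stop("S must be square")
  if (!all(is.finite(S))) stop("S must be finite")
  if (damping < 0.5 || damping >= 1) stop("damping must be in [0.5, 1)")
  scale <- max(abs(S))
  if (scale == 0) scale <- 1
  Sj <- S + with_seed(seed, {
    J <- matrix(rnorm(n * n), n, n)
    1e-12 * scale * (J + t(J)) / 2
  })
  res <- .ap_engine(Sj, damping, as.integer(max_iter), as.integer(conv_window))
  exemplars <- as.integer(res$exemplars)
  if (!length(exemplars))
    stop("affinity propagation produced no exemplars after ", res$iterations,
         " iterations (preference range [", min(diag(S)), ", ", max(diag(S)),
         "]); raise the preference or max_iter")
  exemplars <- .ap_refine(unname(S), exemplars)
  assignment <- .ap_assign(S, exemplars)
  structure(list(exemplars = exemplars,
                 assignment = assignment,
                 iterations = res$iterations,
                 converged = res$converged,
                 net_similarity = .ap_net_similarity(S, exemplars, assignment),
                 preference = diag(S)),
            class = "mapkl_ap")
}

#' @export
print.mapkl_ap <- function(x, ...) {
  cat("affinity propagation:", length(x$exemplars), "exemplars,",
      x$iterations, "iterations,",
      if (isTRUE(x$converged)) "converged" else "not converged",
      sprintf("(net similarity %.4g)\n", x$net_similarity))
  invisible(x)
}

#' Affinity propagation with a target number of exemplars
#'
#' Searches for a shared preference value, by bisection between the minimum
#' off-diagonal similarity (minus a margin) and 0, such that exactly
#' `target_k` exemplars emerge. Exemplar counts grow with the preference, so
#' bisection converges quickly; if the exact count is unreachable within
#' `bisect_max` evaluations, the run with the closest count is returned with
#' `off_target = TRUE` and a warning.
#'
#' @param S Similarity matrix (diagonal is overwritten by the search).
#' @param target_k Desired number of exemplars, `1 <= target_k <= n`.
#' @param bisect_max Maximum number of preference evaluations.
#' @inheritParams ap_run
#' @return A `mapkl_ap` object with additional fields `target_k` and
#'   `off_target`.
#' @export
ap_run_k <- function(S, target_k, bisect_max = 30, damping = 0.9,
                     max_iter = 1000, conv_window = 100, seed = 1) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (target_k < 1 || target_k > n)
    stop("target_k must be between 1 and the number of items (", n, ")")
  off <- S[row(S) != col(S)]
  lo <- min(off) - (max(off) - min(off)) - 1e-8
  hi <- 0  # preference 0 dominates all (negative) off-diagonal similarities
  run_at <- function(pref) {
    Sp <- S
    diag(Sp) <- pref
    ap_run(Sp, damping = damping, max_iter = max_iter,
           conv_window = conv_window, seed = seed)
  }
  best <- NULL
  best_gap <- Inf
  for (step in seq_len(bisect_max)) {
    pref <- if (step == 1) hi else if (step == 2) lo else (lo + hi) / 2
    res <- tryCatch(run_at(pref), error = function(e) NULL)
    k_got <- if (is.null(res)) 0L else length(res$exemplars)
    gap <- abs(k_got - target_k)
    if (!is.null(res) && gap < best_gap) {
      best <- res
      best_gap <- gap
    }
    if (gap == 0) break
    if (k_got > target_k) hi <- pref else lo <- pref
  }
  if (is.null(best))
    stop("affinity propagation failed across the whole preference range")
  best$target_k <- as.integer(target_k)
  best$off_target <- length(best$exemplars) != target_k
  if (best$off_target)
    warning("could not reach exactly ", target_k, " exemplars; closest run has ",
            length(best$exemplars))
  best
}
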