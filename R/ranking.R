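# Two-group statistics and Westfall-Young maxT permutation adjustment.
#
# The permutation engine is vectorized: for B label shuffles the per-gene
# statistics are obtained from one genes x permutations matrix product
# (rank-sum and group-sum statistics are linear in the 0/1 group indicator),
# so B = 1,000 over 10,000 genes runs in seconds.

# Evaluate and restore the RNG state around seeded code.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Per-row mid-ranks and the tie-correction term sum(t^3 - t) used by the
# standardized rank-sum variance.
.row_ranks <- function(X) {
  G <- nrow(X)
  n <- ncol(X)
  Rk <- matrix(0, G, n)
  tie3 <- numeric(G)
  for (g in seq_len(G)) {
    x <- X[g, ]
    Rk[g, ] <- rank(x)
    if (anyDuplicated(x) > 0L) {
      tt <- tabulate(match(x, x))
      tt <- tt[tt > 0L]
      tie3[g] <- sum(tt^3 - tt)
    }
  }
  list(ranks = Rk, tie3 = tie3)
}

# Statistic matrix for a genes x samples matrix X and an n x B 0/1 indicator
# matrix P (1 = disease membership in that permutation). Returns genes x B.
.stat_matrix <- function(X, P, kind = c("wilcoxon", "welch_t")) {
  kind <- match.arg(kind)
  n <- ncol(X)
  n1 <- sum(P[, 1])
  n0 <- n - n1
  if (n1 == 0 || n0 == 0) stop("both groups must be non-empty")
  if (kind == "wilcoxon") {
    rk <- .row_ranks(X)
    W <- rk$ranks %*% P
    EW <- n1 * (n + 1) / 2
    varW <- n1 * n0 / 12 * ((n + 1) - rk$tie3 / (n * (n - 1)))
    sdW <- sqrt(pmax(varW, 0))
    Z <- (W - EW) / ifelse(sdW > 0, sdW, Inf)  # all-tied gene -> 0
    Z
  } else {
    S1 <- X %*% P
    Q1 <- (X * X) %*% P
    S0 <- rowSums(X) - S1
    Q0 <- rowSums(X * X) - Q1
    m1 <- S1 / n1
    m0 <- S0 / n0
    v1 <- pmax((Q1 - n1 * m1 * m1) / (n1 - 1), 0)
    v0 <- pmax((Q0 - n0 * m0 * m0) / (n0 - 1), 0)
    se <- sqrt(v1 / n1 + v0 / n0)
    d <- m1 - m0
    t <- d / se
    deg <- se == 0
    if (any(deg)) t[deg] <- sign(d[deg]) * STAT_MAX  # sign(0) = 0 handles equal means
    t
  }
}

#' Two-group statistic for a single gene
#'
#' Either the standardized Wilcoxon rank-sum z-score (mid-ranks for ties,
#' tie-corrected variance) or the Welch unequal-variance t-statistic,
#' oriented as disease minus normal.
#'
#' @param values Numeric vector of expression values.
#' @param labels 0/1 vector (0 = normal, 1 = disease), same length.
#' @param kind `"wilcoxon"` or `"welch_t"`.
#' @return A single numeric statistic. A Welch t with zero variance in both
#'   groups returns 0 for equal means and a signed large sentinel otherwise.
#' @export
group_statistic <- function(values, labels, kind = c("wilcoxon", "welch_t")) {
  kind <- match.arg(kind)
  stopifnot(length(values) == length(labels))
  labels <- as.integer(labels)
  drop(.stat_matrix(matrix(values, nrow = 1),
                    matrix(labels, ncol = 1), kind))
}

#' maxT permutation-adjusted ranking of all genes
#'
#' Computes a two-group statistic per gene, then adjusts for multiplicity by
#' the permutation distribution of the maximum absolute statistic across
#' genes (family-wise error control). `single_step` compares every gene to
#' the overall per-permutation maximum; `step_down` (Westfall-Young) takes
#' successive maxima over the not-yet-removed genes in decreasing-|T| order
#' and enforces monotonicity of the adjusted p-values down that order.
#' Permutations are uniform shuffles of the label vector (group sizes are
#' preserved automatically), and p-values use +1/(B+1) smoothing with a
#' `>=` comparison so no p is exactly zero.
#'
#' @param ds A [mapkl_dataset()] with both classes present.
#' @param B Number of label permutations (default 1000).
#' @param seed Integer seed; the ranking is deterministic given it.
#' @param kind Ranking statistic, `"wilcoxon"` (default) or `"welch_t"`.
#' @param mode `"step_down"` (default) or `"single_step"`.
#' @return An object of class `mapkl_ranking`: a data.frame with columns
#'   `gene_id`, `statistic`, `adj_p`, `rank`, ordered by rank (adjusted p
#'   ascending, |statistic| descending, input row index ascending), with
#'   attributes `B`, `statistic_kind`, `mode`, `seed`.
#' @export
maxt_adjust <- function(ds, B = 1000, seed = 1,
                        kind = c("wilcoxon", "welch_t"),
                        mode = c("step_down", "single_step")) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (B < 1) stop("B must be >= 1")
  if (length(unique(ds$labels)) < 2) stop("both classes must be present")
  X <- ds$matrix
  G <- nrow(X)
  labels <- unname(ds$labels)

  Tobs <- abs(drop(.stat_matrix(X, matrix(labels, ncol = 1), kind)))
  Tsigned <- drop(.stat_matrix(X, matrix(labels, ncol = 1), kind))

  P <- with_seed(seed, {
    vapply(seq_len(B), function(b) sample(labels), integer(length(labels)))
  })
  storage.mode(P) <- "double"
  Tperm <- abs(.stat_matrix(X, P, kind))

  ord <- order(-Tobs, seq_len(G))  # decreasing |T|, stable
  if (mode == "single_step") {
    colmax <- apply(Tperm, 2, max)
    counts <- vapply(Tobs, function(t) sum(colmax >= t), numeric(1))
    adj_p <- (1 + counts) / (B + 1)
    # monotone in |T| by construction; no enforcement needed
  } else {
    Tp_ord <- Tperm[ord, , drop = FALSE]
    # successive maxima from the bottom of the |T|-ordering, per permutation
    U <- apply(Tp_ord, 2, function(col) rev(cummax(rev(col))))
    if (G == 1) U <- matrix(U, nrow = 1)
    counts_ord <- rowSums(U >= Tobs[ord])
    p_ord <- (1 + counts_ord) / (B + 1)
    p_ord <- cummax(p_ord)  # enforce step-down monotonicity
    adj_p <- numeric(G)
    adj_p[ord] <- p_ord
  }

  rk_ord <- order(adj_p, -Tobs, seq_len(G))
  out <- data.frame(gene_id = rownames(X)[rk_ord],
                    statistic = Tsigned[rk_ord],
                    adj_p = adj_p[rk_ord],
                    rank = seq_len(G),
                    stringsAsFactors = FALSE)
  structure(out, class = c("mapkl_ranking", "data.frame"),
            B = B, statistic_kind = kind, mode = mode, seed = seed)
}

#' Keep the top-N ranked genes of a dataset
#'
#' @param rl A `mapkl_ranking` from [maxt_adjust()].
#' @param ds The [mapkl_dataset()] the ranking was computed on (or any
#'   dataset containing the ranked genes).
#' @param N Number of genes to keep (default 200); capped at the number of
#'   ranked genes.
#' @return A `mapkl_dataset` restricted to the `min(N, G)` best-ranked genes,
#'   rows in rank order, labels untouched.
#' @export
select_top_n <- function(rl, ds, N = 200) {
  if (N < 1) stop("N must be >= 1")
  keep <- head(rl$gene_id, min(N, nrow(rl)))
  subset_genes(ds, keep)
}
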