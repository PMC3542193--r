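# Independent oracles used by the unit and acceptance tests. Everything here
# is written from first principles (closed forms, exhaustive enumeration) and
# never calls the package code paths it is used to check.

# Standardized Wilcoxon rank-sum z from the closed-form moments (mid-ranks,
# tie-corrected variance), disease (1) minus expectation.
oracle_wilcoxon_z <- function(x, labels) {
  r <- rank(x)
  n <- length(x)
  n1 <- sum(labels == 1)
  n0 <- n - n1
  W <- sum(r[labels == 1])
  tt <- table(x)
  EW <- n1 * (n + 1) / 2
  V <- n1 * n0 / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
  (W - EW) / sqrt(V)
}

# Exact single-step maxT adjusted p-values by enumerating every balanced
# assignment of the disease labels (all n1-subsets of the samples).
oracle_maxt_single_step <- function(X, labels) {
  n <- ncol(X)
  n1 <- sum(labels == 1)
  subs <- utils::combn(n, n1)
  absz <- function(lab) abs(apply(X, 1, oracle_wilcoxon_z, labels = lab))
  maxes <- apply(subs, 2, function(idx) {
    lab <- integer(n)
    lab[idx] <- 1L
    max(absz(lab))
  })
  Tobs <- absz(labels)
  vapply(Tobs, function(t) mean(maxes >= t), numeric(1))
}

# Exhaustive net-similarity optimum over all non-empty exemplar subsets of a
# similarity matrix whose diagonal holds the preferences.
oracle_ap_optimum <- function(S) {
  n <- nrow(S)
  best <- -Inf
  best_set <- NULL
  for (mask in seq_len(2^n - 1)) {
    E <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    val <- sum(diag(S)[E]) +
      sum(vapply(setdiff(seq_len(n), E),
                 function(i) max(S[i, E]), numeric(1)))
    if (val > best) {
      best <- val
      best_set <- E
    }
  }
  list(optimum = best, exemplars = best_set)
}

# Two well-separated isotropic Gaussian blobs: n points, d dims, centers at
# the origin and at `sep` on every axis.
make_two_blobs <- function(n = 30, d = 5, sep = 10, sd = 1, seed = 1) {
  stopifnot(n %% 2 == 0)
  with_seed(seed, rbind(
    matrix(rnorm(n / 2 * d, 0, sd), n / 2, d),
    matrix(rnorm(n / 2 * d, sep, sd), n / 2, d)))
}

# Small labeled dataset with named dims for contract tests.
make_dataset <- function(G = 20, n1 = 5, n0 = 5, seed = 1, shift_rows = integer(),
                         shift = 2) {
  with_seed(seed, {
    m <- matrix(rnorm(G * (n0 + n1)), G,
                dimnames = list(sprintf("g%02d", 1:G),
                                sprintf("s%02d", 1:(n0 + n1))))
    labels <- rep(c(0L, 1L), c(n0, n1))
    if (length(shift_rows))
      m[shift_rows, labels == 1L] <- m[shift_rows, labels == 1L] + shift
    mapkl_dataset(m, labels)
  })
}

# with_seed is internal to the package; re-expose it for helper use.
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
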