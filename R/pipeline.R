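# End-to-end hybrid feature selection: maxT ranking -> top-N filter ->
# Krzanowski-Lai cluster count on disease samples -> affinity propagation
# with that cluster count -> exemplar gene signature.

#' Select an exemplar gene signature from a training set
#'
#' Runs the full hybrid selection: (1) rank all genes by a permutation
#' maxT-adjusted two-group statistic; (2) keep the top `N`; (3) estimate the
#' number of gene clusters k among those genes with the Krzanowski-Lai index,
#' computed on the disease-class training samples only; (4) cluster the top-N
#' genes by affinity propagation tuned to yield exactly k exemplars. The
#' exemplars are the signature. Preprocessing (log transform, quantile
#' normalization) is deliberately not implicit; apply it beforehand if the
#' data are raw intensities.
#'
#' @param train A [mapkl_dataset()] with both classes and at least 2 disease
#'   samples.
#' @param N Number of top-ranked genes kept for clustering (default 200).
#' @param B Number of maxT permutations (default 1000).
#' @param statistic_kind `"wilcoxon"` (default) or `"welch_t"`.
#' @param mode maxT mode, `"step_down"` (default) or `"single_step"`.
#' @param k_max Largest candidate cluster count for the KL index (default
#'   30); must be smaller than `N` and is capped at `top-N size - 1`.
#' @param kl_samples Samples the KL index sees: `"disease"` (default) or
#'   `"all"` training samples.
#' @param ap_samples Samples the AP similarity uses: `"all"` (default) or
#'   `"disease"`.
#' @param damping,max_iter,conv_window Affinity propagation controls, see
#'   [ap_run()].
#' @param seed Integer seed; the whole pipeline is deterministic given it.
#' @return An object of class `mapkl_signature`: list with `exemplar_ids`
#'   (gene identifiers, in top-N row order), `membership` (named vector,
#'   top-N gene -> exemplar gene), `k`, `off_target`, `ranking` (the full
#'   `mapkl_ranking`), `kl` (the `mapkl_kl` profile), `ap` (the `mapkl_ap`
#'   result) and `provenance` (the parameters used).
#' @export
mapkl_select <- function(train, N = 200, B = 1000,
                         statistic_kind = c("wilcoxon", "welch_t"),
                         mode = c("step_down", "single_step"),
                         k_max = 30,
                         kl_samples = c("disease", "all"),
                         ap_samples = c("all", "disease"),
                         damping = 0.9, max_iter = 1000, conv_window = 100,
                         seed = 1) {
  statistic_kind <- match.arg(statistic_kind)
  mode <- match.arg(mode)
  kl_samples <- match.arg(kl_samples)
  ap_samples <- match.arg(ap_samples)
  if (k_max >= N) stop("k_max must be smaller than N")
  if (sum(train$labels == 1L) < 2)
    stop("need at least 2 disease samples for the KL index")

  rl <- maxt_adjust(train, B = B, seed = seed, kind = statistic_kind,
                    mode = mode)
  top <- select_top_n(rl, train, N)

  kl_cols <- if (kl_samples == "disease") which(top$labels == 1L)
             else seq_len(n_samples(top))
  k_max_eff <- min(k_max, n_genes(top) - 1)
  if (k_max_eff < 3) stop("top-N set too small for cluster-count estimation")
  kl <- kl_select_k(top$matrix[, kl_cols, drop = FALSE],
                    k_min = 2, k_max = k_max_eff)

  ap_cols <- if (ap_samples == "disease") which(top$labels == 1L)
             else seq_len(n_samples(top))
  S <- similarity_matrix(top$matrix[, ap_cols, drop = FALSE])
  ap <- ap_run_k(S, target_k = kl$k, damping = damping, max_iter = max_iter,
                 conv_window = conv_window, seed = seed)

  ids <- rownames(top$matrix)
  exemplar_ids <- ids[ap$exemplars]
  membership <- setNames(ids[ap$assignment], ids)
  structure(list(exemplar_ids = exemplar_ids,
                 membership = membership,
                 k = kl$k,
                 off_target = isTRUE(ap$off_target),
                 ranking = rl, kl = kl, ap = ap,
                 provenance = list(N = N, B = B,
                                   statistic_kind = statistic_kind,
                                   mode = mode, k_max = k_max,
                                   kl_samples = kl_samples,
                                   ap_samples = ap_samples,
                                   damping = damping, max_iter = max_iter,
                                   conv_window = conv_window, seed = seed)),
            class = "mapkl_signature")
}

#' @export
print.mapkl_signature <- function(x, ...) {
  cat(sprintf("mapkl signature: %d exemplar genes (k = %d%s)\n",
              length(x$exemplar_ids), x$k,
              if (x$off_target) "; OFF TARGET" else ""))
  cat("  ", paste(head(x$exemplar_ids, 10), collapse = ", "),
      if (length(x$exemplar_ids) > 10) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Restrict a dataset to the signature's exemplar genes
#'
#' @param ds A [mapkl_dataset()] containing all signature genes.
#' @param sig A `mapkl_signature` from [mapkl_select()].
#' @return The sub-dataset of the exemplar genes, rows in signature order.
#' @export
apply_signature <- function(ds, sig) {
  subset_genes(ds, sig$exemplar_ids)
}
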