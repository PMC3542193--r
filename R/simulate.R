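# Cluster-structured simulation of two-class expression data with known
# differentially expressed genes (DEGs). Non-DEGs are i.i.d. Normal(0, 0.5)
# in both classes. DEGs follow the null in the normal class; in the disease
# class the genes of cluster j share a per-sample latent factor, giving
# within-cluster correlation rho, plus a cluster-specific mean shift, while
# the marginal variance stays at the null value.

#' Specification of a clustered simulation
#'
#' @param n_clusters Number of planted DEG clusters c.
#' @param genes_per_cluster Genes per cluster g (so c*g DEGs in total).
#' @param n_genes Total number of genes (default 10000).
#' @param samples_per_class Samples per class (default 1200); the first
#'   `train_per_class` of each class form the training set, the remainder the
#'   test set.
#' @param train_per_class Training samples per class (default 100).
#' @param null_mean,null_variance Parameters of the null expression
#'   distribution (defaults 0 and 0.5).
#' @param delta_range Range of the cluster mean shifts in the disease class;
#'   cluster j gets the j-th of `n_clusters` equally spaced values in this
#'   range (default `c(1, 2)`).
#' @param within_cluster_rho Within-cluster correlation of DEGs in the
#'   disease class (share of the marginal variance carried by the shared
#'   per-cluster factor; default 0.8).
#' @param seed Integer seed.
#' @return An object of class `mapkl_simspec` (validated list of the above).
#' @export
simulation_spec <- function(n_clusters, genes_per_cluster,
                            n_genes = 10000, samples_per_class = 1200,
                            train_per_class = 100,
                            null_mean = 0, null_variance = 0.5,
                            delta_range = c(1, 2), within_cluster_rho = 0.8,
                            seed = 1) {
  if (n_clusters * genes_per_cluster > n_genes)
    stop("c * g DEGs must fit in n_genes")
  if (train_per_class > samples_per_class)
    stop("train_per_class must be <= samples_per_class")
  if (null_variance <= 0) stop("null_variance must be positive")
  if (within_cluster_rho < 0 || within_cluster_rho >= 1)
    stop("within_cluster_rho must be in [0, 1)")
  structure(list(n_clusters = as.integer(n_clusters),
                 genes_per_cluster = as.integer(genes_per_cluster),
                 n_genes = as.integer(n_genes),
                 samples_per_class = as.integer(samples_per_class),
                 train_per_class = as.integer(train_per_class),
                 null_mean = null_mean, null_variance = null_variance,
                 delta_range = delta_range,
                 within_cluster_rho = within_cluster_rho,
                 seed = as.integer(seed)),
            class = "mapkl_simspec")
}

#' Generate a clustered two-class simulation
#'
#' @param spec A [simulation_spec()].
#' @return A list with `train` and `test` ([mapkl_dataset()]s; `test` is
#'   `NULL` when `samples_per_class == train_per_class`), and `truth`
#'   (class `mapkl_truth`: `deg_ids`, and `cluster_of`, a named vector
#'   DEG -> cluster index).
#' @export
simulate_clusters_dataset <- function(spec) {
  stopifnot(inherits(spec, "mapkl_simspec"))
  G <- spec$n_genes
  spc <- spec$samples_per_class
  c_ <- spec$n_clusters
  g_ <- spec$genes_per_cluster
  sd0 <- sqrt(spec$null_variance)
  rho <- spec$within_cluster_rho
  load <- sqrt(rho * spec$null_variance)
  sd_eps <- sqrt((1 - rho) * spec$null_variance)
  deltas <- if (c_ == 1) mean(spec$delta_range)
            else seq(spec$delta_range[1], spec$delta_range[2], length.out = c_)

  gene_ids <- sprintf("g%05d", seq_len(G))
  out <- with_seed(spec$seed, {
    deg_idx <- sort(sample.int(G, c_ * g_))
    cluster_of <- rep(seq_len(c_), each = g_)
    X0 <- matrix(rnorm(G * spc, spec$null_mean, sd0), G, spc)
    X1 <- matrix(rnorm(G * spc, spec$null_mean, sd0), G, spc)
    Z <- matrix(rnorm(c_ * spc), c_, spc)  # shared per-cluster factors
    X1[deg_idx, ] <- deltas[cluster_of] + load * Z[cluster_of, , drop = FALSE] +
      matrix(rnorm(c_ * g_ * spc, 0, sd_eps), c_ * g_, spc)
    list(deg_idx = deg_idx, cluster_of = cluster_of, X0 = X0, X1 = X1)
  })

  rownames(out$X0) <- rownames(out$X1) <- gene_ids
  colnames(out$X0) <- sprintf("n%04d", seq_len(spc))
  colnames(out$X1) <- sprintf("d%04d", seq_len(spc))

  tr <- seq_len(spec$train_per_class)
  train <- mapkl_dataset(cbind(out$X0[, tr, drop = FALSE],
                               out$X1[, tr, drop = FALSE]),
                         rep(c(0L, 1L), each = spec$train_per_class))
  test <- NULL
  if (spc > spec$train_per_class) {
    te <- (spec$train_per_class + 1):spc
    test <- mapkl_dataset(cbind(out$X0[, te, drop = FALSE],
                                out$X1[, te, drop = FALSE]),
                          rep(c(0L, 1L), each = length(te)))
  }
  truth <- structure(list(deg_ids = gene_ids[out$deg_idx],
                          cluster_of = setNames(out$cluster_of,
                                                gene_ids[out$deg_idx])),
                     class = "mapkl_truth")
  list(train = train, test = test, truth = truth, spec = spec)
}

#' Score a signature against the simulation ground truth
#'
#' @param sig A `mapkl_signature` (or a character vector of gene ids).
#' @param truth A `mapkl_truth` from [simulate_clusters_dataset()].
#' @return A list with `n_degs_in_signature` (signature genes that are true
#'   DEGs) and `clusters_represented` (distinct planted clusters with at
#'   least one signature gene).
#' @export
recovery_report <- function(sig, truth) {
  genes <- if (inherits(sig, "mapkl_signature")) sig$exemplar_ids else sig
  hits <- intersect(genes, truth$deg_ids)
  list(n_degs_in_signature = length(hits),
       clusters_represented = length(unique(truth$cluster_of[hits])))
}
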