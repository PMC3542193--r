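test_that("spec validation rejects impossible configurations", {
  expect_error(simulation_spec(10, 20, n_genes = 100), "fit")
  expect_error(simulation_spec(2, 5, samples_per_class = 50,
                               train_per_class = 100), "train_per_class")
  expect_error(simulation_spec(2, 5, null_variance = 0), "positive")
  expect_error(simulation_spec(2, 5, within_cluster_rho = 1), "rho")
})

test_that("generated data have the declared shapes and bookkeeping", {
  spec <- simulation_spec(3, 4, n_genes = 200, samples_per_class = 30,
                          train_per_class = 10, seed = 2)
  sim <- simulate_clusters_dataset(spec)
  expect_equal(dim(sim$train$matrix), c(200, 20))
  expect_equal(dim(sim$test$matrix), c(200, 40))
  expect_equal(sum(sim$train$labels == 1L), 10)
  expect_equal(sum(sim$test$labels == 1L), 20)
  expect_length(sim$truth$deg_ids, 12)
  expect_equal(as.vector(table(sim$truth$cluster_of)), rep(4L, 3))
  # train columns are the first samples of each class, disjoint from test
  expect_length(intersect(colnames(sim$train$matrix),
                          colnames(sim$test$matrix)), 0)
  # no test set when every sample is a training sample
  sim2 <- simulate_clusters_dataset(simulation_spec(
    3, 4, n_genes = 100, samples_per_class = 10, train_per_class = 10))
  expect_null(sim2$test)
})

test_that("null genes keep the declared variance; DEGs keep it with shift and correlation", {
  spec <- simulation_spec(5, 10, n_genes = 60, samples_per_class = 1200,
                          train_per_class = 100, seed = 9)
  sim <- simulate_clusters_dataset(spec)
  full <- cbind(sim$train$matrix, sim$test$matrix)
  disease <- c(sim$train$labels, sim$test$labels) == 1L
  nulls <- setdiff(rownames(full), sim$truth$deg_ids)[1:5]
  for (g in nulls)  # 3*SE of a variance estimate at n = 2400 is ~0.03
    expect_lt(abs(var(full[g, ]) - 0.5), 0.06)
  # a DEG keeps marginal variance 0.5 in the disease class and its cluster shift
  deg <- sim$truth$deg_ids[1]
  cl <- sim$truth$cluster_of[deg]
  deltas <- seq(1, 2, length.out = 5)
  expect_lt(abs(var(full[deg, disease]) - 0.5), 0.09)
  expect_lt(abs(mean(full[deg, disease]) - deltas[cl]), 0.1)
  expect_lt(abs(mean(full[deg, !disease])), 0.1)
  # within-cluster correlation of disease-class DEGs near the requested 0.8
  mates <- names(sim$truth$cluster_of[sim$truth$cluster_of == cl])
  cc <- cor(t(full[mates, disease]))
  expect_lt(abs(mean(cc[upper.tri(cc)]) - 0.8), 0.1)
})

test_that("generation is fully reproducible from the spec seed", {
  spec <- simulation_spec(2, 3, n_genes = 50, samples_per_class = 8,
                          train_per_class = 4, seed = 77)
  s1 <- simulate_clusters_dataset(spec)
  s2 <- simulate_clusters_dataset(spec)
  expect_identical(s1$train$matrix, s2$train$matrix)
  expect_identical(s1$truth, s2$truth)
})

test_that("recovery report counts DEG hits and distinct clusters", {
  truth <- structure(list(deg_ids = c("a", "b", "c", "d"),
                          cluster_of = c(a = 1L, b = 1L, c = 2L, d = 2L)),
                     class = "mapkl_truth")
  expect_equal(recovery_report(c("a", "c"), truth),
               list(n_degs_in_signature = 2L, clusters_represented = 2L))
  expect_equal(recovery_report(c("x", "y"), truth),
               list(n_degs_in_signature = 0L, clusters_represented = 0L))
  expect_equal(recovery_report(c("a", "b"), truth)$clusters_represented, 1L)
})

test_that("with no effect the adjusted p-values behave like a global null", {
  # delta 0 and rho 0: DEGs are nulls; small-alpha exceedance stays at alpha
  spec <- simulation_spec(2, 5, n_genes = 300, samples_per_class = 15,
                          train_per_class = 15, delta_range = c(0, 0),
                          within_cluster_rho = 0, seed = 5)
  sim <- simulate_clusters_dataset(spec)
  rl <- maxt_adjust(sim$train, B = 200, seed = 5, mode = "single_step")
  expect_lte(mean(rl$adj_p <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
})
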