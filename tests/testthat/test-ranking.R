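test_that("group statistics match closed forms and handle degenerate groups", {
  # rank-sum z on fully separated groups: W=6, E[W]=10.5, sd=sqrt(5.25)
  z <- group_statistic(1:6, c(1, 1, 1, 0, 0, 0), "wilcoxon")
  expect_equal(z, (6 - 10.5) / sqrt(5.25), tolerance = 1e-12)
  expect_equal(z, oracle_wilcoxon_z(1:6, c(1, 1, 1, 0, 0, 0)))
  # Welch t with unit variances: (2-4)/sqrt(1/3+1/3)
  t <- group_statistic(c(1, 2, 3, 3, 4, 5), c(1, 1, 1, 0, 0, 0), "welch_t")
  expect_equal(t, -2 / sqrt(2 / 3), tolerance = 1e-12)
  # constant data: both kinds return 0
  expect_equal(group_statistic(rep(5, 6), c(1, 1, 1, 0, 0, 0), "wilcoxon"), 0)
  expect_equal(group_statistic(rep(5, 6), c(1, 1, 1, 0, 0, 0), "welch_t"), 0)
  # zero variance, unequal means: signed large sentinel
  t2 <- group_statistic(c(2, 2, 1, 1), c(1, 1, 0, 0), "welch_t")
  expect_gt(t2, 1e6)
  expect_lt(group_statistic(c(1, 1, 2, 2), c(1, 1, 0, 0), "welch_t"), -1e6)
})

test_that("group statistics agree with an independent oracle on random data", {
  for (s in 1:20) {
    x <- with_seed(s, round(rnorm(12), 1))  # rounding induces ties
    lab <- rep(c(0L, 1L), c(5, 7))
    expect_equal(group_statistic(x, lab, "wilcoxon"),
                 oracle_wilcoxon_z(x, lab), tolerance = 1e-10)
    tt <- t.test(x[lab == 1], x[lab == 0])  # Welch by default
    expect_equal(group_statistic(x, lab, "welch_t"),
                 unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("single gene: adjusted p equals the raw permutation p in both modes", {
  ds <- make_dataset(G = 1, n1 = 4, n0 = 4, seed = 3)
  for (mode in c("single_step", "step_down")) {
    rl <- maxt_adjust(ds, B = 500, seed = 9, mode = mode)
    # with one gene the max over genes is the gene itself
    expect_equal(attr(rl, "mode"), mode)
    expect_true(rl$adj_p >= 1 / 501 && rl$adj_p <= 1)
  }
  p1 <- maxt_adjust(ds, B = 500, seed = 9, mode = "single_step")$adj_p
  p2 <- maxt_adjust(ds, B = 500, seed = 9, mode = "step_down")$adj_p
  expect_equal(p1, p2)
})

test_that("step-down p-values are monotone and never exceed single-step", {
  ds <- make_dataset(G = 30, n1 = 6, n0 = 6, seed = 11, shift_rows = 1:5)
  sd_ <- maxt_adjust(ds, B = 300, seed = 2, mode = "step_down")
  ss <- maxt_adjust(ds, B = 300, seed = 2, mode = "single_step")
  # along decreasing |statistic|, step-down adj_p is non-decreasing
  ord <- order(-abs(sd_$statistic))
  expect_true(all(diff(sd_$adj_p[ord]) >= -1e-15))
  # gene-wise: step-down <= single-step
  p_sd <- setNames(sd_$adj_p, sd_$gene_id)
  p_ss <- setNames(ss$adj_p, ss$gene_id)
  expect_true(all(p_sd[names(p_ss)] <= p_ss + 1e-15))
  expect_true(all(p_ss >= 0 & p_ss <= 1))
})

test_that("ranking is invariant to sample reordering and deterministic by seed", {
  ds <- make_dataset(G = 15, n1 = 5, n0 = 5, seed = 4, shift_rows = 1:3)
  perm <- with_seed(8, sample(n_samples(ds)))
  ds2 <- subset_samples(ds, perm)
  r1 <- maxt_adjust(ds, B = 200, seed = 5)
  r2 <- maxt_adjust(ds2, B = 200, seed = 5)
  s1 <- setNames(r1$statistic, r1$gene_id)
  s2 <- setNames(r2$statistic, r2$gene_id)
  expect_equal(s1[names(s2)], s2, tolerance = 1e-12)
  r1b <- maxt_adjust(ds, B = 200, seed = 5)
  expect_identical(r1, r1b)
})

test_that("top-N selection respects rank order, caps at G, breaks ties stably", {
  ds <- make_dataset(G = 10, n1 = 4, n0 = 4, seed = 6, shift_rows = 1:2)
  rl <- maxt_adjust(ds, B = 100, seed = 1)
  top <- select_top_n(rl, ds, 4)
  expect_identical(rownames(top$matrix), rl$gene_id[1:4])
  whole <- select_top_n(rl, ds, 99)
  expect_identical(rownames(whole$matrix), rl$gene_id)
  expect_identical(whole$labels, ds$labels)
  # duplicated gene rows -> identical statistic and adj_p; input order decides
  m <- ds$matrix
  m["g05", ] <- m["g01", ]
  dup <- mapkl_dataset(m, ds$labels)
  rd1 <- maxt_adjust(dup, B = 100, seed = 1)
  rd2 <- maxt_adjust(dup, B = 100, seed = 1)
  expect_identical(rd1$gene_id, rd2$gene_id)
  expect_lt(which(rd1$gene_id == "g01"), which(rd1$gene_id == "g05"))
})
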