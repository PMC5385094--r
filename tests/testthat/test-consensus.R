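two_clouds <- function(n_per = 10, sep = 8, seed = 1) {
  set.seed(seed)
  x <- cbind(matrix(rnorm(5 * n_per, 0), 5), matrix(rnorm(5 * n_per, sep), 5))
  dimnames(x) <- list(paste0("g", 1:5), paste0("s", seq_len(2 * n_per)))
  x
}

test_that("consensus matrix matches direct enumeration of the run fixture", {
  runs <- list(
    list(items = c(1L, 2L, 3L), partition = c(1L, 1L, 2L)),
    list(items = c(1L, 2L, 4L), partition = c(1L, 2L, 2L)),
    list(items = c(1L, 2L, 3L, 4L), partition = c(1L, 1L, 2L, 2L)))
  M <- consensus_matrix(runs, 4)
  expect_equal(M[1, 2], 2 / 3)   # co-sampled 3x, co-clustered runs 1 and 3
  expect_equal(M[2, 4], 1 / 2)   # co-sampled runs 2-3, co-clustered run 2 only
  expect_equal(M[3, 4], 1)       # co-sampled once (run 3), co-clustered
  expect_true(isSymmetric(unclass(M)[1:4, 1:4]))
  expect_true(all(diag(M) == 1))
  # a pair never co-sampled is an error
  expect_error(consensus_matrix(runs[1:2], 4), "co-sampled")
  # two items always together
  M2 <- consensus_matrix(list(list(items = 1:2, partition = c(1L, 1L))), 2)
  expect_equal(unclass(M2)[1:2, 1:2], matrix(1, 2, 2), ignore_attr = TRUE)
})

test_that("PAC follows its definition and a brute-force count", {
  M <- diag(4)
  M[lower.tri(M)] <- c(0.0, 0.5, 1.0, 0.95, 0.2, 0.3)
  M <- M + t(M); diag(M) <- 1
  expect_equal(pac(M, 0.1, 0.9), 3 / 6)  # 0.5, 0.2, 0.3 are ambiguous
  # perfect consensus limit
  Mp <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 1), 3)
  expect_equal(pac(Mp, 0.1, 0.9), 0)
  expect_error(pac(Mp, 0.9, 0.1), "lower < upper")
  # random matrices vs explicit loop
  set.seed(3)
  for (rep in 1:5) {
    n <- 7
    R <- matrix(runif(n * n), n); R <- (R + t(R)) / 2; diag(R) <- 1
    cnt <- 0; tot <- 0
    for (i in 2:n) for (j in 1:(i - 1)) {
      tot <- tot + 1
      if (R[i, j] > 0.1 && R[i, j] < 0.9) cnt <- cnt + 1
    }
    expect_equal(pac(R, 0.1, 0.9), cnt / tot)
  }
})

test_that("the consensus CDF matches a sort-and-rank oracle", {
  M1 <- matrix(1, 3, 3)
  cdf1 <- consensus_cdf(M1)
  expect_equal(cdf1$cdf[cdf1$threshold < 1], rep(0, 100))
  expect_equal(cdf1$cdf[cdf1$threshold == 1], 1)
  # two-point mass at 0.2 / 0.8
  M2 <- diag(3); M2[2, 1] <- M2[1, 2] <- 0.2
  M2[3, 1] <- M2[1, 3] <- 0.2; M2[3, 2] <- M2[2, 3] <- 0.8
  cdf2 <- consensus_cdf(M2)
  expect_equal(cdf2$cdf[cdf2$threshold == 0.5], 2 / 3)
  expect_equal(cdf2$cdf[cdf2$threshold == 0.8], 1)
  set.seed(8)
  R <- matrix(runif(36), 6); R <- (R + t(R)) / 2; diag(R) <- 1
  v <- sort(R[lower.tri(R)])
  cdf <- consensus_cdf(R)
  for (i in seq_len(nrow(cdf)))
    expect_equal(cdf$cdf[i], mean(v <= cdf$threshold[i]))
})

test_that("final clusters recover blocks and match the naive agglomerator", {
  # two perfect blocks
  M <- matrix(0, 6, 6); M[1:3, 1:3] <- 1; M[4:6, 4:6] <- 1
  rownames(M) <- colnames(M) <- paste0("s", 1:6)
  lab <- final_clusters(M, 2)
  expect_true(same_partition(lab, rep(1:2, each = 3)))
  # k = n gives singletons
  expect_equal(sort(unique(final_clusters(M, 6))), 1:6)
  expect_error(final_clusters(M, 7), "exceeds")
  # random consensus matrices vs the O(n^3) oracle
  set.seed(12)
  for (rep in 1:10) {
    n <- sample(5:10, 1)
    R <- matrix(runif(n * n), n); R <- (R + t(R)) / 2; diag(R) <- 1
    rownames(R) <- colnames(R) <- paste0("s", seq_len(n))
    for (k in 2:min(4, n - 1)) {
      got <- final_clusters(R, k)
      want <- complete_linkage_oracle(1 - R, k)
      expect_true(same_partition(got, want),
                  label = sprintf("rep %d k %d partition match", rep, k))
    }
  }
})

test_that("final cluster labels are numbered by decreasing size", {
  M <- matrix(0, 5, 5); M[1:2, 1:2] <- 1; M[3:5, 3:5] <- 1
  rownames(M) <- colnames(M) <- paste0("s", 1:5)
  lab <- final_clusters(M, 2)
  expect_equal(unname(lab), c(2, 2, 1, 1, 1))  # the triple is cluster 1
})

test_that("select_k prefers the smallest k within tolerance of the minimum", {
  expect_equal(select_k(c(`2` = 0.30, `3` = 0.25, `4` = 0.12,
                          `5` = 0.050, `6` = 0.049), 0.01), 5)
  expect_equal(select_k(c(`2` = 0.4)), 2)
  expect_equal(select_k(c(`2` = 0.5, `3` = 0.1, `4` = 0.3), 0), 3)
  expect_error(select_k(numeric(0)), "empty")
})

test_that("resampling respects p_item and is deterministic given the seed", {
  x <- two_clouds()
  prm <- consensus_params(n_resamples = 20, p_item = 1, seed = 5)
  runs <- run_resamples(x, 2, prm)
  expect_true(all(vapply(runs, function(r) length(r$items), integer(1)) == 20))
  # clearly separated clouds: every run splits them identically
  for (r in runs) {
    split_lab <- r$partition[order(r$items)]
    expect_true(same_partition(split_lab, rep(1:2, each = 10)))
  }
  prm2 <- consensus_params(n_resamples = 20, p_item = 0.8, seed = 5)
  expect_identical(run_resamples(x, 2, prm2), run_resamples(x, 2, prm2))
  r08 <- run_resamples(x, 2, prm2)
  expect_true(all(vapply(r08, function(r) length(r$items), integer(1)) == 16))
})

test_that("the full fit is reproducible and finds planted structure", {
  cohort <- simulate_cohort(tiny_config(seed = 2))
  lnc <- expr_subset(cohort$expression,
                     genes = which(cohort$expression$gene_class == "lncRNA"),
                     samples = which(cohort$expression$sample_role == "tumor"))
  x <- log2p1(top_variable(lnc, 60))
  prm <- consensus_params(k_min = 2, k_max = 4, n_resamples = 60, seed = 7)
  fit1 <- consensus_cluster(x, params = prm)
  fit2 <- consensus_cluster(x, params = prm)
  expect_identical(fit1$consensus, fit2$consensus)
  expect_identical(fit1$labels, fit2$labels)
  expect_equal(fit1$selected_k, 3)
  expect_equal(compare_partitions(fit1$labels, cohort$truth_labels), 1)
  # block structure: within-truth-cluster consensus above between-cluster
  M <- fit1$consensus[["3"]]
  truth <- cohort$truth_labels[rownames(M)]
  same <- outer(truth, truth, "==") & lower.tri(M)
  diff <- outer(truth, truth, "!=") & lower.tri(M)
  expect_gt(mean(M[same]), mean(M[diff]))
})

test_that("consensus entries are stable under more resamples", {
  cohort <- simulate_cohort(tiny_config(seed = 14))
  lnc <- expr_subset(cohort$expression,
                     genes = which(cohort$expression$gene_class == "lncRNA"),
                     samples = which(cohort$expression$sample_role == "tumor"))
  x <- log2p1(top_variable(lnc, 60))
  M1 <- consensus_matrix(
    run_resamples(x, 3, consensus_params(n_resamples = 100, seed = 1)),
    ncol(x))
  M2 <- consensus_matrix(
    run_resamples(x, 3, consensus_params(n_resamples = 200, seed = 2)),
    ncol(x))
  expect_lt(mean(abs(M1[lower.tri(M1)] - M2[lower.tri(M2)])), 0.05)
})
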