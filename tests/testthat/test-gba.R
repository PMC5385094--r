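test_that("templates are binary indicators with degeneracy checks", {
  labels <- setNames(c(1L, 1L, 2L, 3L), paste0("s", 1:4))
  expect_equal(unname(make_template(labels, 1)), c(1L, 1L, 0L, 0L))
  expect_equal(unname(make_template(setNames(1:2, c("a", "b")), 2)),
               c(0L, 1L))
  expect_error(make_template(setNames(rep(1L, 3), letters[1:3]), 1),
               "degenerate")
  expect_error(make_template(labels, 9), "absent")
})

test_that("Pearson r and p match hand evaluation", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_with_p(x, x)$r, 1)
  expect_equal(pearson_with_p(x, x)$p, 0)
  expect_equal(pearson_with_p(x, -x)$r, -1)
  got <- pearson_with_p(x, c(1, 2, 3, 4, 6))
  expect_equal(got$r, 12 / sqrt(148), tolerance = 1e-12)
  # p via the t transform, cross-checked against cor.test
  ct <- cor.test(x, c(1, 2, 3, 4, 6))
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
  expect_error(pearson_with_p(rep(1, 5), x), "constant")
  expect_error(pearson_with_p(1:2, 1:2), "n >= 3")
})

test_that("surrogate selection applies all four filters", {
  set.seed(30)
  n_in <- 30; n_out <- 60; n_norm <- 10
  labels <- setNames(rep(c(1L, 2L), c(n_in, n_out)),
                     paste0("t", seq_len(n_in + n_out)))
  tmpl <- as.numeric(labels == 1L)
  mk <- function(logvals) pmax(2^logvals - 1, 0)
  g_good <- mk(3 * tmpl + rnorm(90, 0, 0.1))          # correlated, expressed
  g_flat <- rep(1.0, 90)                              # constant: excluded
  g_low <- mk(3 * tmpl + rnorm(90, 0, 0.1)) * 1e-3    # fails RPKM filter
  g_anti <- mk(3 * (1 - tmpl) + rnorm(90, 0, 0.1))    # anti-correlated
  tum <- rbind(g_good = g_good, g_flat = g_flat, g_low = g_low,
               g_anti = g_anti)
  colnames(tum) <- names(labels)
  # normals: baseline ~0 so planted genes are overexpressed in their cluster
  nrm <- rbind(g_good = mk(rnorm(n_norm, 0, 0.1)),
               g_flat = rep(1.0, n_norm),
               g_low = mk(rnorm(n_norm, 0, 0.1)) * 1e-3,
               g_anti = mk(rnorm(n_norm, 0, 0.1)))
  colnames(nrm) <- paste0("n", seq_len(n_norm))
  surr <- select_surrogates(tum, labels, nrm)
  expect_equal(surr$cluster1$gene, "g_good")
  expect_true(surr$cluster1$r[1] > 0.3)
  expect_lt(surr$cluster1$p[1], 1e-6)
  expect_gte(surr$cluster1$mean_rpkm[1], 0.1)
  expect_lt(surr$cluster1$overexpr_p_adj[1], 0.05)
  # cluster 2 picks the anti-correlated gene (it is cluster 2's marker)
  expect_equal(surr$cluster2$gene, "g_anti")
  expect_error(select_surrogates(tum, labels, nrm[, 1, drop = FALSE]),
               "normal")
})

test_that("default GBA thresholds are the published screen settings", {
  th <- gba_thresholds()
  expect_equal(th$surrogate_r, 0.3)
  expect_equal(th$surrogate_p, 1e-6)
  expect_equal(th$min_cluster_rpkm, 0.1)
  expect_equal(th$overexpr_alpha, 0.05)
  expect_equal(th$pcg_r, 0.3)
  expect_equal(th$pcg_p, 1e-9)
  expect_error(gba_thresholds(surrogate_r = 1.2), "r thresholds")
})

test_that("the cluster mean profile is the columnwise mean of log2(x+1)", {
  v <- matrix(rexp(5 * 8), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  prof <- cluster_mean_profile(v, paste0("g", 1:5))
  manual <- sapply(seq_len(8), function(j) mean(log2(v[, j] + 1)))
  expect_equal(unname(prof), manual, tolerance = 1e-12)
  # single surrogate: the gene's own transformed values
  expect_equal(unname(cluster_mean_profile(v, "g2")),
               unname(log2(v[2, ] + 1)))
  # two genes with values v and -v + c give a flat profile at c/2
  lv <- rbind(a = c(1, 2, 3), b = 5 - c(1, 2, 3))
  vv <- pmax(2^lv - 1, 0); colnames(vv) <- paste0("s", 1:3)
  expect_equal(unname(cluster_mean_profile(vv, c("a", "b"))), rep(2.5, 3))
  expect_error(cluster_mean_profile(v, character(0)), "empty")
  expect_error(cluster_mean_profile(v, "nope"), "absent")
})

test_that("PCG screening separates direct, inverse, and null genes", {
  set.seed(44)
  n <- 300
  profile <- setNames(rnorm(n, 2, 1), paste0("s", seq_len(n)))
  mk <- function(logvals) pmax(2^logvals - 1, 0)
  pcg <- rbind(direct = mk(profile),
               inverse = mk(6 - profile),
               noise = mk(rnorm(n, 2, 1)))
  colnames(pcg) <- names(profile)
  res <- correlated_pcgs(pcg, profile)
  expect_true("direct" %in% res$up$gene)
  expect_true("inverse" %in% res$down$gene)
  expect_false("noise" %in% c(res$up$gene, res$down$gene))
  expect_length(intersect(res$up$gene, res$down$gene), 0)
  # |r| sorted descending
  expect_true(all(diff(abs(res$up$r)) <= 0))
})

test_that("independent noise PCGs are excluded at n = 300", {
  # |r| > 0.3 at n = 300 implies p << 1e-6; a null gene passing p < 1e-9
  # AND |r| > 0.3 is essentially impossible
  set.seed(90)
  n <- 300
  profile <- rnorm(n)
  X <- matrix(rgamma(1000 * n, shape = 2), 1000, n,
              dimnames = list(paste0("g", 1:1000), paste0("s", 1:n)))
  res <- correlated_pcgs(X, setNames(profile, colnames(X)))
  expect_equal(nrow(res$up) + nrow(res$down), 0)
})

test_that("planted markers are recovered as surrogates across seeds", {
  sens <- spec <- up_sens <- down_sens <- numeric(0)
  for (s in 1:10) {
    cohort <- simulate_cohort(tiny_config(seed = 100 + s))
    gba <- gba_analysis(cohort$expression, cohort$truth_labels)
    for (tc in 1:3) {
      el <- gba[[paste0("cluster", tc)]]
      truth <- cohort$truth_markers[[tc]]
      other <- unlist(lapply(setdiff(1:3, tc), function(o)
        cohort$truth_markers[[o]]$lnc))
      sens <- c(sens, mean(truth$lnc %in% el$surrogates$gene))
      spec <- c(spec, mean(!other %in% el$surrogates$gene))
      up_sens <- c(up_sens, mean(truth$pcg_up %in% el$up_pcgs$gene))
      down_sens <- c(down_sens, mean(truth$pcg_down %in% el$down_pcgs$gene))
    }
  }
  expect_gte(mean(sens), 0.9)
  expect_gte(mean(spec), 0.95)
  expect_gte(mean(up_sens), 0.9)
  expect_gte(mean(down_sens), 0.9)
})

test_that("surrogate sets of distinct clusters do not overlap on the preset", {
  cohort <- simulate_cohort(tiny_config(seed = 55))
  gba <- gba_analysis(cohort$expression, cohort$truth_labels)
  genes <- lapply(gba, function(el) el$surrogates$gene)
  for (i in 2:3) for (j in 1:(i - 1))
    expect_length(intersect(genes[[i]], genes[[j]]), 0)
})
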