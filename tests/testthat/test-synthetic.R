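test_that("cohort bookkeeping matches the configuration", {
  cfg <- simulation_config(n_tumors = 5, cluster_sizes = c(2L, 3L),
                           n_normals = 2, n_lnc = 30, n_pcg = 40,
                           markers_per_cluster = 3, pcg_up_per_cluster = 3,
                           pcg_down_per_cluster = 3, seed = 4)
  cohort <- simulate_cohort(cfg)
  expect_equal(unname(table(cohort$truth_labels)), c(2L, 3L),
               ignore_attr = TRUE)
  expect_equal(dim(cohort$expression$values), c(70L, 7L))
  expect_true(all(cohort$expression$values >= 0))
  expect_setequal(names(cohort$truth_labels),
                  colnames(cohort$expression$values)[
                    cohort$expression$sample_role == "tumor"])
  # every planted marker id exists in the matrix
  all_markers <- unlist(cohort$truth_markers)
  expect_true(all(all_markers %in% rownames(cohort$expression$values)))
  # clinical covers exactly the tumor samples
  expect_setequal(cohort$clinical$sample_id, names(cohort$truth_labels))
})

test_that("generation is deterministic given the seed", {
  a <- simulate_cohort(tiny_config(seed = 9))
  b <- simulate_cohort(tiny_config(seed = 9))
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$clinical, b$clinical)
  c_ <- simulate_cohort(tiny_config(seed = 10))
  expect_false(identical(a$expression$values, c_$expression$values))
})

test_that("the hnscc preset has 426 tumors in 5 clusters", {
  cfg <- cohort_preset("hnscc")
  expect_equal(cfg$n_tumors, 426L)
  expect_length(cfg$cluster_sizes, 5)
  expect_equal(sum(cfg$cluster_sizes), 426L)
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(n_tumors = 10, cluster_sizes = c(3L, 3L)),
               "cluster_sizes")
  expect_error(simulation_config(n_tumors = 4, cluster_sizes = c(2L, 2L),
                                 n_lnc = 3, markers_per_cluster = 2),
               "exceeds")
  expect_error(simulation_config(censor_rate = 1.5), "censor_rate")
  bad_spec <- list(f = list(levels = c("a", "b"),
                            probs = matrix(c(0.6, 0.6, 0.5, 0.5), 2)))
  expect_error(simulation_config(n_tumors = 4, cluster_sizes = c(2L, 2L),
                                 covariate_spec = bad_spec),
               "sum to 1")
})

test_that("marker shift moves in-cluster log2 means by the planted amount", {
  cfg <- simulation_config(n_tumors = 150, cluster_sizes = rep(50L, 3),
                           n_normals = 10, n_lnc = 100, n_pcg = 50,
                           markers_per_cluster = 10, pcg_up_per_cluster = 5,
                           pcg_down_per_cluster = 0, marker_shift = 2,
                           noise_sd = 0.5, baseline_log_mean = 3,
                           baseline_log_sd = 0.3, seed = 21)
  cohort <- simulate_cohort(cfg)
  lv <- log2p1(cohort$expression)[, names(cohort$truth_labels)]
  # high baseline keeps values off the zero floor, so log2(v + 1)
  # recovers the planted Gaussian and the shift is estimable
  marker <- cohort$truth_markers$cluster1$lnc[1]
  in_c <- cohort$truth_labels == 1
  diff_hat <- mean(lv[marker, in_c]) - mean(lv[marker, !in_c])
  se <- cfg$noise_sd * sqrt(1 / sum(in_c) + 1 / sum(!in_c))
  expect_lt(abs(diff_hat - 2), 3 * se)
})

test_that("zero marker shift is rejected, tiny shift plants ~no separation", {
  expect_error(simulation_config(marker_shift = 0), "marker_shift")
  # near-zero effect: marker means match non-marker means within noise
  cfg <- simulation_config(n_tumors = 60, cluster_sizes = rep(20L, 3),
                           n_normals = 10, n_lnc = 100, n_pcg = 50,
                           markers_per_cluster = 5, pcg_up_per_cluster = 5,
                           pcg_down_per_cluster = 0, marker_shift = 1e-9,
                           noise_sd = 0.5, seed = 5)
  cohort <- simulate_cohort(cfg)
  lv <- log2p1(cohort$expression)[, names(cohort$truth_labels)]
  marker <- cohort$truth_markers$cluster1$lnc[1]
  in_c <- cohort$truth_labels == 1
  diff_hat <- mean(lv[marker, in_c]) - mean(lv[marker, !in_c])
  se <- cfg$noise_sd * sqrt(1 / sum(in_c) + 1 / sum(!in_c))
  expect_lt(abs(diff_hat), 4 * se)
})

test_that("median survival ratio tracks a 4-fold hazard ratio", {
  # censoring is scale-equivariant, so the median ratio estimates the
  # inverse hazard ratio; average over seeds to tame Monte-Carlo noise
  ratios <- sapply(1:10, function(s) {
    cfg <- simulation_config(n_tumors = 400, cluster_sizes = c(200L, 200L),
                             n_normals = 2, n_lnc = 20, n_pcg = 20,
                             markers_per_cluster = 2, pcg_up_per_cluster = 2,
                             pcg_down_per_cluster = 2,
                             hazard_per_cluster = c(0.04, 0.01),
                             censor_rate = 0.2, seed = 30 + s)
    cohort <- simulate_cohort(cfg)
    med <- tapply(cohort$clinical$os_time, cohort$truth_labels, median)
    med[["1"]] / med[["2"]]
  })
  expect_lt(abs(mean(ratios) - 0.25), 0.25 * 0.25)
})

test_that("a cohort round-trips through disk", {
  cohort <- simulate_cohort(tiny_config(seed = 3))
  dir <- withr::local_tempdir()
  paths <- write_cohort(cohort, dir)
  expr2 <- read_expression(paths[["expression"]],
                           sample_role_map = setNames(
                             cohort$expression$sample_role,
                             colnames(cohort$expression$values)))
  expect_equal(expr2$values, cohort$expression$values, tolerance = 1e-5)
  expect_identical(expr2$gene_class, cohort$expression$gene_class)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(unlist(truth$labels), cohort$truth_labels)
})
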