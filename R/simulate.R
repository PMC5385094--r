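#' Configuration for the synthetic cohort generator
#'
#' Defines a cohort with planted sample clusters in lncRNA space, per-cluster
#' marker lncRNAs, protein-coding genes (PCGs) directly or inversely
#' co-expressed with the markers, a block of normal-tissue samples, and
#' cluster-linked clinical covariates and survival endpoints. Expression is
#' generated on the log2 scale and mapped back to RPKM-like units, so the
#' planted effects live on the same scale the analysis stages use.
#'
#' @param n_tumors Number of tumor samples; must equal `sum(cluster_sizes)`.
#' @param n_normals Number of normal-tissue samples (no planted shifts).
#' @param cluster_sizes Integer vector of planted cluster sizes.
#' @param n_lnc,n_pcg Number of lncRNA and PCG genes.
#' @param markers_per_cluster lncRNA markers overexpressed in each cluster.
#' @param pcg_up_per_cluster,pcg_down_per_cluster PCGs shifted up /
#'   down together with each cluster's markers.
#' @param marker_shift Log2-scale mean increment for a marker within its
#'   cluster (sign-flipped for inverse PCGs).
#' @param noise_sd Log2-scale Gaussian noise standard deviation.
#' @param baseline_log_mean,baseline_log_sd Per-gene baseline log2 means are
#'   drawn from Normal(baseline_log_mean, baseline_log_sd).
#' @param covariate_spec Named list of categorical covariates; each element is
#'   a list with `levels` (character) and `probs` (clusters x levels matrix of
#'   per-cluster category probabilities, rows summing to 1). `NULL` uses a
#'   default set (HPV status, TP53 mutation, smoking, grade, anatomic site)
#'   with one HPV-enriched cluster.
#' @param age_spec List with numeric `mean` and `sd`, one entry per cluster
#'   (recycled if length 1). `NULL` uses defaults with one younger and one
#'   older cluster.
#' @param hazard_per_cluster Positive exponential event hazards, one per
#'   cluster, for the overall-survival endpoint; the recurrence endpoint uses
#'   1.5x these hazards. `NULL` uses defaults with the HPV-like cluster at the
#'   lowest hazard.
#' @param censor_rate Probability in `[0, 1]` that a subject is censored; a
#'   censored subject's observed time is uniform on (0, event time).
#' @param seed Integer seed; the whole cohort is reproducible given the seed.
#'
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_cohort()], [cohort_preset()]
#' @export
simulation_config <- function(n_tumors = 200,
                              n_normals = 20,
                              cluster_sizes = rep(40L, 5),
                              n_lnc = 1000,
                              n_pcg = 2000,
                              markers_per_cluster = 30,
                              pcg_up_per_cluster = 40,
                              pcg_down_per_cluster = 40,
                              marker_shift = 2,
                              noise_sd = 0.5,
                              baseline_log_mean = 1,
                              baseline_log_sd = 1,
                              covariate_spec = NULL,
                              age_spec = NULL,
                              hazard_per_cluster = NULL,
                              censor_rate = 0.3,
                              seed = 1L) {
  k <- length(cluster_sizes)
  if (k < 1 || any(cluster_sizes < 1))
    stop("`cluster_sizes` must be positive integers", call. = FALSE)
  if (sum(cluster_sizes) != n_tumors)
    stop("sum(cluster_sizes) must equal n_tumors", call. = FALSE)
  if (n_normals < 0) stop("`n_normals` must be >= 0", call. = FALSE)
  if (markers_per_cluster * k > n_lnc)
    stop("markers_per_cluster x number of clusters exceeds n_lnc", call. = FALSE)
  if ((pcg_up_per_cluster + pcg_down_per_cluster) * k > n_pcg)
    stop("planted PCGs per cluster exceed n_pcg", call. = FALSE)
  if (marker_shift <= 0) stop("`marker_shift` must be > 0", call. = FALSE)
  if (noise_sd <= 0 || baseline_log_sd <= 0)
    stop("all standard deviations must be > 0", call. = FALSE)
  if (censor_rate < 0 || censor_rate > 1)
    stop("`censor_rate` must be in [0, 1]", call. = FALSE)

  if (is.null(covariate_spec)) covariate_spec <- default_covariate_spec(k)
  validate_covariate_spec(covariate_spec, k)

  if (is.null(age_spec)) {
    mu <- rep(61, k); mu[1] <- 56; if (k >= 2) mu[2] <- 66
    age_spec <- list(mean = mu, sd = rep(9, k))
  }
  age_spec$mean <- rep_len(age_spec$mean, k)
  age_spec$sd <- rep_len(age_spec$sd, k)
  if (any(age_spec$sd <= 0)) stop("age sd must be > 0", call. = FALSE)

  if (is.null(hazard_per_cluster)) {
    hazard_per_cluster <- rep(0.02, k)
    hazard_per_cluster[k] <- 0.006       # best prognosis in the last cluster
    if (k >= 2) hazard_per_cluster[1:2] <- 0.03
  }
  hazard_per_cluster <- rep_len(hazard_per_cluster, k)
  if (any(hazard_per_cluster <= 0))
    stop("`hazard_per_cluster` must be positive", call. = FALSE)

  structure(list(n_tumors = as.integer(n_tumors),
                 n_normals = as.integer(n_normals),
                 cluster_sizes = as.integer(cluster_sizes),
                 n_lnc = as.integer(n_lnc), n_pcg = as.integer(n_pcg),
                 markers_per_cluster = as.integer(markers_per_cluster),
                 pcg_up_per_cluster = as.integer(pcg_up_per_cluster),
                 pcg_down_per_cluster = as.integer(pcg_down_per_cluster),
                 marker_shift = marker_shift, noise_sd = noise_sd,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 covariate_spec = covariate_spec, age_spec = age_spec,
                 hazard_per_cluster = hazard_per_cluster,
                 censor_rate = censor_rate, seed = as.integer(seed)),
            class = "sim_config")
}

default_covariate_spec <- function(k) {
  lastrow <- function(base, last) {
    m <- matrix(rep(base, k), nrow = k, byrow = TRUE)
    m[k, ] <- last
    m
  }
  list(
    hpv = list(levels = c("negative", "positive"),
               probs = lastrow(c(0.92, 0.08), c(0.15, 0.85))),
    tp53_mut = list(levels = c("0", "1"),
                    probs = {
                      m <- lastrow(c(0.4, 0.6), c(0.9, 0.1))
                      if (k >= 2) m[1:2, ] <- rep(c(0.25, 0.75), each = 2)
                      m
                    }),
    smoking = list(levels = c("never", "ever"),
                   probs = {
                     m <- matrix(rep(c(0.45, 0.55), k), nrow = k, byrow = TRUE)
                     if (k >= 2) m[1:2, ] <- rep(c(0.25, 0.75), each = 2)
                     m
                   }),
    grade = list(levels = c("G1", "G2", "G3", "G4"),
                 probs = {
                   m <- matrix(rep(c(0.15, 0.5, 0.3, 0.05), k),
                               nrow = k, byrow = TRUE)
                   m[k, ] <- c(0.05, 0.25, 0.55, 0.15)
                   m
                 }),
    site = list(levels = c("oral", "larynx", "tongue", "tonsil"),
                probs = {
                  m <- matrix(rep(c(0.4, 0.2, 0.25, 0.15), k),
                              nrow = k, byrow = TRUE)
                  if (k >= 2) m[1:2, ] <- rep(c(0.2, 0.55, 0.15, 0.1), each = 2)
                  m[k, ] <- c(0.15, 0.05, 0.1, 0.7)
                  m
                }))
}

validate_covariate_spec <- function(spec, k) {
  if (!is.list(spec) || is.null(names(spec)) || any(names(spec) == ""))
    stop("`covariate_spec` must be a named list", call. = FALSE)
  for (nm in names(spec)) {
    el <- spec[[nm]]
    p <- el$probs
    if (!is.matrix(p) || nrow(p) != k || ncol(p) != length(el$levels))
      stop("covariate '", nm, "': `probs` must be a ", k, " x ",
           length(el$levels), " matrix", call. = FALSE)
    if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-9))
      stop("covariate '", nm, "': probability rows must be non-negative and sum to 1",
           call. = FALSE)
  }
  invisible(spec)
}

#' Named cohort presets
#'
#' `"default"` is the reduced desk-scale preset (200 tumors in five clusters
#' of 40, 1000 lncRNAs, 2000 PCGs). `"hnscc"` mimics the scale of the TCGA
#' head-and-neck cohort: 426 tumors in five clusters, with a small
#' HPV-enriched cluster of 29 samples.
#'
#' @param name `"default"` or `"hnscc"`.
#' @param ... Overrides passed on to [simulation_config()].
#' @return A `sim_config`.
#' @export
cohort_preset <- function(name = c("default", "hnscc"), ...) {
  name <- match.arg(name)
  if (name == "default") return(simulation_config(...))
  simulation_config(n_tumors = 426,
                    cluster_sizes = c(120L, 140L, 60L, 77L, 29L),
                    n_normals = 40, n_lnc = 2000, n_pcg = 4000, ...)
}

# Planted gene identities: disjoint leading blocks of the lncRNA and PCG id
# ranges, one block per cluster.
planted_markers <- function(config) {
  k <- length(config$cluster_sizes)
  lnc_ids <- sprintf("lnc_%04d", seq_len(config$n_lnc))
  pcg_ids <- sprintf("pcg_%04d", seq_len(config$n_pcg))
  out <- vector("list", k)
  for (c_i in seq_len(k)) {
    li <- (c_i - 1) * config$markers_per_cluster + seq_len(config$markers_per_cluster)
    ui <- (c_i - 1) * config$pcg_up_per_cluster + seq_len(config$pcg_up_per_cluster)
    off <- k * config$pcg_up_per_cluster
    di <- off + (c_i - 1) * config$pcg_down_per_cluster +
      seq_len(config$pcg_down_per_cluster)
    out[[c_i]] <- list(lnc = lnc_ids[li], pcg_up = pcg_ids[ui],
                       pcg_down = pcg_ids[di])
  }
  names(out) <- paste0("cluster", seq_len(k))
  out
}

#' Simulate an expression matrix with planted cluster structure
#'
#' On the log2 scale each gene g in sample s is drawn as
#' `x = mu_g + shift(g, s) + Normal(0, noise_sd)`, where `shift` equals
#' `marker_shift` when g is a marker lncRNA or up-PCG of the cluster of s,
#' `-marker_shift` when g is a down-PCG of that cluster, and 0 otherwise
#' (normal samples get no shift). The RPKM-scale value is
#' `max(0, 2^x - 1)`, so values are non-negative and `log2(value + 1)`
#' recovers x wherever x >= 0.
#'
#' @param config A [simulation_config()].
#' @param labels Integer cluster labels for the tumor samples, consistent
#'   with `config$cluster_sizes`.
#' @return An [expr_matrix()] with `n_lnc + n_pcg` genes and
#'   `n_tumors + n_normals` samples (tumors first).
#' @export
simulate_expression <- function(config, labels) {
  stopifnot(inherits(config, "sim_config"))
  k <- length(config$cluster_sizes)
  labels <- as.integer(labels)
  if (length(labels) != config$n_tumors ||
      !identical(as.integer(tabulate(labels, k)), config$cluster_sizes))
    stop("`labels` inconsistent with config$cluster_sizes", call. = FALSE)

  with_seed(config$seed, {
    n_genes <- config$n_lnc + config$n_pcg
    n_samp <- config$n_tumors + config$n_normals
    gene_ids <- c(sprintf("lnc_%04d", seq_len(config$n_lnc)),
                  sprintf("pcg_%04d", seq_len(config$n_pcg)))
    sample_ids <- c(sprintf("tumor_%03d", seq_len(config$n_tumors)),
                    if (config$n_normals > 0)
                      sprintf("normal_%03d", seq_len(config$n_normals)))
    gene_class <- c(rep("lncRNA", config$n_lnc), rep("PCG", config$n_pcg))
    sample_role <- c(rep("tumor", config$n_tumors),
                     rep("normal", config$n_normals))

    mu <- rnorm(n_genes, config$baseline_log_mean, config$baseline_log_sd)
    markers <- planted_markers(config)
    gi <- function(ids) match(ids, gene_ids)
    # Down-regulated planted PCGs start from an expressed baseline: their
    # suppression inside the cluster must survive the zero floor on the
    # RPKM scale to be observable, as it is for real inversely
    # co-expressed genes.
    if (config$pcg_down_per_cluster > 0) {
      for (c_i in seq_len(k)) {
        di <- gi(markers[[c_i]]$pcg_down)
        mu[di] <- mu[di] + config$marker_shift
      }
    }
    x <- matrix(rnorm(n_genes * n_samp, 0, config$noise_sd), n_genes, n_samp)
    x <- x + mu
    for (c_i in seq_len(k)) {
      in_c <- which(labels == c_i)            # tumor columns only
      x[gi(markers[[c_i]]$lnc), in_c] <-
        x[gi(markers[[c_i]]$lnc), in_c] + config$marker_shift
      if (config$pcg_up_per_cluster > 0)
        x[gi(markers[[c_i]]$pcg_up), in_c] <-
          x[gi(markers[[c_i]]$pcg_up), in_c] + config$marker_shift
      if (config$pcg_down_per_cluster > 0)
        x[gi(markers[[c_i]]$pcg_down), in_c] <-
          x[gi(markers[[c_i]]$pcg_down), in_c] - config$marker_shift
    }
    v <- pmax(2^x - 1, 0)
    dimnames(v) <- list(gene_ids, sample_ids)
    expr_matrix(v, gene_class, sample_role)
  })
}

#' Simulate a full synthetic cohort
#'
#' Generates expression (via [simulate_expression()]), the planted tumor
#' cluster labels, the planted marker identities, and a clinical table with
#' per-cluster categorical covariates, Gaussian ages, and two exponential
#' survival endpoints (`os`, `recurrence`) under independent censoring.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_cohort` with elements `expression`
#'   (an `expr_matrix`), `truth_labels` (named integer vector over tumor
#'   samples), `truth_markers` (per-cluster lists of planted lncRNA / up-PCG /
#'   down-PCG identifiers), `clinical` (data.frame), and `config`.
#' @examples
#' cohort <- simulate_cohort(simulation_config(
#'   n_tumors = 20, cluster_sizes = c(10L, 10L), n_normals = 4,
#'   n_lnc = 50, n_pcg = 60, markers_per_cluster = 5,
#'   pcg_up_per_cluster = 5, pcg_down_per_cluster = 5, seed = 7))
#' table(cohort$truth_labels)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- length(config$cluster_sizes)
  labels <- rep(seq_len(k), config$cluster_sizes)
  expr <- simulate_expression(config, labels)
  tumor_ids <- colnames(expr$values)[expr$sample_role == "tumor"]
  names(labels) <- tumor_ids

  clin <- with_seed(config$seed + 1L, {
    df <- data.frame(sample_id = tumor_ids, stringsAsFactors = FALSE)
    for (nm in names(config$covariate_spec)) {
      el <- config$covariate_spec[[nm]]
      df[[nm]] <- vapply(labels, function(c_i)
        sample(el$levels, 1L, prob = el$probs[c_i, ]), character(1))
    }
    df$age <- rnorm(config$n_tumors,
                    config$age_spec$mean[labels], config$age_spec$sd[labels])
    for (ep in c("os", "recurrence")) {
      haz <- config$hazard_per_cluster[labels]
      if (ep == "recurrence") haz <- haz * 1.5
      t_event <- rexp(config$n_tumors, haz)
      censored <- runif(config$n_tumors) < config$censor_rate
      t_obs <- ifelse(censored, runif(config$n_tumors) * t_event, t_event)
      df[[paste0(ep, "_time")]] <- t_obs
      df[[paste0(ep, "_event")]] <- as.integer(!censored)
    }
    df
  })

  structure(list(expression = expr, truth_labels = labels,
                 truth_markers = planted_markers(config),
                 clinical = clin, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d tumors in %d planted clusters, %d normals\n",
              x$config$n_tumors, length(x$config$cluster_sizes),
              x$config$n_normals))
  print(x$expression)
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the expression matrix (TSV with a `gene_class` column), the clinical
#' table (TSV), and the planted truth (JSON: labels and marker identifiers).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory, created if needed.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             truth = file.path(dir, "truth.json"))
  write_expression(cohort$expression, paths[["expression"]])
  utils::write.table(cohort$clinical, paths[["clinical"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(labels = as.list(cohort$truth_labels),
         markers = cohort$truth_markers),
    paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
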