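#' Adjusted Rand index between two partitions
#'
#' Permutation-invariant agreement between two labelings of the same samples:
#' 1 for identical partitions (up to relabeling), approximately 0 for
#' independent ones.
#'
#' @param a,b Label vectors over the same samples. When both are named they
#'   are aligned by name; otherwise they must be positionally aligned.
#' @return The adjusted Rand index, a number in `[-1, 1]`.
#' @export
compare_partitions <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b)))
      stop("partitions cover different sample sets", call. = FALSE)
    b <- b[names(a)]
  }
  if (length(a) != length(b))
    stop("partitions have different lengths", call. = FALSE)
  tab <- table(a, b)
  n <- sum(tab)
  sum_cells <- sum(choose(tab, 2))
  sum_rows <- sum(choose(rowSums(tab), 2))
  sum_cols <- sum(choose(colSums(tab), 2))
  expected <- sum_rows * sum_cols / choose(n, 2)
  max_index <- (sum_rows + sum_cols) / 2
  if (max_index == expected) return(1)   # degenerate: single cluster each
  (sum_cells - expected) / (max_index - expected)
}

# Per-cluster decoy + planted gene sets for self-contained synthetic runs.
truth_gene_sets <- function(cohort, n_decoys = 10, decoy_size = 40) {
  pcg_ids <- rownames(cohort$expression$values)[
    cohort$expression$gene_class == "PCG"]
  sets <- list()
  for (nm in names(cohort$truth_markers)) {
    sets[[paste0(nm, "_up")]] <- cohort$truth_markers[[nm]]$pcg_up
    sets[[paste0(nm, "_down")]] <- cohort$truth_markers[[nm]]$pcg_down
  }
  planted <- unique(unlist(sets))
  pool <- setdiff(pcg_ids, planted)
  with_seed(cohort$config$seed + 2L, {
    for (i in seq_len(n_decoys))
      sets[[sprintf("decoy_%02d", i)]] <-
        sample(pool, min(decoy_size, length(pool)))
  })
  structure(sets, class = "gene_set_collection")
}

#' Run the full clustering and annotation pipeline
#'
#' Executes, in order: cohort simulation (or loading), detectability and
#' top-variability lncRNA selection, consensus clustering with PAC-based k
#' selection, cluster-covariate association, guilt-by-association selection
#' of surrogate lncRNAs and correlated PCGs, gene-set enrichment of the PCG
#' lists, and per-endpoint survival comparison. All stages share one sample
#' alignment and one seed.
#'
#' @param config A [simulation_config()]; ignored when `expression_path` is
#'   given.
#' @param expression_path,clinical_path Optional paths to a real expression
#'   TSV ([read_expression()]) and clinical TSV ([read_clinical()]); both or
#'   neither.
#' @param normal_ids For file input: sample ids to treat as normal tissue
#'   (expression files do not carry the role). Without normal samples the
#'   guilt-by-association and enrichment stages are skipped with a warning.
#' @param gene_sets Optional `gene_set_collection` or GMT path for the
#'   enrichment stage. On synthetic runs, `NULL` builds sets from the planted
#'   truth plus seeded decoys; on real runs, `NULL` skips enrichment.
#' @param detectable_rpkm Detectability threshold (mean raw RPKM).
#' @param top_k Number of most-variable lncRNAs to cluster on (capped at the
#'   detectable gene count).
#' @param consensus A [consensus_params()]; its seed is overridden by
#'   `config$seed` on synthetic runs.
#' @param thresholds A [gba_thresholds()].
#' @param covariates Character vector of clinical columns to associate;
#'   `NULL` associates every categorical column, and tests `age` with Welch's
#'   t per cluster when present.
#' @param endpoints Survival endpoints to test (need `<endpoint>_time` /
#'   `<endpoint>_event` columns).
#' @param horizon Optional administrative-censoring horizon for survival.
#' @param out_dir Optional directory: writes labels, PAC table, CDF table,
#'   association table, per-cluster GBA tables, survival summary and a JSON
#'   run manifest with file digests.
#' @return A list of class `lncluster_run`: `cohort` (synthetic runs only),
#'   `expression`, `selected` (the clustered `expr_matrix`), `fit`
#'   (`consensus_fit`), `labels`, `associations`, `age_tests`, `gba`,
#'   `enrichment`, `survival`, `manifest`.
#' @export
run_full <- function(config = simulation_config(),
                     expression_path = NULL, clinical_path = NULL,
                     normal_ids = NULL, gene_sets = NULL,
                     detectable_rpkm = 0.3, top_k = 300,
                     consensus = consensus_params(n_resamples = 250),
                     thresholds = gba_thresholds(),
                     covariates = NULL,
                     endpoints = c("os", "recurrence"),
                     horizon = NULL,
                     out_dir = NULL) {
  warnings <- character(0)
  synthetic <- is.null(expression_path)
  if (synthetic) {
    cohort <- simulate_cohort(config)
    expr <- cohort$expression
    clinical <- cohort$clinical
    consensus$seed <- config$seed
  } else {
    if (is.null(clinical_path))
      stop("real runs need both `expression_path` and `clinical_path`",
           call. = FALSE)
    cohort <- NULL
    role_map <- if (is.null(normal_ids)) NULL
    else stats::setNames(rep("normal", length(normal_ids)), normal_ids)
    expr <- read_expression(expression_path, sample_role_map = role_map)
    # type age and the endpoint columns; everything else stays categorical
    header <- names(utils::read.delim(clinical_path, nrows = 1,
                                      check.names = FALSE))
    schema <- character(0)
    if ("age" %in% header) schema["age"] <- "continuous"
    for (ep in endpoints) {
      tcol <- paste0(ep, "_time"); ecol <- paste0(ep, "_event")
      if (tcol %in% header) schema[tcol] <- "time"
      if (ecol %in% header) schema[ecol] <- "event"
    }
    clinical <- read_clinical(clinical_path,
                              schema = if (length(schema)) schema else NULL)
  }
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)

  tumor_ids <- colnames(expr$values)[expr$sample_role == "tumor"]
  missing_clin <- setdiff(tumor_ids, clinical$sample_id)
  if (length(missing_clin) > 0)
    stop("sample id(s) in expression but not clinical: ",
         paste(utils::head(missing_clin, 5), collapse = ", "),
         if (length(missing_clin) > 5) ", ..." else "", call. = FALSE)

  # feature selection on tumor columns of the lncRNA block
  lnc <- expr_subset(expr, genes = which(expr$gene_class == "lncRNA"))
  lnc_tumor <- expr_subset(lnc, samples = tumor_ids)
  detect <- filter_detectable(lnc_tumor, detectable_rpkm)
  k_sel <- min(top_k, nrow(detect$values))
  if (k_sel < top_k)
    warnings <- c(warnings, sprintf(
      "top_k reduced to %d detectable genes", k_sel))
  selected <- top_variable(detect, k_sel)

  # consensus clustering on log2(RPKM + 1)
  fit <- consensus_cluster(log2p1(selected), params = consensus)
  labels <- fit$labels

  # cluster-covariate association
  if (is.null(covariates)) {
    skip <- c("sample_id", "age",
              paste0(rep(endpoints, each = 2), c("_time", "_event")))
    covariates <- setdiff(names(clinical), skip)
    covariates <- covariates[vapply(clinical[covariates], function(col)
      is.character(col) || is.factor(col), logical(1))]
  }
  idx <- match(names(labels), clinical$sample_id)
  associations <- list()
  for (cov in covariates) {
    feat <- clinical[[cov]][idx]
    associations[[cov]] <- tryCatch(
      cluster_feature_association(labels, feat),
      error = function(e) {
        warnings <<- c(warnings, sprintf("association '%s' skipped: %s",
                                         cov, conditionMessage(e)))
        NULL
      })
  }
  age_tests <- NULL
  if ("age" %in% names(clinical)) {
    age <- clinical$age[idx]
    age_tests <- do.call(rbind, lapply(sort(unique(labels)), function(cl) {
      wt <- welch_t(age[labels == cl], age[labels != cl])
      data.frame(cluster = cl, mean_in = mean(age[labels == cl], na.rm = TRUE),
                 mean_out = mean(age[labels != cl], na.rm = TRUE),
                 t = wt$t, df = wt$df, p_value = wt$p_value)
    }))
  }

  # guilt-by-association + enrichment
  gba <- NULL
  enrichment <- NULL
  if (!any(expr$sample_role == "normal")) {
    warnings <- c(warnings,
                  "no normal samples: GBA and enrichment stages skipped")
  } else {
    gba <- gba_analysis(expr, labels, thresholds)
    if (is.null(gene_sets) && synthetic) gene_sets <- truth_gene_sets(cohort)
    if (!is.null(gene_sets)) {
      universe <- rownames(expr$values)[expr$gene_class == "PCG"]
      enrichment <- enrich_all_clusters(gba, gene_sets, universe)
    }
  }

  # survival
  surv <- list()
  for (ep in endpoints) {
    surv[[ep]] <- tryCatch(
      cluster_survival(labels, clinical, ep, horizon),
      error = function(e) {
        warnings <<- c(warnings, sprintf("survival endpoint '%s' skipped: %s",
                                         ep, conditionMessage(e)))
        NULL
      })
  }

  manifest <- list(
    tool = "lncluster",
    version = as.character(utils::packageVersion("lncluster")),
    seed = if (synthetic) config$seed else consensus$seed,
    synthetic = synthetic,
    n_tumors = length(tumor_ids),
    n_genes = nrow(expr$values),
    stages = list(
      feature_selection = list(detectable = nrow(detect$values),
                               selected = nrow(selected$values)),
      clustering = list(selected_k = fit$selected_k,
                        pac = as.list(fit$pac),
                        cluster_sizes = tabulate(labels, fit$selected_k)),
      association = list(features_tested = length(associations)),
      gba = if (is.null(gba)) NULL
      else list(surrogates = vapply(gba, function(el)
        nrow(el$surrogates), integer(1))),
      survival = lapply(surv, function(s)
        if (is.null(s)) NULL else list(p_value = s$test$p_value))),
    warnings = warnings)

  run <- structure(list(cohort = cohort, expression = expr,
                        selected = selected, fit = fit, labels = labels,
                        associations = associations, age_tests = age_tests,
                        gba = gba, enrichment = enrichment, survival = surv,
                        manifest = manifest),
                   class = "lncluster_run")
  if (!is.null(out_dir)) run$manifest <- write_run(run, out_dir)
  run
}

# Serialize a run's tabular outputs + manifest (with md5 digests) to disk.
write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wtsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  files <- character(0)
  files["labels"] <- wtsv(data.frame(sample_id = names(run$labels),
                                     cluster = unname(run$labels)),
                          "labels.tsv")
  files["pac"] <- wtsv(data.frame(k = as.integer(names(run$fit$pac)),
                                  pac = unname(run$fit$pac)), "pac.tsv")
  cdf_tab <- do.call(rbind, lapply(names(run$fit$cdf), function(k)
    cbind(k = as.integer(k), run$fit$cdf[[k]])))
  files["cdf"] <- wtsv(cdf_tab, "cdf.tsv")
  assoc_rows <- lapply(names(run$associations), function(cov) {
    a <- run$associations[[cov]]
    if (is.null(a)) return(NULL)
    cbind(feature = cov, a$per_cluster,
          global_p = a$global$p_value)
  })
  assoc_rows <- assoc_rows[!vapply(assoc_rows, is.null, logical(1))]
  if (length(assoc_rows))
    files["associations"] <- wtsv(do.call(rbind, assoc_rows),
                                  "associations.tsv")
  for (nm in names(run$gba)) {   # no-op when GBA was skipped
    el <- run$gba[[nm]]
    files[paste0(nm, "_surrogates")] <-
      wtsv(el$surrogates, paste0(nm, "_surrogates.tsv"))
    if (!is.null(el$up_pcgs))
      files[paste0(nm, "_up")] <- wtsv(el$up_pcgs, paste0(nm, "_up_pcgs.tsv"))
    if (!is.null(el$down_pcgs))
      files[paste0(nm, "_down")] <- wtsv(el$down_pcgs,
                                         paste0(nm, "_down_pcgs.tsv"))
  }
  surv_rows <- lapply(names(run$survival), function(ep) {
    s <- run$survival[[ep]]
    if (is.null(s)) return(NULL)
    data.frame(endpoint = ep, statistic = s$test$statistic, df = s$test$df,
               p_value = s$test$p_value)
  })
  surv_rows <- surv_rows[!vapply(surv_rows, is.null, logical(1))]
  if (length(surv_rows))
    files["survival"] <- wtsv(do.call(rbind, surv_rows), "survival.tsv")
  manifest <- run$manifest
  manifest$files <- as.list(stats::setNames(
    unname(tools::md5sum(files)), names(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' @export
print.lncluster_run <- function(x, ...) {
  cat("lncluster pipeline run\n")
  cat(sprintf("  %d tumors, %d genes; clustered on %d selected lncRNAs\n",
              x$manifest$n_tumors, x$manifest$n_genes,
              nrow(x$selected$values)))
  cat(sprintf("  selected k = %d (PAC: %s)\n", x$fit$selected_k,
              paste(sprintf("%s=%.3f", names(x$fit$pac), x$fit$pac),
                    collapse = ", ")))
  for (nm in names(x$gba))
    cat(sprintf("  %s: %d surrogates, %d up-PCGs, %d down-PCGs\n", nm,
                nrow(x$gba[[nm]]$surrogates),
                if (is.null(x$gba[[nm]]$up_pcgs)) 0L
                else nrow(x$gba[[nm]]$up_pcgs),
                if (is.null(x$gba[[nm]]$down_pcgs)) 0L
                else nrow(x$gba[[nm]]$down_pcgs)))
  for (ep in names(x$survival))
    if (!is.null(x$survival[[ep]]))
      cat(sprintf("  survival '%s': log-rank p = %.3g\n", ep,
                  x$survival[[ep]]$test$p_value))
  invisible(x)
}
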