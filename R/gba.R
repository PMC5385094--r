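#' Thresholds for the guilt-by-association screen
#'
#' Defaults follow the established template-correlation screen for surrogate
#' lncRNA selection: template correlation r > 0.3 at p < 1e-6, mean raw RPKM
#' >= 0.1 within the cluster, overexpression versus normal tissue at
#' BH-corrected p < 0.05, and PCG correlation |r| > 0.3 at p < 1e-9.
#'
#' @param surrogate_r,surrogate_p Template-correlation thresholds for
#'   surrogate lncRNAs.
#' @param min_cluster_rpkm Minimum mean raw expression within the cluster.
#' @param overexpr_alpha Corrected-p threshold for overexpression versus
#'   normals.
#' @param pcg_r,pcg_p Correlation thresholds for PCG association with the
#'   cluster mean profile.
#' @return A list of class `gba_thresholds`.
#' @export
gba_thresholds <- function(surrogate_r = 0.3, surrogate_p = 1e-6,
                           min_cluster_rpkm = 0.1, overexpr_alpha = 0.05,
                           pcg_r = 0.3, pcg_p = 1e-9) {
  if (!(surrogate_r > 0 && surrogate_r < 1) || !(pcg_r > 0 && pcg_r < 1))
    stop("r thresholds must lie in (0, 1)", call. = FALSE)
  if (!(surrogate_p > 0 && surrogate_p < 1) ||
      !(pcg_p > 0 && pcg_p < 1) ||
      !(overexpr_alpha > 0 && overexpr_alpha < 1))
    stop("p thresholds must lie in (0, 1)", call. = FALSE)
  if (min_cluster_rpkm < 0)
    stop("`min_cluster_rpkm` must be >= 0", call. = FALSE)
  structure(list(surrogate_r = surrogate_r, surrogate_p = surrogate_p,
                 min_cluster_rpkm = min_cluster_rpkm,
                 overexpr_alpha = overexpr_alpha,
                 pcg_r = pcg_r, pcg_p = pcg_p),
            class = "gba_thresholds")
}

#' Binary template vector for one cluster
#'
#' Indicator over the labelled samples: 1 inside the target cluster, 0
#' outside. Used as the correlation target when screening for genes maximally
#' expressed in that cluster.
#'
#' @param labels Cluster labels, named by sample id.
#' @param cluster_id The target cluster.
#' @return Integer 0/1 vector aligned with (and named like) `labels`.
#' @export
make_template <- function(labels, cluster_id) {
  if (!cluster_id %in% labels)
    stop("cluster '", cluster_id, "' absent from `labels`", call. = FALSE)
  tmpl <- as.integer(labels == cluster_id)
  if (all(tmpl == 1L))
    stop("degenerate template: cluster '", cluster_id,
         "' covers every sample", call. = FALSE)
  names(tmpl) <- names(labels)
  tmpl
}

#' Pearson correlation with a t-based p-value
#'
#' Sample correlation r (clipped to `[-1, 1]`) with two-sided p-value from
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`; neither constant.
#' @return A list with `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  r <- max(-1, min(1, stats::cor(x, y)))
  p <- if (abs(r) == 1) 0 else {
    t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(t_stat), n - 2)
  }
  list(r = r, p = p)
}

# Vectorized row-wise Pearson r and p of each row of X against y.
# Constant rows get NA (treated as non-correlated by callers).
row_cor_with_p <- function(X, y) {
  n <- length(y)
  Xc <- X - rowMeans(X)
  yc <- y - mean(y)
  ssx <- rowSums(Xc^2)
  ssy <- sum(yc^2)
  r <- as.vector(Xc %*% yc) / sqrt(ssx * ssy)
  r[ssx == 0] <- NA
  r <- pmax(-1, pmin(1, r))
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  t_stat <- r[ok] * sqrt(n - 2) / sqrt(pmax(1 - r[ok]^2, 0))
  p[ok] <- ifelse(abs(r[ok]) == 1, 0, 2 * stats::pt(-abs(t_stat), n - 2))
  list(r = r, p = p)
}

# Vectorized Welch t-test of each row of A against the same row of B.
row_welch <- function(A, B) {
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t_stat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t = t_stat, df = df, p = p, mean_a = ma, mean_b = mb)
}

#' Select surrogate lncRNAs for each cluster
#'
#' A lncRNA is a surrogate of cluster c when (i) its log2(RPKM + 1) profile
#' correlates with the cluster's binary template at `r > surrogate_r` and
#' `p < surrogate_p`; (ii) its mean raw expression within c is at least
#' `min_cluster_rpkm`; and (iii) it is overexpressed in cluster-c tumors
#' relative to normal tissue (Welch t on log2(RPKM + 1), BH-adjusted
#' `p < overexpr_alpha`, cluster mean above normal mean). The BH family for
#' (iii) is the set of genes passing (i)-(ii) for that cluster. Constant
#' genes are non-correlated and silently excluded (counted).
#'
#' @param lnc_expr lncRNA expression over the labelled tumor samples, raw
#'   RPKM-like scale ([expr_matrix()] or matrix; columns must cover
#'   `names(labels)`).
#' @param labels Cluster labels named by tumor sample id.
#' @param normal_expr Expression of the same genes in normal samples (raw
#'   scale); must be non-empty with >= 2 samples.
#' @param thresholds A [gba_thresholds()].
#' @param overexpr_vs Compare normals against `"cluster"` tumors (default) or
#'   against `"all_tumors"`.
#' @return A list of class `surrogate_set`: per cluster, a data.frame with
#'   columns `gene`, `r`, `p`, `mean_rpkm`, `overexpr_p`, `overexpr_p_adj`.
#'   Attribute `n_constant` counts constant genes excluded.
#' @export
select_surrogates <- function(lnc_expr, labels, normal_expr,
                              thresholds = gba_thresholds(),
                              overexpr_vs = c("cluster", "all_tumors")) {
  overexpr_vs <- match.arg(overexpr_vs)
  v <- expr_values(lnc_expr)
  nv <- expr_values(normal_expr)
  if (ncol(nv) < 2)
    stop("need >= 2 normal samples for the overexpression test", call. = FALSE)
  if (!all(names(labels) %in% colnames(v)))
    stop("`lnc_expr` must cover all labelled tumor samples", call. = FALSE)
  if (!all(rownames(v) == rownames(nv)))
    stop("`normal_expr` must cover the same genes in the same order",
         call. = FALSE)
  v <- v[, names(labels), drop = FALSE]
  lv <- log2(v + 1)
  lnv <- log2(nv + 1)
  clusters <- sort(unique(labels))
  out <- list()
  n_constant <- 0L
  for (cl in clusters) {
    tmpl <- make_template(labels, cl)
    cp <- row_cor_with_p(lv, tmpl)
    n_constant <- max(n_constant, sum(is.na(cp$r)))
    in_c <- labels == cl
    mean_rpkm <- rowMeans(v[, in_c, drop = FALSE])
    pass12 <- !is.na(cp$r) & cp$r > thresholds$surrogate_r &
      cp$p < thresholds$surrogate_p & mean_rpkm >= thresholds$min_cluster_rpkm
    idx <- which(pass12)
    df <- data.frame(gene = character(0), r = numeric(0), p = numeric(0),
                     mean_rpkm = numeric(0), overexpr_p = numeric(0),
                     overexpr_p_adj = numeric(0), stringsAsFactors = FALSE)
    if (length(idx) > 0) {
      tum <- if (overexpr_vs == "cluster") lv[idx, in_c, drop = FALSE]
      else lv[idx, , drop = FALSE]
      wt <- row_welch(tum, lnv[idx, , drop = FALSE])
      adj <- bh_adjust(wt$p)
      keep <- adj < thresholds$overexpr_alpha & wt$mean_a > wt$mean_b
      sel <- idx[keep]
      df <- data.frame(gene = rownames(v)[sel], r = cp$r[sel], p = cp$p[sel],
                       mean_rpkm = mean_rpkm[sel],
                       overexpr_p = wt$p[keep], overexpr_p_adj = adj[keep],
                       stringsAsFactors = FALSE)
      df <- df[order(-df$r, df$gene, method = "radix"), ]
      rownames(df) <- NULL
    }
    out[[paste0("cluster", cl)]] <- df
  }
  structure(out, class = "surrogate_set", n_constant = n_constant)
}

#' @export
print.surrogate_set <- function(x, ...) {
  cat("Surrogate lncRNA sets:\n")
  for (nm in names(x))
    cat(sprintf("  %s: %d surrogate(s)\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Mean expression profile of a surrogate set
#'
#' Per-sample arithmetic mean of log2(RPKM + 1) over the surrogate genes;
#' the correlation target for the protein-coding-gene screen.
#'
#' @param lnc_expr Expression ([expr_matrix()] or matrix) on the raw scale.
#' @param surrogate_ids Non-empty character vector of gene ids.
#' @return Named numeric vector over the samples of `lnc_expr`.
#' @export
cluster_mean_profile <- function(lnc_expr, surrogate_ids) {
  if (length(surrogate_ids) == 0)
    stop("empty surrogate list: no profile can be formed", call. = FALSE)
  v <- expr_values(lnc_expr)
  missing_ids <- setdiff(surrogate_ids, rownames(v))
  if (length(missing_ids) > 0)
    stop("surrogate gene(s) absent from the matrix: ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  colMeans(log2(v[surrogate_ids, , drop = FALSE] + 1))
}

#' Protein-coding genes correlated with a cluster profile
#'
#' Screens every PCG against the cluster's mean surrogate profile:
#' `up` = genes with `r > pcg_r` and `p < pcg_p`; `down` = genes with
#' `r < -pcg_r` and `p < pcg_p`. The lists are disjoint and sorted by
#' decreasing `|r|`. Constant genes are excluded.
#'
#' @param pcg_expr PCG expression over the profile's samples, raw scale
#'   ([expr_matrix()] or matrix); log2(RPKM + 1) is applied internally.
#' @param profile Numeric vector (log2 scale), named by sample id.
#' @param thresholds A [gba_thresholds()].
#' @return A list with data.frames `up` and `down` (columns `gene`, `r`,
#'   `p`).
#' @export
correlated_pcgs <- function(pcg_expr, profile,
                            thresholds = gba_thresholds()) {
  v <- expr_values(pcg_expr)
  if (!is.null(names(profile))) {
    if (!all(names(profile) %in% colnames(v)))
      stop("`pcg_expr` must cover the profile's samples", call. = FALSE)
    v <- v[, names(profile), drop = FALSE]
  } else if (ncol(v) != length(profile))
    stop("`profile` length must match the sample count", call. = FALSE)
  lv <- log2(v + 1)
  cp <- row_cor_with_p(lv, profile)
  mk <- function(sel) {
    df <- data.frame(gene = rownames(v)[sel], r = cp$r[sel], p = cp$p[sel],
                     stringsAsFactors = FALSE)
    df <- df[order(-abs(df$r), df$gene, method = "radix"), ]
    rownames(df) <- NULL
    df
  }
  ok <- !is.na(cp$r)
  list(up = mk(which(ok & cp$r > thresholds$pcg_r & cp$p < thresholds$pcg_p)),
       down = mk(which(ok & cp$r < -thresholds$pcg_r & cp$p < thresholds$pcg_p)))
}

#' Full guilt-by-association analysis of a clustered cohort
#'
#' For every cluster: select surrogate lncRNAs ([select_surrogates()]), form
#' the mean surrogate profile ([cluster_mean_profile()]), and screen the
#' protein-coding genes for direct and inverse correlation
#' ([correlated_pcgs()]). Clusters with no surrogates are skipped with a
#' message.
#'
#' @param expr An [expr_matrix()] holding both lncRNA and PCG rows, tumor and
#'   normal columns, raw scale.
#' @param labels Cluster labels named by tumor sample id.
#' @param thresholds A [gba_thresholds()].
#' @param overexpr_vs Passed to [select_surrogates()].
#' @return A list of class `gba_result`: per cluster, a list with
#'   `surrogates` (data.frame), `profile` (named vector or `NULL`), `up_pcgs`
#'   and `down_pcgs` (data.frames).
#' @export
gba_analysis <- function(expr, labels, thresholds = gba_thresholds(),
                         overexpr_vs = c("cluster", "all_tumors")) {
  stopifnot(inherits(expr, "expr_matrix"))
  overexpr_vs <- match.arg(overexpr_vs)
  lnc <- expr_subset(expr, genes = which(expr$gene_class == "lncRNA"))
  pcg <- expr_subset(expr, genes = which(expr$gene_class == "PCG"))
  tumor_cols <- which(expr$sample_role == "tumor")
  normal_cols <- which(expr$sample_role == "normal")
  if (length(normal_cols) == 0)
    stop("no normal samples: the overexpression filter needs normal tissue",
         call. = FALSE)
  lnc_tumor <- expr_subset(lnc, samples = tumor_cols)
  lnc_normal <- expr_subset(lnc, samples = normal_cols)
  pcg_tumor <- expr_subset(pcg, samples = tumor_cols)
  surr <- select_surrogates(lnc_tumor, labels, lnc_normal, thresholds,
                            overexpr_vs)
  out <- list()
  for (nm in names(surr)) {
    s <- surr[[nm]]
    if (nrow(s) == 0) {
      message("cluster '", nm, "': no surrogate lncRNAs; skipped")
      out[[nm]] <- list(surrogates = s, profile = NULL,
                        up_pcgs = NULL, down_pcgs = NULL)
      next
    }
    prof <- cluster_mean_profile(
      expr_subset(lnc_tumor, samples = names(labels)), s$gene)
    pcgs <- correlated_pcgs(pcg_tumor, prof, thresholds)
    out[[nm]] <- list(surrogates = s, profile = prof,
                      up_pcgs = pcgs$up, down_pcgs = pcgs$down)
  }
  structure(out, class = "gba_result", thresholds = thresholds)
}

#' @export
print.gba_result <- function(x, ...) {
  cat("Guilt-by-association result:\n")
  for (nm in names(x)) {
    el <- x[[nm]]
    cat(sprintf("  %s: %d surrogate lncRNA(s), %d up-PCG(s), %d down-PCG(s)\n",
                nm, nrow(el$surrogates),
                if (is.null(el$up_pcgs)) 0L else nrow(el$up_pcgs),
                if (is.null(el$down_pcgs)) 0L else nrow(el$down_pcgs)))
  }
  invisible(x)
}
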