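#' Parameters for consensus clustering
#'
#' Defaults follow the established consensus-clustering settings for tumor
#' subtyping: k swept over 2..6, 1000 resamples, 80% item subsampling, all
#' features, k-medoids (PAM) on Euclidean distance, complete-linkage
#' consensus tree, and the standard PAC window (0.1, 0.9).
#'
#' @param k_min,k_max Range of cluster numbers to evaluate (`2 <= k_min <=
#'   k_max`).
#' @param n_resamples Number of subsampled clustering runs per k.
#' @param p_item Proportion of items (samples) drawn per run, in (0, 1].
#' @param p_feature Proportion of features (genes) drawn per run, in (0, 1].
#' @param distance `"euclidean"` (default) or `"pearson"` (1 - Pearson
#'   correlation between items).
#' @param inner_linkage Accepted for configuration parity and ignored: the
#'   base clusterer is k-medoids, which has no inner linkage. A note is
#'   emitted once per fit.
#' @param final_linkage Agglomeration rule for the consensus tree; only
#'   `"complete"` is offered.
#' @param pac_lower,pac_upper PAC window; a consensus value strictly inside
#'   (pac_lower, pac_upper) is ambiguous.
#' @param k_tolerance [select_k()] tolerance: the smallest k whose PAC is
#'   within `k_tolerance` of the minimum is selected.
#' @param median_center Median-center genes before computing distances.
#' @param seed Integer seed for the resampling streams.
#' @return A list of class `consensus_params`.
#' @export
consensus_params <- function(k_min = 2L, k_max = 6L, n_resamples = 1000L,
                             p_item = 0.8, p_feature = 1,
                             distance = c("euclidean", "pearson"),
                             inner_linkage = "complete",
                             final_linkage = "complete",
                             pac_lower = 0.1, pac_upper = 0.9,
                             k_tolerance = 0.01, median_center = FALSE,
                             seed = 1L) {
  distance <- match.arg(distance)
  if (!(k_min >= 2 && k_min <= k_max))
    stop("need 2 <= k_min <= k_max", call. = FALSE)
  if (!(p_item > 0 && p_item <= 1) || !(p_feature > 0 && p_feature <= 1))
    stop("`p_item` and `p_feature` must be in (0, 1]", call. = FALSE)
  if (!(pac_lower >= 0 && pac_lower < pac_upper && pac_upper <= 1))
    stop("need 0 <= pac_lower < pac_upper <= 1", call. = FALSE)
  if (final_linkage != "complete")
    stop("only complete final linkage is supported", call. = FALSE)
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 n_resamples = as.integer(n_resamples),
                 p_item = p_item, p_feature = p_feature, distance = distance,
                 inner_linkage = inner_linkage, final_linkage = final_linkage,
                 pac_lower = pac_lower, pac_upper = pac_upper,
                 k_tolerance = k_tolerance, median_center = median_center,
                 seed = as.integer(seed)),
            class = "consensus_params")
}

item_dist <- function(x, distance) {
  if (distance == "euclidean") stats::dist(t(x))
  else stats::as.dist(1 - stats::cor(x))
}

#' Subsampled k-medoids partitions for one k
#'
#' Draws `n_resamples` subsamples of `ceiling(p_item * n)` items (sample
#' columns) and `ceiling(p_feature * m)` features (gene rows), without
#' replacement, and partitions each subsample into k groups by PAM (k-medoids)
#' on the configured distance. Deterministic given `params$seed` (the per-k
#' stream is derived as `seed + 131 * k`).
#'
#' @param expr Numeric matrix (features x items), already transformed and
#'   feature-selected, or an [expr_matrix()] whose values are used as-is.
#' @param k Number of groups per run.
#' @param params A [consensus_params()].
#' @return List of runs; each run is a list with `items` (integer indices of
#'   the sampled items) and `partition` (integer group labels aligned with
#'   `items`).
#' @export
run_resamples <- function(expr, k, params = consensus_params()) {
  x <- expr_values(expr)
  n <- ncol(x); m <- nrow(x)
  n_item <- ceiling(params$p_item * n)
  n_feat <- ceiling(params$p_feature * m)
  if (params$median_center) x <- x - apply(x, 1, stats::median)
  full_d <- if (n_feat == m) as.matrix(item_dist(x, params$distance)) else NULL
  with_seed(params$seed + 131L * as.integer(k), {
    lapply(seq_len(params$n_resamples), function(run) {
      for (attempt in 1:10) {
        items <- sort(sample.int(n, n_item))
        if (length(items) >= k) {
          d <- if (!is.null(full_d)) stats::as.dist(full_d[items, items])
          else item_dist(x[sort(sample.int(m, n_feat)), items, drop = FALSE],
                         params$distance)
          part <- cluster::pam(d, k, diss = TRUE, cluster.only = TRUE)
          return(list(items = items, partition = as.integer(part)))
        }
        message("resample ", run, ": fewer sampled items than k; retrying")
      }
      stop("could not draw a subsample with >= k items after 10 attempts",
           call. = FALSE)
    })
  })
}

#' Consensus matrix from resampled partitions
#'
#' `M(i, j) = C(i, j) / N(i, j)`, where `N` counts the runs in which items i
#' and j were both sampled and `C` the runs in which they were additionally
#' placed in the same group. The diagonal is 1 by convention.
#'
#' @param runs List of runs as returned by [run_resamples()].
#' @param n_items Total number of items.
#' @return A symmetric `n_items x n_items` matrix with entries in `[0, 1]`,
#'   with attributes `N` and `C` holding the count matrices.
#' @export
consensus_matrix <- function(runs, n_items) {
  if (length(runs) < 1) stop("need at least one run", call. = FALSE)
  N <- matrix(0, n_items, n_items)
  C <- matrix(0, n_items, n_items)
  for (r in runs) {
    N[r$items, r$items] <- N[r$items, r$items] + 1
    for (g in split(r$items, r$partition))
      C[g, g] <- C[g, g] + 1
  }
  off <- upper.tri(N) | lower.tri(N)
  if (any(N[off] == 0))
    stop("some item pairs were never co-sampled; increase n_resamples or p_item",
         call. = FALSE)
  M <- C / pmax(N, 1)
  diag(M) <- 1
  structure(M, N = N, C = C)
}

#' Proportion of ambiguous clustering (PAC)
#'
#' The fraction of strict-lower-triangle consensus values lying strictly
#' inside the open interval `(lower, upper)`. Low PAC means most sample pairs
#' are either always or never co-clustered; the best-supported k minimizes
#' PAC.
#'
#' @param M Consensus matrix.
#' @param lower,upper Ambiguity window, `0 <= lower < upper <= 1`.
#' @return A number in `[0, 1]`.
#' @export
pac <- function(M, lower = 0.1, upper = 0.9) {
  if (!(lower < upper)) stop("need lower < upper", call. = FALSE)
  v <- M[lower.tri(M)]
  mean(v > lower & v < upper)
}

#' Empirical CDF of consensus values
#'
#' Cumulative fraction of strict-lower-triangle consensus entries at each
#' threshold of the fixed grid 0, 0.01, ..., 1.
#'
#' @param M Consensus matrix.
#' @return A data.frame with columns `threshold` and `cdf`.
#' @export
consensus_cdf <- function(M) {
  v <- M[lower.tri(M)]
  grid <- seq(0, 1, by = 0.01)
  data.frame(threshold = grid,
             cdf = vapply(grid, function(t) mean(v <= t), numeric(1)))
}

#' Final cluster call from a consensus matrix
#'
#' Agglomerative hierarchical clustering with complete linkage on the
#' dissimilarity `1 - M`, cut at k groups. Labels are renumbered 1..k by
#' decreasing cluster size, ties broken by the smallest contained item index.
#'
#' @param M Consensus matrix.
#' @param k Number of clusters, `2 <= k <= n_items` (k = n_items gives
#'   singletons).
#' @param linkage Agglomeration rule; only `"complete"` is offered.
#' @return Integer vector of cluster labels in 1..k, named with the rownames
#'   of `M` when present.
#' @export
final_clusters <- function(M, k, linkage = "complete") {
  n <- nrow(M)
  if (k > n) stop("`k` exceeds the number of items", call. = FALSE)
  if (linkage != "complete")
    stop("only complete linkage is supported", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(1 - M), method = "complete")
  raw <- stats::cutree(hc, k = k)
  out <- renumber_labels(raw)
  names(out) <- rownames(M)
  out
}

# Renumber labels 1..k by decreasing size; ties by smallest member index.
renumber_labels <- function(raw) {
  lev <- sort(unique(raw))
  sizes <- vapply(lev, function(l) sum(raw == l), integer(1))
  firsts <- vapply(lev, function(l) min(which(raw == l)), integer(1))
  ord <- order(-sizes, firsts)
  map <- integer(max(lev))
  map[lev[ord]] <- seq_along(lev)
  map[raw]
}

#' Select the number of clusters from PAC values
#'
#' Returns the smallest k whose PAC is within `tolerance` of the minimum PAC,
#' encoding a preference for fewer clusters when PAC differences are minor.
#'
#' @param pac_by_k Named numeric vector of PAC values (names = k).
#' @param tolerance Non-negative slack on the PAC minimum.
#' @return The selected k (integer).
#' @export
select_k <- function(pac_by_k, tolerance = 0.01) {
  if (length(pac_by_k) == 0) stop("`pac_by_k` is empty", call. = FALSE)
  if (is.null(names(pac_by_k)))
    stop("`pac_by_k` must be named by k", call. = FALSE)
  ks <- as.integer(names(pac_by_k))
  ord <- order(ks)
  ks <- ks[ord]; p <- unname(pac_by_k[ord])
  ks[which(p <= min(p) + tolerance)[1]]
}

#' Consensus clustering of samples with PAC-based model selection
#'
#' Fits the full consensus-clustering procedure: for each k in
#' `[k_min, k_max]`, repeatedly subsamples items (samples) and features
#' (genes), partitions each subsample by k-medoids, accumulates the per-k
#' consensus matrix, and summarizes it by its CDF and PAC. The number of
#' clusters is the smallest k whose PAC is within `k_tolerance` of the
#' minimum, and final labels come from complete-linkage clustering of
#' `1 - M_k`.
#'
#' The input matrix is used as given; callers working from RPKM-like units
#' should pass `log2p1(expr)` restricted to the selected features (Euclidean
#' distance on the raw scale is dominated by a few highly expressed genes).
#'
#' @param x Numeric matrix, features x items (genes x samples), or an
#'   [expr_matrix()] whose values are used as-is.
#' @param ... Passed to [consensus_params()].
#' @param params A [consensus_params()]; overrides `...` when supplied.
#' @return An object of class `consensus_fit` with components `consensus`
#'   (per-k consensus matrices), `pac` (named vector), `cdf` (per-k
#'   data.frames), `labels_by_k`, `selected_k`, `labels` (labels at the
#'   selected k, named by item), `n_items`, and `params`.
#' @examples
#' x <- cbind(matrix(rnorm(40, 0), 4, 10), matrix(rnorm(40, 4), 4, 10))
#' colnames(x) <- paste0("s", 1:20); rownames(x) <- paste0("g", 1:4)
#' fit <- consensus_cluster(x, k_min = 2, k_max = 3, n_resamples = 50,
#'                          seed = 1)
#' fit$selected_k
#' @export
consensus_cluster <- function(x, ..., params = NULL) {
  if (is.null(params)) params <- consensus_params(...)
  stopifnot(inherits(params, "consensus_params"))
  v <- expr_values(x)
  n <- ncol(v)
  if (params$k_max > n)
    stop("k_max exceeds the number of items", call. = FALSE)
  if (!identical(params$inner_linkage, "complete"))
    message("note: inner_linkage is ignored (base clusterer is k-medoids)")
  ks <- params$k_min:params$k_max
  consensus <- list(); cdfs <- list(); labels_by_k <- list()
  pac_by_k <- stats::setNames(numeric(length(ks)), ks)
  for (k in ks) {
    runs <- run_resamples(v, k, params)
    M <- consensus_matrix(runs, n)
    rownames(M) <- colnames(M) <- colnames(v)
    key <- as.character(k)
    consensus[[key]] <- M
    cdfs[[key]] <- consensus_cdf(M)
    pac_by_k[key] <- pac(M, params$pac_lower, params$pac_upper)
    labels_by_k[[key]] <- final_clusters(M, k)
  }
  sel <- select_k(pac_by_k, params$k_tolerance)
  structure(list(consensus = consensus, pac = pac_by_k, cdf = cdfs,
                 labels_by_k = labels_by_k, selected_k = sel,
                 labels = labels_by_k[[as.character(sel)]],
                 n_items = n, params = params, call = match.call()),
            class = "consensus_fit")
}

#' @export
print.consensus_fit <- function(x, ...) {
  cat("Consensus clustering fit\n")
  cat(sprintf("  items: %d, k range: %d..%d, resamples per k: %d\n",
              x$n_items, x$params$k_min, x$params$k_max,
              x$params$n_resamples))
  cat("  PAC by k: ",
      paste(sprintf("k=%s: %.3f", names(x$pac), x$pac), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("  selected k = %d (tolerance %.3g)\n",
              x$selected_k, x$params$k_tolerance))
  cat("  cluster sizes: ",
      paste(tabulate(x$labels, x$selected_k), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.consensus_fit <- function(object, ...) {
  s <- data.frame(k = as.integer(names(object$pac)),
                  pac = unname(object$pac))
  s$selected <- s$k == object$selected_k
  s$mean_consensus <- vapply(object$consensus,
                             function(M) mean(M[lower.tri(M)]), numeric(1))
  structure(list(table = s, selected_k = object$selected_k,
                 sizes = tabulate(object$labels, object$selected_k)),
            class = "summary.consensus_fit")
}

#' @export
print.summary.consensus_fit <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("selected k = %d; sizes: %s\n", x$selected_k,
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Plot PAC and consensus CDF curves
#'
#' Left panel: PAC versus k with the selected k marked. Right panel: per-k
#' empirical CDFs of consensus values.
#'
#' @param x A `consensus_fit`.
#' @param ... Ignored.
#' @return Invisibly, `x`.
#' @export
plot.consensus_fit <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  ks <- as.integer(names(x$pac))
  graphics::plot(ks, x$pac, type = "b", pch = 19, xlab = "k", ylab = "PAC",
                 main = "PAC by k")
  graphics::abline(v = x$selected_k, lty = 2)
  graphics::plot(NA, xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "consensus value", ylab = "CDF",
                 main = "Consensus CDF")
  for (i in seq_along(x$cdf))
    graphics::lines(x$cdf[[i]]$threshold, x$cdf[[i]]$cdf, col = i)
  graphics::legend("bottomright", legend = paste0("k=", names(x$cdf)),
                   col = seq_along(x$cdf), lty = 1, cex = 0.8)
  invisible(x)
}
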