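#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Conditional on the margins, the two-sided p-value is the total
#' hypergeometric probability of all tables whose probability does not exceed
#' that of the observed table (probability-mass rule, with relative tolerance
#' 1e-12 on the comparison). The odds ratio is the sample cross-product
#' `ad/bc`: `Inf` when `bc = 0` and `ad > 0`, and `NA` (not applicable) when
#' both products are 0.
#'
#' @param table 2x2 matrix of non-negative integer counts, positive total.
#' @param alpha Significance level for the direction call.
#' @return A list of class `contingency_result` with `table`, `statistic`
#'   (the observed table probability), `df` (`NA` for an exact test),
#'   `p_value`, `odds_ratio`, and `direction` (`"enriched"` if OR > 1 and
#'   p < alpha, `"depleted"` if OR < 1 and p < alpha, else `"none"`).
#' @examples
#' fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2))$p_value  # 34/70
#' @export
fisher_exact_2x2 <- function(table, alpha = 0.05) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2, 2)))
    stop("`table` must be 2x2", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab)) || any(!is.finite(tab)))
    stop("`table` must hold non-negative integer counts", call. = FALSE)
  if (sum(tab) == 0) stop("`table` has zero grand total", call. = FALSE)
  a <- tab[1, 1]; b <- tab[1, 2]; c_ <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b            # row-1 total
  n <- c_ + d           # row-2 total
  kk <- a + c_          # column-1 total
  support <- max(0, kk - n):min(kk, m)
  probs <- stats::dhyper(support, m, n, kk)
  p_obs <- stats::dhyper(a, m, n, kk)
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
  or <- if (a * d == 0 && b * c_ == 0) NA_real_
  else if (b * c_ == 0) Inf
  else (a * d) / (b * c_)
  direction <- "none"
  if (!is.na(or) && p < alpha) {
    if (or > 1) direction <- "enriched"
    if (or < 1) direction <- "depleted"
  }
  structure(list(table = tab, statistic = p_obs, df = NA_integer_,
                 p_value = p, odds_ratio = or, direction = direction,
                 method = "fisher_exact"),
            class = "contingency_result")
}

#' Pearson chi-square test for an r x c contingency table
#'
#' Uncorrected Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the margins and an upper-tail chi-square p-value on
#' `(r - 1)(c - 1)` degrees of freedom. No continuity correction.
#'
#' @param table r x c matrix of non-negative counts; every row and column
#'   margin must be positive (all expected counts > 0).
#' @param alpha Significance level used only to flag `direction` for 2x2
#'   input (based on the cross-product odds ratio); larger tables get
#'   `"none"`.
#' @return A `contingency_result` (see [fisher_exact_2x2()]); `odds_ratio`
#'   is `NA` unless the table is 2x2.
#' @export
chi_square <- function(table, alpha = 0.05) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(!is.finite(tab)))
    stop("`table` must hold non-negative counts", call. = FALSE)
  if (nrow(tab) < 2 || ncol(tab) < 2)
    stop("`table` must be at least 2x2", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row/column margin gives expected count 0", call. = FALSE)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  or <- NA_real_
  direction <- "none"
  if (all(dim(tab) == c(2, 2))) {
    or <- if (tab[1, 1] * tab[2, 2] == 0 && tab[1, 2] * tab[2, 1] == 0)
      NA_real_
    else if (tab[1, 2] * tab[2, 1] == 0) Inf
    else (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
    if (!is.na(or) && ct$p.value < alpha)
      direction <- if (or > 1) "enriched" else if (or < 1) "depleted" else "none"
  }
  structure(list(table = tab, statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p_value = ct$p.value,
                 odds_ratio = or, direction = direction,
                 method = "chi_square"),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g", x$method, x$statistic))
  if (!is.na(x$df)) cat(sprintf(", df = %d", x$df))
  cat(sprintf(", p = %.4g", x$p_value))
  if (!is.null(x$odds_ratio) && !is.na(x$odds_ratio))
    cat(sprintf(", OR = %.4g", x$odds_ratio))
  cat(sprintf(" [%s]\n", x$direction))
  invisible(x)
}

#' Associate cluster membership with a categorical feature
#'
#' Global test: chi-square on the k x L clusters-by-levels table (Fisher's
#' exact test when the table is 2x2). Per-cluster tests: for every
#' (cluster, level) pair, a Fisher 2x2 test of in-cluster vs out-of-cluster
#' against level vs rest, with a direction call at `alpha` and
#' Benjamini-Hochberg adjusted p-values across all per-cluster tests of the
#' feature. Samples with a missing feature value are dropped (count
#' reported).
#'
#' @param labels Integer cluster labels, named by sample id.
#' @param feature Categorical vector aligned with `labels` (same order or
#'   names).
#' @param alpha Significance level for direction calls.
#' @return A list of class `cluster_association` with `global`
#'   (a `contingency_result`), `per_cluster` (data.frame: cluster, level,
#'   table cells, odds_ratio, p_value, p_adjusted, direction), `table`
#'   (k x L counts), and `n_dropped`.
#' @export
cluster_feature_association <- function(labels, feature, alpha = 0.05) {
  if (!is.null(names(labels)) && !is.null(names(feature)))
    feature <- feature[names(labels)]
  if (length(feature) != length(labels))
    stop("`labels` and `feature` must align on the same samples", call. = FALSE)
  keep <- !is.na(feature) & !is.na(labels)
  n_dropped <- sum(!keep)
  labels <- labels[keep]; feature <- as.character(feature[keep])
  if (length(unique(labels)) < 2 || length(unique(feature)) < 2)
    stop("need >= 2 clusters and >= 2 feature levels after dropping missing",
         call. = FALSE)
  tab <- table(cluster = labels, level = feature)
  global <- if (all(dim(tab) == c(2, 2))) fisher_exact_2x2(unclass(tab), alpha)
  else chi_square(unclass(tab), alpha)
  rows <- list()
  for (cl in rownames(tab)) {
    for (lev in colnames(tab)) {
      a <- sum(labels == cl & feature == lev)
      b <- sum(labels == cl & feature != lev)
      c_ <- sum(labels != cl & feature == lev)
      d <- sum(labels != cl & feature != lev)
      ft <- fisher_exact_2x2(matrix(c(a, c_, b, d), 2), alpha)
      rows[[paste(cl, lev)]] <- data.frame(
        cluster = cl, level = lev, in_with = a, in_without = b,
        out_with = c_, out_without = d, odds_ratio = ft$odds_ratio,
        p_value = ft$p_value, stringsAsFactors = FALSE)
    }
  }
  per <- do.call(rbind, rows)
  rownames(per) <- NULL
  per$p_adjusted <- bh_adjust(per$p_value)
  per$direction <- ifelse(
    is.na(per$odds_ratio) | per$p_value >= alpha, "none",
    ifelse(per$odds_ratio > 1, "enriched",
           ifelse(per$odds_ratio < 1, "depleted", "none")))
  structure(list(global = global, per_cluster = per, table = tab,
                 n_dropped = n_dropped, alpha = alpha),
            class = "cluster_association")
}

#' @export
print.cluster_association <- function(x, ...) {
  cat("Cluster-feature association (", nrow(x$table), " clusters x ",
      ncol(x$table), " levels; ", x$n_dropped, " sample(s) dropped)\n",
      sep = "")
  cat("Global: "); print(x$global)
  sig <- x$per_cluster[x$per_cluster$direction != "none", , drop = FALSE]
  if (nrow(sig)) {
    cat("Per-cluster calls at alpha =", x$alpha, ":\n")
    print(sig[, c("cluster", "level", "odds_ratio", "p_value", "p_adjusted",
                  "direction")], row.names = FALSE)
  } else cat("No per-cluster calls at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Welch's unequal-variance t-test
#'
#' Two-sided Welch statistic with Welch-Satterthwaite degrees of freedom.
#'
#' @param group_a,group_b Numeric vectors with >= 2 non-missing values each.
#' @return A list with `t`, `df`, and `p_value`.
#' @export
welch_t <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs >= 2 non-missing values", call. = FALSE)
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; values are clipped to `[0, 1]`
#' and are monotone non-decreasing in the sorted order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values, method = c("BH", "bonferroni")) {
  method <- match.arg(method)
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = method)
}
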