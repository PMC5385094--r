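#' Keep genes with detectable expression
#'
#' A gene is detectable when its arithmetic mean expression (raw RPKM-like
#' units) across all samples is at least `threshold`. The conventional cutoff
#' for lncRNA RPKM data is 0.3. Gene order is preserved.
#'
#' @param expr An [expr_matrix()] or numeric matrix.
#' @param threshold Non-negative mean-expression cutoff.
#' @return Object of the same type as `expr`, restricted to detectable genes.
#' @export
filter_detectable <- function(expr, threshold = 0.3) {
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    stop("`threshold` must be a single non-negative number", call. = FALSE)
  v <- expr_values(expr)
  keep <- rowMeans(v) >= threshold
  if (inherits(expr, "expr_matrix")) expr_subset(expr, genes = which(keep))
  else v[keep, , drop = FALSE]
}

#' Select the most variable genes
#'
#' Ranks genes by a variability statistic computed on the log2(RPKM + 1)
#' scale and keeps the top `k`. Ties are broken by gene-id lexicographic
#' order (C locale), so runs are reproducible. Raw-scale variability is
#' available for comparison via `log_scale = FALSE`.
#'
#' @param expr An [expr_matrix()] or numeric matrix.
#' @param k Number of genes to keep; must not exceed the gene count. The
#'   convention for lncRNA-based tumor clustering is the top 500.
#' @param measure One of `"variance"`, `"sd"`, `"mad"`.
#' @param log_scale Compute variability on log2(x + 1) (default) or raw scale.
#' @return Object of the same type as `expr` with the `k` selected genes, in
#'   their original row order.
#' @export
top_variable <- function(expr, k = 500,
                         measure = c("variance", "sd", "mad"),
                         log_scale = TRUE) {
  measure <- match.arg(measure)
  v <- expr_values(expr)
  if (!is.numeric(k) || length(k) != 1 || k < 1 || k > nrow(v))
    stop("`k` must be a single integer in [1, number of genes]", call. = FALSE)
  x <- if (log_scale) log2(v + 1) else v
  stat <- switch(measure,
                 variance = apply(x, 1, stats::var),
                 sd = apply(x, 1, stats::sd),
                 mad = apply(x, 1, stats::mad))
  ord <- order(-stat, rownames(v), method = "radix")
  keep <- sort(ord[seq_len(k)])
  if (inherits(expr, "expr_matrix")) expr_subset(expr, genes = keep)
  else v[keep, , drop = FALSE]
}
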