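#' Hypergeometric gene-set over-representation
#'
#' One-sided upper-tail hypergeometric test per gene set: the probability of
#' observing at least the observed overlap between the query and the set,
#' drawing `|query|` genes from the universe. Sets are intersected with the
#' universe first; sets with empty intersection are skipped. Rows are sorted
#' by ascending p; significance at `alpha` is called on the raw p (the BH
#' column is informational).
#'
#' @param query Character vector of gene ids; must be a subset of `universe`.
#' @param sets A `gene_set_collection` (see [read_gmt()]) or named list of
#'   character vectors.
#' @param universe Character vector: the measured gene background.
#' @param alpha Raw-p significance threshold.
#' @return A data.frame of class `enrichment_table` with columns `set`,
#'   `overlap`, `query_size`, `set_size`, `universe_size`, `p_value`,
#'   `p_adjusted`, `significant`, `genes` (comma-separated overlap ids).
#' @examples
#' universe <- paste0("g", 1:20)
#' sets <- list(S1 = paste0("g", 1:5))
#' hypergeom_enrich(paste0("g", c(1, 2, 3, 10, 11)), sets, universe)
#' @export
hypergeom_enrich <- function(query, sets, universe, alpha = 0.05) {
  query <- unique(query)
  universe <- unique(universe)
  outside <- setdiff(query, universe)
  if (length(outside) > 0)
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "),
         if (length(outside) > 5) ", ..." else "", call. = FALSE)
  n_u <- length(universe)
  n_q <- length(query)
  rows <- list()
  for (nm in names(sets)) {
    s <- intersect(unique(sets[[nm]]), universe)
    if (length(s) == 0) next
    ov <- intersect(query, s)
    # P(X >= |ov|), X ~ Hypergeometric(set size, universe - set, query size)
    p <- stats::phyper(length(ov) - 1, length(s), n_u - length(s), n_q,
                       lower.tail = FALSE)
    rows[[nm]] <- data.frame(
      set = nm, overlap = length(ov), query_size = n_q,
      set_size = length(s), universe_size = n_u, p_value = p,
      genes = paste(ov, collapse = ","), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(set = character(0), overlap = integer(0),
                  query_size = integer(0), set_size = integer(0),
                  universe_size = integer(0), p_value = numeric(0),
                  genes = character(0), stringsAsFactors = FALSE)
  out$p_adjusted <- bh_adjust(out$p_value)
  out$significant <- out$p_value < alpha
  out <- out[order(out$p_value, out$set, method = "radix"),
             c("set", "overlap", "query_size", "set_size", "universe_size",
               "p_value", "p_adjusted", "significant", "genes")]
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}

#' Enrichment of correlated PCG lists for every cluster
#'
#' Runs [hypergeom_enrich()] separately on each cluster's directly correlated
#' (up) and inversely correlated (down) PCG list from a [gba_analysis()]
#' result. Clusters with an empty list get an empty table.
#'
#' @param gba A `gba_result`.
#' @param sets Gene sets (see [hypergeom_enrich()]).
#' @param universe Background gene ids; conventionally all PCGs measured in
#'   the expression matrix.
#' @param alpha Raw-p significance threshold.
#' @return Nested list: `result[[cluster]][[direction]]` is an
#'   `enrichment_table`, directions `"up"` and `"down"`.
#' @export
enrich_all_clusters <- function(gba, sets, universe, alpha = 0.05) {
  stopifnot(inherits(gba, "gba_result"))
  out <- list()
  for (nm in names(gba)) {
    el <- gba[[nm]]
    res <- list()
    for (dir in c("up", "down")) {
      lst <- el[[paste0(dir, "_pcgs")]]
      genes <- if (is.null(lst)) character(0) else lst$gene
      genes <- intersect(genes, universe)
      res[[dir]] <- if (length(genes) == 0)
        hypergeom_enrich(character(0), sets, universe, alpha)
      else hypergeom_enrich(genes, sets, universe, alpha)
    }
    out[[nm]] <- res
  }
  out
}
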