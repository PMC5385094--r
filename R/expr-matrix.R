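#' Expression matrix with gene and sample annotations
#'
#' Container for a genes x samples matrix of non-negative expression values
#' (RPKM-like units), with a per-gene class tag (`"lncRNA"` or `"PCG"`) and a
#' per-sample role tag (`"tumor"` or `"normal"`). Gene and sample identifiers
#' are carried as the dimnames of `values` and must be unique.
#'
#' @param values Numeric matrix, genes in rows, samples in columns. Must have
#'   unique, non-empty rownames (gene ids) and colnames (sample ids); all
#'   entries finite and >= 0.
#' @param gene_class Character vector, one of `"lncRNA"`, `"PCG"` per gene.
#' @param sample_role Character vector, one of `"tumor"`, `"normal"` per
#'   sample. Defaults to all-tumor.
#'
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `gene_class`, `sample_role`.
#' @examples
#' m <- matrix(abs(rnorm(6)), 2, 3,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' em <- expr_matrix(m, gene_class = c("lncRNA", "PCG"))
#' dim(em)
#' @export
expr_matrix <- function(values, gene_class, sample_role = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(gid))
    stop("duplicate gene identifier(s): ",
         paste(unique(gid[duplicated(gid)]), collapse = ", "), call. = FALSE)
  if (anyDuplicated(sid))
    stop("duplicate sample identifier(s): ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must be finite (no NA/NaN/Inf)", call. = FALSE)
  if (any(values < 0))
    stop("expression values must be non-negative", call. = FALSE)
  if (missing(gene_class)) gene_class <- rep("lncRNA", nrow(values))
  gene_class <- as.character(gene_class)
  if (length(gene_class) != nrow(values))
    stop("`gene_class` length must match the number of genes", call. = FALSE)
  if (!all(gene_class %in% c("lncRNA", "PCG")))
    stop("`gene_class` entries must be 'lncRNA' or 'PCG'", call. = FALSE)
  if (is.null(sample_role)) sample_role <- rep("tumor", ncol(values))
  sample_role <- as.character(sample_role)
  if (length(sample_role) != ncol(values))
    stop("`sample_role` length must match the number of samples", call. = FALSE)
  if (!all(sample_role %in% c("tumor", "normal")))
    stop("`sample_role` entries must be 'tumor' or 'normal'", call. = FALSE)
  structure(list(values = values, gene_class = gene_class,
                 sample_role = sample_role),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%d lncRNA, %d PCG; %d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$gene_class == "lncRNA"), sum(x$gene_class == "PCG"),
              sum(x$sample_role == "tumor"), sum(x$sample_role == "normal")))
  invisible(x)
}

#' Subset an expression matrix by gene and/or sample
#'
#' Annotation vectors are subset in step with the matrix.
#'
#' @param x An `expr_matrix`.
#' @param genes,samples Index vectors (integer, logical, or names); `NULL`
#'   keeps everything.
#' @return An `expr_matrix`.
#' @export
expr_subset <- function(x, genes = NULL, samples = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  gi <- if (is.null(genes)) seq_len(nrow(x$values)) else genes
  si <- if (is.null(samples)) seq_len(ncol(x$values)) else samples
  v <- x$values[gi, si, drop = FALSE]
  gidx <- match(rownames(v), rownames(x$values))
  sidx <- match(colnames(v), colnames(x$values))
  expr_matrix(v, x$gene_class[gidx], x$sample_role[sidx])
}

# Accept either an expr_matrix or a bare numeric matrix.
expr_values <- function(x) {
  if (inherits(x, "expr_matrix")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else stop("expected an `expr_matrix` or a numeric matrix", call. = FALSE)
}

#' Log2(x + 1) transform of an expression matrix
#'
#' The scale on which all correlation, clustering and t-test stages operate.
#'
#' @param x An `expr_matrix` or numeric matrix of non-negative values.
#' @return A numeric matrix of the same shape.
#' @export
log2p1 <- function(x) log2(expr_values(x) + 1)

# Run `expr` with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
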