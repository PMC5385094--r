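#' Read an expression matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample identifiers, the
#' first column holding gene identifiers, and optionally a gene-class column
#' (values `lncRNA` / `PCG`). All remaining cells must be finite non-negative
#' numbers; missing cells are rejected.
#'
#' @param path Path to the TSV file.
#' @param gene_class_column Name of the column holding the gene class tag, or
#'   `NULL` if absent (all genes are then tagged `lncRNA`).
#' @param sample_role_map Optional named character vector mapping sample id to
#'   `"tumor"` / `"normal"`; unmapped samples default to `"tumor"`.
#' @return An [expr_matrix()].
#' @seealso [write_expression()]
#' @export
read_expression <- function(path, gene_class_column = "gene_class",
                            sample_role_map = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("expression file '", path, "': need a gene id column plus >=1 sample",
         call. = FALSE)
  gene_ids <- as.character(df[[1]])
  if (anyDuplicated(gene_ids))
    stop("expression file '", path, "': duplicated gene id(s): ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  df <- df[, -1, drop = FALSE]
  if (!is.null(gene_class_column) && gene_class_column %in% names(df)) {
    gene_class <- as.character(df[[gene_class_column]])
    df <- df[, setdiff(names(df), gene_class_column), drop = FALSE]
  } else gene_class <- rep("lncRNA", length(gene_ids))
  vals <- as.matrix(df)
  if (!is.numeric(vals))
    stop("expression file '", path, "': non-numeric cell(s) in column(s): ",
         paste(names(df)[!vapply(df, is.numeric, logical(1))], collapse = ", "),
         call. = FALSE)
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop("expression file '", path, "': missing value at gene '",
         gene_ids[bad[1]], "', sample '", colnames(vals)[bad[2]], "'",
         call. = FALSE)
  }
  if (any(vals < 0)) {
    bad <- which(vals < 0, arr.ind = TRUE)[1, ]
    stop("expression file '", path, "': negative value at gene '",
         gene_ids[bad[1]], "', sample '", colnames(vals)[bad[2]], "'",
         call. = FALSE)
  }
  rownames(vals) <- gene_ids
  role <- rep("tumor", ncol(vals))
  if (!is.null(sample_role_map)) {
    hit <- colnames(vals) %in% names(sample_role_map)
    role[hit] <- unname(sample_role_map[colnames(vals)[hit]])
  }
  expr_matrix(vals, gene_class, role)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression()] up to 6-significant-digit numeric text
#' round-trip. The gene class is written as a `gene_class` column after the
#' gene id.
#'
#' @param expr An [expr_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  stopifnot(inherits(expr, "expr_matrix"))
  df <- data.frame(gene_id = rownames(expr$values),
                   gene_class = expr$gene_class,
                   signif(expr$values, 6),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. Members are deduplicated preserving
#' first-occurrence order.
#'
#' @param path Path to the GMT file.
#' @return A named list of class `gene_set_collection`; each element is a
#'   character vector of member ids with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("GMT file '", path, "' line ", i,
           ": expected >= 3 tab-separated fields", call. = FALSE)
    nm <- f[1]
    if (nm %in% names(sets))
      stop("GMT file '", path, "' line ", i, ": duplicated set name '", nm,
           "'", call. = FALSE)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop("GMT file '", path, "' line ", i, ": set '", nm, "' is empty",
           call. = FALSE)
    attr(members, "description") <- f[2]
    sets[[nm]] <- members
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param sets A `gene_set_collection` or named list of character vectors.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical annotation table
#'
#' One row per sample, typed by a schema. Unparseable cells under the declared
#' type become missing and are counted (see the `n_unparseable` attribute of
#' the result); structural problems (missing sample-id column, negative
#' times) are errors.
#'
#' @param path Path to the TSV file.
#' @param schema Named character vector mapping column name to one of
#'   `"categorical"`, `"continuous"`, `"time"`, `"event"`. Columns not in the
#'   schema are kept as-is.
#' @param id_column Name of the sample-id column (default `"sample_id"`).
#' @return A data.frame with unique `sample_id`, typed columns, and attribute
#'   `n_unparseable` (named integer vector of coerced-to-missing counts).
#' @export
read_clinical <- function(path, schema = NULL, id_column = "sample_id") {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"), colClasses = "character")
  if (!id_column %in% names(df))
    stop("clinical file '", path, "': sample id column '", id_column,
         "' absent", call. = FALSE)
  if (anyDuplicated(df[[id_column]]))
    stop("clinical file '", path, "': duplicated sample id(s)", call. = FALSE)
  names(df)[names(df) == id_column] <- "sample_id"
  bad_counts <- integer(0)
  if (!is.null(schema)) {
    for (col in names(schema)) {
      if (!col %in% names(df))
        stop("clinical file '", path, "': schema column '", col, "' absent",
             call. = FALSE)
      kind <- schema[[col]]
      raw <- df[[col]]
      if (kind == "categorical") next
      num <- suppressWarnings(as.numeric(raw))
      coerced <- sum(!is.na(raw) & is.na(num))
      if (kind == "event") {
        ok <- is.na(num) | num %in% c(0, 1)
        coerced <- coerced + sum(!ok, na.rm = TRUE)
        num[!ok] <- NA
        num <- as.integer(num)
      }
      if (kind == "time" && any(num < 0, na.rm = TRUE)) {
        i <- which(num < 0)[1]
        stop("clinical file '", path, "' row ", i, ", column '", col,
             "': negative time", call. = FALSE)
      }
      if (coerced > 0) {
        warning("clinical file '", path, "': ", coerced,
                " unparseable cell(s) in column '", col,
                "' set to missing", call. = FALSE)
        bad_counts[col] <- coerced
      }
      df[[col]] <- num
    }
  }
  attr(df, "n_unparseable") <- bad_counts
  df
}
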