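#' Construct an expression matrix with sample group labels
#'
#' The container used throughout the package: a non-negative gene-by-sample
#' numeric matrix (expression units such as FPKM) together with a
#' tumor/normal label for every sample. Gene identifiers may be duplicated
#' before [collapse_duplicates()] has been applied (multiple probes per
#' gene); sample identifiers must be unique.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   rownames (gene or probe identifiers) and colnames (sample identifiers).
#' @param group character vector of per-sample labels in `c("tumor",
#'   "normal")`; either unnamed in column order or named by sample id. A
#'   single value is recycled.
#' @return an object of class `expression_matrix`: a list with elements
#'   `values` (the matrix) and `group` (named character vector).
#' @export
expression_matrix <- function(values, group = "tumor") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("`values` must have rownames (genes) and colnames (samples)")
  }
  if (anyDuplicated(colnames(values))) {
    stopf("duplicated sample identifiers: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]),
                collapse = ", "))
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stopf("expression values must be finite and non-negative")
  }
  ns <- ncol(values)
  if (length(group) == 1L) group <- rep(group, ns)
  if (!is.null(names(group))) {
    if (!all(colnames(values) %in% names(group))) {
      stopf("`group` is missing labels for some samples")
    }
    group <- group[colnames(values)]
  }
  if (length(group) != ns) {
    stopf("`group` must label every sample (%d labels for %d samples)",
          length(group), ns)
  }
  group <- as.character(group)
  if (!all(group %in% c("tumor", "normal"))) {
    stopf("group labels must be 'tumor' or 'normal'")
  }
  names(group) <- colnames(values)
  structure(list(values = values, group = group),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples (%d tumor, %d normal)\n",
              nrow(x$values), ncol(x$values),
              sum(x$group == "tumor"), sum(x$group == "normal")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by gene and/or sample
#'
#' @param x an `expression_matrix`.
#' @param genes,samples character or integer indices; `NULL` keeps all.
#' @return an `expression_matrix`.
#' @export
subset_expression <- function(x, genes = NULL, samples = NULL) {
  v <- x$values
  if (!is.null(genes)) v <- v[genes, , drop = FALSE]
  if (!is.null(samples)) v <- v[, samples, drop = FALSE]
  expression_matrix(v, x$group[colnames(v)])
}

.read_delim_auto <- function(path, sep = NULL) {
  sep <- sep %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) parse_error(sprintf("'%s': need a header and at least one data row", path))
  fields <- strsplit(lines, sep, fixed = TRUE)
  n_head <- length(fields[[1L]])
  widths <- lengths(fields[-1L])
  # header may omit the corner cell for the id column
  ok <- widths == n_head | widths == n_head + 1L
  if (!all(widths == widths[1L]) || !any(ok)) {
    bad <- which(widths != widths[1L])[1L] + 1L
    parse_error(sprintf("'%s': ragged row %d (%d fields, expected %d)",
                        path, bad, widths[bad - 1L], widths[1L]))
  }
  list(header = fields[[1L]], rows = fields[-1L], n_head = n_head)
}

#' Read a delimited expression matrix
#'
#' Reads a TSV or CSV file (dialect chosen from the file extension, or via
#' `sep`) with one header row of identifiers and one identifier column.
#' Values must parse as finite non-negative numbers; offending cells are
#' reported by row and column. Duplicate gene identifiers (multiple probes)
#' are kept as-is — collapse them with [collapse_duplicates()].
#'
#' @param path file path.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param group per-sample tumor/normal labels, as in [expression_matrix()].
#' @param sep field separator; `NULL` auto-detects from the extension.
#' @return an `expression_matrix`.
#' @export
read_expression_matrix <- function(path,
                                   orientation = c("genes_in_rows", "samples_in_rows"),
                                   group = "tumor", sep = NULL) {
  orientation <- match.arg(orientation)
  parsed <- .read_delim_auto(path, sep)
  header <- parsed$header
  rows <- parsed$rows
  w <- lengths(rows)[1L]
  col_ids <- if (w == parsed$n_head + 1L) header else header[-1L]
  row_ids <- vapply(rows, `[[`, "", 1L)
  cells <- lapply(rows, function(r) r[-1L])
  num <- suppressWarnings(lapply(cells, as.numeric))
  for (i in seq_along(num)) {
    bad <- which(is.na(num[[i]]) | !is.finite(num[[i]]))
    if (length(bad)) {
      parse_error(sprintf("'%s': non-numeric value '%s' at row '%s', column '%s'",
                          path, cells[[i]][bad[1L]], row_ids[i], col_ids[bad[1L]]))
    }
    bad <- which(num[[i]] < 0)
    if (length(bad)) {
      parse_error(sprintf("'%s': negative value at row '%s', column '%s'",
                          path, row_ids[i], col_ids[bad[1L]]))
    }
  }
  m <- do.call(rbind, num)
  rownames(m) <- row_ids
  colnames(m) <- col_ids
  if (orientation == "samples_in_rows") m <- t(m)
  expression_matrix(m, group)
}

#' Write an expression matrix to delimited text
#'
#' Genes in rows, header of sample identifiers; TSV unless the path ends in
#' `.csv`. Values are written with full precision so that a write/read
#' round trip reproduces them exactly.
#'
#' @param x an `expression_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- x$values
  header <- paste(c("gene", colnames(m)), collapse = sep)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], digits = 17, trim = TRUE,
                                   scientific = FALSE)), collapse = sep)
  }, "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Collapse duplicate probes and multi-sample patients by averaging
#'
#' Multiple probes mapping to one gene are replaced by their arithmetic mean
#' per sample; multiple samples from one patient are replaced by their
#' arithmetic mean per gene. Output rows and columns are in lexicographic
#' identifier order, making the operation deterministic and idempotent.
#'
#' @param m an `expression_matrix`.
#' @param probe_to_gene optional named character vector mapping probe (row)
#'   identifiers to gene symbols; rows not named in the map keep their own
#'   identifier. Map entries referencing unknown probes are an error.
#' @param sample_to_patient optional named character vector mapping sample
#'   (column) identifiers to patient identifiers, same conventions. Samples
#'   collapsing together must share a tumor/normal label.
#' @return an `expression_matrix` with unique gene and sample identifiers.
#' @export
collapse_duplicates <- function(m, probe_to_gene = NULL, sample_to_patient = NULL) {
  v <- m$values
  gene_ids <- rownames(v)
  if (!is.null(probe_to_gene)) {
    unknown <- setdiff(names(probe_to_gene), gene_ids)
    if (length(unknown)) {
      stopf("probe_to_gene references unknown probes: %s",
            paste(unknown, collapse = ", "))
    }
    hit <- match(gene_ids, names(probe_to_gene))
    gene_ids <- ifelse(is.na(hit), gene_ids, unname(probe_to_gene[hit]))
  }
  v <- rowsum(v, group = gene_ids) / as.vector(table(gene_ids)[sort(unique(gene_ids))])
  v <- v[order(rownames(v)), , drop = FALSE]

  sample_ids <- colnames(v)
  if (!is.null(sample_to_patient)) {
    unknown <- setdiff(names(sample_to_patient), sample_ids)
    if (length(unknown)) {
      stopf("sample_to_patient references unknown samples: %s",
            paste(unknown, collapse = ", "))
    }
    hit <- match(sample_ids, names(sample_to_patient))
    sample_ids <- ifelse(is.na(hit), sample_ids, unname(sample_to_patient[hit]))
  }
  grp <- m$group[colnames(v)]
  mixed <- tapply(grp, sample_ids, function(g) length(unique(g)) > 1L)
  if (any(mixed)) {
    stopf("samples with different tumor/normal labels collapse to patient(s): %s",
          paste(names(mixed)[mixed], collapse = ", "))
  }
  vt <- rowsum(t(v), group = sample_ids) /
    as.vector(table(sample_ids)[sort(unique(sample_ids))])
  v <- t(vt)
  v <- v[, order(colnames(v)), drop = FALSE]
  new_group <- tapply(grp, sample_ids, `[[`, 1L)[colnames(v)]
  expression_matrix(v, as.character(new_group))
}
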