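#' Read a gene-expression matrix
#'
#' Reads a genes-by-samples matrix of log-scale intensities from plain TSV
#' (first column gene identifiers, header row sample identifiers) or GCT 1.2
#' (the `#1.2` version line, a dimensions line, then `Name`/`Description`
#' columns before the samples). Values are assumed already log-transformed
#' and normalised; no preprocessing is applied. Empty cells and `NA` become
#' explicit missing values; anything else non-numeric is an error that names
#' the offending row and column.
#'
#' @param path Path to the file.
#' @param format `"tsv"` or `"gct"`.
#' @return A numeric matrix, genes in rows (rownames = gene ids), samples in
#'   columns (colnames = sample ids), row and column order as in the file.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' write_expression(m, f)
#' all.equal(read_expression(f), m)
#' @export
read_expression <- function(path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  if (format == "gct") {
    if (length(lines) < 3L || !startsWith(trimws(lines[[1L]]), "#1.2")) {
      abort("not a GCT 1.2 file: expected '#1.2' on the first line")
    }
    dims <- suppressWarnings(as.integer(strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]][1:2]))
    if (any(is.na(dims))) abort("GCT dimensions line is not two integers")
    body <- lines[-(1:2)]
    tab <- parse_delim_matrix(body, id_cols = 2L, path = path)
    if (nrow(tab$values) != dims[[1L]] || ncol(tab$values) != dims[[2L]]) {
      abort(sprintf(
        "GCT header declares %d genes x %d samples but the table has %d x %d",
        dims[[1L]], dims[[2L]], nrow(tab$values), ncol(tab$values)))
    }
  } else {
    tab <- parse_delim_matrix(lines, id_cols = 1L, path = path)
  }
  validate_expression_matrix(tab$values)
}

# Shared tab-delimited parser: `id_cols` leading columns are identifiers
# (gene id [+ description]); the remainder must be numeric or empty.
parse_delim_matrix <- function(lines, id_cols, path) {
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) abort(sprintf("no data rows in %s", path))
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  sample_ids <- unquote_field(header[-seq_len(id_cols)])
  if (anyDuplicated(sample_ids)) {
    abort(sprintf("duplicate sample id: %s",
                  sample_ids[duplicated(sample_ids)][[1L]]))
  }
  rows <- cells[-1L]
  gene_ids <- unquote_field(vapply(rows, `[[`, character(1L), 1L))
  if (anyDuplicated(gene_ids)) {
    abort(sprintf("duplicate gene id: %s", gene_ids[duplicated(gene_ids)][[1L]]))
  }
  n <- length(sample_ids)
  values <- matrix(NA_real_, length(rows), n,
                   dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(rows)) {
    raw <- rows[[i]][-seq_len(id_cols)]
    if (length(raw) > n) {
      abort(sprintf("row %s has %d value cells, expected %d",
                    gene_ids[[i]], length(raw), n))
    }
    # strsplit drops trailing empty fields, so short rows are trailing
    # missing cells; pad them back as explicit NAs
    length(raw) <- n
    empty <- is.na(raw) | raw %in% c("", "NA", "na", "NaN")
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!empty & is.na(num))
    if (length(bad)) {
      abort(sprintf("non-numeric value '%s' at gene %s, sample %s",
                    raw[bad[[1L]]], gene_ids[[i]], sample_ids[bad[[1L]]]))
    }
    num[empty] <- NA_real_
    values[i, ] <- num
  }
  list(values = values)
}

unquote_field <- function(x) gsub('^"|"$', "", trimws(x))

#' Validate an expression matrix
#'
#' Checks the expression-matrix contract: a numeric matrix with unique,
#' non-empty row (gene) and column (sample) names whose entries are finite or
#' explicitly `NA`.
#'
#' @param x A numeric matrix.
#' @return `x`, invisibly validated (returned so calls can be chained).
#' @export
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) abort("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) {
    abort(sprintf("duplicate gene id: %s",
                  rownames(x)[duplicated(rownames(x))][[1L]]))
  }
  if (anyDuplicated(colnames(x))) {
    abort(sprintf("duplicate sample id: %s",
                  colnames(x)[duplicated(colnames(x))][[1L]]))
  }
  if (any(is.infinite(x) | is.nan(x))) abort("expression values must be finite or NA")
  x
}

#' Write a gene-expression matrix
#'
#' Inverse of [read_expression()]: TSV or GCT 1.2 with values printed at 15
#' significant digits, so write-then-read is an identity to double precision.
#' Missing entries are written as empty cells.
#'
#' @param x Numeric genes-by-samples matrix with dimnames.
#' @param path Output path.
#' @param format `"tsv"` or `"gct"`.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  validate_expression_matrix(x)
  fmt <- function(v) {
    out <- vapply(v, function(e) if (is.na(e)) "" else format(e, digits = 15),
                  character(1L))
    out
  }
  body <- vapply(seq_len(nrow(x)), function(i) {
    prefix <- if (format == "gct") paste(rownames(x)[i], "na", sep = "\t") else rownames(x)[i]
    paste(c(prefix, fmt(x[i, ])), collapse = "\t")
  }, character(1L))
  header_ids <- paste(colnames(x), collapse = "\t")
  lines <- if (format == "gct") {
    c("#1.2", paste(nrow(x), ncol(x), sep = "\t"),
      paste("Name", "Description", header_ids, sep = "\t"), body)
  } else {
    c(paste("gene_id", header_ids, sep = "\t"), body)
  }
  writeLines(lines, path)
  invisible(path)
}
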