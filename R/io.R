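SCHEMA_LINE <- "# ramrsgl-tsv v1"

#' Write a matrix as tab-delimited text
#'
#' Canonical interchange format: a schema-version comment line, a header row
#' of column identifiers, and one row per sample with the row identifier in
#' the first column. Values are written at full (17 significant digit)
#' precision so a write/read round trip is bit-identical.
#'
#' @param x Numeric matrix with row and column names.
#' @param path Output file path.
#' @export
write_expression <- function(x, path) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("row_%d", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- sprintf("col_%d", seq_len(ncol(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(SCHEMA_LINE, con)
  writeLines(paste(c("id", colnames(x)), collapse = "\t"), con)
  body <- apply(format(x, digits = 17, trim = TRUE, scientific = TRUE), 1,
                paste, collapse = "\t")
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

check_schema <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "# ramrsgl-tsv") && first != SCHEMA_LINE) {
    stop("schema version mismatch in ", path, ": found '", first,
         "', expected '", SCHEMA_LINE, "'")
  }
  invisible(TRUE)
}

#' Read an expression matrix from delimited text
#'
#' Reads a tab-delimited matrix with a header row of IDs and a first column
#' of IDs, in either orientation, and returns it as samples by genes.
#'
#' @param path Input file (optionally starting with the package's
#'   schema-version comment line; a mismatched version is rejected).
#' @param orientation `"samples_in_rows"` (default) or `"genes_in_rows"`.
#' @return Numeric matrix, samples in rows, genes in columns, with IDs as
#'   dimnames.
#' @export
read_expression <- function(path, orientation = c("samples_in_rows", "genes_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  check_schema(path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 2L) stop("file ", path, " has no data rows")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(parts)
  if (any(widths != widths[1L])) {
    stop("ragged rows in ", path, ": line ", which(widths != widths[1L])[1L] + 1L,
         " has ", widths[widths != widths[1L]][1L], " fields, expected ", widths[1L])
  }
  header <- parts[[1L]][-1L]
  row_ids <- vapply(parts[-1L], `[[`, "", 1L)
  if (anyDuplicated(header)) {
    stop("duplicate column ID in ", path, ": ", header[duplicated(header)][1L])
  }
  if (anyDuplicated(row_ids)) {
    stop("duplicate row ID in ", path, ": ", row_ids[duplicated(row_ids)][1L])
  }
  vals <- suppressWarnings(
    vapply(parts[-1L], function(p) as.numeric(p[-1L]), numeric(length(header))))
  vals <- if (length(header) == 1L) matrix(vals, nrow = 1L) else vals
  bad <- which(colSums(is.na(vals)) > 0)  # columns of vals = file rows
  if (length(bad)) stop("non-numeric cell in ", path, " at line ", bad[1L] + 2L)
  m <- t(vals)
  dimnames(m) <- list(row_ids, header)
  if (orientation == "genes_in_rows") m <- t(m)
  m
}

#' Write per-sample class labels
#'
#' @param sample_ids Character vector of sample IDs.
#' @param labels Class labels (character or integer), same length.
#' @param path Output file path.
#' @export
write_labels <- function(sample_ids, labels, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(SCHEMA_LINE, con)
  writeLines("sample\tclass", con)
  writeLines(paste(sample_ids, labels, sep = "\t"), con)
  invisible(path)
}

#' Read per-sample class labels
#'
#' Reads a two-column table (sample ID, class name) and maps class names to
#' integers `1..K` in order of first appearance.
#'
#' @param path Input file.
#' @param sample_ids Optional sample IDs from the expression file; labels are
#'   reordered to match, and samples missing from either side are an error.
#' @return List with `y` (integer labels), `levels` (class names, index
#'   `k` is class `k`), `sample_ids`.
#' @export
read_labels <- function(path, sample_ids = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  check_schema(path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("label file must have exactly two columns")
  if (identical(tolower(parts[[1L]][1L]), "sample")) parts <- parts[-1L]
  ids <- vapply(parts, `[[`, "", 1L)
  cls <- vapply(parts, `[[`, "", 2L)
  if (anyDuplicated(ids)) stop("duplicate sample ID: ", ids[duplicated(ids)][1L])
  levels <- unique(cls)   # first-appearance order in the file
  if (!is.null(sample_ids)) {
    missing_lab <- setdiff(sample_ids, ids)
    extra_lab <- setdiff(ids, sample_ids)
    if (length(missing_lab) || length(extra_lab)) {
      stop("sample mismatch between expression and label files; missing: ",
           paste(missing_lab, collapse = ", "), "; extra: ",
           paste(extra_lab, collapse = ", "))
    }
    ord <- match(sample_ids, ids)
    ids <- ids[ord]; cls <- cls[ord]
  }
  if (length(levels) < 2L) stop("at least two classes are required")
  list(y = match(cls, levels), levels = levels, sample_ids = ids)
}
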