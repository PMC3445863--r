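#' Read a log2 expression matrix
#'
#' Reads a tab-delimited genes x samples matrix. Two dialects are supported:
#' plain TSV (first column gene identifiers, header row of sample
#' identifiers) and GCT 1.2 (a `#1.2` preamble line, a dimensions line, and
#' `NAME`/`Description` columns preceding the samples; the Description
#' column is discarded).
#'
#' Duplicate gene rows are an error at this stage: collapsing
#' multiple probes per gene is an explicit, separate operation
#' ([collapse_probes()]).
#'
#' @param path file to read.
#' @param dialect `"tsv"` or `"gct"`.
#' @param allow_na permit missing cells (probe-level matrices only).
#' @return numeric matrix, genes x samples (see
#'   [validate_expression_matrix()]).
#' @seealso [write_expression_matrix()]
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "gct"),
                                   allow_na = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  drop_desc <- FALSE
  if (dialect == "gct") {
    if (length(lines) < 3L || !startsWith(lines[[1L]], "#1.2")) {
      stop("malformed GCT header at line 1: expected '#1.2'", call. = FALSE)
    }
    dims <- strsplit(lines[[2L]], "\t", fixed = TRUE)[[1L]]
    if (length(dims) < 2L || anyNA(suppressWarnings(as.integer(dims[1:2])))) {
      stop("malformed GCT dimensions at line 2: ", lines[[2L]], call. = FALSE)
    }
    lines <- lines[-(1:2)]
    drop_desc <- TRUE
  }
  if (!length(lines)) stop("empty matrix file: ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  n_skip <- if (drop_desc) 2L else 1L
  if (length(header) <= n_skip) {
    stop("malformed header at line ", if (drop_desc) 3L else 1L,
         ": no sample columns", call. = FALSE)
  }
  sample_ids <- header[-seq_len(n_skip)]
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (!length(body)) stop("matrix has no gene rows: ", path, call. = FALSE)
  cells <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(cells)
  bad <- which(widths != length(header))
  if (length(bad)) {
    stop("row ", bad[[1L]], " has ", widths[[bad[[1L]]]],
         " fields, expected ", length(header), call. = FALSE)
  }
  gene_ids <- vapply(cells, `[[`, character(1L), 1L)
  vals <- matrix(NA_real_, length(body), length(sample_ids),
                 dimnames = list(gene_ids, sample_ids))
  for (i in seq_along(cells)) {
    raw <- cells[[i]][-seq_len(n_skip)]
    v <- suppressWarnings(as.numeric(raw))
    bad_cell <- which(is.na(v) & !(raw %in% c("NA", "")))
    if (length(bad_cell)) {
      stop("non-numeric cell at gene row '", gene_ids[[i]], "', sample '",
           sample_ids[[bad_cell[[1L]]]], "': '", raw[[bad_cell[[1L]]]], "'",
           call. = FALSE)
    }
    vals[i, ] <- v
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) {
    stop("duplicate gene identifiers: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  validate_expression_matrix(vals, allow_na = allow_na, arg = path)
  vals
}

#' Write a log2 expression matrix
#'
#' Values are written with 17 significant digits so a read/write round trip
#' reproduces the matrix to full double precision.
#'
#' @param matrix numeric genes x samples matrix.
#' @param path output file.
#' @param dialect `"tsv"` or `"gct"` (GCT 1.2; Description column written
#'   as the gene identifier).
#' @param allow_na permit missing cells.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(matrix, path, dialect = c("tsv", "gct"),
                                    allow_na = FALSE) {
  dialect <- match.arg(dialect)
  validate_expression_matrix(matrix, allow_na = allow_na)
  fmt <- function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "NA"
    out
  }
  rows <- vapply(seq_len(nrow(matrix)), function(i) {
    paste(c(rownames(matrix)[i],
            if (dialect == "gct") rownames(matrix)[i],
            fmt(matrix[i, ])), collapse = "\t")
  }, character(1L))
  header <- paste(c(if (dialect == "gct") c("NAME", "Description") else "gene_id",
                    colnames(matrix)), collapse = "\t")
  pre <- if (dialect == "gct") {
    c("#1.2", paste(nrow(matrix), ncol(matrix), sep = "\t"))
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(pre, header, rows), con)
  invisible(path)
}
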