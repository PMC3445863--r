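#' Validate an expression matrix
#'
#' An expression matrix is a base numeric matrix of log2-scale intensities
#' with genes as rows and samples as columns, unique identifiers on both
#' axes, and (unless probe-level data still awaiting collapsing is declared
#' via `allow_na`) only finite values.
#'
#' @param x numeric matrix, genes x samples, with rownames and colnames.
#' @param allow_na logical; permit `NA` values (probe-level matrices before
#'   [collapse_probes()] only). Infinite values are never permitted.
#' @param arg name used in error messages.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_expression_matrix <- function(x, allow_na = FALSE, arg = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(arg, " must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop(arg, " must have at least 1 gene and 1 sample", call. = FALSE)
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(arg, " must carry gene rownames and sample colnames", call. = FALSE)
  }
  dup_g <- unique(rownames(x)[duplicated(rownames(x))])
  if (length(dup_g)) {
    stop(arg, ": duplicate gene identifiers: ",
         paste(dup_g, collapse = ", "), call. = FALSE)
  }
  dup_s <- unique(colnames(x)[duplicated(colnames(x))])
  if (length(dup_s)) {
    stop(arg, ": duplicate sample identifiers: ",
         paste(dup_s, collapse = ", "), call. = FALSE)
  }
  if (any(is.infinite(x))) {
    stop(arg, " contains non-finite values", call. = FALSE)
  }
  if (!allow_na && anyNA(x)) {
    stop(arg, " contains missing values; collapse probes first or pass allow_na = TRUE",
         call. = FALSE)
  }
  invisible(x)
}

#' Validate a centroid set
#'
#' A centroid set is a numeric genes x 5 matrix whose columns are exactly
#' the five subtype labels [SUBTYPE_LABELS] (in that order) and whose entries
#' are finite log2-scale means; the optional `signature` attribute names the
#' intrinsic gene list the panel came from.
#'
#' @param x candidate centroid matrix.
#' @param arg name used in error messages.
#' @return `x` invisibly.
#' @export
validate_centroid_set <- function(x, arg = "centroids") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(arg, " must be a numeric matrix (genes x 5 subtypes)", call. = FALSE)
  }
  if (ncol(x) != 5L || !identical(colnames(x), SUBTYPE_LABELS)) {
    stop(arg, " must have exactly the 5 subtype columns ",
         paste(SUBTYPE_LABELS, collapse = ", "), " in order", call. = FALSE)
  }
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop(arg, " must have unique gene rownames", call. = FALSE)
  }
  if (nrow(x) < 1L || !all(is.finite(x))) {
    stop(arg, " must be non-empty with all values finite", call. = FALSE)
  }
  invisible(x)
}

#' Validate a batch design
#'
#' @param batches data.frame with columns `sample_id`, `batch`.
#' @param sample_ids optional sample identifiers that must all be covered.
#' @param require_two require exactly 2 distinct batch labels (DWD use).
#' @return `batches` invisibly.
#' @export
validate_batch_design <- function(batches, sample_ids = NULL, require_two = FALSE) {
  if (!is.data.frame(batches) || !all(c("sample_id", "batch") %in% names(batches))) {
    stop("batches must be a data.frame with columns sample_id, batch", call. = FALSE)
  }
  if (anyDuplicated(batches$sample_id)) {
    stop("batch design has duplicated sample identifiers", call. = FALSE)
  }
  if (!is.null(sample_ids)) {
    missing_ids <- setdiff(sample_ids, batches$sample_id)
    if (length(missing_ids)) {
      stop("samples without a batch label: ",
           paste(head(missing_ids, 5L), collapse = ", "), call. = FALSE)
    }
  }
  if (require_two && length(unique(batches$batch)) != 2L) {
    stop("exactly 2 distinct batch labels are required, got ",
         length(unique(batches$batch)), call. = FALSE)
  }
  invisible(batches)
}

#' Construct a gene signature
#'
#' @param name signature name, e.g. `"PAM50"`, `"Hu306"`, `"Sorlie500"`.
#' @param gene_symbols unique, non-empty character vector of gene symbols.
#' @param probe_map optional data.frame with columns `probe_id`,
#'   `gene_symbol`; every probe maps to exactly one gene symbol.
#' @return an object of class `gene_signature`.
#' @export
gene_signature <- function(name, gene_symbols, probe_map = NULL) {
  gene_symbols <- as.character(gene_symbols)
  if (!length(gene_symbols) || anyDuplicated(gene_symbols) || anyNA(gene_symbols)) {
    stop("gene_symbols must be non-empty and unique", call. = FALSE)
  }
  if (!is.null(probe_map)) {
    if (!is.data.frame(probe_map) ||
        !all(c("probe_id", "gene_symbol") %in% names(probe_map))) {
      stop("probe_map must have columns probe_id, gene_symbol", call. = FALSE)
    }
    if (anyDuplicated(probe_map$probe_id)) {
      stop("probe_map: a probe maps to more than one gene symbol", call. = FALSE)
    }
  }
  structure(list(name = name, gene_symbols = gene_symbols, probe_map = probe_map),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature '", x$name, "': ", length(x$gene_symbols), " genes",
      if (!is.null(x$probe_map)) paste0(", ", nrow(x$probe_map), " mapped probes"),
      "\n", sep = "")
  invisible(x)
}
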