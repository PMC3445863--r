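#' Quantile normalization
#'
#' Forces every sample (column) to share one empirical distribution: the
#' across-sample mean of sorted columns. Within-sample rank order is
#' preserved; values tied within a sample all receive the mean of the
#' reference values at the ranks the tied block occupies.
#'
#' @param matrix numeric genes x samples matrix, no missing values, >= 2
#'   samples.
#' @return matrix of the same shape; sorted columns are identical across
#'   samples.
#' @export
quantile_normalize <- function(matrix) {
  validate_expression_matrix(matrix)
  if (ncol(matrix) < 2L) {
    stop("quantile normalization needs at least 2 samples", call. = FALSE)
  }
  ref <- rowMeans(apply(matrix, 2L, sort))
  out <- matrix
  for (j in seq_len(ncol(matrix))) {
    out[, j] <- qn_map_column(matrix[, j], ref)
  }
  out
}

# Map one column onto the reference distribution, averaging the reference
# over each tied block of ranks.
qn_map_column <- function(x, ref) {
  o <- order(x)
  sx <- x[o]
  out <- numeric(length(x))
  i <- 1L
  n <- length(x)
  while (i <= n) {
    j <- i
    while (j < n && sx[j + 1L] == sx[i]) j <- j + 1L
    out[o[i:j]] <- mean(ref[i:j])
    i <- j + 1L
  }
  out
}

#' Gene-wise centring
#'
#' Subtracts each gene's across-sample mean (or median), removing
#' gene-level location bias between cohorts or platforms. The arithmetic
#' mean is the default; the median variant is offered for cross-checks
#' because part of the PAM50 lineage centres on medians.
#'
#' @param matrix numeric genes x samples matrix, no missing values.
#' @param method `"mean"` or `"median"`.
#' @return matrix with every gene row centred (mean method: |row mean| <
#'   1e-10; within-row differences unchanged).
#' @export
mean_center_genes <- function(matrix, method = c("mean", "median")) {
  method <- match.arg(method)
  validate_expression_matrix(matrix)
  ctr <- if (method == "mean") rowMeans(matrix) else apply(matrix, 1L, median)
  matrix - ctr
}

#' Pool two cohorts
#'
#' Column-binds two expression matrices restricted to their shared gene
#' panel (in the first cohort's gene order), optionally quantile-normalizes
#' the pooled matrix, and records which cohort each sample came from as a
#' 2-level batch design.
#'
#' @param a,b expression matrices with disjoint sample identifiers.
#' @param labels length-2 character vector of batch labels for `a` and `b`.
#' @param normalize quantile-normalize the pooled matrix (default TRUE,
#'   mirroring pooling followed by quantile normalization to strip the
#'   between-site batch effect).
#' @return list with elements `matrix` (pooled genes x samples) and
#'   `batches` (data.frame `sample_id`, `batch`).
#' @export
pool_cohorts <- function(a, b, labels = c("a", "b"), normalize = TRUE) {
  validate_expression_matrix(a, arg = "a")
  validate_expression_matrix(b, arg = "b")
  clash <- intersect(colnames(a), colnames(b))
  if (length(clash)) {
    stop("cohorts share sample identifiers: ",
         paste(head(clash, 5L), collapse = ", "), call. = FALSE)
  }
  genes <- rownames(a)[rownames(a) %in% rownames(b)]
  if (!length(genes)) stop("cohorts share no genes", call. = FALSE)
  pooled <- cbind(a[genes, , drop = FALSE], b[genes, , drop = FALSE])
  if (normalize) pooled <- quantile_normalize(pooled)
  batches <- data.frame(
    sample_id = colnames(pooled),
    batch = rep(labels, c(ncol(a), ncol(b))),
    stringsAsFactors = FALSE
  )
  list(matrix = pooled, batches = batches)
}
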