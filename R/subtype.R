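#' Collapse probe rows to gene symbols
#'
#' Genes represented by multiple probesets are collapsed by averaging:
#' the row of a gene is the unweighted arithmetic mean of its probes'
#' rows. Probes absent from the map are dropped (count reported via a
#' message); missing probe values are excluded from the mean, and a gene
#' whose probes are all missing for some sample is an error.
#'
#' @param matrix probes x samples matrix (missing values permitted).
#' @param probe_map data.frame with columns `probe_id`, `gene_symbol`.
#' @return genes x samples matrix with no missing values.
#' @export
collapse_probes <- function(matrix, probe_map) {
  validate_expression_matrix(matrix, allow_na = TRUE)
  if (!is.data.frame(probe_map) ||
      !all(c("probe_id", "gene_symbol") %in% names(probe_map))) {
    stop("probe_map must have columns probe_id, gene_symbol", call. = FALSE)
  }
  if (anyDuplicated(probe_map$probe_id)) {
    stop("probe_map: a probe maps to more than one gene symbol", call. = FALSE)
  }
  keep <- rownames(matrix) %in% probe_map$probe_id
  dropped <- sum(!keep)
  if (!any(keep)) {
    stop("no probes left after intersecting with probe_map", call. = FALSE)
  }
  if (dropped) message(dropped, " unmapped probe(s) dropped")
  m <- matrix[keep, , drop = FALSE]
  gene <- probe_map$gene_symbol[match(rownames(m), probe_map$probe_id)]
  present <- !is.na(m)
  m0 <- m
  m0[!present] <- 0
  sums <- rowsum(m0, gene)
  counts <- rowsum(present + 0, gene)
  if (any(counts == 0)) {
    bad <- which(counts == 0, arr.ind = TRUE)[1L, ]
    stop("gene '", rownames(counts)[bad[[1L]]], "' has no non-missing probe ",
         "value for sample '", colnames(counts)[bad[[2L]]], "'", call. = FALSE)
  }
  out <- sums / counts
  validate_expression_matrix(out, arg = "collapsed matrix")
  out
}

#' Compute subtype centroids from labelled training data
#'
#' A subtype's centroid is the per-gene arithmetic mean over the training
#' samples carrying that label, on the panel formed by intersecting the
#' signature's genes with the training matrix.
#'
#' @param training genes x samples matrix.
#' @param labels subtype label per training sample: a named character
#'   vector (names = sample ids) or a data.frame `sample_id`, `label`.
#'   Labels must be among [SUBTYPE_LABELS]; every subtype needs >= 1
#'   sample.
#' @param signature a [gene_signature()]; the centroid panel is the
#'   signature genes found in `training` (a message reports incomplete
#'   coverage).
#' @return genes x 5 centroid matrix with `signature` attribute.
#' @export
compute_centroids <- function(training, labels, signature) {
  validate_expression_matrix(training, arg = "training")
  if (is.data.frame(labels)) {
    labels <- setNames(as.character(labels$label), labels$sample_id)
  }
  labels <- labels[colnames(training)]
  if (anyNA(labels)) stop("every training sample needs a label", call. = FALSE)
  bad <- setdiff(unique(labels), SUBTYPE_LABELS)
  if (length(bad)) {
    stop("unknown subtype label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(SUBTYPE_LABELS, labels)
  if (length(absent)) {
    stop("subtype(s) without training samples: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  genes <- signature$gene_symbols[signature$gene_symbols %in% rownames(training)]
  if (!length(genes)) {
    stop("no signature genes found in the training matrix", call. = FALSE)
  }
  if (length(genes) < length(signature$gene_symbols)) {
    message(length(genes), "/", length(signature$gene_symbols),
            " signature genes present in training data")
  }
  m <- vapply(SUBTYPE_LABELS, function(k) {
    rowMeans(training[genes, labels == k, drop = FALSE])
  }, numeric(length(genes)))
  rownames(m) <- genes
  attr(m, "signature") <- signature$name
  validate_centroid_set(m)
  m
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked vectors (ties receive the mean of
#' the ranks they occupy). A constant vector has no rank ordering, so the
#' correlation is undefined and an error is raised rather than returning
#' `NA`.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired values", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) {
    stop("Spearman correlation undefined for a constant vector", call. = FALSE)
  }
  cor(rx, ry)
}

#' Classify one sample by nearest centroid (single-sample prediction)
#'
#' Computes the Spearman correlation between the sample and each of the
#' five subtype centroids over their shared gene panel. The call is the
#' subtype with the highest correlation, or `Unclassified` when all five
#' correlations fall below the threshold (strictly: a correlation equal to
#' the threshold classifies). An exact tie at the maximum is resolved
#' deterministically in the fixed order [SUBTYPE_LABELS] and flagged.
#'
#' @param sample named numeric vector of log2 expression over genes.
#' @param centroids genes x 5 centroid matrix.
#' @param threshold unclassified threshold on the correlations (default
#'   0.1).
#' @param min_genes minimum shared-panel size (default 10); fewer shared
#'   genes is an error, not a silent small-panel correlation.
#' @param sample_id identifier recorded in the call.
#' @return one-row data.frame: `sample_id`, `label`, `rho_LumA` ..
#'   `rho_Basal`, `threshold`, `tie_flag`.
#' @export
classify_sample <- function(sample, centroids, threshold = 0.1,
                            min_genes = 10L, sample_id = "sample") {
  validate_centroid_set(centroids)
  if (is.null(names(sample))) stop("sample vector must be gene-named", call. = FALSE)
  shared <- intersect(names(sample), rownames(centroids))
  if (length(shared) < min_genes) {
    stop("only ", length(shared), " genes shared with the centroid panel ",
         "(floor ", min_genes, ") for sample '", sample_id, "'", call. = FALSE)
  }
  x <- sample[shared]
  rhos <- vapply(SUBTYPE_LABELS, function(k) {
    spearman_rho(x, centroids[shared, k])
  }, numeric(1L))
  if (all(rhos < threshold)) {
    label <- "Unclassified"
    tie <- FALSE
  } else {
    at_max <- which(rhos == max(rhos))
    label <- SUBTYPE_LABELS[at_max[[1L]]]
    tie <- length(at_max) > 1L
  }
  out <- data.frame(sample_id = sample_id, label = label,
                    t(setNames(rhos, paste0("rho_", SUBTYPE_LABELS))),
                    threshold = threshold, tie_flag = tie,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Classify every sample of a cohort
#'
#' @param matrix genes x samples matrix.
#' @param centroids genes x 5 centroid matrix.
#' @inheritParams classify_sample
#' @return data.frame of calls (class `subtype_calls`), one row per sample,
#'   with the category distribution available via [subtype_distribution()].
#' @export
classify_cohort <- function(matrix, centroids, threshold = 0.1,
                            min_genes = 10L) {
  validate_expression_matrix(matrix)
  if (ncol(matrix) < 1L) stop("empty cohort", call. = FALSE)
  calls <- lapply(colnames(matrix), function(s) {
    tryCatch(
      classify_sample(matrix[, s], centroids, threshold = threshold,
                      min_genes = min_genes, sample_id = s),
      error = function(e) {
        stop("classification failed for sample '", s, "': ",
             conditionMessage(e), call. = FALSE)
      })
  })
  out <- do.call(rbind, calls)
  class(out) <- c("subtype_calls", class(out))
  out
}

#' Distribution of subtype calls
#'
#' Counts of the 6 call categories (5 subtypes + Unclassified) in fixed
#' order; counts always sum to the cohort size.
#'
#' @param calls a calls data.frame ([classify_cohort()] or
#'   [read_table()] with schema `"calls"`).
#' @return named integer vector over [CALL_LABELS].
#' @export
subtype_distribution <- function(calls) {
  table(factor(calls$label, levels = CALL_LABELS))
}
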