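#' Cross-tabulate two call sets
#'
#' Builds the K x K contingency table of paired subtype calls over the
#' (identical) sample sets of two classifiers. `Unclassified` is either
#' kept as a sixth category (default, so kappa is computed on all n
#' samples) or samples unclassified by either caller are dropped (K = 5).
#'
#' @param a,b calls data.frames (columns `sample_id`, `label`).
#' @param unclassified `"category"` (keep, K = 6) or `"drop"` (exclude,
#'   K = 5).
#' @return K x K contingency table; rows follow `a`, columns follow `b`.
#' @export
crosstab <- function(a, b, unclassified = c("category", "drop")) {
  unclassified <- match.arg(unclassified)
  if (!setequal(a$sample_id, b$sample_id) ||
      length(a$sample_id) != length(b$sample_id)) {
    diff <- union(setdiff(a$sample_id, b$sample_id),
                  setdiff(b$sample_id, a$sample_id))
    stop("call sets cover different samples: ",
         paste(head(diff, 5L), collapse = ", "), call. = FALSE)
  }
  lb <- b$label[match(a$sample_id, b$sample_id)]
  la <- a$label
  if (unclassified == "drop") {
    keep <- la != "Unclassified" & lb != "Unclassified"
    la <- la[keep]; lb <- lb[keep]
    levels_ <- SUBTYPE_LABELS
  } else {
    levels_ <- CALL_LABELS
  }
  table(a = factor(la, levels = levels_), b = factor(lb, levels = levels_))
}

#' Unweighted Cohen's kappa with large-sample confidence interval
#'
#' Chance-corrected agreement for a square contingency table:
#' `kappa = (po - pe) / (1 - pe)` with `po` the observed and `pe` the
#' chance (product-marginal) agreement. The standard error is the
#' large-sample delta-method variance of Fleiss, Cohen and Everitt, and the
#' 95% CI is `kappa +/- 1.96 se` (not truncated at \[-1, 1\]).
#'
#' @param table square K x K count table (matrix or `table`), total >= 2.
#' @return object of class `agreement_result`: `table`, `kappa`, `se`,
#'   `ci_low`, `ci_high`, `n`, `po`, `pe`, `categories`.
#' @export
cohen_kappa <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) != ncol(m)) stop("table must be square", call. = FALSE)
  if (any(m < 0) || any(m != round(m))) {
    stop("table must hold non-negative counts", call. = FALSE)
  }
  n <- sum(m)
  if (n < 2) stop("need at least 2 paired calls", call. = FALSE)
  p <- m / n
  pr <- rowSums(p)
  pc <- colSums(p)
  po <- sum(diag(p))
  pe <- sum(pr * pc)
  if (1 - pe < .Machine$double.eps^0.5) {
    stop("kappa undefined: both raters constant and identical (pe = 1)",
         call. = FALSE)
  }
  kappa <- (po - pe) / (1 - pe)
  # Fleiss-Cohen-Everitt large-sample variance of unweighted kappa
  W <- outer(pc, pr, "+")                       # W[i, j] = p.i + pj.
  A <- sum(diag(p) * (1 - (pr + pc) * (1 - kappa))^2)
  off <- p * W^2
  diag(off) <- 0
  B <- (1 - kappa)^2 * sum(off)
  C <- (kappa - pe * (1 - kappa))^2
  var_k <- (A + B - C) / (n * (1 - pe)^2)
  se <- sqrt(max(var_k, 0))
  structure(list(
    table = m, kappa = kappa, se = se,
    ci_low = kappa - 1.96 * se, ci_high = kappa + 1.96 * se,
    n = n, po = po, pe = pe,
    categories = rownames(m) %||% as.character(seq_len(nrow(m)))
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa (unweighted): %.4f  se %.4f  95%% CI %.4f-%.4f  (n = %d)\n",
              x$kappa, x$se, x$ci_low, x$ci_high, x$n))
  invisible(x)
}

#' Pairwise agreement between two call sets
#'
#' Convenience wrapper: [crosstab()] then [cohen_kappa()].
#'
#' @inheritParams crosstab
#' @return an `agreement_result`.
#' @export
agreement <- function(a, b, unclassified = c("category", "drop")) {
  cohen_kappa(crosstab(a, b, unclassified = unclassified))
}

#' Samples called identically by two classifiers
#'
#' Returns sample identifiers whose labels agree and are not
#' `Unclassified` (two classifiers agreeing that a sample is unclassifiable
#' is not an assignment to a subtype).
#'
#' @param calls_a,calls_b calls data.frames over the same samples.
#' @return character vector of sample identifiers, in `calls_a` order.
#' @export
consistent_samples <- function(calls_a, calls_b) {
  lb <- calls_b$label[match(calls_a$sample_id, calls_b$sample_id)]
  if (anyNA(lb) || !setequal(calls_a$sample_id, calls_b$sample_id)) {
    stop("call sets cover different samples", call. = FALSE)
  }
  calls_a$sample_id[calls_a$label == lb & calls_a$label != "Unclassified"]
}

#' Samples called identically by all classifiers
#'
#' Intersection of [consistent_samples()] over every pair of call sets.
#'
#' @param call_sets list of >= 2 calls data.frames over identical samples.
#' @return character vector of sample identifiers.
#' @export
multi_way_consistent <- function(call_sets) {
  if (length(call_sets) < 2L) stop("need at least 2 call sets", call. = FALSE)
  pairs <- combn(length(call_sets), 2L, simplify = FALSE)
  Reduce(intersect, lapply(pairs, function(ij) {
    consistent_samples(call_sets[[ij[[1L]]]], call_sets[[ij[[2L]]]])
  }))
}
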