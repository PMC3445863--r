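#' Subtype-by-clinical-feature association tables
#'
#' Cross-tabulates each clinical feature against the subtype calls.
#' Missing values are excluded from the feature's denominator and reported
#' as a count; proportions are per subtype column.
#'
#' @param calls calls data.frame (`sample_id`, `label`).
#' @param clinical clinical records data.frame (see [read_table()] schema
#'   `"clinical"`); must cover every called sample.
#' @param features subset of `er`, `her2`, `grade`, `nodal`, `lvi`.
#' @return named list, one element per feature: `counts` (categories x
#'   subtype columns in fixed [CALL_LABELS] order), `proportions`
#'   (column-wise), `missing` (count of samples without a value).
#' @export
clinical_by_subtype <- function(calls, clinical,
                                features = names(CLINICAL_LEVELS)) {
  bad <- setdiff(features, names(CLINICAL_LEVELS))
  if (length(bad)) {
    stop("unknown clinical feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(calls$sample_id, clinical$sample_id)
  if (anyNA(idx)) {
    stop("clinical records missing for sample(s): ",
         paste(head(calls$sample_id[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  }
  cl <- clinical[idx, , drop = FALSE]
  label <- factor(calls$label, levels = CALL_LABELS)
  out <- lapply(features, function(f) {
    v <- factor(cl[[f]], levels = CLINICAL_LEVELS[[f]])
    counts <- table(category = v, subtype = label)
    totals <- colSums(counts)
    prop <- sweep(counts, 2L, ifelse(totals > 0, totals, NA_real_), "/")
    list(counts = counts, proportions = prop, missing = sum(is.na(v)))
  })
  setNames(out, features)
}

#' Per-feature marginal counts with printed-style percentages
#'
#' Counts each clinical category and attaches the integer percentage
#' (half-up rounding) of the non-missing denominator — the format clinical
#' demographic tables print.
#'
#' @param clinical clinical records data.frame.
#' @param features subset of the clinical feature names.
#' @return named list per feature: data.frame `category`, `count`,
#'   `percent`, plus attribute-free columns `denominator` and `missing`.
#' @export
marginal_summary <- function(clinical, features = names(CLINICAL_LEVELS)) {
  if (!nrow(clinical)) stop("no clinical records", call. = FALSE)
  bad <- setdiff(features, names(CLINICAL_LEVELS))
  if (length(bad)) {
    stop("unknown clinical feature(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(features, function(f) {
    v <- factor(clinical[[f]], levels = CLINICAL_LEVELS[[f]])
    counts <- table(v)
    denom <- sum(counts)
    data.frame(
      category = names(counts),
      count = as.integer(counts),
      percent = if (denom > 0) round_half_up(100 * as.integer(counts) / denom)
                else NA_integer_,
      denominator = denom,
      missing = sum(is.na(v)),
      stringsAsFactors = FALSE
    )
  })
  setNames(out, features)
}

# round-half-up to integer (base round() is banker's rounding)
round_half_up <- function(x) as.integer(floor(x + 0.5))

#' IHC surrogate subtype
#'
#' The conventional pathology surrogate for the intrinsic subtypes:
#' ER-positive tumours are luminal-like, ER-negative/HER2 over-expressed
#' are HER2-like, ER-negative/HER2-negative are triple-negative-like; any
#' missing input yields `unknown`.
#'
#' @param clinical clinical records data.frame (columns `er`, `her2`).
#' @return character vector, one surrogate label per record.
#' @export
ihc_surrogate <- function(clinical) {
  er <- clinical$er
  her2 <- clinical$her2
  out <- rep("unknown", length(er))
  known_er <- !is.na(er)
  out[known_er & er == "positive"] <- "luminal-like"
  neg <- known_er & er == "negative" & !is.na(her2)
  out[neg & her2 == "over-expressed"] <- "HER2-like"
  out[neg & her2 == "not"] <- "triple-negative-like"
  out
}
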