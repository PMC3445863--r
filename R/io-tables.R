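#' Read a typed tab-delimited table
#'
#' One reader for the package's ancillary artefacts. All files are UTF-8,
#' tab-delimited, `"."` decimal, with a header row; missing clinical
#' categories are encoded as the literal token `NA`.
#'
#' Schemas:
#' \describe{
#'   \item{signature}{columns `gene_symbol` and optionally `probe_id`;
#'     returns a [gene_signature()] (name taken from `name` or the file).}
#'   \item{centroids}{columns `gene_symbol`, `LumA`, `LumB`, `Normal`,
#'     `Her2E`, `Basal` (exactly); returns a centroid matrix.}
#'   \item{clinical}{columns `sample_id`, `er`, `her2`, `grade`, `nodal`,
#'     `lvi` with the categorical enumerations of the clinical model.}
#'   \item{survival}{columns `sample_id`, `time` (months, >= 0), `event`
#'     (0/1).}
#'   \item{batch}{columns `sample_id`, `batch`.}
#'   \item{calls}{columns `sample_id`, `label`, `rho_LumA` .. `rho_Basal`,
#'     `threshold`, `tie_flag`.}
#' }
#'
#' @param path file to read.
#' @param schema one of the schema names above.
#' @param name signature name when `schema = "signature"`.
#' @return typed data.frame (or `gene_signature` / centroid matrix).
#' @export
read_table <- function(path,
                       schema = c("signature", "centroids", "clinical",
                                  "survival", "batch", "calls"),
                       name = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = "NA",
                   fileEncoding = "UTF-8")
  need <- function(cols) {
    missing_cols <- setdiff(cols, names(df))
    if (length(missing_cols)) {
      stop(schema, " table ", path, " is missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  switch(schema,
    signature = {
      need("gene_symbol")
      probe_map <- if ("probe_id" %in% names(df)) {
        df[!is.na(df$probe_id), c("probe_id", "gene_symbol")]
      }
      gene_signature(name %||% sub("\\.[^.]*$", "", basename(path)),
                     unique(df$gene_symbol), probe_map)
    },
    centroids = {
      need("gene_symbol")
      subtype_cols <- setdiff(names(df), "gene_symbol")
      if (!identical(subtype_cols, SUBTYPE_LABELS)) {
        stop("centroid table must have exactly the subtype columns ",
             paste(SUBTYPE_LABELS, collapse = ", "), " in order; found: ",
             paste(subtype_cols, collapse = ", "), call. = FALSE)
      }
      m <- as.matrix(df[SUBTYPE_LABELS])
      rownames(m) <- df$gene_symbol
      validate_centroid_set(m, arg = path)
      m
    },
    clinical = {
      need(c("sample_id", names(CLINICAL_LEVELS)))
      for (f in names(CLINICAL_LEVELS)) {
        v <- as.character(df[[f]])
        bad <- unique(v[!is.na(v) & !(v %in% CLINICAL_LEVELS[[f]])])
        if (length(bad)) {
          stop("clinical column '", f, "': unknown token(s) ",
               paste(sQuote(bad), collapse = ", "), "; allowed: ",
               paste(CLINICAL_LEVELS[[f]], collapse = ", "), " or NA",
               call. = FALSE)
        }
        df[[f]] <- v
      }
      validate_clinical(df)
      df[c("sample_id", names(CLINICAL_LEVELS))]
    },
    survival = {
      need(c("sample_id", "time", "event"))
      df$time <- as.numeric(df$time)
      df$event <- as.integer(df$event)
      validate_survival(df)
      df[c("sample_id", "time", "event")]
    },
    batch = {
      need(c("sample_id", "batch"))
      validate_batch_design(df)
      df[c("sample_id", "batch")]
    },
    calls = {
      rho_cols <- paste0("rho_", SUBTYPE_LABELS)
      need(c("sample_id", "label", rho_cols, "threshold", "tie_flag"))
      bad <- unique(df$label[!(df$label %in% CALL_LABELS)])
      if (length(bad)) {
        stop("calls table: unknown label(s) ",
             paste(sQuote(bad), collapse = ", "), call. = FALSE)
      }
      df$tie_flag <- as.logical(df$tie_flag)
      df[c("sample_id", "label", rho_cols, "threshold", "tie_flag")]
    })
}

validate_clinical <- function(df) {
  if (anyDuplicated(df$sample_id)) {
    stop("clinical table has duplicated sample identifiers", call. = FALSE)
  }
  invisible(df)
}

validate_survival <- function(df) {
  if (anyNA(df$time) || any(df$time < 0)) {
    stop("survival time must be a non-negative number of months", call. = FALSE)
  }
  if (anyNA(df$event) || !all(df$event %in% c(0L, 1L))) {
    stop("survival event must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  if (anyDuplicated(df$sample_id)) {
    stop("survival table has duplicated sample identifiers", call. = FALSE)
  }
  invisible(df)
}

#' Write a typed tab-delimited table
#'
#' Inverse of [read_table()]; numeric columns are written with 17
#' significant digits and missing categories as the token `NA`.
#'
#' @param x data.frame, `gene_signature`, or centroid matrix.
#' @param path output file.
#' @param schema schema name as in [read_table()].
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path,
                        schema = c("signature", "centroids", "clinical",
                                   "survival", "batch", "calls")) {
  schema <- match.arg(schema)
  if (schema == "signature") {
    df <- if (is.null(x$probe_map)) {
      data.frame(gene_symbol = x$gene_symbols)
    } else {
      data.frame(probe_id = x$probe_map$probe_id,
                 gene_symbol = x$probe_map$gene_symbol)
    }
    x <- df
  } else if (schema == "centroids") {
    validate_centroid_set(x)
    x <- data.frame(gene_symbol = rownames(x), as.data.frame(x),
                    check.names = FALSE)
  }
  num <- vapply(x, is.numeric, logical(1L))
  x[num] <- lapply(x[num], function(v) {
    out <- sprintf("%.17g", v)
    out[is.na(v)] <- "NA"
    out
  })
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
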