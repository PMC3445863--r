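#' Validate a pipeline configuration
#'
#' Checks the structure of a [run_full()] configuration and reports every
#' violation at once (character vector of messages; empty means valid).
#'
#' A configuration is a list with:
#' \describe{
#'   \item{expression / batches}{matrix (or TSV path) plus 2-level batch
#'     design — or instead `simulation`, a [sim_config()] whose cohort
#'     stands in for real data.}
#'   \item{signatures}{named list; each element either
#'     `list(centroids = <matrix or path>)` or `list(training =, labels =,
#'     signature =)` for [compute_centroids()].}
#'   \item{adjustments}{subset of `"none"`, `"center"`, `"dwd"`.}
#'   \item{threshold, min_genes}{classifier settings (defaults 0.1, 10).}
#'   \item{clinical, survival}{optional record tables for the association
#'     and survival stages.}
#' }
#'
#' @param config configuration list.
#' @return character vector of error messages (length 0 if valid).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  if (!is.list(config)) return("config must be a list")
  if (is.null(config$simulation) && is.null(config$expression)) {
    add("config$expression (or config$simulation) is required")
  }
  if (!is.null(config$simulation) && !inherits(config$simulation, "sim_config")) {
    add("config$simulation must be a sim_config object")
  }
  if (!is.null(config$expression) && is.null(config$batches) &&
      "dwd" %in% (config$adjustments %||% character(0))) {
    add("config$batches is required for DWD adjustment of supplied expression data")
  }
  if (is.null(config$signatures) || !length(config$signatures)) {
    add("config$signatures must name at least one signature")
  } else if (is.null(names(config$signatures)) ||
             any(!nzchar(names(config$signatures)))) {
    add("config$signatures must be a named list")
  } else {
    for (nm in names(config$signatures)) {
      sg <- config$signatures[[nm]]
      has_centroids <- !is.null(sg$centroids)
      has_training <- !is.null(sg$training) && !is.null(sg$labels) &&
        !is.null(sg$signature)
      if (!has_centroids && !has_training) {
        add(sprintf("config$signatures$%s needs centroids or training+labels+signature", nm))
      }
    }
  }
  adj <- config$adjustments %||% c("none", "center", "dwd")
  bad_adj <- setdiff(adj, c("none", "center", "dwd"))
  if (length(bad_adj)) {
    add(paste0("config$adjustments: unknown token(s) ",
               paste(bad_adj, collapse = ", ")))
  }
  thr <- config$threshold %||% 0.1
  if (!is.numeric(thr) || length(thr) != 1L || thr < -1 || thr > 1) {
    add("config$threshold must be a single number in [-1, 1]")
  }
  mg <- config$min_genes %||% 10L
  if (!is.numeric(mg) || mg < 1) add("config$min_genes must be >= 1")
  errs
}

load_matrix_arg <- function(x, dialect = "tsv") {
  if (is.character(x) && length(x) == 1L) {
    read_expression_matrix(x, dialect = dialect)
  } else x
}

load_table_arg <- function(x, schema) {
  if (is.character(x) && length(x) == 1L) read_table(x, schema = schema) else x
}

#' Run the full consistency analysis
#'
#' Orchestrates the whole workflow: obtain a cohort (simulated or
#' supplied), classify it against each signature's centroids under each
#' bias-adjustment regime, tabulate the subtype distributions, compute
#' pairwise agreement (unweighted kappa) between every pair of
#' signature-by-adjustment call sets, extract the multi-way consistent
#' samples and their clinical association tables, and optionally run the
#' subtype survival comparison. The run is deterministic given the
#' configuration.
#'
#' @param config configuration list (see [validate_config()]).
#' @param out_dir optional directory; when given, per-cell call TSVs and a
#'   `report.json` are written there.
#' @return report list: `cells` (per signature x adjustment: calls and
#'   distribution), `agreement` (per pair), `consistent_samples`,
#'   `clinical_tables`, `survival`, `config_digest`.
#' @export
run_full <- function(config, out_dir = NULL) {
  errs <- validate_config(config)
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  threshold <- config$threshold %||% 0.1
  min_genes <- config$min_genes %||% 10L
  adjustments <- config$adjustments %||% c("none", "center", "dwd")
  unclassified <- config$unclassified %||% "category"

  # --- stage: inputs ------------------------------------------------------
  if (!is.null(config$simulation)) {
    sim <- simulate_cohort(config$simulation)
    expr <- sim$matrix
    batches <- sim$batches
    truth <- sim$labels
  } else {
    expr <- load_matrix_arg(config$expression,
                            dialect = config$dialect %||% "tsv")
    batches <- load_table_arg(config$batches, "batch")
    truth <- NULL
  }
  validate_expression_matrix(expr)
  if (!is.null(config$probe_map)) {
    expr <- collapse_probes(expr, config$probe_map)
  }
  message("input: ", nrow(expr), " genes x ", ncol(expr), " samples")

  # --- stage: signatures --------------------------------------------------
  centroid_sets <- lapply(names(config$signatures), function(nm) {
    sg <- config$signatures[[nm]]
    if (!is.null(sg$centroids)) {
      cs <- if (is.character(sg$centroids)) {
        read_table(sg$centroids, "centroids")
      } else sg$centroids
      validate_centroid_set(cs, arg = paste0("signatures$", nm))
      cs
    } else {
      compute_centroids(load_matrix_arg(sg$training), sg$labels, sg$signature)
    }
  })
  names(centroid_sets) <- names(config$signatures)

  # --- stage: adjustment regimes -----------------------------------------
  dwd_model <- NULL
  adjusted <- lapply(adjustments, function(a) {
    switch(a,
      none = expr,
      center = mean_center_genes(expr, method = config$center_method %||% "mean"),
      dwd = {
        validate_batch_design(batches, sample_ids = colnames(expr),
                              require_two = TRUE)
        dwd_model <<- fit_dwd(expr, batches, cost = config$dwd_cost %||% "auto")
        dwd_adjust(expr, dwd_model)
      })
  })
  names(adjusted) <- adjustments

  # --- stage: classification ---------------------------------------------
  cells <- list()
  for (nm in names(centroid_sets)) {
    for (a in adjustments) {
      key <- paste(nm, a, sep = ".")
      calls <- classify_cohort(adjusted[[a]], centroid_sets[[nm]],
                               threshold = threshold, min_genes = min_genes)
      dist <- subtype_distribution(calls)
      message("cell ", key, ": ", dist[["Unclassified"]], " unclassified")
      cells[[key]] <- list(signature = nm, adjustment = a, calls = calls,
                           distribution = dist)
    }
  }

  # --- stage: agreement ---------------------------------------------------
  keys <- names(cells)
  agreement_results <- list()
  if (length(keys) > 1L) {
    for (ij in combn(length(keys), 2L, simplify = FALSE)) {
      k1 <- keys[[ij[[1L]]]]; k2 <- keys[[ij[[2L]]]]
      ar <- agreement(cells[[k1]]$calls, cells[[k2]]$calls,
                      unclassified = unclassified)
      agreement_results[[paste(k1, k2, sep = " vs ")]] <- ar
    }
  }

  consistent <- if (length(keys) > 1L) {
    multi_way_consistent(lapply(cells, `[[`, "calls"))
  } else cells[[1L]]$calls$sample_id[cells[[1L]]$calls$label != "Unclassified"]

  # --- stage: clinical / survival ----------------------------------------
  clinical <- load_table_arg(config$clinical, "clinical")
  if (is.null(clinical) && !is.null(config$simulation) && !is.null(truth)) {
    clinical <- simulate_clinical(truth, config$simulation)
  }
  ref_calls <- cells[[1L]]$calls
  clinical_tables <- if (!is.null(clinical) && length(consistent)) {
    cc <- ref_calls[ref_calls$sample_id %in% consistent, , drop = FALSE]
    clinical_by_subtype(cc, clinical)
  }

  surv <- load_table_arg(config$survival, "survival")
  if (is.null(surv) && !is.null(config$simulation) && !is.null(truth) &&
      isTRUE(config$simulate_survival)) {
    surv <- simulate_survival(truth, config$simulation)
  }
  survival_result <- if (!is.null(surv)) {
    survival_by_subtype(ref_calls, surv, clinical = clinical,
                        filter = config$survival_filter)
  }

  report <- list(
    cells = cells,
    agreement = agreement_results,
    consistent_samples = consistent,
    clinical_tables = clinical_tables,
    survival = survival_result,
    truth = truth,
    dwd_model = dwd_model,
    settings = list(threshold = threshold, min_genes = min_genes,
                    adjustments = adjustments, unclassified = unclassified,
                    seed = config$simulation$seed %||% NA_integer_)
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  invisible(report)
}

# Persist a run_full() report: one calls TSV per cell plus a JSON summary
# from which every reported number is recomputable.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(report$cells)) {
    write_table(report$cells[[key]]$calls,
                file.path(out_dir, paste0("calls_", gsub("[^A-Za-z0-9_.-]", "_", key), ".tsv")),
                schema = "calls")
  }
  json <- list(
    settings = report$settings,
    distributions = lapply(report$cells, function(cell) {
      as.list(setNames(as.integer(cell$distribution), names(cell$distribution)))
    }),
    agreement = lapply(report$agreement, function(ar) {
      list(kappa = ar$kappa, se = ar$se, ci = c(ar$ci_low, ar$ci_high),
           n = ar$n, table = unclass(ar$table))
    }),
    consistent_samples = report$consistent_samples
  )
  writeLines(jsonlite::toJSON(json, auto_unbox = TRUE, digits = 10, pretty = TRUE),
             file.path(out_dir, "report.json"))
  invisible(out_dir)
}
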