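#' Kaplan-Meier curve
#'
#' Product-limit estimate of event-free survival. The curve starts at 1,
#' steps down only at event times, and censoring shrinks the risk set
#' without a step. Backed by [survival::survfit()].
#'
#' @param records survival data.frame (`sample_id`, `time` in months,
#'   `event` 0/1).
#' @return data.frame `time`, `n_risk`, `n_event`, `n_censor`, `surv`,
#'   beginning with the `time = 0, surv = 1` anchor row.
#' @export
km_curve <- function(records) {
  validate_survival(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           data = records, conf.type = "none")
  s <- summary(fit, censored = TRUE)
  out <- data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                    n_censor = s$n.censor, surv = s$surv)
  if (!nrow(out) || out$time[[1L]] > 0) {
    out <- rbind(data.frame(time = 0, n_risk = nrow(records), n_event = 0,
                            n_censor = 0, surv = 1), out)
  }
  out
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square across >= 2 groups
#' with the hypergeometric variance at (tied) event times, df = groups - 1.
#' Backed by [survival::survdiff()] (rho = 0).
#'
#' @param groups either a named list of survival data.frames, or a single
#'   survival data.frame plus a `group` vector/column.
#' @param group grouping vector when `groups` is one data.frame.
#' @return list `statistic`, `df`, `p_value`, `n`, `observed`, `expected`
#'   (per group).
#' @export
logrank_test <- function(groups, group = NULL) {
  if (is.data.frame(groups)) {
    df <- groups
    g <- group %||% df$group
    if (is.null(g)) stop("supply a group vector or column", call. = FALSE)
  } else {
    if (length(groups) < 2L) stop("need >= 2 groups", call. = FALSE)
    nm <- names(groups) %||% as.character(seq_along(groups))
    df <- do.call(rbind, groups)
    g <- rep(nm, vapply(groups, nrow, integer(1L)))
  }
  # same record may legitimately appear in several comparisons; only the
  # time/event invariants are enforced here
  if (anyNA(df$time) || any(df$time < 0)) {
    stop("survival time must be a non-negative number of months", call. = FALSE)
  }
  if (anyNA(df$event) || !all(df$event %in% c(0L, 1L))) {
    stop("survival event must be 0 (censored) or 1 (event)", call. = FALSE)
  }
  g <- as.character(g)
  if (length(g) != nrow(df)) stop("group length mismatch", call. = FALSE)
  if (length(unique(g)) < 2L) stop("need >= 2 groups", call. = FALSE)
  if (sum(df$event) < 1L) {
    stop("log-rank statistic undefined with zero events", call. = FALSE)
  }
  df$group <- g
  fit <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- length(fit$n)
  list(statistic = unname(fit$chisq), df = k - 1L,
       p_value = pchisq(fit$chisq, df = k - 1L, lower.tail = FALSE),
       n = unname(fit$n), observed = fit$obs, expected = fit$exp)
}

#' Survival comparison across subtype calls
#'
#' Joins calls with survival records, optionally filters on a clinical
#' covariate (e.g. `er = "negative"`) and restricts to chosen subtypes,
#' then returns per-group KM curves and the log-rank test. Subgroup
#' analyses are this same path with a filter, not a separate code path.
#'
#' @param calls calls data.frame.
#' @param surv survival data.frame.
#' @param clinical optional clinical records for filtering.
#' @param filter optional named list of clinical values that must match,
#'   e.g. `list(er = "negative")`.
#' @param subtypes subtype labels to compare (default: all labels present,
#'   `Unclassified` excluded).
#' @return list `km` (named list of KM curves), `logrank`, `n` per group.
#' @export
survival_by_subtype <- function(calls, surv, clinical = NULL, filter = NULL,
                                subtypes = NULL) {
  idx <- match(calls$sample_id, surv$sample_id)
  keep <- !is.na(idx)
  df <- data.frame(sample_id = calls$sample_id[keep],
                   label = calls$label[keep],
                   time = surv$time[idx[keep]],
                   event = surv$event[idx[keep]],
                   stringsAsFactors = FALSE)
  if (!is.null(filter)) {
    if (is.null(clinical)) stop("filter requires clinical records", call. = FALSE)
    cl <- clinical[match(df$sample_id, clinical$sample_id), , drop = FALSE]
    for (f in names(filter)) {
      df <- df[!is.na(cl[[f]]) & cl[[f]] == filter[[f]], , drop = FALSE]
      cl <- cl[!is.na(cl[[f]]) & cl[[f]] == filter[[f]], , drop = FALSE]
    }
  }
  subtypes <- subtypes %||% setdiff(unique(df$label), "Unclassified")
  df <- df[df$label %in% subtypes, , drop = FALSE]
  if (!nrow(df)) stop("no samples left after filtering", call. = FALSE)
  km <- lapply(split(df, df$label), km_curve)
  lr <- if (length(unique(df$label)) >= 2L && sum(df$event) >= 1L) {
    logrank_test(df, group = df$label)
  }
  list(km = km, logrank = lr, n = table(df$label))
}
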