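#' Default subtype-conditional clinical probability tables
#'
#' P(category | subtype) per clinical feature, with the subtype-specific
#' probabilities taken from the observed cross-tabulation of a 117-sample
#' consistently-subtyped Han Chinese cohort (e.g. no ER-positive basal-like
#' tumours; 18/21 HER2-enriched tumours HER2 over-expressed).
#'
#' @return named list (er, her2, grade, nodal, lvi) of category x subtype
#'   probability matrices; every subtype column sums to 1.
#' @export
default_clinical_conditionals <- function() {
  cond <- function(counts) {
    m <- do.call(cbind, counts)[, SUBTYPE_LABELS, drop = FALSE]
    sweep(m, 2L, colSums(m), "/")
  }
  list(
    er = cond(list(
      LumA = c(positive = 35, negative = 0),
      LumB = c(positive = 15, negative = 1),
      Normal = c(positive = 2, negative = 4),
      Her2E = c(positive = 3, negative = 18),
      Basal = c(positive = 0, negative = 39))),
    her2 = cond(list(
      LumA = c(`over-expressed` = 2, not = 33),
      LumB = c(`over-expressed` = 5, not = 11),
      Normal = c(`over-expressed` = 2, not = 4),
      Her2E = c(`over-expressed` = 18, not = 3),
      Basal = c(`over-expressed` = 2, not = 37))),
    grade = cond(list(
      LumA = c(I = 17, II = 16, III = 2),
      LumB = c(I = 0, II = 4, III = 12),
      Normal = c(I = 1, II = 2, III = 3),
      Her2E = c(I = 0, II = 4, III = 17),
      Basal = c(I = 0, II = 2, III = 37))),
    nodal = cond(list(
      LumA = c(positive = 16, negative = 19),
      LumB = c(positive = 9, negative = 7),
      Normal = c(positive = 5, negative = 1),
      Her2E = c(positive = 14, negative = 7),
      Basal = c(positive = 10, negative = 29))),
    lvi = cond(list(
      LumA = c(positive = 14, negative = 21),
      LumB = c(positive = 11, negative = 5),
      Normal = c(positive = 4, negative = 2),
      Her2E = c(positive = 13, negative = 8),
      Basal = c(positive = 11, negative = 28)))
  )
}

#' Simulation configuration
#'
#' Full parameterization of a synthetic two-site cohort with intrinsic
#' subtype structure. Defaults mirror the 169-sample Han Chinese cohort
#' the pipeline was designed around: 169 samples split across the five
#' subtypes, a 125/169 second-site fraction, centroid dispersion `tau = 1`
#' log2 units with within-subtype noise `sigma = 0.5 tau`, a gene-wise
#' additive site shift of sd `batch_beta`, clinical covariates drawn from
#' [default_clinical_conditionals()], and subtype-dependent exponential
#' survival with uniform administrative censoring.
#'
#' @param n_genes intrinsic panel size (default 50).
#' @param subtype_sizes named or positional counts per subtype in
#'   [SUBTYPE_LABELS] order (default `c(58, 32, 8, 30, 41)`, n = 169).
#' @param tau sd of centroid entries, log2 units (default 1.0).
#' @param sigma within-subtype per-gene noise sd (default 0.5).
#' @param batch_beta sd of the per-gene additive shift applied to site-2
#'   samples (default 1.0; systemic bias shared by the whole site, not
#'   per-sample noise).
#' @param batch_fraction fraction of samples assigned to site 2 (default
#'   125/169).
#' @param clinical_conditionals list of P(category | subtype) matrices.
#' @param hazards per-subtype exponential event rates per month (defaults
#'   chosen to qualitatively order luminal A best and luminal B /
#'   HER2-enriched worst; they are generator knobs, not estimates).
#' @param censor_time_max uniform administrative censoring bound, months
#'   (default 62).
#' @param seed integer RNG seed.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 50L,
                       subtype_sizes = c(LumA = 58L, LumB = 32L, Normal = 8L,
                                         Her2E = 30L, Basal = 41L),
                       tau = 1.0,
                       sigma = 0.5,
                       batch_beta = 1.0,
                       batch_fraction = 125 / 169,
                       clinical_conditionals = default_clinical_conditionals(),
                       hazards = c(LumA = 0.004, LumB = 0.015, Normal = 0.006,
                                   Her2E = 0.015, Basal = 0.008),
                       censor_time_max = 62,
                       seed = 1L) {
  if (is.null(names(subtype_sizes))) names(subtype_sizes) <- SUBTYPE_LABELS
  subtype_sizes <- subtype_sizes[SUBTYPE_LABELS]
  if (anyNA(subtype_sizes) || any(subtype_sizes < 0) ||
      sum(subtype_sizes) < 1) {
    stop("subtype_sizes must be 5 non-negative counts summing to >= 1",
         call. = FALSE)
  }
  if (n_genes < 1L) stop("n_genes must be positive", call. = FALSE)
  for (p in c(tau = tau, sigma = sigma, batch_beta = batch_beta)) {
    if (!is.finite(p) || p < 0) stop("sds must be >= 0", call. = FALSE)
  }
  if (batch_fraction < 0 || batch_fraction > 1) {
    stop("batch_fraction must lie in [0, 1]", call. = FALSE)
  }
  for (f in names(clinical_conditionals)) {
    m <- clinical_conditionals[[f]]
    if (!all(SUBTYPE_LABELS %in% colnames(m))) {
      stop("clinical conditional '", f, "' must cover all 5 subtypes",
           call. = FALSE)
    }
    if (any(abs(colSums(m[, SUBTYPE_LABELS]) - 1) > 1e-9)) {
      stop("clinical conditional '", f,
           "': probabilities must sum to 1 per subtype", call. = FALSE)
    }
  }
  if (is.null(names(hazards))) names(hazards) <- SUBTYPE_LABELS
  hazards <- hazards[SUBTYPE_LABELS]
  if (anyNA(hazards) || any(hazards <= 0)) {
    stop("hazards must be positive for all 5 subtypes", call. = FALSE)
  }
  if (censor_time_max <= 0) stop("censor_time_max must be positive", call. = FALSE)
  seed <- as.integer(seed)
  structure(list(
    n_genes = as.integer(n_genes), subtype_sizes = subtype_sizes,
    tau = tau, sigma = sigma, batch_beta = batch_beta,
    batch_fraction = batch_fraction,
    clinical_conditionals = clinical_conditionals,
    hazards = hazards, censor_time_max = censor_time_max, seed = seed
  ), class = "sim_config")
}

with_sim_seed <- function(seed, offset, code) {
  rng <- get_rng_state()
  on.exit(restore_rng_state(rng))
  set.seed((seed + offset) %% .Machine$integer.max)
  code
}

#' Simulate subtype centroids
#'
#' Centroid entries are drawn independently Normal(0, tau^2) on the log2
#' scale; the five centroids are therefore mutually uncorrelated rank
#' profiles, the idealized geometry the nearest-centroid predictor
#' assumes.
#'
#' @param config a [sim_config()].
#' @return genes x 5 centroid matrix (deterministic given the seed).
#' @export
simulate_centroids <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, 0L, {
    m <- matrix(rnorm(config$n_genes * 5L, sd = config$tau),
                nrow = config$n_genes, ncol = 5L,
                dimnames = list(sprintf("g%04d", seq_len(config$n_genes)),
                                SUBTYPE_LABELS))
    validate_centroid_set(m)
    m
  })
}

#' Simulate a two-site cohort
#'
#' Each sample is its subtype centroid plus independent Normal(0, sigma^2)
#' noise per gene. A fixed fraction of samples belongs to site 2, and all
#' site-2 samples share one per-gene shift drawn Normal(0, batch_beta^2):
#' a systemic additive bias, the artefact that gene centring and DWD are
#' meant to remove.
#'
#' @param config a [sim_config()].
#' @param centroids genes x 5 centroid matrix (default: simulated from the
#'   config).
#' @return list `matrix` (genes x samples), `labels` (named character
#'   vector of true subtypes), `batches` (data.frame `sample_id`,
#'   `batch` in `site1`/`site2`), `batch_shift` (per-gene site-2 shift).
#' @export
simulate_cohort <- function(config, centroids = simulate_centroids(config)) {
  stopifnot(inherits(config, "sim_config"))
  validate_centroid_set(centroids)
  n <- sum(config$subtype_sizes)
  labels <- rep(SUBTYPE_LABELS, config$subtype_sizes)
  ids <- sprintf("S%04d", seq_len(n))
  with_sim_seed(config$seed, 1L, {
    noise <- matrix(rnorm(nrow(centroids) * n, sd = config$sigma),
                    nrow = nrow(centroids))
    X <- centroids[, labels, drop = FALSE] + noise
    dimnames(X) <- list(rownames(centroids), ids)
    n2 <- round(n * config$batch_fraction)
    site2 <- sample(n, n2)
    batch <- rep("site1", n)
    batch[site2] <- "site2"
    shift <- rnorm(nrow(centroids), sd = config$batch_beta)
    X[, site2] <- X[, site2, drop = FALSE] + shift
    list(matrix = X,
         labels = setNames(labels, ids),
         batches = data.frame(sample_id = ids, batch = batch,
                              stringsAsFactors = FALSE),
         batch_shift = setNames(shift, rownames(centroids)))
  })
}

#' Simulate subtype-conditional clinical covariates
#'
#' Each feature of each sample is drawn independently from the configured
#' P(category | subtype) table.
#'
#' @param labels named character vector of true subtype labels.
#' @param config a [sim_config()].
#' @return clinical records data.frame (deterministic given the seed).
#' @export
simulate_clinical <- function(labels, config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, 2L, {
    out <- data.frame(sample_id = names(labels), stringsAsFactors = FALSE)
    for (f in names(config$clinical_conditionals)) {
      m <- config$clinical_conditionals[[f]]
      out[[f]] <- vapply(labels, function(k) {
        sample(rownames(m), 1L, prob = m[, k])
      }, character(1L), USE.NAMES = FALSE)
    }
    out
  })
}

#' Simulate subtype-dependent survival
#'
#' Event times are exponential with the subtype's hazard; censoring times
#' are uniform on (0, censor_time_max); the observed time is the minimum
#' and the event indicator marks events observed before censoring.
#'
#' @inheritParams simulate_clinical
#' @return survival records data.frame (deterministic given the seed).
#' @export
simulate_survival <- function(labels, config) {
  stopifnot(inherits(config, "sim_config"))
  with_sim_seed(config$seed, 3L, {
    rate <- config$hazards[labels]
    t_event <- rexp(length(labels), rate = rate)
    t_cens <- runif(length(labels), 0, config$censor_time_max)
    data.frame(sample_id = names(labels),
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               stringsAsFactors = FALSE)
  })
}
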