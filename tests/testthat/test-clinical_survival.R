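# Clinical table of the 117-sample consistently-subtyped cohort, rebuilt in
# code from its per-subtype cross-tabulation (joint assignment within a
# subtype column is arbitrary; the tables only use per-column counts).
consistent_cohort_fixture <- function() {
  counts <- list(  # per subtype: er+, her2 over, grade (I, II, III), nodal+, lvi+
    LumA   = list(n = 35, er = 35, her2 = 2, grade = c(17, 16, 2), nodal = 16, lvi = 14),
    LumB   = list(n = 16, er = 15, her2 = 5, grade = c(0, 4, 12), nodal = 9, lvi = 11),
    Normal = list(n = 6,  er = 2,  her2 = 2, grade = c(1, 2, 3),  nodal = 5, lvi = 4),
    Her2E  = list(n = 21, er = 3,  her2 = 18, grade = c(0, 4, 17), nodal = 14, lvi = 13),
    Basal  = list(n = 39, er = 0,  her2 = 2, grade = c(0, 2, 37), nodal = 10, lvi = 11)
  )
  rows <- lapply(names(counts), function(k) {
    ct <- counts[[k]]
    fill <- function(pos, levels, n = ct$n) rep(levels, c(pos, n - sum(pos)))
    data.frame(
      sample_id = sprintf("%s_%02d", k, seq_len(ct$n)),
      label = k,
      er = fill(ct$er, c("positive", "negative")),
      her2 = fill(ct$her2, c("over-expressed", "not")),
      grade = fill(ct$grade[1:2], c("I", "II", "III")),
      nodal = fill(ct$nodal, c("positive", "negative")),
      lvi = fill(ct$lvi, c("positive", "negative")),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("clinical_by_subtype reproduces the consistent-cohort cross-tabs", {
  fx <- consistent_cohort_fixture()
  calls <- make_calls(fx$sample_id, fx$label)
  tabs <- clinical_by_subtype(calls, fx)
  er <- tabs$er$counts
  expect_equal(er["positive", "Basal"], 0)
  expect_equal(tabs$er$proportions["positive", "Basal"], 0)      # 0/39
  expect_equal(er["positive", "LumA"], 35)
  expect_equal(tabs$er$proportions["positive", "LumA"], 1)       # 35/35
  expect_equal(tabs$her2$counts["over-expressed", "Her2E"], 18)
  expect_equal(tabs$her2$proportions["over-expressed", "Her2E"], 18 / 21)
  expect_equal(unname(colSums(er)[SUBTYPE_LABELS]), c(35, 16, 6, 21, 39))
  expect_equal(tabs$er$missing, 0)
  expect_error(clinical_by_subtype(calls, fx, features = "ki67"),
               "unknown clinical feature")
  expect_error(clinical_by_subtype(make_calls("zzz", "LumA"), fx),
               "missing for sample")
})

test_that("all-missing feature yields empty counts and a full missing count", {
  fx <- consistent_cohort_fixture()
  fx$lvi <- NA_character_
  calls <- make_calls(fx$sample_id, fx$label)
  tabs <- clinical_by_subtype(calls, fx, features = "lvi")
  expect_equal(sum(tabs$lvi$counts), 0)
  expect_equal(tabs$lvi$missing, nrow(fx))
})

test_that("marginal_summary reproduces printed pooled demographics", {
  tw <- read_table(extdata("clinical_taiwan_marginals_synthetic.tsv"), "clinical")
  cn <- read_table(extdata("clinical_china_marginals_synthetic.tsv"), "clinical")
  pooled <- rbind(tw, cn)
  s <- marginal_summary(pooled)
  expect_equal(s$er$count, c(96L, 73L))
  expect_equal(s$er$percent, c(57L, 43L))
  expect_equal(s$her2$percent, c(30L, 70L))
  expect_equal(s$grade$percent, c(18L, 29L, 53L))
  expect_equal(s$nodal$percent, c(50L, 50L))
  # one unrecorded lymphovascular case: denominator 168, 73/168 -> 43
  expect_equal(s$lvi$count, c(73L, 95L))
  expect_equal(s$lvi$denominator, c(168L, 168L))
  expect_equal(s$lvi$missing, c(1L, 1L))
  expect_equal(s$lvi$percent, c(43L, 57L))
  # per-site spot checks
  expect_equal(marginal_summary(tw)$er$percent, c(50L, 50L))
  expect_equal(marginal_summary(cn)$er$percent, c(59L, 41L))
  expect_equal(marginal_summary(tw)$lvi$percent, c(63L, 37L))
  # degenerate single-category input
  one <- data.frame(sample_id = "s", er = "positive", her2 = "not",
                    grade = "II", nodal = "negative", lvi = "negative")
  expect_equal(marginal_summary(one)$er$percent, c(100L, 0L))
  expect_error(marginal_summary(one[0, ]), "no clinical records")
})

test_that("half-up integer rounding (not banker's) is used for percentages", {
  # 74/125 = 59.2 -> 59 ; 61/169*... pick 0.5 boundary: 1/8 = 12.5 -> 13
  df <- data.frame(sample_id = sprintf("s%d", 1:8),
                   er = rep(c("positive", "negative"), c(1, 7)),
                   her2 = "not", grade = "I", nodal = "positive",
                   lvi = "positive", stringsAsFactors = FALSE)
  expect_equal(marginal_summary(df)$er$percent, c(13L, 88L))
})

test_that("ihc_surrogate follows the ER/HER2 dominance rule", {
  cl <- data.frame(
    sample_id = sprintf("s%d", 1:5),
    er = c("positive", "negative", "negative", NA, "negative"),
    her2 = c("over-expressed", "over-expressed", "not", "not", NA),
    stringsAsFactors = FALSE)
  expect_identical(ihc_surrogate(cl),
                   c("luminal-like", "HER2-like", "triple-negative-like",
                     "unknown", "unknown"))
})

test_that("km_curve matches the hand product-limit example", {
  rec <- data.frame(sample_id = 1:3, time = c(1, 2, 3), event = c(1, 0, 1))
  km <- km_curve(rec)
  expect_equal(km$surv[km$time == 0], 1)
  expect_equal(km$surv[km$time == 1], 2 / 3)
  expect_equal(km$surv[km$time == 2], 2 / 3)  # censoring: no step
  expect_equal(km$surv[km$time == 3], 0)
  # all censored -> survival identically 1
  kc <- km_curve(data.frame(sample_id = 1:4, time = 1:4, event = 0))
  expect_true(all(kc$surv == 1))
  # duplicate event times collapse into a single step
  kd <- km_curve(data.frame(sample_id = 1:4, time = c(2, 2, 2, 5),
                            event = c(1, 1, 1, 0)))
  expect_equal(sum(kd$time == 2), 1)
  expect_equal(kd$surv[kd$time == 2], 1 / 4)
  # non-increasing, S(0) = 1
  set.seed(41)
  kr <- km_curve(data.frame(sample_id = 1:50, time = rexp(50, 0.05),
                            event = rbinom(50, 1, 0.6)))
  expect_true(all(diff(kr$surv) <= 1e-12))
  expect_equal(kr$surv[1], 1)
})

test_that("logrank_test matches the hand-built risk-table example", {
  A <- data.frame(sample_id = c("a1", "a2"), time = c(1, 4), event = c(1, 1))
  B <- data.frame(sample_id = c("b1", "b2"), time = c(2, 5), event = c(1, 0))
  # risk tables at event times 1, 2, 4:
  #  t=1: n=4 (2 in A), event in A -> E_A = 1/2, V = 1/4
  #  t=2: n=3 (1 in A), event in B -> E_A = 1/3, V = 2/9
  #  t=4: n=2 (1 in A), event in A -> E_A = 1/2, V = 1/4
  # U = O_A - E_A = 2 - 4/3 = 2/3; chi2 = U^2 / (13/18) = 8/13
  lr <- logrank_test(list(A = A, B = B))
  expect_equal(lr$statistic, 8 / 13, tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  expect_equal(lr$p_value, pchisq(8 / 13, 1, lower.tail = FALSE))
  # identical groups -> statistic 0, p = 1
  same <- logrank_test(list(x = A, y = A))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1)
  # df rule for 5 groups
  set.seed(43)
  gs <- lapply(1:5, function(i) data.frame(
    sample_id = sprintf("g%d_%d", i, 1:10),
    time = rexp(10, 0.1), event = rbinom(10, 1, 0.7)))
  expect_equal(logrank_test(gs)$df, 4L)
  # zero events is an error
  A0 <- A; A0$event <- 0L
  B0 <- B; B0$event <- 0L
  expect_error(logrank_test(list(A0, B0)), "zero events")
  expect_error(logrank_test(list(A)), ">= 2 groups")
})

test_that("log-rank type-I error is calibrated under equal hazards", {
  set.seed(47)
  n_rep <- 1000L
  rejections <- 0L
  for (r in seq_len(n_rep)) {
    df <- data.frame(sample_id = sprintf("s%d", 1:50),
                     time = pmin(rexp(50, 0.02), 60),
                     event = NA_integer_)
    te <- rexp(50, 0.02)
    tc <- runif(50, 0, 60)
    df$time <- pmin(te, tc)
    df$event <- as.integer(te <= tc)
    if (sum(df$event) == 0) next
    lr <- logrank_test(df, group = rep(c("x", "y"), each = 25))
    if (lr$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / n_rep, 0.03)
  expect_lte(rejections / n_rep, 0.07)
})

test_that("log-rank power at hazard ratio 3 (n = 20 + 20) is adequate", {
  set.seed(53)
  n_rep <- 500L
  rejections <- 0L
  for (r in seq_len(n_rep)) {
    te <- c(rexp(20, 0.01), rexp(20, 0.03))
    tc <- runif(40, 0, 120)
    df <- data.frame(sample_id = sprintf("s%d", 1:40),
                     time = pmin(te, tc), event = as.integer(te <= tc))
    lr <- logrank_test(df, group = rep(c("lo", "hi"), each = 20))
    if (lr$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / n_rep, 0.6)
})

test_that("survival_by_subtype filters express subgroup analyses", {
  cfg <- sim_config(seed = 61, subtype_sizes = c(20, 20, 5, 15, 15),
                    batch_beta = 0)
  coh <- simulate_cohort(cfg)
  calls <- make_calls(names(coh$labels), unname(coh$labels))
  cl <- simulate_clinical(coh$labels, cfg)
  sv <- simulate_survival(coh$labels, cfg)
  res <- survival_by_subtype(calls, sv, clinical = cl)
  expect_setequal(names(res$km), unique(calls$label))
  expect_equal(res$logrank$df, 4L)
  # ER-negative luminal/basal contrast mirrors the subgroup path
  sub <- survival_by_subtype(calls, sv, clinical = cl,
                             filter = list(er = "negative"),
                             subtypes = c("Her2E", "Basal"))
  expect_true(all(names(sub$km) %in% c("Her2E", "Basal")))
  expect_equal(sum(sub$n), sum(cl$er == "negative" &
                                 coh$labels %in% c("Her2E", "Basal")))
  expect_error(survival_by_subtype(calls, sv, filter = list(er = "negative")),
               "requires clinical")
})
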