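test_that("DWD recovers the separating direction on the 2-D toy", {
  X <- rbind(c(-1, 0), c(-1, 0.5), c(1, 0), c(1, -0.5))
  inst <- list(X = X, y = c(-1, -1, 1, 1))
  inp <- as_dwd_inputs(inst)
  fit <- fit_dwd(inp$matrix, inp$batches, cost = 1)
  oracle <- dwd_oracle_2d(X, inst$y, C = 1, step_deg = 0.25)
  ang <- acos(min(1, abs(sum(fit$direction * oracle$direction))))
  expect_lt(ang, 1e-2)
  # the toy is point-symmetric, not mirror-symmetric: the optimum tilts
  # ~12.5 degrees off (1, 0); the contract is agreement with the oracle
  expect_gt(fit$direction[["g1"]], 0.97)
  expect_lte(fit$objective, oracle$objective * (1 + 1e-4))
  expect_equal(sqrt(sum(fit$direction^2)), 1, tolerance = 1e-8)
})

test_that("fitted objective matches the brute-force grid oracle (random 2-D)", {
  worst <- 0
  for (seed in 1:10) {
    inst <- random_dwd_instance(seed)
    inp <- as_dwd_inputs(inst)
    fit <- fit_dwd(inp$matrix, inp$batches, cost = 5)
    oracle <- dwd_oracle_2d(inst$X, inst$y, C = 5, step_deg = 1)
    rel <- (fit$objective - oracle$objective) / oracle$objective
    worst <- max(worst, rel)
    expect_lt(rel, 1e-2)
  }
  expect_lt(worst, 1e-2)
})

test_that("direction is equivariant under rotation of the data", {
  inst <- random_dwd_instance(42)
  inp <- as_dwd_inputs(inst)
  fit <- fit_dwd(inp$matrix, inp$batches, cost = 2)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- inp
  rot$matrix <- R %*% inp$matrix
  dimnames(rot$matrix) <- dimnames(inp$matrix)
  fit_rot <- fit_dwd(rot$matrix, rot$batches, cost = 2)
  ang <- acos(min(1, abs(sum(fit_rot$direction * (R %*% fit$direction)))))
  expect_lt(ang, 1e-3)
})

test_that("dwd_adjust zeroes batch mean projections and keeps the orthogonal part", {
  set.seed(5)
  cen <- rnorm(20)
  shift <- rnorm(20)
  m <- cbind(sapply(1:6, function(i) cen + rnorm(20, sd = 0.3)),
             sapply(1:8, function(i) cen + shift + rnorm(20, sd = 0.3)))
  dimnames(m) <- list(sprintf("g%02d", 1:20), sprintf("S%02d", 1:14))
  batches <- data.frame(sample_id = colnames(m),
                        batch = rep(c("A", "B"), c(6, 8)))
  fit <- fit_dwd(m, batches, cost = "auto")
  adj <- dwd_adjust(m, fit)
  b <- batches$batch
  proj <- drop(crossprod(adj, fit$direction))
  expect_lt(abs(mean(proj[b == "A"])), 1e-8)
  expect_lt(abs(mean(proj[b == "B"])), 1e-8)
  # components orthogonal to the direction are untouched
  ortho <- function(x) x - fit$direction %*% crossprod(fit$direction, x)
  expect_equal(ortho(adj), ortho(m), tolerance = 1e-10)
  # between-batch mean difference has zero projection on w
  gap <- rowMeans(adj[, b == "B"]) - rowMeans(adj[, b == "A"])
  expect_lt(abs(sum(gap * fit$direction)), 1e-8)
  # reference mode holds the reference batch fixed
  adj_ref <- dwd_adjust(m, fit, reference = "A")
  expect_equal(adj_ref[, b == "A"], m[, b == "A"])
})

test_that("dwd_adjust identities: zero offsets and pure shift along w", {
  inst <- random_dwd_instance(7)
  inp <- as_dwd_inputs(inst)
  fit <- fit_dwd(inp$matrix, inp$batches, cost = 1)
  zero <- fit
  zero$batch_offsets[] <- 0
  expect_equal(dwd_adjust(inp$matrix, zero), inp$matrix)
  # two identical batches offset by a constant delta along the model
  # direction collapse onto each other after adjustment (hand-built model)
  set.seed(8)
  base <- random_expr_matrix(15, 5, seed = 8, prefix = "A")
  w <- rnorm(15); w <- w / sqrt(sum(w^2))
  names(w) <- rownames(base)
  shifted <- base + 2.5 * w
  colnames(shifted) <- sprintf("B%03d", 1:5)
  pooled <- cbind(base, shifted)
  batches <- data.frame(sample_id = colnames(pooled),
                        batch = rep(c("A", "B"), each = 5))
  proj <- drop(crossprod(pooled, w))
  model <- structure(list(direction = w, intercept = 0, cost = 1,
                          batch_offsets = tapply(proj, batches$batch, mean),
                          batch_levels = c("A", "B"), batches = batches),
                     class = "dwd_model")
  adj <- dwd_adjust(pooled, model)
  expect_equal(unname(adj[, 1:5]), unname(adj[, 6:10]), tolerance = 1e-8)
  # gene panel mismatch is an error
  bad <- pooled
  rownames(bad)[1] <- "zzz"
  expect_error(dwd_adjust(bad, model), "panel mismatch")
})

test_that("auto_cost implements the scale-free median-distance heuristic", {
  # 3 + 3 samples with hand-enumerable cross distances
  a <- matrix(c(0, 0, 1, 0, 2, 0), nrow = 2)
  b <- matrix(c(0, 1, 1, 1, 2, 1), nrow = 2)
  m <- cbind(a, b)
  dimnames(m) <- list(c("g1", "g2"), sprintf("S%d", 1:6))
  batches <- data.frame(sample_id = colnames(m),
                        batch = rep(c("A", "B"), each = 3))
  # 9 cross distances: 1,sqrt2,sqrt5 / sqrt2,1,sqrt2 / sqrt5,sqrt2,1 -> median sqrt(2)
  expect_equal(auto_cost(m, batches), 100 / 2)
  # all pairs at distance 1 -> C = 100
  m1 <- matrix(c(0, 0, 0, 0, 1, 0, 1, 0), nrow = 2)
  dimnames(m1) <- list(c("g1", "g2"), sprintf("S%d", 1:4))
  b1 <- data.frame(sample_id = colnames(m1), batch = c("A", "A", "B", "B"))
  expect_equal(auto_cost(m1, b1), 100)
  # scaling data by s scales C by 1/s^2
  expect_equal(auto_cost(3 * m, batches), auto_cost(m, batches) / 9)
  # degenerate: all cross distances zero
  m0 <- matrix(1, 2, 4, dimnames = dimnames(m1))
  expect_error(auto_cost(m0, b1), "zero")
})

test_that("DWD removes a cross-platform-scale site bias (beta = 10 tau)", {
  # a shift of ~10x the centroid dispersion is what it takes for the
  # unclassified phenomenon to appear at all (see methods vignette); DWD
  # restores perfect recovery because the site shift is exactly rank-one
  for (seed in 1:3) {
    cfg <- sim_config(seed = seed, sigma = 0.5, tau = 1, batch_beta = 10,
                      subtype_sizes = c(20, 10, 4, 10, 16))
    cen <- simulate_centroids(cfg)
    coh <- simulate_cohort(cfg, cen)
    raw <- classify_cohort(coh$matrix, cen)
    m <- fit_dwd(coh$matrix, coh$batches)
    adj <- classify_cohort(dwd_adjust(coh$matrix, m), cen)
    expect_lte(sum(adj$label == "Unclassified"),
               sum(raw$label == "Unclassified"))
    expect_gte(mean(adj$label == coh$labels), 0.95)
    expect_gt(mean(adj$label == coh$labels),
              mean(raw$label == coh$labels) - 1e-12)
  }
})

test_that("batch design preconditions are enforced", {
  m <- random_expr_matrix(5, 6, seed = 2)
  b3 <- data.frame(sample_id = colnames(m),
                   batch = c("A", "A", "B", "B", "C", "C"))
  expect_error(fit_dwd(m, b3), "exactly 2 distinct batch labels")
  b1 <- data.frame(sample_id = colnames(m),
                   batch = c("A", rep("B", 5)))
  expect_error(fit_dwd(m, b1), ">= 2 samples")
  expect_error(fit_dwd(m, data.frame(sample_id = colnames(m)[-1],
                                     batch = rep(c("A", "B"), c(2, 3)))),
               "without a batch label")
})
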