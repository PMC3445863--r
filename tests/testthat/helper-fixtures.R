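# Shared fixture builders. Everything is generated in code; no binary data.

random_expr_matrix <- function(n_genes = 6L, n_samples = 4L, seed = 1L,
                               prefix = "S") {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples, mean = 8, sd = 2), n_genes, n_samples,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("%s%03d", prefix, seq_len(n_samples))))
}

random_centroids <- function(n_genes = 50L, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * 5L), n_genes, 5L,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              SUBTYPE_LABELS))
  m
}

make_calls <- function(sample_ids, labels) {
  df <- data.frame(sample_id = sample_ids, label = labels,
                   stringsAsFactors = FALSE)
  for (k in SUBTYPE_LABELS) df[[paste0("rho_", k)]] <- 0.5
  df$threshold <- 0.1
  df$tie_flag <- FALSE
  df
}

# Per-sample DWD loss after minimizing out the slack variables:
# V(m) = 1/m for m >= 1/sqrt(C), else 2 sqrt(C) - C m.
dwd_loss <- function(m, C) {
  sum(ifelse(m >= 1 / sqrt(C), 1 / m, 2 * sqrt(C) - C * m))
}

# Brute-force DWD oracle for 2-D instances: scan unit directions on a
# degree grid, minimizing the convex 1-D intercept problem inside each.
dwd_oracle_2d <- function(X, y, C, step_deg = 1) {
  stopifnot(ncol(X) == 2L)
  span <- max(abs(X)) + 10
  best <- list(objective = Inf, direction = NULL, intercept = NA_real_)
  for (deg in seq(0, 360 - step_deg, by = step_deg)) {
    th <- deg * pi / 180
    w <- c(cos(th), sin(th))
    p <- drop(X %*% w)
    o <- optimize(function(b) dwd_loss(y * (p + b), C),
                  lower = -span, upper = span, tol = 1e-10)
    if (o$objective < best$objective) {
      best <- list(objective = o$objective, direction = w,
                   intercept = o$minimum)
    }
  }
  best
}

# A random 2-D two-batch instance with n <= 12 samples.
random_dwd_instance <- function(seed, n_max = 12L) {
  set.seed(seed)
  n1 <- sample(2:(n_max %/% 2), 1L)
  n2 <- sample(2:(n_max - n1), 1L)
  sep <- runif(1, 0.5, 3)
  X <- rbind(matrix(rnorm(2 * n1, mean = -sep / 2), ncol = 2),
             matrix(rnorm(2 * n2, mean = sep / 2), ncol = 2))
  list(X = X, y = rep(c(-1, 1), c(n1, n2)))
}

as_dwd_inputs <- function(inst) {
  m <- t(inst$X)
  dimnames(m) <- list(c("g1", "g2"), sprintf("S%03d", seq_len(ncol(m))))
  batches <- data.frame(sample_id = colnames(m),
                        batch = ifelse(inst$y > 0, "B", "A"),
                        stringsAsFactors = FALSE)
  list(matrix = m, batches = batches)
}

extdata <- function(name) {
  system.file("extdata", name, package = "sspconcord", mustWork = TRUE)
}
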