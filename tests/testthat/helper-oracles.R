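# Independent oracles used to check the implementation by a second route.
# These are deliberately written naively (plain loops, textbook formulas)
# and share no code with the package internals.

# Brute-force IGR: every midpoint split, entropies recomputed from scratch.
oracle_igr <- function(values, labels) {
  labels <- as.character(labels)
  H <- function(x) {
    if (length(x) == 0) return(0)
    p <- table(x) / length(x)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  v <- sort(unique(values))
  n <- length(values)
  best <- 0; thr <- NA_real_
  if (length(v) >= 2) {
    for (i in seq_len(length(v) - 1)) {
      t <- (v[i] + v[i + 1]) / 2
      left <- labels[values <= t]; right <- labels[values > t]
      ig <- H(labels) - length(left) / n * H(left) -
        length(right) / n * H(right)
      si <- -(length(left) / n) * log2(length(left) / n) -
        (length(right) / n) * log2(length(right) / n)
      igr <- ig / si
      if (igr > best + 1e-12) { best <- igr; thr <- t }
    }
  }
  list(igr = best, split_threshold = thr)
}

# Partial F for the group term by explicit normal-equations solves of the
# nested models.
oracle_partial_f <- function(y, covariates) {
  g <- as.numeric(factor(covariates$group)) - 1
  Xf <- cbind(1, g, covariates$age, covariates$sex, covariates$education,
              covariates$tremor_duration)
  Xr <- Xf[, -2, drop = FALSE]
  rss <- function(X) {
    beta <- solve(t(X) %*% X, t(X) %*% y)
    sum((y - X %*% beta)^2)
  }
  rf <- rss(Xf); rr <- rss(Xr)
  df2 <- nrow(Xf) - ncol(Xf)
  list(f = (rr - rf) / (rf / df2), df1 = 1, df2 = df2,
       diff = solve(t(Xf) %*% Xf, t(Xf) %*% y)[2])
}

# Hard-margin maximum-margin separator by KKT active-set enumeration:
# every candidate support set of 2..(d+1) points (both classes present)
# defines a linear system; a candidate with nonnegative multipliers whose
# hyperplane is feasible for all points is the optimum. Only intended for
# small separable fixtures.
oracle_hard_margin <- function(X, y) {
  X <- as.matrix(X)
  ypm <- ifelse(y == sort(unique(as.character(y)))[2], 1, -1)
  n <- nrow(X); d <- ncol(X)
  best_margin <- 0; found <- FALSE
  for (size in 2:min(d + 1, n)) {
    for (S in utils::combn(n, size, simplify = FALSE)) {
      if (length(unique(ypm[S])) < 2) next
      K <- X[S, , drop = FALSE] %*% t(X[S, , drop = FALSE])
      A <- rbind(cbind(outer(ypm[S], ypm[S]) * K, ypm[S]),
                 c(ypm[S], 0))
      rhs <- c(rep(1, size), 0)
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      lambda <- sol[seq_len(size)]; b <- sol[size + 1]
      if (any(lambda < -1e-9)) next
      w <- drop(t(X[S, , drop = FALSE]) %*% (lambda * ypm[S]))
      if (sum(w^2) < 1e-18) next
      f <- drop(X %*% w) + b
      if (min(ypm * f) >= 1 - 1e-7) {
        found <- TRUE
        best_margin <- max(best_margin, 2 / sqrt(sum(w^2)))
      }
    }
  }
  list(separable = found, margin = best_margin)
}

# Compact null cohort on a flat catalog, shared by several tests.
null_cohort <- function(p = 10, n_a = 14, n_b = 15, seed = 1) {
  generate_cohort(synthetic_spec(
    n_group_a = n_a, n_group_b = n_b,
    feature_catalog = simple_catalog(p), seed = seed))
}

# Seeded evaluation for test-local draws.
with_seed_helper <- function(seed, code) {
  set.seed(seed)
  code
}

# Binomial 95% band (as proportions) around rate p for one n-subject run.
binom_band <- function(n, p) {
  c(qbinom(0.025, n, p), qbinom(0.975, n, p)) / n
}
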