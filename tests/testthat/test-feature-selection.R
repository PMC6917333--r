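# IGR scoring, ranking, fold plans, CV accuracy, and the greedy wrapper.

test_that("IGR handles the canonical small cases", {
  r <- information_gain_ratio(c(1, 1, 2, 2), c("A", "A", "B", "B"))
  expect_equal(r$igr, 1)
  expect_equal(r$split_threshold, 1.5)

  expect_warning(r0 <- information_gain_ratio(c(3, 3, 3, 3),
                                              c("A", "B", "A", "B")),
                 "constant")
  expect_equal(r0$igr, 0)
  expect_true(is.na(r0$split_threshold))

  # interleaved labels: best of the three midpoint splits, tie to the left
  r2 <- information_gain_ratio(c(1, 2, 3, 4), c("A", "B", "A", "B"))
  ig <- 1 - 0.75 * (-(1 / 3) * log2(1 / 3) - (2 / 3) * log2(2 / 3))
  si <- -(0.25 * log2(0.25) + 0.75 * log2(0.75))
  expect_equal(r2$igr, ig / si, tolerance = 1e-12)
  expect_equal(r2$split_threshold, 1.5)

  expect_error(information_gain_ratio(c(1, 2), c("A", "A")), "both classes")
})

test_that("IGR agrees with the brute-force oracle and is monotone-invariant", {
  for (i in 1:20) {
    n <- 14
    x <- with_seed_helper(i, rnorm(n))
    y <- rep(c("A", "B"), length.out = n)
    got <- information_gain_ratio(x, y)
    want <- oracle_igr(x, y)
    expect_equal(got$igr, want$igr, tolerance = 1e-12)
    expect_equal(got$split_threshold, want$split_threshold)
    expect_true(got$igr >= 0 && got$igr <= 1)
    # strictly increasing transforms preserve the score
    for (f in list(function(v) exp(v), function(v) v^3,
                   function(v) atan(v))) {
      expect_equal(information_gain_ratio(f(x), y)$igr, got$igr,
                   tolerance = 1e-9)
    }
  }
})

test_that("IGR is 1 exactly for a perfectly separating feature", {
  x <- c(rnorm(8, -5), rnorm(8, 5))
  y <- rep(c("A", "B"), each = 8)
  expect_equal(information_gain_ratio(x, y)$igr, 1)
})

test_that("ranking is descending with deterministic lexicographic ties", {
  co <- make_separable_cohort(
    synthetic_spec(feature_catalog = simple_catalog(8), seed = 3),
    k_informative = 1, margin = 3)
  X <- co$table$values
  X <- cbind(X, `f00_copy` = X[, "f01"])   # duplicate the separating column
  rk <- rank_features(X, co$covariates$group)
  expect_equal(rk$rank, seq_len(nrow(rk)))
  expect_true(all(diff(rk$igr) <= 1e-12))
  # the two identical columns occupy adjacent ranks in lexicographic order
  ix <- which(rk$feature_id %in% c("f01", "f00_copy"))
  expect_equal(diff(ix), 1)
  expect_equal(rk$feature_id[ix], c("f00_copy", "f01"))
  # rank 1 is a perfect separator
  expect_equal(rk$igr[1], 1)
})

test_that("fold plans partition subjects with balanced, stratified folds", {
  for (seed in 1:5) {
    for (k in c(2, 5, 10)) {
      y <- rep(c("OT", "ET"), c(14, 15))
      plan <- cv_plan(y, n_folds = k, stratified = TRUE, seed = seed)
      expect_length(plan$fold, 29)
      sizes <- tabulate(plan$fold, k)
      expect_lte(max(sizes) - min(sizes), 1)
      for (lv in c("OT", "ET")) {
        cls <- tabulate(plan$fold[y == lv], k)
        expect_lte(max(cls) - min(cls), 1)
      }
    }
  }
  y <- rep(c("A", "B"), 5)
  expect_identical(cv_plan(y, 5, TRUE, seed = 2)$fold,
                   cv_plan(y, 5, TRUE, seed = 2)$fold)
  expect_error(cv_plan(y, 1), "n_folds")
  expect_error(cv_plan(y, 11), "n_folds")
})

test_that("far-separated clusters cross-validate perfectly", {
  x <- matrix(c(-10 + 0.1 * rnorm(10), 10 + 0.1 * rnorm(10)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c("A", "B"), each = 10)
  plan <- cv_plan(y, 10, TRUE, seed = 1)
  acc <- cv_accuracy("f", x, y, plan)
  expect_equal(as.numeric(acc), 1)
  expect_equal(attr(acc, "correct"), 20L)
})

test_that("CV accuracy equals an independent fold-by-fold simulation", {
  co <- make_separable_cohort(
    synthetic_spec(n_group_a = 4, n_group_b = 4,
                   feature_catalog = simple_catalog(2), seed = 12),
    k_informative = 1, margin = 2)
  X <- co$table$values
  y <- factor(co$covariates$group)
  plan <- cv_plan(y, 4, TRUE, seed = 12)
  cfg <- svm_config()
  correct <- 0
  for (k in 1:4) {
    tr <- which(plan$fold != k); te <- which(plan$fold == k)
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2, sd); sdv[sdv == 0] <- 1
    fit <- e1071::svm(scale(X[tr, , drop = FALSE], mu, sdv),
                      droplevels(y[tr]), kernel = "linear", cost = cfg$cost,
                      tolerance = cfg$tolerance, scale = FALSE)
    pred <- predict(fit, scale(X[te, , drop = FALSE], mu, sdv))
    correct <- correct + sum(as.character(pred) == as.character(y[te]))
  }
  acc <- cv_accuracy(colnames(X), X, y, plan, cfg)
  expect_equal(attr(acc, "correct"), as.integer(correct))
})

test_that("label permutation destroys CV accuracy (empirical null at chance)", {
  co <- null_cohort(p = 4, seed = 77)
  X <- co$table$values
  y <- co$covariates$group
  plan <- cv_plan(y, 10, TRUE, seed = 77)
  accs <- numeric(100)
  for (i in seq_len(100)) {
    yp <- with_seed_helper(700 + i, sample(as.character(y)))
    accs[i] <- as.numeric(cv_accuracy(colnames(X), X, yp, plan))
  }
  band <- binom_band(29, 15 / 29)
  expect_gte(mean(accs), band[1])
  expect_lte(mean(accs), band[2])
})

test_that("single-class training folds predict the trained class", {
  x <- matrix(rnorm(6), ncol = 1, dimnames = list(NULL, "f"))
  y <- c("A", "A", "A", "A", "A", "B")
  plan <- structure(list(fold = c(1L, 1L, 2L, 2L, 3L, 3L), n_folds = 3L,
                         stratified = FALSE, seed = 1L), class = "cv_plan")
  acc <- cv_accuracy("f", x, y, plan)   # fold 3 train set is all A + B
  expect_true(is.finite(as.numeric(acc)))
})

test_that("greedy wrapper keeps a dominant feature and obeys its invariants", {
  co <- make_separable_cohort(
    synthetic_spec(feature_catalog = simple_catalog(10), seed = 31),
    k_informative = 1, margin = 5)
  X <- co$table$values
  y <- co$covariates$group
  plan <- cv_plan(y, 10, TRUE, seed = 31)
  rk <- rank_features(X, y)
  tr <- greedy_wrapper_select(rk, X, y, plan)
  expect_true("f01" %in% tr$final_subset)
  expect_equal(tr$final_accuracy, 1)
  expect_equal(nrow(tr$steps), 10)
  # kept-step accuracies are non-decreasing
  kept <- tr$steps$cv_accuracy[tr$steps$decision == "kept"]
  expect_true(all(diff(kept) >= -1e-12))
  # final subset is the kept features in acceptance order
  expect_identical(tr$final_subset,
                   tr$steps$feature_id[tr$steps$decision == "kept"])
  expect_gte(tr$final_accuracy, tr$steps$cv_accuracy[1])
})

test_that("greedy decisions replay exactly from the public CV routine", {
  co <- null_cohort(p = 6, seed = 41)
  X <- co$table$values
  y <- co$covariates$group
  plan <- cv_plan(y, 10, TRUE, seed = 41)
  rk <- rank_features(X, y)
  tr <- greedy_wrapper_select(rk, X, y, plan)
  # independent replay of the acceptance rule
  subset <- rk$feature_id[1]
  best <- attr(cv_accuracy(subset, X, y, plan), "correct")
  for (i in 2:nrow(rk)) {
    cand <- attr(cv_accuracy(c(subset, rk$feature_id[i]), X, y, plan),
                 "correct")
    keep <- cand >= best
    expect_equal(tr$steps$decision[i] == "kept", keep)
    if (keep) { subset <- c(subset, rk$feature_id[i]); best <- cand }
  }
  expect_identical(tr$final_subset, subset)
  # the whole selection is a pure function of (table, labels, seed)
  tr2 <- greedy_wrapper_select(rk, X, y, cv_plan(y, 10, TRUE, seed = 41))
  expect_identical(tr$steps, tr2$steps)
})
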