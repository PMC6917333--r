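# ANCOVA screening, effect sizes, and the demographic comparison battery.

test_that("ANCOVA degrees of freedom follow n and the covariate count", {
  co <- null_cohort(p = 2, seed = 101)
  res <- ancova_feature(co$table$values[, 1], co$covariates)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 23)   # 29 - (intercept + group + 4 covariates)
  # subgroup-sized cohort: 14 subjects, same four covariates -> df2 = 8
  co14 <- generate_cohort(synthetic_spec(
    n_group_a = 9, n_group_b = 5, feature_catalog = simple_catalog(2),
    seed = 102))
  res14 <- ancova_feature(co14$table$values[, 1], co14$covariates)
  expect_equal(res14$df2, 8)
})

test_that("ANCOVA matches an explicit normal-equations oracle", {
  co <- generate_cohort(synthetic_spec(
    n_group_a = 5, n_group_b = 5, feature_catalog = simple_catalog(3),
    effect_map = c(f02 = 1.5), seed = 1))
  for (j in 1:3) {
    y <- co$table$values[, j]
    got <- ancova_feature(y, co$covariates)
    want <- oracle_partial_f(y, co$covariates)
    expect_equal(got$f_stat, want$f, tolerance = 1e-8)
    expect_equal(got$df2, want$df2)
    expect_equal(got$adjusted_diff, unname(want$diff), tolerance = 1e-8)
    # internal consistency of the reported effect size
    expect_equal(got$partial_eta2,
                 got$f_stat * got$df1 / (got$f_stat * got$df1 + got$df2),
                 tolerance = 1e-9)
  }
})

test_that("constant response yields F = 0 with a warning", {
  co <- null_cohort(p = 1, seed = 5)
  expect_warning(res <- ancova_feature(rep(1.5, 29), co$covariates),
                 "constant")
  expect_equal(res$f_stat, 0)
  expect_equal(res$partial_eta2, 0)
  expect_equal(res$p_value, 1)
})

test_that("with constant covariates ANCOVA reduces to the pooled t-test", {
  co <- null_cohort(p = 1, seed = 7)
  covs <- co$covariates
  covs$age <- 50; covs$sex <- 1; covs$education <- 10
  covs$tremor_duration <- 5
  y <- co$table$values[, 1]
  suppressMessages(res <- ancova_feature(y, covs))
  tt <- t.test(y ~ covs$group, var.equal = TRUE)
  expect_equal(res$f_stat, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(res$df2, 27)
})

test_that("statistics are invariant to subject row order", {
  co <- null_cohort(p = 3, seed = 9)
  perm <- sample(29)
  a <- screen_features(co$table$values, co$covariates, alpha = 1)
  b <- screen_features(co$table$values[perm, ],
                       co$covariates[perm, ], alpha = 1)
  fa <- attr(a, "full_results"); fb <- attr(b, "full_results")
  expect_equal(fa$f_stat, fb$f_stat, tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with the collinear column named", {
  co <- null_cohort(p = 1, seed = 11)
  covs <- co$covariates
  covs$education <- covs$age * 2   # exactly collinear
  expect_error(ancova_feature(co$table$values[, 1], covs), "education|age")
})

test_that("partial eta-squared reproduces tabled effect sizes from F", {
  expect_equal(round(partial_eta_squared_from_f(13.084, 1, 23), 3), 0.363)
  expect_equal(round(partial_eta_squared_from_f(62.627, 1, 23), 3), 0.731)
  expect_equal(partial_eta_squared_from_f(0, 1, 23), 0)
  expect_error(partial_eta_squared_from_f(-1, 1, 23), "nonnegative")
  expect_error(partial_eta_squared_from_f(1, 0, 23), "df")
  # strictly increasing in F, bounded in [0, 1)
  f <- seq(0, 200, length.out = 50)
  e <- partial_eta_squared_from_f(f, 1, 23)
  expect_true(all(diff(e) > 0))
  expect_true(all(e >= 0 & e < 1))
})

test_that("screening returns only significant features; alpha = 0 empties it", {
  co <- generate_cohort(synthetic_spec(
    feature_catalog = simple_catalog(20), effect_map = c(f03 = 3),
    seed = 23))
  sig <- screen_features(co$table, co$covariates, alpha = 0.05)
  expect_true("f03" %in% sig$feature_id)
  expect_true(all(sig$p_value < 0.05))
  full <- attr(sig, "full_results")
  expect_equal(nrow(full), 20)
  none <- screen_features(co$table, co$covariates, alpha = 0)
  expect_equal(nrow(none), 0)
})

test_that("identical group distributions compare as indistinguishable", {
  x <- rep(seq(1, 10, length.out = 10), 2)
  df <- data.frame(group = rep(c("A", "B"), each = 10), score = x)
  out <- compare_demographics(df, continuous_vars = "score")
  expect_equal(out$p_value, 1, tolerance = 1e-12)
  if (out$test == "t-test") expect_equal(out$statistic, 0)
})

test_that("binary variables get the uncorrected chi-squared of the 2x2 table", {
  sex <- c(rep(1, 12), rep(0, 2), rep(1, 11), rep(0, 4))
  grp <- rep(c("OT", "ET"), c(14, 15))
  df <- data.frame(group = grp, sex = sex)
  out <- compare_demographics(df, continuous_vars = character(0),
                              binary_vars = "sex")
  # hand-computed Pearson chi-squared from the contingency formula
  tab <- table(grp, sex)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi2 <- sum((tab - expected)^2 / expected)
  expect_equal(out$statistic, chi2, tolerance = 1e-10)
})

test_that("a tremor-duration-sized shift is detected by the gated battery", {
  n_seeds <- 200
  hits <- 0
  for (i in seq_len(n_seeds)) {
    co <- generate_cohort(synthetic_spec(
      feature_catalog = simple_catalog(1), seed = 40000 + i))
    out <- compare_demographics(co$covariates[
      , c("group", "age", "sex", "education", "tremor_duration")])
    p <- out$p_value[out$variable == "tremor_duration"]
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / n_seeds, 0.80)
})

test_that("tiny groups fall back to Mann-Whitney with a warning", {
  df <- data.frame(group = rep(c("A", "B"), c(2, 8)), score = rnorm(10))
  expect_warning(out <- compare_demographics(df, continuous_vars = "score"),
                 "< 3 subjects")
  expect_equal(out$test, "Mann-Whitney")
})

test_that("adjusted association is honest under the null and powered under shift", {
  co0 <- null_cohort(p = 1, seed = 55)
  # constant outcome -> zero effect
  out <- adjusted_association(rep(3, 29), co0$covariates,
                              depressive_symptoms = rnorm(29))
  expect_equal(out$estimate, 0, tolerance = 1e-10)
  expect_equal(out$p_value, 1)

  n_seeds <- 100
  null_rej <- shift_rej <- 0
  for (i in seq_len(n_seeds)) {
    co <- null_cohort(p = 1, seed = 60000 + i)
    score_null <- 2 * co$covariates$age + co$table$values[, 1]
    a <- adjusted_association(score_null, co$covariates,
                              depressive_symptoms = NULL)
    null_rej <- null_rej + (a$p_value < 0.05)
    g <- as.numeric(co$covariates$group == "ET")
    score_shift <- co$table$values[, 1] + 3 * g
    b <- adjusted_association(score_shift, co$covariates,
                              depressive_symptoms = NULL)
    shift_rej <- shift_rej + (b$p_value < 0.01)
  }
  expect_lte(null_rej / n_seeds, 0.12)    # ~5% nominal type-I error
  expect_gte(shift_rej / n_seeds, 0.95)   # 3-SD shift is near-certain
})
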