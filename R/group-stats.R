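# Covariate-adjusted group contrasts. Each morphometric feature is tested
# with an ANCOVA: least squares of the feature on intercept + group + age +
# sex + education + tremor duration, with the group term's partial F
# computed from the nested-model residual sums of squares (identical to the
# Type-III test for this single two-level factor). Effect sizes are partial
# eta-squared. Screening is deliberately uncorrected for multiplicity: it
# is a filter feeding the wrapper, not a confirmatory family of tests.

ancova_covariate_names <- c("age", "sex", "education", "tremor_duration")

# Build full and reduced design matrices from a covariate data.frame.
# Constant covariate columns are dropped (with a message); any remaining
# rank deficiency is an error naming the collinear columns.
ancova_design <- function(covariates,
                          covariate_names = ancova_covariate_names) {
  if (!all(c("group", covariate_names) %in% names(covariates))) {
    stop("ancova: covariates must contain 'group' and ",
         paste(covariate_names, collapse = ", "))
  }
  grp <- covariates$group
  if (!is.factor(grp)) grp <- factor(grp)
  grp <- droplevels(grp)
  if (nlevels(grp) != 2) {
    stop("ancova: exactly two groups required, got ", nlevels(grp))
  }
  if (min(table(grp)) < 2) stop("ancova: need >= 2 subjects per group")
  g <- as.numeric(grp == levels(grp)[2])
  covs <- as.matrix(
    data.frame(lapply(covariates[covariate_names], as.numeric)))
  constant <- apply(covs, 2, function(x) diff(range(x)) == 0)
  if (any(constant)) {
    message("ancova: dropping constant covariate(s): ",
            paste(covariate_names[constant], collapse = ", "))
    covs <- covs[, !constant, drop = FALSE]
  }
  X_full <- cbind(`(Intercept)` = 1, group = g, covs)
  qr_full <- qr(X_full)
  if (qr_full$rank < ncol(X_full)) {
    bad <- colnames(X_full)[qr_full$pivot[(qr_full$rank + 1):ncol(X_full)]]
    stop("ancova: rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(X_full)
  if (n <= ncol(X_full)) {
    stop("ancova: n (", n, ") must exceed the number of model parameters (",
         ncol(X_full), ")")
  }
  X_red <- X_full[, colnames(X_full) != "group", drop = FALSE]
  list(qr_full = qr_full, qr_red = qr(X_red), n = n,
       df1 = 1L, df2 = as.integer(n - ncol(X_full)),
       group_levels = levels(grp))
}

# Vectorized ANCOVA over the columns of Y. Returns a data.frame, one row
# per column, in column order.
ancova_core <- function(Y, design, alpha = 0.05) {
  Y <- as.matrix(Y)
  rss_full <- colSums(qr.resid(design$qr_full, Y)^2)
  rss_red <- colSums(qr.resid(design$qr_red, Y)^2)
  coefs <- qr.coef(design$qr_full, Y)
  adj_diff <- coefs["group", ]
  tss <- colSums(scale(Y, scale = FALSE)^2)
  f <- ((rss_red - rss_full) / design$df1) / (rss_full / design$df2)
  constant <- tss < .Machine$double.eps * design$n
  if (any(constant)) {
    warning("ancova: constant response for ",
            paste(colnames(Y)[constant], collapse = ", "),
            "; returning F = 0")
    f[constant] <- 0
    adj_diff[constant] <- 0
  }
  # perfect full-model fit: infinite F if the group term absorbed signal,
  # zero if the reduced model was already exact
  eps <- .Machine$double.eps * design$n
  zero_full <- rss_full < eps & !constant
  f[zero_full] <- ifelse(rss_red[zero_full] - rss_full[zero_full] > eps,
                         Inf, 0)
  f <- pmax(f, 0)
  p <- stats::pf(f, design$df1, design$df2, lower.tail = FALSE)
  eta2 <- ifelse(is.infinite(f), 1,
                 f * design$df1 / (f * design$df1 + design$df2))
  data.frame(
    feature_id = colnames(Y) %||% sprintf("y%d", seq_along(f)),
    f_stat = unname(f), df1 = design$df1, df2 = design$df2,
    p_value = unname(p), partial_eta2 = unname(eta2),
    adjusted_diff = unname(adj_diff),
    significant = unname(p < alpha),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Covariate-adjusted ANCOVA for one feature
#'
#' Least-squares fit of `y` on intercept + group indicator + age + sex +
#' education + tremor duration. The reported F is the partial F for the
#' group term (nested residual-sum-of-squares comparison, df1 = 1,
#' df2 = n - p); `adjusted_diff` is the group coefficient, signed second
#' group level minus first; `partial_eta2 = F / (F + df2)`.
#' With 29 subjects and the four standard covariates, df2 = 23.
#'
#' @param y numeric vector of per-subject feature values.
#' @param covariates data.frame with `group` plus the covariate columns.
#' @param alpha significance threshold recorded in `significant`.
#' @param covariate_names covariates to adjust for.
#' @return list of class `ancova_result` with fields `feature_id`,
#'   `f_stat`, `df1`, `df2`, `p_value`, `partial_eta2`, `adjusted_diff`,
#'   `significant`.
#' @export
ancova_feature <- function(y, covariates, alpha = 0.05,
                           covariate_names = ancova_covariate_names) {
  if (length(y) != nrow(covariates)) {
    stop("ancova_feature: y and covariates disagree on n")
  }
  design <- ancova_design(covariates, covariate_names)
  Y <- matrix(y, ncol = 1, dimnames = list(NULL, "y"))
  res <- ancova_core(Y, design, alpha)
  out <- as.list(res[1, ])
  out$group_levels <- design$group_levels
  class(out) <- "ancova_result"
  out
}

#' @export
print.ancova_result <- function(x, ...) {
  cat(sprintf("ANCOVA group contrast (%s - %s): F(%d,%d) = %.3f, p = %.4g, partial eta^2 = %.3f, adj. diff = %.5g\n",
              x$group_levels[2], x$group_levels[1], x$df1, x$df2, x$f_stat,
              x$p_value, x$partial_eta2, x$adjusted_diff))
  invisible(x)
}

#' Partial eta-squared from an F statistic
#'
#' `eta2 = F * df1 / (F * df1 + df2)`, the share of residual-plus-effect
#' variance attributable to the tested term. For the group contrasts
#' reported by [ancova_feature()] (df1 = 1, df2 = 23 at n = 29 with four
#' covariates), e.g. F = 13.084 gives 0.363.
#'
#' @param f_stat nonnegative F statistic (vectorized).
#' @param df1,df2 numerator and denominator degrees of freedom (>= 1).
#' @return effect size(s) in \[0, 1).
#' @export
partial_eta_squared_from_f <- function(f_stat, df1, df2) {
  if (any(!is.finite(df1)) || any(df1 < 1) ||
      any(!is.finite(df2)) || any(df2 < 1)) {
    stop("partial_eta_squared_from_f: df1 and df2 must be >= 1")
  }
  if (any(f_stat < 0)) {
    stop("partial_eta_squared_from_f: F must be nonnegative")
  }
  f_stat * df1 / (f_stat * df1 + df2)
}

#' Screen features by covariate-adjusted ANCOVA
#'
#' Runs [ancova_feature()] for every column of the table and returns the
#' features significant at `alpha` (uncorrected, by design: the screen is
#' a pre-filter for the wrapper stage). The complete per-feature results
#' are attached as `attr(, "full_results")`.
#'
#' @param table a [morphometry_table()] or numeric matrix.
#' @param covariates data.frame with `group` plus covariate columns, rows
#'   aligned with the table's subjects.
#' @param alpha screening threshold in (0, 1\]; `alpha = 0` screens out
#'   everything.
#' @param covariate_names covariates to adjust for.
#' @return data.frame of significant features (columns as
#'   [ancova_feature()]), ordered by ascending p; full results in
#'   `attr(, "full_results")`.
#' @export
screen_features <- function(table, covariates, alpha = 0.05,
                            covariate_names = ancova_covariate_names) {
  Y <- if (inherits(table, "morphometry_table")) table$values else as.matrix(table)
  if (nrow(Y) != nrow(covariates)) {
    stop("screen_features: table and covariates disagree on n")
  }
  design <- ancova_design(covariates, covariate_names)
  res <- ancova_core(Y, design, alpha)
  sig <- res[res$significant, , drop = FALSE]
  sig <- sig[order(sig$p_value, sig$feature_id, method = "radix"), ,
             drop = FALSE]
  rownames(sig) <- NULL
  attr(sig, "full_results") <- res
  attr(sig, "alpha") <- alpha
  sig
}

#' Demographic and neuropsychological comparison battery
#'
#' Per-variable two-group comparison as conventionally reported in a
#' cohort table: continuous variables are routed by a Shapiro-Wilk
#' normality gate (alpha = 0.05 in both groups) to Student's t-test or the
#' Mann-Whitney U test; binary variables get an (uncorrected) chi-squared
#' test on the 2x2 contingency table. Groups with fewer than 3 subjects
#' cannot be gated and fall back to Mann-Whitney with a warning.
#'
#' @param data data.frame containing `group` and the variables.
#' @param continuous_vars,binary_vars names of variables to compare; by
#'   default every numeric column other than `group`/`subject_id` is
#'   treated as continuous unless it has exactly two distinct values.
#' @return data.frame with one row per variable: per-group
#'   `mean (median) +- SD` (or counts) summaries, test name, statistic, p.
#' @export
compare_demographics <- function(data, continuous_vars = NULL,
                                 binary_vars = NULL) {
  grp <- droplevels(factor(data$group))
  if (nlevels(grp) != 2) stop("compare_demographics: two groups required")
  auto <- setdiff(names(data), c("group", "subject_id"))
  if (is.null(continuous_vars) && is.null(binary_vars)) {
    nvals <- vapply(auto, function(v) length(unique(data[[v]])), integer(1))
    isnum <- vapply(auto, function(v) is.numeric(data[[v]]), logical(1))
    binary_vars <- auto[nvals == 2]
    continuous_vars <- auto[isnum & nvals > 2]
  }
  gate_ok <- min(table(grp)) >= 3
  if (!gate_ok && length(continuous_vars) > 0) {
    warning("compare_demographics: a group has < 3 subjects; ",
            "normality gate skipped, using Mann-Whitney throughout")
  }
  summarize <- function(x) sprintf("%.1f (%.1f) ± %.1f", mean(x),
                                   stats::median(x), stats::sd(x))
  rows <- list()
  for (v in continuous_vars) {
    xa <- data[[v]][grp == levels(grp)[1]]
    xb <- data[[v]][grp == levels(grp)[2]]
    normal <- gate_ok &&
      stats::shapiro.test(xa)$p.value >= 0.05 &&
      stats::shapiro.test(xb)$p.value >= 0.05
    if (normal) {
      tt <- stats::t.test(xa, xb, var.equal = TRUE)
      test <- "t-test"; statistic <- unname(tt$statistic); p <- tt$p.value
    } else {
      wt <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE))
      test <- "Mann-Whitney"; statistic <- unname(wt$statistic); p <- wt$p.value
    }
    rows[[v]] <- data.frame(variable = v, group_a = summarize(xa),
                            group_b = summarize(xb), test = test,
                            statistic = statistic, p_value = p,
                            stringsAsFactors = FALSE)
  }
  for (v in binary_vars) {
    tab <- table(grp, data[[v]])
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    counts <- function(i) sprintf("%d/%d", tab[i, ncol(tab)], sum(tab[i, ]))
    rows[[v]] <- data.frame(variable = v, group_a = counts(1),
                            group_b = counts(2), test = "chi-squared",
                            statistic = unname(ct$statistic),
                            p_value = ct$p.value, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  names(out)[names(out) == "group_a"] <- levels(grp)[1]
  names(out)[names(out) == "group_b"] <- levels(grp)[2]
  out
}

#' Covariate-adjusted association of an outcome with diagnosis
#'
#' Ordinary least squares of a (typically neuropsychological) score on
#' group + age + sex + education + depressive symptoms, optionally also
#' tremor duration, returning the group term's estimate, confidence
#' interval, and p-value.
#'
#' @param score numeric outcome, one value per subject.
#' @param covariates data.frame with `group`, `age`, `sex`, `education`.
#' @param depressive_symptoms numeric vector (e.g. a depression rating
#'   total), aligned with `covariates`; or NULL to omit.
#' @param include_tremor_duration also adjust for tremor duration.
#' @param conf_level confidence level of the interval.
#' @return list with `estimate` (second group level minus first),
#'   `ci_lower`, `ci_upper`, `p_value`, `term`.
#' @export
adjusted_association <- function(score, covariates,
                                 depressive_symptoms = NULL,
                                 include_tremor_duration = FALSE,
                                 conf_level = 0.95) {
  df <- data.frame(score = score,
                   group = droplevels(factor(covariates$group)),
                   age = covariates$age, sex = covariates$sex,
                   education = covariates$education)
  form <- score ~ group + age + sex + education
  if (!is.null(depressive_symptoms)) {
    df$depressive <- depressive_symptoms
    form <- stats::update(form, . ~ . + depressive)
  }
  if (include_tremor_duration) {
    df$tremor_duration <- covariates$tremor_duration
    form <- stats::update(form, . ~ . + tremor_duration)
  }
  if (nrow(df) <= length(attr(stats::terms(form), "term.labels")) + 1) {
    stop("adjusted_association: n must exceed the number of parameters")
  }
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) {
    stop("adjusted_association: rank-deficient design: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  }
  term <- grep("^group", names(stats::coef(fit)), value = TRUE)
  est <- stats::coef(fit)[[term]]
  if (stats::var(df$score) == 0) {
    return(list(estimate = 0, ci_lower = 0, ci_upper = 0, p_value = 1,
                term = term))
  }
  ci <- stats::confint(fit, term, level = conf_level)
  p <- summary(fit)$coefficients[term, "Pr(>|t|)"]
  list(estimate = est, ci_lower = ci[1], ci_upper = ci[2], p_value = p,
       term = term)
}
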