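# Final-model evaluation: an exhaustive subset-search oracle against which
# the greedy wrapper can be checked, a hard-margin linear-separability
# report, scatter-matrix figures, and the subgroup re-run of the whole
# selection machinery.

#' Exhaustive subset search
#'
#' Evaluates [cv_accuracy()] for every subset of the candidate features of
#' size 1..`max_size` and returns the best subset(s). Enumeration is
#' guarded: more than 20 candidate features combined with `max_size > 4`
#' is refused with a pointer to the greedy path. By construction the best
#' exhaustive accuracy is an upper bound on the greedy wrapper's final
#' accuracy whenever `max_size` covers the greedy subset size.
#'
#' @param features character vector of candidate feature ids.
#' @param table,labels,plan,config as in [cv_accuracy()].
#' @param max_size largest subset size to enumerate (>= 1).
#' @return list with `best_subsets` (list of character vectors, ties
#'   included, deterministic order), `best_accuracy`, `n_evaluated`.
#' @export
exhaustive_subset_search <- function(features, table, labels, plan,
                                     config = svm_config(), max_size) {
  if (max_size < 1) stop("exhaustive_subset_search: max_size must be >= 1")
  max_size <- min(max_size, length(features))
  if (length(features) > 20 && max_size > 4) {
    stop("exhaustive_subset_search: enumeration guard exceeded (",
         length(features), " features, max_size ", max_size,
         "); use greedy_wrapper_select() instead")
  }
  best_correct <- -1L
  best <- list()
  n_eval <- 0L
  for (size in seq_len(max_size)) {
    combos <- utils::combn(features, size, simplify = FALSE)
    for (subset in combos) {
      acc <- cv_accuracy(subset, table, labels, plan, config)
      n_eval <- n_eval + 1L
      corr <- attr(acc, "correct")
      if (corr > best_correct) {
        best_correct <- corr
        best <- list(subset)
      } else if (corr == best_correct) {
        best[[length(best) + 1L]] <- subset
      }
    }
  }
  list(best_subsets = best, best_accuracy = best_correct / length(plan$fold),
       n_evaluated = n_eval)
}

#' Hard-margin linear separability of a feature subset
#'
#' Tests whether a maximum-margin hyperplane separates the two classes on
#' the given features and reports its width. Features are z-scored over
#' all subjects by default (set `scale = FALSE` to work in raw units). The
#' maximum-margin problem is solved as a soft-margin linear SVM at a very
#' large cost (1e6); the configuration is declared separable when no
#' training point violates the margin beyond a 1e-3 slack tolerance, and
#' the margin is the geometric width `2 / ||w||`. Non-separable subsets
#' report `margin = 0`.
#'
#' @param subset character vector of feature ids (non-empty).
#' @param table a [morphometry_table()] or numeric matrix.
#' @param labels two-class labels.
#' @param scale z-score features over all subjects first (default TRUE).
#' @return object of class `separation_report`: `subset`, `separable`,
#'   `margin`, `weights`, `offset`.
#' @export
linear_separation <- function(subset, table, labels, scale = TRUE) {
  if (length(subset) == 0) stop("linear_separation: subset must be non-empty")
  X <- if (inherits(table, "morphometry_table")) {
    table$values[, feature_columns(table, subset), drop = FALSE]
  } else {
    as.matrix(table)[, subset, drop = FALSE]
  }
  y <- droplevels(factor(labels))
  if (nlevels(y) != 2) stop("linear_separation: two classes required")
  if (scale) {
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    X <- base::scale(X, center = TRUE, scale = sdv)
  }
  ypm <- ifelse(y == levels(y)[2], 1, -1)
  fit <- e1071::svm(X, y, kernel = "linear", cost = 1e6,
                    tolerance = 1e-6, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # the SVM solution fixes the hyperplane up to sign; orient it so the
  # second factor level sits on the positive side
  f <- drop(X %*% w) + b
  if (min(-ypm * f) > min(ypm * f)) { w <- -w; b <- -b; f <- -f }
  min_margin <- min(ypm * f)
  separable <- min_margin >= 1 - 1e-3
  structure(
    list(subset = subset, separable = separable,
         margin = if (separable) 2 / sqrt(sum(w^2)) else 0,
         weights = w, offset = b),
    class = "separation_report"
  )
}

#' @export
print.separation_report <- function(x, ...) {
  cat("<separation_report> {", paste(x$subset, collapse = ", "), "}: ",
      if (x$separable) sprintf("separable, margin %.4f", x$margin)
      else "not linearly separable", "\n", sep = "")
  invisible(x)
}

#' Scatter-matrix figure for a feature subset
#'
#' Writes a pairwise scatter-panel grid for the subset, colored by group,
#' with per-group histograms on the diagonal (a single histogram panel for
#' a one-feature subset).
#'
#' @param subset character vector of feature ids (non-empty).
#' @param table a [morphometry_table()] or numeric matrix.
#' @param labels two-class labels; both classes must be present.
#' @param out_path output PNG path.
#' @param width,height device size in pixels.
#' @return `out_path`, invisibly.
#' @export
scatter_matrix_report <- function(subset, table, labels, out_path,
                                  width = 200 * max(length(subset), 2),
                                  height = 200 * max(length(subset), 2)) {
  if (length(subset) == 0) stop("scatter_matrix_report: empty subset")
  y <- droplevels(factor(labels))
  if (nlevels(y) != 2 || any(table(y) == 0)) {
    stop("scatter_matrix_report: both classes must be present")
  }
  X <- if (inherits(table, "morphometry_table")) {
    table$values[, feature_columns(table, subset), drop = FALSE]
  } else {
    as.matrix(table)[, subset, drop = FALSE]
  }
  cols <- c("#1f78b4", "#e31a1c")
  k <- length(subset)
  grDevices::png(out_path, width = width, height = height)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(k, k), mar = c(2.5, 2.5, 1.5, 0.5),
                      mgp = c(1.5, 0.5, 0))
  on.exit(graphics::par(op), add = TRUE)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) {
        xi <- X[, i]
        brk <- pretty(xi, n = 12)
        h1 <- graphics::hist(xi[y == levels(y)[1]], breaks = brk, plot = FALSE)
        h2 <- graphics::hist(xi[y == levels(y)[2]], breaks = brk, plot = FALSE)
        ymax <- max(h1$counts, h2$counts)
        graphics::plot(h1, col = grDevices::adjustcolor(cols[1], 0.6),
                       border = NA, main = subset[i], xlab = "", ylab = "",
                       ylim = c(0, ymax))
        graphics::plot(h2, col = grDevices::adjustcolor(cols[2], 0.6),
                       border = NA, add = TRUE)
      } else {
        graphics::plot(X[, j], X[, i], col = cols[as.integer(y)], pch = 19,
                       xlab = subset[j], ylab = subset[i], main = "")
      }
    }
  }
  invisible(out_path)
}

#' Re-run the selection pipeline on a subgroup contrast
#'
#' Identical machinery to the primary analysis - ANCOVA screen, IGR
#' ranking, greedy wrapper, separability report - applied to a different
#' label column (e.g. primary cases versus cases with mild parkinsonian
#' signs). When the smaller class has fewer members than the requested
#' fold count, the plan is downgraded to leave-one-out with a warning;
#' classes below 3 subjects additionally warn that the contrast is fragile.
#'
#' @param table a [morphometry_table()] or numeric matrix.
#' @param covariates covariate data.frame (its `group` column is replaced
#'   by `subgroup_labels` for screening).
#' @param subgroup_labels two-level labels aligned with subjects.
#' @param alpha screening threshold.
#' @param n_folds requested fold count (default 10).
#' @param seed fold-plan seed.
#' @param config an [svm_config()].
#' @return list with `screen`, `ranking`, `trace`, `separation`, `plan`;
#'   `ranking`, `trace` and `separation` are NULL when nothing survives
#'   screening.
#' @export
run_subgroup_analysis <- function(table, covariates, subgroup_labels,
                                  alpha = 0.05, n_folds = 10, seed = 1,
                                  config = svm_config()) {
  y <- droplevels(factor(subgroup_labels))
  if (nlevels(y) != 2) {
    stop("run_subgroup_analysis: both subgroup labels must be present")
  }
  sizes <- table(y)
  if (min(sizes) < 3) {
    warning("run_subgroup_analysis: a subgroup has fewer than 3 subjects; ",
            "results are fragile")
  }
  covs <- covariates
  covs$group <- y
  screen <- screen_features(table, covs, alpha = alpha)
  if (nrow(screen) == 0) {
    return(list(screen = screen, ranking = NULL, trace = NULL,
                separation = NULL, plan = NULL))
  }
  n <- length(y)
  folds <- n_folds
  if (min(sizes) < n_folds) {
    warning("run_subgroup_analysis: smallest class (", min(sizes),
            ") below fold count (", n_folds,
            "); using leave-one-out cross-validation")
    folds <- n
  }
  plan <- cv_plan(y, n_folds = folds, stratified = TRUE, seed = seed)
  sub_table <- if (inherits(table, "morphometry_table")) {
    table$values[, screen$feature_id, drop = FALSE]
  } else {
    as.matrix(table)[, screen$feature_id, drop = FALSE]
  }
  ranking <- rank_features(sub_table, y)
  trace <- greedy_wrapper_select(ranking, sub_table, y, plan, config)
  separation <- linear_separation(trace$final_subset, sub_table, y)
  list(screen = screen, ranking = ranking, trace = trace,
       separation = separation, plan = plan)
}
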