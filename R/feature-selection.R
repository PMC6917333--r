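# Selection core: information-gain-ratio scoring of continuous features on
# their best binary midpoint split, descending ranking, and a greedy
# forward wrapper whose acceptance criterion is stratified k-fold
# cross-validated accuracy of a linear SVM on the candidate subset.

#' Information gain ratio of a continuous feature
#'
#' Scores a feature on a two-class label by its best binary split:
#' candidate thresholds are the midpoints between consecutive distinct
#' sorted values; for each, the information gain is
#' `IG = H(labels) - sum_i (n_i/n) H(labels_i)` over the two sides and the
#' split information is `SI = -sum_i (n_i/n) log2(n_i/n)` (entropies in
#' bits); the score is `IGR = IG / SI`, maximized over thresholds. Ties are
#' broken toward the lowest threshold. A constant feature has no candidate
#' split and scores 0 (with a warning and an `NA` threshold).
#'
#' IGR is invariant under strictly increasing transformations of the
#' feature and lies in \[0, 1\], hitting 1 exactly when some threshold
#' separates the classes perfectly.
#'
#' @param values numeric feature values (>= 2 subjects).
#' @param labels two-class labels aligned with `values`.
#' @return list with `igr` and `split_threshold`.
#' @examples
#' information_gain_ratio(c(1, 1, 2, 2), c("A", "A", "B", "B"))
#' @export
information_gain_ratio <- function(values, labels) {
  if (length(values) < 2 || length(values) != length(labels)) {
    stop("information_gain_ratio: need >= 2 aligned values and labels")
  }
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2) {
    stop("information_gain_ratio: both classes must be present")
  }
  ord <- order(values)
  v <- values[ord]; l <- labels[ord]
  n <- length(v)
  cuts <- which(diff(v) > 0)
  if (length(cuts) == 0) {
    warning("information_gain_ratio: constant feature, no candidate split")
    return(list(igr = 0, split_threshold = NA_real_))
  }
  h0 <- entropy_bits(table(l))
  # cumulative class counts make each split O(1)
  counts <- sapply(levels(l), function(lv) cumsum(l == lv))
  total <- table(l)[levels(l)]
  best <- -Inf; best_thr <- NA_real_
  for (i in cuts) {
    left <- counts[i, ]
    right <- as.numeric(total) - left
    ig <- h0 - (i / n) * entropy_bits(left) -
      ((n - i) / n) * entropy_bits(right)
    si <- entropy_bits(c(i, n - i))
    igr <- ig / si
    if (igr > best + 1e-12) {
      best <- igr
      best_thr <- (v[i] + v[i + 1]) / 2
    }
  }
  list(igr = min(max(best, 0), 1), split_threshold = best_thr)
}

#' Rank features by information gain ratio
#'
#' Computes [information_gain_ratio()] per feature and sorts in descending
#' order, ties broken by feature id (C-locale lexicographic) for
#' determinism.
#'
#' @param table a [morphometry_table()] or numeric matrix (typically
#'   restricted to screened features).
#' @param labels two-class labels aligned with rows.
#' @return data.frame with `feature_id`, `igr`, `split_threshold`, `rank`.
#' @export
rank_features <- function(table, labels) {
  X <- if (inherits(table, "morphometry_table")) table$values else as.matrix(table)
  if (ncol(X) < 1) stop("rank_features: need at least one feature")
  scores <- lapply(seq_len(ncol(X)), function(j) {
    suppressWarnings(information_gain_ratio(X[, j], labels))
  })
  out <- data.frame(
    feature_id = colnames(X) %||% sprintf("f%d", seq_len(ncol(X))),
    igr = vapply(scores, `[[`, numeric(1), "igr"),
    split_threshold = vapply(scores, `[[`, numeric(1), "split_threshold"),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$igr, out$feature_id, method = "radix"), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Deterministic (stratified) cross-validation plan
#'
#' Assigns every subject to exactly one fold. Stratified assignment
#' shuffles each class with the seeded RNG and deals subjects round-robin
#' across folds, so fold sizes differ by at most one and per-fold class
#' counts are within one of proportionality. The plan is frozen and reused
#' across all wrapper steps, making subset accuracies comparable.
#'
#' @param labels class labels, named by subject id if available.
#' @param n_folds number of folds (default 10); `n_folds = length(labels)`
#'   gives leave-one-out.
#' @param stratified stratify folds by class (default TRUE).
#' @param seed integer seed for the shuffle.
#' @return object of class `cv_plan`: `fold` (integer vector aligned with
#'   labels), `n_folds`, `stratified`, `seed`.
#' @export
cv_plan <- function(labels, n_folds = 10, stratified = TRUE, seed = 1) {
  n <- length(labels)
  if (n_folds < 2 || n_folds > n) {
    stop("cv_plan: n_folds must be in [2, n]")
  }
  fold <- integer(n)
  with_seed(seed, {
    if (stratified) {
      pos <- 0L
      for (lv in levels(droplevels(factor(labels)))) {
        idx <- which(labels == lv)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- ((pos + seq_along(idx) - 1L) %% n_folds) + 1L
        pos <- pos + length(idx)
      }
    } else {
      fold <- ((sample.int(n) - 1L) %% n_folds) + 1L
    }
  })
  names(fold) <- names(labels)
  structure(list(fold = fold, n_folds = as.integer(n_folds),
                 stratified = stratified, seed = as.integer(seed)),
            class = "cv_plan")
}

#' Linear SVM classifier settings
#'
#' The classifier underlying the wrapper: a linear ("dot") kernel support
#' vector machine with soft-margin cost `cost` and convergence tolerance
#' `tolerance` (default 1e-3). Features are z-scored on each training fold
#' before fitting, since raw morphometry mixes mm^3-scale volumes with
#' mm-scale thicknesses.
#'
#' @param cost soft-margin penalty C (default 1).
#' @param tolerance optimizer convergence tolerance (default 1e-3).
#' @return object of class `svm_config`.
#' @export
svm_config <- function(cost = 1, tolerance = 1e-3) {
  if (cost <= 0) stop("svm_config: cost must be positive")
  structure(list(kernel = "linear", cost = cost, tolerance = tolerance),
            class = "svm_config")
}

# Fit on training rows (z-scored) and predict the held-out rows. A
# single-class training fold predicts its class everywhere.
fit_predict_fold <- function(X, y, train, test, config) {
  ytr <- droplevels(y[train])
  if (nlevels(ytr) < 2) {
    return(factor(rep(levels(ytr)[1], length(test)), levels = levels(y)))
  }
  Xtr <- X[train, , drop = FALSE]
  mu <- colMeans(Xtr)
  sdv <- apply(Xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xtr <- scale(Xtr, center = mu, scale = sdv)
  Xte <- scale(X[test, , drop = FALSE], center = mu, scale = sdv)
  fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = config$cost,
                    tolerance = config$tolerance, scale = FALSE)
  stats::predict(fit, Xte)
}

# Pooled count of correct held-out predictions over all folds.
cv_correct_count <- function(X, labels, plan, config) {
  y <- droplevels(factor(labels))
  correct <- 0L
  for (k in sort(unique(plan$fold))) {
    test <- which(plan$fold == k)
    train <- which(plan$fold != k)
    pred <- fit_predict_fold(X, y, train, test, config)
    correct <- correct + sum(as.character(pred) == as.character(y[test]))
  }
  as.integer(correct)
}

#' Cross-validated accuracy of a feature subset
#'
#' For each fold of the plan: z-score the subset's features on the
#' training rows, fit the linear SVM, predict the held-out rows. Accuracy
#' pools correct predictions over all folds. The exact correct count is
#' attached as attributes `correct` and `n` so that downstream accuracy
#' comparisons are integer-exact.
#'
#' @param subset character vector of feature ids (non-empty).
#' @param table a [morphometry_table()] or numeric matrix.
#' @param labels two-class labels aligned with rows.
#' @param plan a [cv_plan()] covering all subjects.
#' @param config an [svm_config()].
#' @return accuracy in \[0, 1\] with attributes `correct`, `n`.
#' @export
cv_accuracy <- function(subset, table, labels, plan,
                        config = svm_config()) {
  if (length(subset) == 0) stop("cv_accuracy: subset must be non-empty")
  X <- if (inherits(table, "morphometry_table")) {
    table$values[, feature_columns(table, subset), drop = FALSE]
  } else {
    as.matrix(table)[, subset, drop = FALSE]
  }
  if (length(plan$fold) != nrow(X)) {
    stop("cv_accuracy: plan does not cover all subjects")
  }
  correct <- cv_correct_count(X, labels, plan, config)
  structure(correct / nrow(X), correct = correct, n = nrow(X))
}

#' Greedy forward wrapper subset selection
#'
#' The selection procedure at the heart of the pipeline: initialize the
#' subset with the top-ranked feature and its cross-validated accuracy;
#' then walk the ranking, tentatively adding each feature, recomputing CV
#' accuracy on the identical frozen fold plan, and keeping the feature if
#' and only if accuracy is equal or higher than the current best
#' (comparison on exact correct counts). The walk stops after every ranked
#' feature has been tried once; the trace records every decision.
#'
#' @param ranked data.frame from [rank_features()] (non-empty).
#' @param table,labels,plan,config as in [cv_accuracy()].
#' @return object of class `selection_trace`: `steps` (data.frame of
#'   `step`, `feature_id`, `cv_accuracy`, `decision`), `final_subset`,
#'   `final_accuracy`, `plan`, `config`.
#' @export
greedy_wrapper_select <- function(ranked, table, labels, plan,
                                  config = svm_config()) {
  if (nrow(ranked) == 0) stop("greedy_wrapper_select: ranking is empty")
  n <- length(plan$fold)
  subset <- ranked$feature_id[1]
  acc <- cv_accuracy(subset, table, labels, plan, config)
  best_correct <- attr(acc, "correct")
  steps <- list(data.frame(step = 1L, feature_id = subset,
                           cv_accuracy = as.numeric(acc), decision = "kept",
                           stringsAsFactors = FALSE))
  if (nrow(ranked) > 1) {
    for (i in 2:nrow(ranked)) {
      fid <- ranked$feature_id[i]
      acc_i <- cv_accuracy(c(subset, fid), table, labels, plan, config)
      keep <- attr(acc_i, "correct") >= best_correct
      if (keep) {
        subset <- c(subset, fid)
        best_correct <- attr(acc_i, "correct")
      }
      steps[[i]] <- data.frame(step = i, feature_id = fid,
                               cv_accuracy = as.numeric(acc_i),
                               decision = if (keep) "kept" else "discarded",
                               stringsAsFactors = FALSE)
    }
  }
  structure(
    list(steps = do.call(rbind, steps), final_subset = subset,
         final_accuracy = best_correct / n, plan = plan, config = config),
    class = "selection_trace"
  )
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace> ", nrow(x$steps), " steps, ",
      length(x$final_subset), " features kept, final CV accuracy ",
      sprintf("%.3f", x$final_accuracy), "\n", sep = "")
  cat("  subset: ", paste(x$final_subset, collapse = ", "), "\n", sep = "")
  invisible(x)
}
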