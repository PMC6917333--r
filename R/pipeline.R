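# End-to-end orchestration: input (stats directory, feature CSV, or
# synthetic spec) -> demographics -> ANCOVA screen -> IGR ranking -> greedy
# wrapper -> separability report -> report bundle on disk. A manifest
# records the seed and a config fingerprint; a fixed config and seed give a
# byte-identical results.json.

#' Pipeline configuration
#'
#' Exactly one input mode must be set: a features CSV plus covariates CSV,
#' a stats directory plus covariates CSV, or a [synthetic_spec()].
#'
#' @param features_csv path to a canonical features CSV
#'   (see [write_feature_csv()]).
#' @param stats_dir directory of per-subject stats files
#'   (see [read_stats_dir()]).
#' @param covariates_csv path to a covariates CSV (subject_id, group, age,
#'   sex, education, tremor_duration, ...).
#' @param synthetic a [synthetic_spec()] used in place of files.
#' @param label_column covariates column holding the two-class label
#'   (default `"group"`); point it at a subgroup column to run a subgroup
#'   contrast.
#' @param alpha ANCOVA screening threshold in (0, 1).
#' @param n_folds,stratified,seed cross-validation plan settings.
#' @param svm an [svm_config()].
#' @param out_dir output directory for the report bundle.
#' @param scatter also write the scatter-matrix PNG of the final subset.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(features_csv = NULL, stats_dir = NULL,
                            covariates_csv = NULL, synthetic = NULL,
                            label_column = "group", alpha = 0.05,
                            n_folds = 10, stratified = TRUE, seed = 1,
                            svm = svm_config(), out_dir = tempfile("morphoclass_"),
                            scatter = FALSE) {
  modes <- c(files = !is.null(features_csv) || !is.null(stats_dir),
             synthetic = !is.null(synthetic))
  if (sum(modes) != 1) {
    stop("pipeline_config: exactly one input mode must be set ",
         "(features_csv/stats_dir + covariates_csv, or synthetic)")
  }
  if (modes[["files"]]) {
    if (!is.null(features_csv) && !is.null(stats_dir)) {
      stop("pipeline_config: give features_csv or stats_dir, not both")
    }
    if (is.null(covariates_csv)) {
      stop("pipeline_config: file input requires covariates_csv")
    }
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha >= 1) {
    stop("pipeline_config: alpha must be in [0, 1)")
  }
  if (n_folds < 2) stop("pipeline_config: folds must be >= 2")
  structure(
    list(features_csv = features_csv, stats_dir = stats_dir,
         covariates_csv = covariates_csv, synthetic = synthetic,
         label_column = label_column, alpha = alpha,
         n_folds = as.integer(n_folds), stratified = stratified,
         seed = as.integer(seed), svm = svm, out_dir = out_dir,
         scatter = scatter),
    class = "pipeline_config"
  )
}

config_fingerprint <- function(config) {
  drop_paths <- config[setdiff(names(config), "out_dir")]
  fnv1a_hex(jsonlite::toJSON(drop_paths, auto_unbox = TRUE, digits = NA,
                             force = TRUE, null = "null"))
}

#' Run the full classification pipeline
#'
#' Stages, in order: load or generate the cohort; demographic comparison
#' battery; per-feature covariate-adjusted ANCOVA screen at `alpha`; IGR
#' ranking of the survivors; greedy forward-wrapper SVM selection on a
#' frozen stratified fold plan; hard-margin separability report of the
#' final subset. Writes a report bundle to `config$out_dir`:
#' `results.json`, `screen.csv` (all per-feature ANCOVA results),
#' `demographics.csv`, `ranking.csv`, `trace.csv`, `manifest.json`, and
#' optionally `scatter_matrix.png`. If no feature survives screening the
#' pipeline stops after the screen with status
#' `"no features passed screening"`.
#'
#' @param config a [pipeline_config()].
#' @return the results list, invisibly; its `status` field is `"ok"` or
#'   `"no features passed screening"`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("run_pipeline: config must be a pipeline_config")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  # --- load ---------------------------------------------------------------
  cohort <- stage("input", {
    if (!is.null(config$synthetic)) {
      generate_cohort(config$synthetic)
    } else {
      table <- if (!is.null(config$features_csv)) {
        read_feature_csv(config$features_csv)
      } else {
        read_stats_dir(config$stats_dir)
      }
      covariates <- utils::read.csv(config$covariates_csv,
                                    stringsAsFactors = FALSE)
      ord <- match(table$subjects, covariates$subject_id)
      if (anyNA(ord)) {
        stop("covariates missing for subjects: ",
             paste(table$subjects[is.na(ord)], collapse = ", "))
      }
      list(covariates = covariates[ord, , drop = FALSE], table = table)
    }
  })
  labels <- cohort$covariates[[config$label_column]]
  if (is.null(labels)) {
    stop("pipeline stage [input] failed: no label column '",
         config$label_column, "' in covariates", call. = FALSE)
  }
  labels <- droplevels(factor(labels))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  demographics <- stage("demographics", {
    covs <- cohort$covariates
    covs$group <- labels
    compare_demographics(covs)
  })
  screen_covs <- cohort$covariates
  screen_covs$group <- labels
  screen <- stage("screen",
                  screen_features(cohort$table, screen_covs, config$alpha))
  results <- list(
    status = "ok",
    n_subjects = length(labels),
    groups = as.list(table(labels)),
    alpha = config$alpha,
    n_features = ncol(cohort$table$values),
    n_significant = nrow(screen)
  )
  utils::write.csv(attr(screen, "full_results"),
                   file.path(config$out_dir, "screen.csv"), row.names = FALSE)
  utils::write.csv(demographics,
                   file.path(config$out_dir, "demographics.csv"),
                   row.names = FALSE)

  if (nrow(screen) == 0) {
    results$status <- "no features passed screening"
  } else {
    X <- cohort$table$values[, screen$feature_id, drop = FALSE]
    ranking <- stage("rank", rank_features(X, labels))
    plan <- stage("cv_plan", {
      folds <- config$n_folds
      if (min(table(labels)) < folds) {
        warning("smallest class below fold count; using leave-one-out")
        folds <- length(labels)
      }
      cv_plan(labels, n_folds = folds, stratified = config$stratified,
              seed = config$seed)
    })
    trace <- stage("select",
                   greedy_wrapper_select(ranking, X, labels, plan, config$svm))
    separation <- stage("evaluate",
                        linear_separation(trace$final_subset, X, labels))
    utils::write.csv(ranking, file.path(config$out_dir, "ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(trace$steps, file.path(config$out_dir, "trace.csv"),
                     row.names = FALSE)
    if (isTRUE(config$scatter)) {
      stage("report", scatter_matrix_report(
        trace$final_subset, X, labels,
        file.path(config$out_dir, "scatter_matrix.png")))
    }
    results$ranking <- ranking
    results$selection <- list(
      steps = trace$steps,
      final_subset = trace$final_subset,
      final_accuracy = trace$final_accuracy
    )
    results$separation <- list(
      subset = separation$subset, separable = separation$separable,
      margin = separation$margin
    )
  }
  results$screen_significant <- screen

  jsonlite::write_json(results, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  manifest <- list(
    package = "morphoclass",
    package_version = as.character(utils::packageVersion("morphoclass")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_fingerprint = config_fingerprint(config),
    label_column = config$label_column,
    alpha = config$alpha, n_folds = config$n_folds
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}

#' Command-line entry point
#'
#' Thin argument-vector interface used by the `inst/cli/morphoclass.R`
#' script: `morphoclass.R <simulate|run> [--out DIR] [--seed N]
#' [--alpha A] [--folds K] [--label-column COL] [--features-csv F
#' --covariates-csv C | --stats-dir D --covariates-csv C]`.
#' `simulate` writes a default synthetic cohort (features + covariates
#' CSV) to `--out`; `run` executes the pipeline and writes the report
#' bundle to `--out`.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, 0 on success (invisibly).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: morphoclass.R <simulate|run> [--out DIR] [--seed N] [--alpha A]",
    "  [--folds K] [--label-column COL]",
    "  [--features-csv F --covariates-csv C | --stats-dir D --covariates-csv C]",
    sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opts <- list(out = "morphoclass_out", seed = 1L, alpha = 0.05,
               folds = 10L, `label-column` = "group",
               `features-csv` = NULL, `covariates-csv` = NULL,
               `stats-dir` = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts) || i == length(args)) {
      message("unknown or incomplete option: ", args[i], "\n", usage)
      return(invisible(1L))
    }
    opts[[key]] <- args[i + 1]
    i <- i + 2
  }
  seed <- as.integer(opts$seed)
  if (cmd == "simulate") {
    dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
    cohort <- generate_cohort(synthetic_spec(seed = seed))
    write_cohort_csv(cohort, file.path(opts$out, "features.csv"),
                     file.path(opts$out, "covariates.csv"))
    message("wrote synthetic cohort to ", opts$out)
    return(invisible(0L))
  }
  if (cmd != "run") { message(usage); return(invisible(1L)) }
  config <- pipeline_config(
    features_csv = opts$`features-csv`, stats_dir = opts$`stats-dir`,
    covariates_csv = opts$`covariates-csv`,
    synthetic = if (is.null(opts$`features-csv`) && is.null(opts$`stats-dir`))
      synthetic_spec(seed = seed) else NULL,
    label_column = opts$`label-column`, alpha = as.numeric(opts$alpha),
    n_folds = as.integer(opts$folds), seed = seed, out_dir = opts$out
  )
  res <- run_pipeline(config)
  message("pipeline status: ", res$status, "; bundle in ", opts$out)
  invisible(0L)
}
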