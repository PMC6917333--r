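#' Subjects-by-features morphometry table
#'
#' Container for an assembled regional morphometry matrix together with its
#' per-feature descriptors and the per-subject normalizing volumes.
#' Validates on construction: matching dimensions, unique subject and
#' feature ids, positive ICV and GM with GM < ICV, thickness and roughness
#' features unnormalized, and every ICV- or GM-normalized volume strictly
#' inside (0, 1).
#'
#' @param values numeric matrix, subjects in rows, features in columns.
#' @param descriptors data.frame of feature descriptors (as produced by
#'   [default_feature_catalog()]), one row per column of `values`, in
#'   column order.
#' @param subjects character vector of subject ids (defaults to rownames).
#' @param icv,gm per-subject total intracranial and total grey-matter
#'   volumes in mm^3; optional (NULL) when the table was imported from a
#'   bare feature matrix, in which case normalized-range checks that need
#'   them are skipped.
#' @return object of class `morphometry_table` with fields `subjects`,
#'   `descriptors`, `values`, `icv`, `gm`.
#' @export
morphometry_table <- function(values, descriptors,
                              subjects = rownames(values),
                              icv = NULL, gm = NULL) {
  values <- as.matrix(values)
  if (is.null(subjects)) stop("morphometry_table: subjects are required")
  subjects <- as.character(subjects)
  if (anyDuplicated(subjects)) stop("morphometry_table: duplicate subject ids")
  if (any(is.na(subjects)) || any(subjects == "")) {
    stop("morphometry_table: missing subject ids")
  }
  if (nrow(values) != length(subjects)) {
    stop("morphometry_table: values has ", nrow(values),
         " rows but there are ", length(subjects), " subjects")
  }
  if (nrow(descriptors) != ncol(values)) {
    stop("morphometry_table: ", nrow(descriptors),
         " descriptors for ", ncol(values), " feature columns")
  }
  if (anyDuplicated(descriptors$feature_id)) {
    stop("morphometry_table: duplicate feature_id in descriptors")
  }
  bad_norm <- descriptors$measure %in% c("thickness_mean", "roughness") &
    descriptors$normalizer != "none"
  if (any(bad_norm)) {
    stop("morphometry_table: thickness/roughness features must be ",
         "unnormalized: ", paste(descriptors$feature_id[bad_norm], collapse = ", "))
  }
  if (!is.null(icv)) {
    if (length(icv) != length(subjects) || any(icv <= 0)) {
      stop("morphometry_table: icv must be positive for every subject")
    }
    if (is.null(gm)) stop("morphometry_table: gm missing while icv present")
    if (length(gm) != length(subjects) || any(gm <= 0)) {
      stop("morphometry_table: gm must be positive for every subject")
    }
    if (any(gm >= icv)) stop("morphometry_table: gm must be < icv")
    norm_cols <- which(descriptors$normalizer %in% c("ICV", "GM"))
    if (length(norm_cols) > 0) {
      v <- values[, norm_cols, drop = FALSE]
      if (any(v <= 0) || any(v >= 1)) {
        stop("morphometry_table: normalized volumes must lie in (0, 1)")
      }
    }
  }
  rownames(values) <- subjects
  colnames(values) <- descriptors$feature_id
  structure(
    list(subjects = subjects, descriptors = descriptors, values = values,
         icv = icv, gm = gm),
    class = "morphometry_table"
  )
}

#' @export
dim.morphometry_table <- function(x) dim(x$values)

#' @export
as.matrix.morphometry_table <- function(x, ...) x$values

#' @export
print.morphometry_table <- function(x, ...) {
  cat("<morphometry_table> ", length(x$subjects), " subjects x ",
      nrow(x$descriptors), " features\n", sep = "")
  meas <- table(x$descriptors$measure)
  cat("  measures: ", paste(names(meas), meas, sep = "=", collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$icv)) {
    cat("  ICV range: ", format(min(x$icv), big.mark = ","), " - ",
        format(max(x$icv), big.mark = ","), " mm^3\n", sep = "")
  }
  invisible(x)
}

# Resolve a feature subset to column indices, with a clear error.
feature_columns <- function(table, subset) {
  idx <- match(subset, table$descriptors$feature_id)
  if (anyNA(idx)) {
    stop("unknown feature id(s): ", paste(subset[is.na(idx)], collapse = ", "))
  }
  idx
}
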