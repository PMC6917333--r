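# Synthetic two-group cohort generator. Emulates the structure of a small
# case-case tremor study: two diagnostic groups of ~14/15 subjects, four
# clinical covariates (age, sex, education, tremor duration), and a few
# hundred regional morphometry features with optional planted group effects
# and covariate leakage. Everything downstream of image processing can be
# exercised and calibrated against it.

default_covariate_params <- function() {
  # Group A emulates the orthostatic tremor arm, group B the essential
  # tremor arm of the motivating cohort: age 65.0+-13.9 vs 68.5+-8.3 y,
  # education 8.0+-4.9 vs 6.9+-3.1 y, tremor duration 9.4+-6.9 vs
  # 24.9+-18.4 y, sex (female) 12/14 vs 11/15.
  list(
    age = list(a = c(mean = 65.0, sd = 13.9), b = c(mean = 68.5, sd = 8.3)),
    sex = list(a = 12 / 14, b = 11 / 15),
    education = list(a = c(mean = 8.0, sd = 4.9), b = c(mean = 6.9, sd = 3.1)),
    tremor_duration = list(a = c(mean = 9.4, sd = 6.9),
                           b = c(mean = 24.9, sd = 18.4))
  )
}

#' Specification of a synthetic cohort
#'
#' Bundles everything [generate_cohort()] needs: group sizes, covariate
#' distributions, the feature catalog, a map of planted standardized group
#' effects, optional covariate leakage into features, a global noise level
#' and a seed. Defaults reproduce the study conditions this package
#' models: 14 vs 15 subjects, the covariate distributions above, and the
#' 281-feature catalog of [default_feature_catalog()].
#'
#' @param n_group_a,n_group_b group sizes (each >= 2).
#' @param groups labels for groups a and b (default `c("OT", "ET")`).
#' @param covariate_params list with elements `age`, `sex`, `education`,
#'   `tremor_duration`; continuous entries carry per-group `c(mean, sd)`
#'   (truncated at 0 when drawn), `sex` carries per-group probabilities of
#'   the indicator level (female = 1).
#' @param feature_catalog descriptor data.frame; see
#'   [default_feature_catalog()] and [simple_catalog()].
#' @param effect_map named numeric vector of standardized effect sizes
#'   (Cohen's d, signed group_b - group_a) keyed by feature id. Keys must
#'   name directly drawn features; /GM-normalized columns are derived from
#'   their /ICV counterpart, so plant the effect there.
#' @param covariate_leakage optional named list (by feature id) of named
#'   numeric slopes on covariates, in feature units per covariate unit.
#' @param noise_sd positive noise multiplier; a feature's residual SD is
#'   `noise_sd * scale` in its own units, so a planted `d` shifts the group
#'   mean by `d * noise_sd * scale`.
#' @param seed integer seed; fixed seed gives bit-identical cohorts.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_group_a = 14, n_group_b = 15,
                           groups = c("OT", "ET"),
                           covariate_params = default_covariate_params(),
                           feature_catalog = default_feature_catalog(),
                           effect_map = NULL,
                           covariate_leakage = NULL,
                           noise_sd = 1, seed = 1) {
  if (!is.numeric(n_group_a) || n_group_a < 2) {
    stop("synthetic_spec: n_group_a must be >= 2")
  }
  if (!is.numeric(n_group_b) || n_group_b < 2) {
    stop("synthetic_spec: n_group_b must be >= 2")
  }
  if (length(groups) != 2 || anyDuplicated(groups)) {
    stop("synthetic_spec: groups must be two distinct labels")
  }
  need <- c("age", "sex", "education", "tremor_duration")
  if (!all(need %in% names(covariate_params))) {
    stop("synthetic_spec: covariate_params must define ",
         paste(setdiff(need, names(covariate_params)), collapse = ", "))
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1 || noise_sd <= 0) {
    stop("synthetic_spec: noise_sd must be a positive scalar")
  }
  if (!is.null(effect_map)) {
    if (is.null(names(effect_map)) || any(names(effect_map) == "")) {
      stop("synthetic_spec: effect_map must be a named numeric vector")
    }
    unknown <- setdiff(names(effect_map), feature_catalog$feature_id)
    if (length(unknown) > 0) {
      stop("synthetic_spec: effect_map names not in feature_catalog: ",
           paste(unknown, collapse = ", "))
    }
    derived <- names(effect_map)[
      feature_catalog$derived[match(names(effect_map),
                                    feature_catalog$feature_id)]]
    if (length(derived) > 0) {
      stop("synthetic_spec: effects cannot be planted on derived /GM ",
           "columns (", paste(derived, collapse = ", "),
           "); plant them on the /ICV variant instead")
    }
  }
  if (!is.null(covariate_leakage)) {
    unknown <- setdiff(names(covariate_leakage), feature_catalog$feature_id)
    if (length(unknown) > 0) {
      stop("synthetic_spec: covariate_leakage names not in feature_catalog: ",
           paste(unknown, collapse = ", "))
    }
  }
  structure(
    list(n_group_a = as.integer(n_group_a), n_group_b = as.integer(n_group_b),
         groups = as.character(groups), covariate_params = covariate_params,
         feature_catalog = feature_catalog,
         effect_map = effect_map, covariate_leakage = covariate_leakage,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

draw_covariates <- function(spec) {
  n_a <- spec$n_group_a; n_b <- spec$n_group_b
  p <- spec$covariate_params
  ids <- sprintf("sub%03d", seq_len(n_a + n_b))
  grp <- factor(rep(spec$groups, c(n_a, n_b)), levels = spec$groups)
  draw_cont <- function(par) c(
    rnorm_trunc0(n_a, par$a[["mean"]], par$a[["sd"]]),
    rnorm_trunc0(n_b, par$b[["mean"]], par$b[["sd"]])
  )
  # fixed draw order: age, sex, education, tremor duration
  age <- draw_cont(p$age)
  sex <- c(stats::rbinom(n_a, 1, p$sex$a), stats::rbinom(n_b, 1, p$sex$b))
  education <- draw_cont(p$education)
  tremor <- draw_cont(p$tremor_duration)
  data.frame(subject_id = ids, group = grp, age = age, sex = sex,
             education = education, tremor_duration = tremor,
             stringsAsFactors = FALSE)
}

draw_features <- function(spec, covariates) {
  cat <- spec$feature_catalog
  n <- nrow(covariates)
  g <- as.integer(covariates$group == spec$groups[2])
  d_of <- function(fid) {
    if (!is.null(spec$effect_map) && fid %in% names(spec$effect_map)) {
      spec$effect_map[[fid]]
    } else 0
  }
  leak_of <- function(fid) {
    if (!is.null(spec$covariate_leakage) &&
        fid %in% names(spec$covariate_leakage)) {
      sl <- spec$covariate_leakage[[fid]]
      rowSums(vapply(names(sl),
                     function(cv) sl[[cv]] * covariates[[cv]], numeric(n)))
    } else 0
  }
  values <- matrix(NA_real_, n, nrow(cat),
                   dimnames = list(covariates$subject_id, cat$feature_id))
  # ICV and GM first: they normalize the derived columns. ICV may itself be
  # a catalog feature with a planted effect.
  icv_row <- which(cat$feature_id == "ICV")
  if (length(icv_row) == 1) {
    icv <- cat$baseline[icv_row] +
      spec$noise_sd * cat$scale[icv_row] *
        (d_of("ICV") * g + stats::rnorm(n)) + leak_of("ICV")
    icv <- pmax(icv, 1)    # guard: volumes must stay positive
  } else {
    icv <- rnorm_trunc0(n, 1.45e6, spec$noise_sd * 1.3e5)
  }
  gm_frac <- pmin(pmax(stats::rnorm(n, 0.45, 0.03), 0.2), 0.8)
  gm <- icv * gm_frac
  # remaining features in catalog order; one consecutive block of draws per
  # feature, so appending catalog rows never perturbs earlier columns
  for (j in seq_len(nrow(cat))) {
    fid <- cat$feature_id[j]
    if (fid == "ICV") { values[, j] <- icv; next }
    if (cat$derived[j]) next
    values[, j] <- cat$baseline[j] +
      spec$noise_sd * cat$scale[j] * (d_of(fid) * g + stats::rnorm(n)) +
      leak_of(fid)
  }
  # derived /GM columns: same underlying raw volume as the /ICV draw
  for (j in which(cat$derived)) {
    icv_id <- sub("/GM$", "/ICV", cat$feature_id[j])
    values[, j] <- values[, icv_id] * icv / gm
  }
  list(values = values, icv = icv, gm = gm)
}

#' Generate a synthetic cohort
#'
#' Draws covariates from the configured per-group distributions (continuous
#' ones truncated at 0) and features as
#' `baseline + noise_sd * scale * (d * group + z) + leakage`, with `z`
#' standard normal, `d` the planted standardized effect (signed group_b -
#' group_a), and /GM-normalized subcortical columns derived from their /ICV
#' draw via the subject's ICV/GM ratio. Deterministic for a fixed seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `covariates` (data.frame of subject_id, group, age,
#'   sex, education, tremor_duration) and `table` (a
#'   [morphometry_table()], columns sorted by feature id).
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) {
    stop("generate_cohort: spec must be a synthetic_spec")
  }
  with_seed(spec$seed, {
    covariates <- draw_covariates(spec)
    drawn <- draw_features(spec, covariates)
  })
  ord <- order_cstr(spec$feature_catalog$feature_id)
  desc <- spec$feature_catalog[ord, , drop = FALSE]
  rownames(desc) <- NULL
  table <- morphometry_table(drawn$values[, ord, drop = FALSE], desc,
                             subjects = covariates$subject_id,
                             icv = drawn$icv, gm = drawn$gm)
  list(covariates = covariates, table = table)
}

#' Generate a cohort with a guaranteed linearly separable signal
#'
#' Starts from a null cohort (no planted effects) and rewrites
#' `k_informative` designated feature columns (the first `k` directly drawn
#' cortical-style features in catalog order) so that the two groups are
#' jointly linearly separable with Euclidean margin at least `margin` in
#' per-feature scale units: each informative coordinate gets a group gap of
#' `margin * scale / sqrt(k)` with folded-normal noise pushed outward from
#' the gap. All other features carry no group signal. The designated ids
#' are attached as `attr(, "informative_features")`.
#'
#' @param spec a [synthetic_spec()]; its `effect_map` is ignored.
#' @param k_informative number of informative features (>= 1).
#' @param margin required Euclidean margin, in per-feature scale units.
#' @return as [generate_cohort()], with the informative ids attached.
#' @export
make_separable_cohort <- function(spec, k_informative, margin) {
  if (!inherits(spec, "synthetic_spec")) {
    stop("make_separable_cohort: spec must be a synthetic_spec")
  }
  cat <- spec$feature_catalog
  eligible <- which(!cat$derived & cat$normalizer == "none" &
                      cat$feature_id != "ICV")
  if (k_informative < 0 || k_informative > length(eligible)) {
    stop("make_separable_cohort: k_informative must be between 0 and ",
         length(eligible), " eligible features")
  }
  if (k_informative > 0 &&
      (!is.numeric(margin) || !is.finite(margin) || margin <= 0)) {
    stop("make_separable_cohort: margin must be a positive finite number")
  }
  spec$effect_map <- NULL
  cohort <- generate_cohort(spec)
  if (k_informative == 0) {
    attr(cohort, "informative_features") <- character(0)
    return(cohort)
  }
  inf_rows <- eligible[seq_len(k_informative)]
  inf_ids <- cat$feature_id[inf_rows]
  g <- cohort$covariates$group == spec$groups[2]
  n_a <- sum(!g); n_b <- sum(g)
  with_seed((spec$seed + 7919L) %% .Machine$integer.max, {
    for (j in seq_along(inf_rows)) {
      row <- inf_rows[j]
      gap <- margin * cat$scale[row] / sqrt(k_informative)
      lo <- cat$baseline[row] - gap / 2 -
        abs(stats::rnorm(n_a)) * spec$noise_sd * cat$scale[row]
      hi <- cat$baseline[row] + gap / 2 +
        abs(stats::rnorm(n_b)) * spec$noise_sd * cat$scale[row]
      cohort$table$values[!g, cat$feature_id[row]] <- lo
      cohort$table$values[g, cat$feature_id[row]] <- hi
    }
  })
  attr(cohort, "informative_features") <- inf_ids
  cohort
}

#' Write a generated cohort to disk
#'
#' `write_cohort_csv()` writes the canonical features CSV plus a covariates
#' CSV. `write_cohort_stats()` writes a directory of FreeSurfer-dialect
#' stats files (`<subject>/stats/aseg.stats`, `lh.aparc.stats`,
#' `rh.aparc.stats`) that [read_stats_dir()] can consume, reconstructing the
#' raw subcortical volumes from the /ICV columns so that normalized values
#' round-trip. Requires a cohort generated from a catalog with the standard
#' naming scheme (e.g. [default_feature_catalog()]).
#'
#' @param cohort result of [generate_cohort()].
#' @param features_csv,covariates_csv,dir output paths.
#' @return the written path(s), invisibly.
#' @export
write_cohort_csv <- function(cohort, features_csv, covariates_csv) {
  write_feature_csv(cohort$table, features_csv)
  utils::write.csv(cohort$covariates, covariates_csv, row.names = FALSE)
  invisible(c(features_csv, covariates_csv))
}

#' @rdname write_cohort_csv
#' @export
write_cohort_stats <- function(cohort, dir) {
  tab <- cohort$table
  desc <- tab$descriptors
  num <- function(x) sprintf("%.6f", x)
  sub_rows <- which(desc$normalizer == "ICV")    # one per structure
  cort_rows <- which(desc$normalizer == "none" & desc$feature_id != "ICV" &
                       desc$measure == "volume")
  for (si in seq_along(tab$subjects)) {
    s <- tab$subjects[si]
    base <- file.path(dir, s, "stats")
    dir.create(base, recursive = TRUE, showWarnings = FALSE)
    icv <- tab$icv[si]; gm <- tab$gm[si]
    aseg <- c(
      "# Title Segmentation Statistics",
      sprintf("# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, %s, mm^3", num(icv)),
      sprintf("# Measure TotalGray, TotalGrayVol, Total gray matter volume, %s, mm^3", num(gm)),
      "# ColHeaders Index SegId NVoxels Volume_mm3 StructName"
    )
    for (k in seq_along(sub_rows)) {
      j <- sub_rows[k]
      raw <- tab$values[si, j] * icv
      aseg <- c(aseg, sprintf("%3d %4d %8d %s %s", k, k, as.integer(round(raw)),
                              num(raw), desc$fs_name[j]))
    }
    writeLines(aseg, file.path(base, "aseg.stats"))
    for (hemi in c("left", "right")) {
      rows <- cort_rows[desc$hemisphere[cort_rows] == hemi]
      lines <- c(
        "# Table of cortical parcellation anatomical statistics",
        sprintf("# hemi %s", if (hemi == "left") "lh" else "rh"),
        "# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd"
      )
      for (j in rows) {
        region_fs <- desc$fs_name[j]
        th <- tab$values[si, feature_id(desc$region[j], hemi, "thickness_mean")]
        rg <- tab$values[si, feature_id(desc$region[j], hemi, "roughness")]
        lines <- c(lines, sprintf("%s %6d %6d %s %s %s", region_fs,
                                  1000L, 800L, num(tab$values[si, j]),
                                  num(th), num(rg)))
      }
      writeLines(lines, file.path(
        base, sprintf("%s.aparc.stats", if (hemi == "left") "lh" else "rh")))
    }
  }
  invisible(dir)
}
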