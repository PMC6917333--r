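# Readers and writers for the FreeSurfer regional-statistics dialect used
# here: '# Measure <name>, <short>, <description>, <value>, <unit>' header
# lines, an optional '# ColHeaders ...' line, and a whitespace-delimited
# column table body. Only regional summaries are consumed; no image or
# surface processing happens in this package.

read_stats_lines <- function(path) {
  if (!file.exists(path)) stop("stats file not found: ", path)
  readLines(path, warn = FALSE)
}

parse_measure_lines <- function(lines) {
  ml <- grep("^# Measure ", lines, value = TRUE)
  out <- list()
  for (line in ml) {
    body <- sub("^# Measure ", "", line)
    parts <- trimws(strsplit(body, ",")[[1]])
    if (length(parts) < 4) next
    val <- suppressWarnings(as.numeric(parts[length(parts) - 1L]))
    out[[parts[1]]] <- val
    out[[parts[2]]] <- val
  }
  out
}

parse_colheaders <- function(lines) {
  ch <- grep("^# ColHeaders", lines, value = TRUE)
  if (length(ch) == 0) return(NULL)
  strsplit(trimws(sub("^# ColHeaders", "", ch[1])), "[[:space:]]+")[[1]]
}

#' Read a subcortical segmentation statistics table
#'
#' Parses an aseg-dialect stats file: structure volumes from the column
#' table body plus total intracranial volume (`EstimatedTotalIntraCranialVol`)
#' and total grey-matter volume (`TotalGray`) from the `# Measure` header
#' lines.
#'
#' @param path path to the stats file.
#' @return list with `volumes` (named numeric vector, mm^3), `icv`, `gm`.
#' @export
read_subcortical_stats <- function(path) {
  lines <- read_stats_lines(path)
  measures <- parse_measure_lines(lines)
  icv <- measures[["EstimatedTotalIntraCranialVol"]] %||% measures[["eTIV"]]
  gm <- measures[["TotalGray"]] %||% measures[["TotalGrayVol"]]
  if (is.null(icv) || is.na(icv)) {
    stop("format error in ", path,
         ": missing '# Measure EstimatedTotalIntraCranialVol' header line")
  }
  if (is.null(gm) || is.na(gm)) {
    stop("format error in ", path,
         ": missing '# Measure TotalGray' header line")
  }
  headers <- parse_colheaders(lines)
  vol_col <- 4L; name_col <- 5L
  if (!is.null(headers)) {
    vol_col <- match("Volume_mm3", headers)
    name_col <- match("StructName", headers)
    if (is.na(vol_col) || is.na(name_col)) {
      stop("format error in ", path,
           ": ColHeaders lacks Volume_mm3/StructName")
    }
  }
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  vols <- numeric(0)
  for (i in body_idx) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) < max(vol_col, name_col)) {
      stop("format error in ", path, " line ", i, ": too few columns")
    }
    v <- suppressWarnings(as.numeric(parts[vol_col]))
    if (is.na(v)) {
      stop("format error in ", path, " line ", i,
           ": non-numeric volume '", parts[vol_col], "'")
    }
    vols[parts[name_col]] <- v
  }
  list(volumes = vols, icv = icv, gm = gm)
}

#' Read a cortical parcellation statistics table
#'
#' Parses an aparc-dialect stats file for one hemisphere, returning mean
#' thickness, thickness standard deviation (the roughness metric as tabled
#' by the segmentation tool), and grey volume per atlas region. The
#' `# ColHeaders` line is required to locate the `StructName`, `ThickAvg`,
#' `ThickStd`, and `GrayVol` columns.
#'
#' @param path path to the stats file.
#' @param hemisphere `"left"` or `"right"` (recorded on the result).
#' @return data.frame with columns `region` (FreeSurfer parcellation name),
#'   `thickness_mean` (mm), `thickness_sd` (mm), `grey_volume` (mm^3).
#' @export
read_cortical_stats <- function(path, hemisphere = c("left", "right")) {
  hemisphere <- match.arg(hemisphere)
  lines <- read_stats_lines(path)
  headers <- parse_colheaders(lines)
  if (is.null(headers)) {
    stop("format error in ", path, ": no '# ColHeaders' line; ",
         "unknown column layout")
  }
  need <- c("StructName", "ThickAvg", "ThickStd", "GrayVol")
  cols <- match(need, headers)
  if (anyNA(cols)) {
    stop("format error in ", path, ": ColHeaders lacks ",
         paste(need[is.na(cols)], collapse = ", "))
  }
  body_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(body_idx) == 0) {
    warning("no regions found in ", path)
    return(data.frame(region = character(0), thickness_mean = numeric(0),
                      thickness_sd = numeric(0), grey_volume = numeric(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(body_idx, function(i) {
    parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(parts) < max(cols)) {
      stop("format error in ", path, " line ", i, ": too few columns")
    }
    vals <- suppressWarnings(as.numeric(parts[cols[2:4]]))
    if (anyNA(vals)) {
      stop("format error in ", path, " line ", i, ": non-numeric entry")
    }
    data.frame(region = parts[cols[1]], thickness_mean = vals[1],
               thickness_sd = vals[2], grey_volume = vals[3],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (anyDuplicated(out$region)) {
    stop("format error in ", path, ": duplicate region rows: ",
         paste(unique(out$region[duplicated(out$region)]), collapse = ", "))
  }
  attr(out, "hemisphere") <- hemisphere
  out
}

#' Roughness of a set of thickness samples
#'
#' The roughness of a cortical region is defined as the standard deviation
#' of cortical thickness within the region (sample SD, n-1 denominator).
#' Non-uniform thinning raises roughness even when the regional mean
#' thickness is preserved, which is what makes it a useful atrophy proxy.
#'
#' @param thickness_values numeric vector of per-vertex (or per-sample)
#'   thickness values in mm; at least 2 values, all positive.
#' @return roughness in mm.
#' @examples
#' compute_roughness(c(2.0, 2.5, 3.0)) # 0.5
#' @export
compute_roughness <- function(thickness_values) {
  if (length(thickness_values) < 2) {
    stop("compute_roughness: need at least 2 thickness values")
  }
  if (any(!is.finite(thickness_values)) || any(thickness_values <= 0)) {
    stop("compute_roughness: thickness values must be positive and finite")
  }
  stats::sd(thickness_values)
}

#' Assemble the normalized feature table from per-subject stats
#'
#' Combines subcortical and cortical regional summaries into one
#' subjects-by-features [morphometry_table()]: per cortical region and
#' hemisphere a grey volume (unnormalized), a mean thickness, and a
#' roughness column; per subcortical structure two volume columns,
#' normalized by ICV and by GM; plus raw ICV. Column order is
#' deterministic (feature ids sorted in the C locale). Subjects missing a
#' source table are dropped with a warning; regions must agree across the
#' retained subjects.
#'
#' @param subcortical named list (by subject id) of
#'   [read_subcortical_stats()] results.
#' @param cortical named list (by subject id) of lists with elements
#'   `left` and `right`, each a [read_cortical_stats()] result.
#' @return a [morphometry_table()].
#' @export
assemble_features <- function(subcortical, cortical) {
  subjects <- names(subcortical)
  if (is.null(subjects) || length(subjects) == 0) {
    stop("assemble_features: no subjects")
  }
  complete <- vapply(subjects, function(s) {
    !is.null(cortical[[s]]) && !is.null(cortical[[s]]$left) &&
      !is.null(cortical[[s]]$right)
  }, logical(1))
  extra <- setdiff(names(cortical), subjects)
  if (length(extra) > 0) {
    warning("assemble_features: cortical data without subcortical data ",
            "dropped for: ", paste(extra, collapse = ", "))
  }
  if (!all(complete)) {
    warning("assemble_features: dropping subjects with incomplete data: ",
            paste(subjects[!complete], collapse = ", "))
    subjects <- subjects[complete]
  }
  if (length(subjects) == 0) stop("assemble_features: no complete subjects")

  ref_sub <- names(subcortical[[subjects[1]]]$volumes)
  ref_cort <- subcortical_ref <- NULL
  ref_cort_l <- cortical[[subjects[1]]]$left$region
  ref_cort_r <- cortical[[subjects[1]]]$right$region
  for (s in subjects) {
    if (!setequal(names(subcortical[[s]]$volumes), ref_sub) ||
        !setequal(cortical[[s]]$left$region, ref_cort_l) ||
        !setequal(cortical[[s]]$right$region, ref_cort_r)) {
      stop("assemble_features: region sets differ between subjects ",
           "(first mismatch: ", s, ")")
    }
  }

  # descriptor construction
  desc <- list()
  add <- function(fid, region, fs, hemi, meas, nrm) {
    desc[[length(desc) + 1L]] <<- data.frame(
      feature_id = fid, region = region, fs_name = fs, hemisphere = hemi,
      measure = meas, normalizer = nrm, baseline = NA_real_,
      scale = NA_real_, derived = (nrm == "GM"), stringsAsFactors = FALSE
    )
  }
  for (fs in sort(ref_sub, method = "radix")) {
    hemi <- if (startsWith(fs, "Left-")) "left"
            else if (startsWith(fs, "Right-")) "right" else "none"
    label <- aseg_label(sub("^(Left|Right)-", "", fs))
    for (nrm in c("ICV", "GM")) {
      add(feature_id(label, hemi, "volume", nrm), label, fs, hemi,
          "volume", nrm)
    }
  }
  cort_label <- function(fs) {
    if (fs %in% names(.dk_regions)) unname(.dk_regions[fs]) else fs
  }
  for (hemi in c("left", "right")) {
    regs <- if (hemi == "left") ref_cort_l else ref_cort_r
    for (fs in sort(regs, method = "radix")) {
      label <- cort_label(fs)
      add(feature_id(label, hemi, "volume"), label, fs, hemi, "volume", "none")
      add(feature_id(label, hemi, "thickness_mean"), label, fs, hemi,
          "thickness_mean", "none")
      add(feature_id(label, hemi, "roughness"), label, fs, hemi,
          "roughness", "none")
    }
  }
  add("ICV", "ICV", "ICV", "none", "volume", "none")
  desc <- do.call(rbind, desc)
  desc <- desc[order_cstr(desc$feature_id), , drop = FALSE]
  rownames(desc) <- NULL

  icv <- vapply(subjects, function(s) subcortical[[s]]$icv, numeric(1))
  gm <- vapply(subjects, function(s) subcortical[[s]]$gm, numeric(1))

  values <- matrix(NA_real_, length(subjects), nrow(desc),
                   dimnames = list(subjects, desc$feature_id))
  for (si in seq_along(subjects)) {
    s <- subjects[si]
    sc <- subcortical[[s]]
    for (j in seq_len(nrow(desc))) {
      d <- desc[j, ]
      values[si, j] <- if (d$feature_id == "ICV") {
        sc$icv
      } else if (d$normalizer != "none") {
        raw <- sc$volumes[[d$fs_name]]
        raw / (if (d$normalizer == "ICV") sc$icv else sc$gm)
      } else {
        tab <- cortical[[s]][[d$hemisphere]]
        row <- tab[tab$region == d$fs_name, ]
        switch(d$measure,
          volume = row$grey_volume,
          thickness_mean = row$thickness_mean,
          roughness = row$thickness_sd
        )
      }
    }
  }
  morphometry_table(values, desc, subjects = subjects, icv = icv, gm = gm)
}

#' Read a morphometry table from stats-file directories
#'
#' Expects `dir/<subject>/stats/aseg.stats`, `lh.aparc.stats`, and
#' `rh.aparc.stats`, as written by [write_cohort_stats()] or by the
#' standard surface-reconstruction toolchain.
#'
#' @param dir root directory; each subdirectory is one subject.
#' @return a [morphometry_table()].
#' @export
read_stats_dir <- function(dir) {
  subjects <- sort(list.dirs(dir, recursive = FALSE, full.names = FALSE),
                   method = "radix")
  if (length(subjects) == 0) stop("read_stats_dir: no subject directories in ", dir)
  subcortical <- list(); cortical <- list()
  for (s in subjects) {
    base <- file.path(dir, s, "stats")
    subcortical[[s]] <- read_subcortical_stats(file.path(base, "aseg.stats"))
    cortical[[s]] <- list(
      left = read_cortical_stats(file.path(base, "lh.aparc.stats"), "left"),
      right = read_cortical_stats(file.path(base, "rh.aparc.stats"), "right")
    )
  }
  assemble_features(subcortical, cortical)
}

#' Write / read the canonical features CSV
#'
#' The canonical interchange format is a plain CSV with a `subject_id`
#' column followed by one column per feature id. ICV and GM are carried as
#' `.icv`/`.gm` columns when available so the table round-trips.
#'
#' @param table a [morphometry_table()].
#' @param path output path.
#' @return `path`, invisibly (writer); a [morphometry_table()] (reader).
#' @export
write_feature_csv <- function(table, path) {
  df <- data.frame(subject_id = table$subjects, table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(table$icv)) {
    df$.icv <- table$icv
    df$.gm <- table$gm
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(df)) {
    stop("feature CSV must have a subject_id column: ", path)
  }
  icv <- if (".icv" %in% names(df)) df$.icv else NULL
  gm <- if (".gm" %in% names(df)) df$.gm else NULL
  fcols <- setdiff(names(df), c("subject_id", ".icv", ".gm"))
  values <- as.matrix(df[, fcols, drop = FALSE])
  # bare matrices carry no descriptor metadata; mark measure unknown so no
  # normalization invariants are asserted spuriously
  desc <- data.frame(
    feature_id = fcols, region = fcols, fs_name = fcols, hemisphere = "none",
    measure = "volume", normalizer = "none", baseline = NA_real_,
    scale = NA_real_, derived = FALSE, stringsAsFactors = FALSE
  )
  morphometry_table(values, desc, subjects = df$subject_id, icv = icv, gm = gm)
}
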