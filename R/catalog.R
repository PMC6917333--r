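# Region vocabularies and the default feature catalog.
#
# Feature identifiers follow the reporting convention
#   "<L|R> <region> <measure>[/ICV|/GM]"
# e.g. "L thalamus proper volume/ICV", "R superior parietal thickness",
# "R inferior parietal roughness", with the bare "ICV" total as its own
# feature. Midline subcortical structures carry no hemisphere prefix.

# Desikan-Killiany gyral parcellation: FreeSurfer aparc name -> human label.
.dk_regions <- c(
  bankssts                = "bankssts",
  caudalanteriorcingulate = "caudal anterior cingulate",
  caudalmiddlefrontal     = "caudal middle frontal",
  cuneus                  = "cuneus",
  entorhinal              = "entorhinal",
  frontalpole             = "frontal pole",
  fusiform                = "fusiform",
  inferiorparietal        = "inferior parietal",
  inferiortemporal        = "inferior temporal",
  insula                  = "insula",
  isthmuscingulate        = "isthmus cingulate",
  lateraloccipital        = "lateral occipital",
  lateralorbitofrontal    = "lateral orbitofrontal",
  lingual                 = "lingual",
  medialorbitofrontal     = "medial orbitofrontal",
  middletemporal          = "middle temporal",
  paracentral             = "paracentral",
  parahippocampal         = "parahippocampal",
  parsopercularis         = "pars opercularis",
  parsorbitalis           = "pars orbitalis",
  parstriangularis        = "pars triangularis",
  pericalcarine           = "pericalcarine",
  postcentral             = "postcentral",
  posteriorcingulate      = "posterior cingulate",
  precentral              = "precentral",
  precuneus               = "precuneus",
  rostralanteriorcingulate = "rostral anterior cingulate",
  rostralmiddlefrontal    = "rostral middle frontal",
  superiorfrontal         = "superior frontal",
  superiorparietal        = "superior parietal",
  superiortemporal        = "superior temporal",
  supramarginal           = "supramarginal",
  temporalpole            = "temporal pole",
  transversetemporal      = "transverse temporal"
)

# Subcortical segmentation structures (aseg dialect). Bilateral structures
# appear with Left-/Right- prefixes in stats files; midline ones do not.
.aseg_bilateral <- c(
  "Thalamus-Proper", "Caudate", "Putamen", "Pallidum", "Hippocampus",
  "Amygdala", "Accumbens-area", "VentralDC", "Cerebellum-White-Matter",
  "Cerebellum-Cortex", "Lateral-Ventricle", "Inf-Lat-Vent",
  "choroid-plexus", "vessel"
)
.aseg_midline <- c(
  "Brain-Stem", "3rd-Ventricle", "4th-Ventricle", "CSF", "Optic-Chiasm",
  "CC_Posterior", "CC_Mid_Posterior", "CC_Central", "CC_Mid_Anterior",
  "CC_Anterior"
)

# Human label for an aseg structure name: lowercase, separators to spaces.
aseg_label <- function(fs_name) {
  gsub("[-_]+", " ", tolower(fs_name))
}

# Compose a feature id from its descriptor parts.
feature_id <- function(region, hemisphere, measure, normalizer = "none") {
  word <- switch(measure,
    volume = "volume", thickness_mean = "thickness", roughness = "roughness",
    stop("unknown measure: ", measure)
  )
  prefix <- switch(hemisphere, left = "L ", right = "R ", none = "")
  suffix <- switch(normalizer, none = "", ICV = "/ICV", GM = "/GM")
  paste0(prefix, region, " ", word, suffix)
}

#' Default morphometric feature catalog
#'
#' Builds the descriptor table the synthetic cohort generator draws from:
#' the 34 Desikan-Killiany cortical regions per hemisphere, each with grey
#' volume, mean cortical thickness, and roughness (the within-region
#' standard deviation of thickness); 38 subcortical segmentation volumes,
#' each emitted twice, normalized by total intracranial volume (ICV) and by
#' total grey-matter volume (GM); and raw ICV. With the default vocabularies
#' this yields 34 x 2 x 3 + 38 x 2 + 1 = 281 features. The cortical and
#' subcortical vocabularies are arguments, so smaller (or larger) catalogs
#' can be configured.
#'
#' Columns: `feature_id`, `region` (human label), `fs_name` (stats-file
#' name), `hemisphere` (`left`/`right`/`none`), `measure` (`volume`,
#' `thickness_mean`, `roughness`), `normalizer` (`none`/`ICV`/`GM`),
#' `baseline` and `scale` (feature units; the generator draws
#' `baseline + noise_sd * scale * z`), and `derived` (TRUE for /GM columns,
#' which are computed from the /ICV draw so both normalizations of one
#' structure stay coherent).
#'
#' @param cortical_regions named character vector, aparc name -> label.
#' @param subcortical_bilateral,subcortical_midline aseg structure names.
#' @return data.frame of feature descriptors, one row per feature.
#' @examples
#' cat <- default_feature_catalog()
#' nrow(cat) # 281
#' @export
default_feature_catalog <- function(cortical_regions = .dk_regions,
                                    subcortical_bilateral = .aseg_bilateral,
                                    subcortical_midline = .aseg_midline) {
  rows <- list()
  # cortical block: volume / thickness / roughness, per hemisphere
  scales <- list(
    volume = c(baseline = 8000, scale = 800),
    thickness_mean = c(baseline = 2.5, scale = 0.15),
    roughness = c(baseline = 0.5, scale = 0.06)
  )
  for (i in seq_along(cortical_regions)) {
    fs <- names(cortical_regions)[i]
    label <- unname(cortical_regions[i])
    for (hemi in c("left", "right")) {
      for (meas in names(scales)) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = feature_id(label, hemi, meas),
          region = label, fs_name = fs, hemisphere = hemi, measure = meas,
          normalizer = "none",
          baseline = scales[[meas]][["baseline"]],
          scale = scales[[meas]][["scale"]],
          derived = FALSE, stringsAsFactors = FALSE
        )
      }
    }
  }
  # subcortical block: /ICV drawn, /GM derived
  sub_entry <- function(fs, hemi) {
    label <- aseg_label(fs)
    full_fs <- if (hemi == "left") paste0("Left-", fs)
               else if (hemi == "right") paste0("Right-", fs) else fs
    do.call(rbind, lapply(c("ICV", "GM"), function(nrm) data.frame(
      feature_id = feature_id(label, hemi, "volume", nrm),
      region = label, fs_name = full_fs, hemisphere = hemi,
      measure = "volume", normalizer = nrm,
      baseline = 0.004, scale = 3e-4,
      derived = (nrm == "GM"), stringsAsFactors = FALSE
    )))
  }
  for (fs in subcortical_bilateral) {
    rows[[length(rows) + 1L]] <- sub_entry(fs, "left")
    rows[[length(rows) + 1L]] <- sub_entry(fs, "right")
  }
  for (fs in subcortical_midline) {
    rows[[length(rows) + 1L]] <- sub_entry(fs, "none")
  }
  # raw intracranial volume as its own feature
  rows[[length(rows) + 1L]] <- data.frame(
    feature_id = "ICV", region = "ICV", fs_name = "ICV", hemisphere = "none",
    measure = "volume", normalizer = "none",
    baseline = 1.45e6, scale = 1.3e5, derived = FALSE,
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (anyDuplicated(out$feature_id)) {
    stop("feature_catalog: duplicate feature ids")
  }
  out
}

#' Minimal feature catalog for experiments and tests
#'
#' A flat catalog of `p` directly drawn cortical-style features named
#' `f01, f02, ...`, all with the same baseline and unit scale. Convenient
#' for simulation studies where the morphometric naming scheme and the
#' normalization bookkeeping of [default_feature_catalog()] are irrelevant.
#'
#' @param p number of features.
#' @param baseline,scale feature-unit location and per-unit-noise scale.
#' @param measure measure tag used for all features.
#' @return data.frame with the same columns as [default_feature_catalog()].
#' @export
simple_catalog <- function(p, baseline = 0, scale = 1,
                           measure = "thickness_mean") {
  ids <- sprintf("f%02d", seq_len(p))
  data.frame(
    feature_id = ids, region = ids, fs_name = ids, hemisphere = "none",
    measure = measure, normalizer = "none",
    baseline = baseline, scale = scale, derived = FALSE,
    stringsAsFactors = FALSE
  )
}
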