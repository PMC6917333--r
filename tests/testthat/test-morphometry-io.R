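# Stats-file dialect readers, the roughness metric, and feature assembly.

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".stats",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

aseg_fixture <- function(icv = 1500000, gm = 650000,
                         rows = c("  1 10  7000 7000.000000 Left-Thalamus-Proper")) {
  c("# Title Segmentation Statistics",
    sprintf("# Measure EstimatedTotalIntraCranialVol, eTIV, Estimated Total Intracranial Volume, %.6f, mm^3", icv),
    sprintf("# Measure TotalGray, TotalGrayVol, Total gray matter volume, %.6f, mm^3", gm),
    "# ColHeaders Index SegId NVoxels Volume_mm3 StructName",
    rows)
}

test_that("subcortical reader recovers measures and volumes", {
  path <- write_lines_tmp(aseg_fixture())
  out <- read_subcortical_stats(path)
  expect_equal(out$icv, 1500000)
  expect_equal(out$gm, 650000)
  expect_equal(out$volumes[["Left-Thalamus-Proper"]], 7000)
})

test_that("subcortical reader rejects malformed files with precise errors", {
  no_gm <- aseg_fixture()[-3]
  expect_error(read_subcortical_stats(write_lines_tmp(no_gm)), "TotalGray")
  no_icv <- aseg_fixture()[-2]
  expect_error(read_subcortical_stats(write_lines_tmp(no_icv)),
               "EstimatedTotalIntraCranialVol")
  bad <- aseg_fixture(rows = c("  1 10 7000 7000.0 Left-Thalamus-Proper",
                               "  2 11 8000 oops Right-Thalamus-Proper"))
  expect_error(read_subcortical_stats(write_lines_tmp(bad)),
               "line 6.*non-numeric|non-numeric.*line 6")
})

test_that("cortical reader parses regions and flags layout problems", {
  lines <- c("# Table of cortical parcellation anatomical statistics",
             "# ColHeaders StructName NumVert SurfArea GrayVol ThickAvg ThickStd",
             "superiorparietal 9000 6000 12000.000000 2.100000 0.550000",
             "precuneus 8000 5500 9500.000000 2.300000 0.480000")
  out <- read_cortical_stats(write_lines_tmp(lines), "right")
  expect_equal(nrow(out), 2)
  row <- out[out$region == "superiorparietal", ]
  expect_equal(row$thickness_mean, 2.10)
  expect_equal(row$thickness_sd, 0.55)
  expect_equal(row$grey_volume, 12000)

  dup <- c(lines, "precuneus 8000 5500 9500.0 2.3 0.48")
  expect_error(read_cortical_stats(write_lines_tmp(dup), "left"),
               "duplicate region")
  no_hdr <- lines[-2]
  expect_error(read_cortical_stats(write_lines_tmp(no_hdr), "left"),
               "ColHeaders")
  empty <- lines[1:2]
  expect_warning(out0 <- read_cortical_stats(write_lines_tmp(empty), "left"),
                 "no regions")
  expect_equal(nrow(out0), 0)
})

test_that("roughness is the sample SD of thickness and is shift-invariant", {
  expect_equal(compute_roughness(c(2.5, 2.5, 2.5)), 0)
  expect_equal(compute_roughness(c(2.0, 2.5, 3.0)), 0.5)
  x <- abs(rnorm(50)) + 0.5
  expect_equal(compute_roughness(x), compute_roughness(x + 3))
  expect_error(compute_roughness(2.5), "at least 2")
  expect_error(compute_roughness(c(2, -1)), "positive")
})

test_that("assembly normalizes subcortical volumes by ICV and GM", {
  sub <- list(s1 = list(volumes = c("Left-Thalamus-Proper" = 7000),
                        icv = 1400000, gm = 700000))
  cort <- list(s1 = list(
    left = data.frame(region = "precuneus", thickness_mean = 2.3,
                      thickness_sd = 0.5, grey_volume = 9000),
    right = data.frame(region = "precuneus", thickness_mean = 2.4,
                       thickness_sd = 0.6, grey_volume = 9100)))
  tab <- assemble_features(sub, cort)
  v <- tab$values["s1", ]
  expect_equal(v[["L thalamus proper volume/ICV"]], 0.005)
  expect_equal(v[["L thalamus proper volume/GM"]], 0.01)
  expect_equal(v[["R precuneus roughness"]], 0.6)
  expect_equal(v[["ICV"]], 1400000)
  # column order is the C-locale sort of feature ids
  expect_identical(colnames(tab$values),
                   sort(colnames(tab$values), method = "radix"))
})

test_that("common volume rescaling leaves normalized features unchanged", {
  make <- function(f) list(s1 = list(
    volumes = c("Left-Thalamus-Proper" = 7000 * f,
                "Right-Putamen" = 5000 * f),
    icv = 1400000 * f, gm = 700000 * f))
  cort <- list(s1 = list(
    left = data.frame(region = "precuneus", thickness_mean = 2.3,
                      thickness_sd = 0.5, grey_volume = 9000),
    right = data.frame(region = "precuneus", thickness_mean = 2.4,
                       thickness_sd = 0.6, grey_volume = 9100)))
  t1 <- assemble_features(make(1), cort)
  t2 <- assemble_features(make(2.5), cort)
  norm_cols <- grepl("/ICV$|/GM$", colnames(t1$values))
  expect_equal(t1$values[, norm_cols], t2$values[, norm_cols])
})

test_that("incomplete subjects are dropped with a warning", {
  sub <- list(
    s1 = list(volumes = c("Left-Thalamus-Proper" = 7000),
              icv = 1.4e6, gm = 7e5),
    s2 = list(volumes = c("Left-Thalamus-Proper" = 7100),
              icv = 1.5e6, gm = 7.2e5))
  cort_one <- data.frame(region = "precuneus", thickness_mean = 2.3,
                         thickness_sd = 0.5, grey_volume = 9000)
  cort <- list(s1 = list(left = cort_one, right = cort_one))
  expect_warning(tab <- assemble_features(sub, cort), "s2")
  expect_equal(tab$subjects, "s1")
})

test_that("default catalog assembles to 281 features and round-trips exactly", {
  co <- generate_cohort(synthetic_spec(seed = 17))
  expect_equal(ncol(co$table$values), 281)
  dir <- withr::local_tempdir()
  write_cohort_stats(co, dir)
  back <- read_stats_dir(dir)
  expect_identical(colnames(back$values), colnames(co$table$values))
  rel <- abs(back$values - co$table$values) /
    pmax(abs(co$table$values), 1e-9)
  expect_lt(max(rel), 1e-5)
  expect_equal(back$icv, co$table$icv, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("feature CSV round-trips through the canonical writer", {
  co <- generate_cohort(synthetic_spec(feature_catalog = simple_catalog(4),
                                       seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_csv(co$table, path)
  back <- read_feature_csv(path)
  expect_equal(back$values, co$table$values, tolerance = 1e-12)
  expect_equal(back$subjects, co$table$subjects)
})

test_that("table constructor enforces its invariants", {
  desc <- simple_catalog(2)
  vals <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), desc$feature_id))
  expect_error(morphometry_table(vals, desc, icv = c(10, 10), gm = c(11, 9)),
               "gm")
  expect_error(morphometry_table(vals[1, , drop = FALSE], desc,
                                 subjects = c("a", "b")),
               "rows")
  desc_norm <- desc
  desc_norm$normalizer <- "ICV"
  desc_norm$measure <- "volume"
  expect_error(morphometry_table(vals, desc_norm, icv = c(10, 10),
                                 gm = c(5, 5)),
               "\\(0, 1\\)")
})
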