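test_that("generation is deterministic given seed and index", {
  cfg <- small_config(n_slides = 3, seed = 9)
  a <- generate_slide(cfg, 2, render = TRUE)
  b <- generate_slide(cfg, 2, render = TRUE)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$regions$polygon, b$regions$polygon)
  expect_identical(a$seg$objects$certainty, b$seg$objects$certainty)
  expect_identical(a$true_label, b$true_label)
})

test_that("zero prevalence yields only low-risk slides and regions", {
  cfg <- small_config(n_slides = 8, seed = 5, high_risk_prevalence = 0)
  for (i in seq_len(8)) {
    s <- generate_slide(cfg, i)
    expect_identical(s$true_label, "low_risk")
    expect_false(any(s$regions$category %in% high_risk_categories()))
  }
})

test_that("high-risk count follows the binomial prior", {
  # central 99% binomial interval at n = 200, p = 0.5 is [71, 129]
  cfg <- synthetic_config(n_slides = 200, high_risk_prevalence = 0.5,
                          seed = 31)
  labels <- vapply(seq_len(200),
                   function(i) generate_slide(cfg, i)$true_label,
                   character(1))
  n_high <- sum(labels == "high_risk")
  expect_gte(n_high, 71)
  expect_lte(n_high, 129)
})

test_that("true label bookkeeping matches the region list", {
  cfg <- small_config(n_slides = 20, seed = 13)
  for (i in seq_len(20)) {
    s <- generate_slide(cfg, i)
    has_hr <- any(s$regions$category %in% high_risk_categories())
    expect_identical(s$true_label,
                     if (has_hr) "high_risk" else "low_risk")
  }
})

test_that("regions lie in bounds; areas and certainties are consistent", {
  cfg <- small_config(n_slides = 6, seed = 21)
  for (i in seq_len(6)) {
    s <- generate_slide(cfg, i)
    for (p in s$regions$polygon) {
      expect_true(all(p[, 1] >= 0 & p[, 1] <= cfg$image_width))
      expect_true(all(p[, 2] >= 0 & p[, 2] <= cfg$image_height))
    }
    expect_true(all(s$seg$objects$certainty >= 0 &
                      s$seg$objects$certainty <= 1))
    expect_true(all(s$regions$area_px > 0))
    # mpp-converted areas agree with the polygon (shoelace) areas
    shoelace <- vapply(s$regions$polygon, polygon_area, numeric(1))
    expect_equal(s$regions$area_mm2, px_to_mm2(shoelace, cfg$mpp),
                 tolerance = 0.01)
  }
})

test_that("dataset writing produces a complete, reloadable manifest", {
  cfg <- small_config(n_slides = 0, seed = 1)
  out <- withr::local_tempdir()
  ds <- generate_dataset(cfg, out_dir = file.path(out, "empty"))
  expect_identical(nrow(ds$manifest), 0L)
  expect_identical(
    setdiff(list.files(file.path(out, "empty")), "manifest.csv"),
    character(0)
  )

  cfg <- small_config(n_slides = 4, seed = 2)
  dir <- file.path(out, "cohort")
  ds <- generate_dataset(cfg, out_dir = dir, render = TRUE)
  expect_identical(nrow(ds$manifest), 4L)
  for (k in seq_len(4)) {
    expect_true(file.exists(file.path(dir, ds$manifest$image[k])))
    expect_true(file.exists(file.path(dir, ds$manifest$annotations[k])))
    expect_true(file.exists(file.path(dir, ds$manifest$segmentation[k])))
  }
  # GeoJSON round trip preserves categories, certainties and areas
  seg <- read_segmentation_geojson(file.path(dir, ds$manifest$segmentation[2]))
  orig <- ds$slides[[2]]$seg
  expect_identical(seg$objects$category, orig$objects$category)
  expect_equal(seg$objects$certainty, orig$objects$certainty,
               tolerance = 1e-6)
  expect_equal(seg$objects$area_mm2, orig$objects$area_mm2,
               tolerance = 1e-4)
  expect_equal(seg$tissue_area_mm2, orig$tissue_area_mm2, tolerance = 1e-6)
  ann <- read_annotations_geojson(file.path(dir, ds$manifest$annotations[2]))
  expect_identical(ann$category, ds$slides[[2]]$regions$category)
})

test_that("files are byte-identical across regeneration", {
  cfg <- small_config(n_slides = 2, seed = 77)
  out <- withr::local_tempdir()
  generate_dataset(cfg, out_dir = file.path(out, "a"), render = TRUE)
  generate_dataset(cfg, out_dir = file.path(out, "b"), render = TRUE)
  for (f in list.files(file.path(out, "a"))) {
    expect_identical(
      readBin(file.path(out, "a", f), "raw", n = 1e7),
      readBin(file.path(out, "b", f), "raw", n = 1e7),
      info = f
    )
  }
})

test_that("sharper certainty separation does not lower achievable AUC", {
  auc_for <- function(correct_law) {
    cfg <- small_config(n_slides = 60, seed = 101,
                        certainty_correct = correct_law)
    ft <- labeled_features(cfg)
    roc_auc(ft$label, ft$f_wmean)$auc
  }
  weak <- auc_for(c(4, 4))    # mean 0.5, close to the false-object law
  strong <- auc_for(c(16, 2)) # mean ~0.89
  expect_gte(strong, weak)
})

test_that("invalid configurations name the offending field", {
  expect_error(synthetic_config(high_risk_prevalence = 1.5),
               "high_risk_prevalence")
  expect_error(synthetic_config(mpp = 0), "mpp")
  expect_error(synthetic_config(count_mean_high = -1), "count_mean_high")
  expect_error(small_config(category_weights_low = c(0, 1, 0, 0, 0, 0, 0)),
               "category_weights_low")
})
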