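make_seg <- function(categories, certainties, areas_mm2, tissue_mm2 = 10,
                     mpp = 4) {
  n <- length(categories)
  area_px <- areas_mm2 * 1e6 / mpp^2
  polys <- lapply(area_px, function(a) {
    ellipse_polygon(500, 400, sqrt(a / pi), sqrt(a / pi))
  })
  objs <- tibble::tibble(
    object_id = seq_len(n), category = categories, certainty = certainties,
    polygon = polys, area_px = area_px, area_mm2 = areas_mm2,
    spurious = FALSE
  )
  slide_segmentation("s1", objs, tissue_mm2, mpp_x = mpp)
}

test_that("tile labeling follows the any-overlap rule", {
  tile <- tibble::tibble(x0 = 0, y0 = 0, width = 775, height = 522)
  far <- annotation_regions("adenoca_or_hgd",
                            list(ellipse_polygon(2000, 2000, 50, 50)),
                            mpp_x = 4)
  expect_identical(label_tile(tile, far), "low_risk")
  # a single pixel of overlap flips the tile to high risk
  graze <- annotation_regions("low_grade_dysplasia",
                              list(ellipse_polygon(775, 522, 1.2, 1.2)),
                              mpp_x = 4)
  expect_identical(label_tile(tile, graze), "high_risk")
  # full coverage by a benign category stays low risk
  benign <- annotation_regions("benign_gland",
                               list(ellipse_polygon(387, 261, 600, 600)),
                               mpp_x = 4)
  expect_identical(label_tile(tile, benign), "low_risk")
  # monotone: adding a high-risk region can only raise the label
  both <- annotation_regions(
    c("benign_gland", "adenoca_or_hgd"),
    list(ellipse_polygon(387, 261, 600, 600),
         ellipse_polygon(400, 300, 30, 30)),
    mpp_x = 4
  )
  expect_identical(label_tile(tile, both), "high_risk")
})

test_that("label_tiles annotates a grid against generator truth", {
  s <- generate_slide(small_config(n_slides = 1, seed = 12), 1,
                      render = TRUE)
  mask <- compute_tissue_mask(s$image)
  tiles <- label_tiles(tile_slide(s$image, mask), s$regions)
  expect_true(all(tiles$label %in% risk_levels()))
  if (s$true_label == "high_risk") {
    expect_true(any(tiles$label == "high_risk"))
  } else {
    expect_true(all(tiles$label == "low_risk"))
  }
})

test_that("weighted percentile is the left-continuous inverse CDF", {
  expect_equal(weighted_percentile(0.7, 2.5, 1), 0.7)
  expect_equal(weighted_percentile(1:100, rep(1, 100), 1), 1)
  # light weight below the cut: cumulative 0.005 < 0.01 -> next value
  expect_equal(weighted_percentile(c(0.2, 0.9), c(0.005, 0.995), 1), 0.9)
  expect_equal(weighted_percentile(c(0.2, 0.9), c(0.02, 0.98), 1), 0.2)
  expect_error(weighted_percentile(numeric(0), numeric(0), 1),
               class = "wsitriage_domain_error")
})

test_that("the four slide features match hand computation", {
  seg <- make_seg("adenoca_or_hgd", 0.9, 1.0, tissue_mm2 = 10)
  f <- compute_slide_features(seg)
  expect_equal(f$f_area_pct, 10.0)
  expect_equal(f$f_wmean, 0.9)
  expect_identical(f$f_flag, 1L)
  expect_equal(f$f_wpctl1, 0.9)

  # no high-risk-category objects: all features zero
  f0 <- compute_slide_features(make_seg(c("benign_gland", "mucin"),
                                        c(0.99, 0.9), c(1, 1)))
  expect_equal(unlist(f0[, -1]), c(f_area_pct = 0, f_wmean = 0,
                                   f_flag = 0, f_wpctl1 = 0))

  # certainty exactly at the 70% threshold is excluded (strict >)
  f70 <- compute_slide_features(make_seg("adenoca_or_hgd", 0.70, 1.0))
  expect_equal(f70$f_area_pct, 0)
  expect_equal(f70$f_wmean, 0.70)  # mean/percentile take all of H

  # the flag area is cumulative over qualifying objects
  fcum <- compute_slide_features(make_seg(
    rep("low_grade_dysplasia", 3), c(0.9, 0.9, 0.5), c(0.06, 0.06, 5)
  ))
  expect_identical(fcum$f_flag, 1L)  # 0.06 + 0.06 >= 0.1
  fone <- compute_slide_features(make_seg("low_grade_dysplasia", 0.9, 0.06))
  expect_identical(fone$f_flag, 0L)
})

test_that("adding a high-risk object never lowers area or flag", {
  base <- make_seg(rep("adenoca_or_hgd", 2), c(0.8, 0.95), c(0.3, 0.05))
  more <- make_seg(rep("adenoca_or_hgd", 3), c(0.8, 0.95, 0.99),
                   c(0.3, 0.05, 0.2))
  fb <- compute_slide_features(base)
  fm <- compute_slide_features(more)
  expect_gte(fm$f_area_pct, fb$f_area_pct)
  expect_gte(fm$f_flag, fb$f_flag)
})

test_that("features table is ordered, unique and oracle-equivalent", {
  expect_identical(nrow(features_table(list())), 0L)
  cfg <- small_config(n_slides = 8, seed = 33, spurious_rate = 0)
  ds <- generate_dataset(cfg)
  tab <- features_table(purrr::map(ds$slides, "seg"))
  expect_identical(nrow(tab), 8L)
  expect_identical(tab$slide_id, sort(tab$slide_id))
  expect_error(
    features_table(list(ds$slides[[1]]$seg, ds$slides[[1]]$seg)),
    class = "wsitriage_input_error"
  )
  # with a perfect oracle, features equal those computed from ground
  # truth with certainty 1
  perfect <- purrr::map(ds$slides, function(s) {
    oracle_segment(s$regions, zero_corruption(), mpp_x = cfg$mpp,
                   tissue_area_mm2 = s$tissue_area_mm2,
                   slide_id = s$slide_id, seed = 1)
  })
  truth <- purrr::map(ds$slides, function(s) {
    objs <- tibble::tibble(
      object_id = s$regions$region_id, category = s$regions$category,
      certainty = rep(1, nrow(s$regions)), polygon = s$regions$polygon,
      area_px = s$regions$area_px, area_mm2 = s$regions$area_mm2,
      spurious = FALSE
    )
    slide_segmentation(s$slide_id, objs, s$tissue_area_mm2, cfg$mpp)
  })
  expect_equal(features_table(perfect), features_table(truth))
})
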