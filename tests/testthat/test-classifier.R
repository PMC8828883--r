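# Separable by a threshold on f_area_pct. Feature values are drawn
# from small discrete sets so every fold's held-out values also occur
# in its training folds (split thresholds then generalize exactly).
separable_data <- function(n = 100, seed = 1) {
  withr::with_seed(seed, {
    label <- rep(c("high_risk", "low_risk"), length.out = n)
    pick <- function(vals) sample(vals, n, replace = TRUE)
    tibble::tibble(
      slide_id = sprintf("s%03d", seq_len(n)), label = label,
      f_area_pct = ifelse(label == "high_risk",
                          pick(c(6, 8, 10, 15, 20)),
                          pick(c(0, 0.2, 0.5, 1))),
      f_wmean = ifelse(label == "high_risk", pick(c(0.8, 0.9, 0.95)),
                       pick(c(0.1, 0.2, 0.4))),
      f_flag = as.integer(label == "high_risk"),
      f_wpctl1 = pick(c(0.1, 0.3, 0.5, 0.7))
    )
  })
}

test_that("cross-validation reaches accuracy 1 on separable features", {
  cv <- cross_validate_select(separable_data(), classifier_config(seed = 3))
  expect_equal(max(cv$cv$mean_accuracy), 1.0)
  expect_equal(cv$best$mean_accuracy, 1.0)
})

test_that("permuted labels give chance-level best accuracy", {
  d <- separable_data(n = 100, seed = 2)
  d$label <- withr::with_seed(99, sample(d$label))
  cv <- cross_validate_select(d, classifier_config(seed = 3))
  expect_gte(cv$best$mean_accuracy, 0.35)
  expect_lte(cv$best$mean_accuracy, 0.65)
})

test_that("selection is deterministic and ties break to simpler models", {
  d <- separable_data()
  cfg <- classifier_config(seed = 11)
  a <- cross_validate_select(d, cfg)
  b <- cross_validate_select(d, cfg)
  expect_identical(a$best, b$best)
  expect_identical(a$cv$mean_accuracy, b$cv$mean_accuracy)
  # separable data ties many grid points at 1.0; the chosen point must
  # be the smallest tree count, then lowest depth, among the ties
  ties <- a$cv[a$cv$mean_accuracy == a$best$mean_accuracy, ]
  expect_identical(a$best$trees, min(ties$trees))
  expect_identical(a$best$depth,
                   min(ties$depth[ties$trees == a$best$trees]))
})

test_that("degenerate inputs are rejected", {
  d <- separable_data(20)
  d$label <- "high_risk"
  expect_error(cross_validate_select(d, classifier_config()),
               class = "wsitriage_input_error")
  d2 <- separable_data(6)  # 3 per class < 5 folds
  expect_error(cross_validate_select(d2, classifier_config()),
               class = "wsitriage_input_error")
})

test_that("the final fit memorizes separable data and is reproducible", {
  d <- separable_data()
  cv <- cross_validate_select(d, classifier_config(seed = 7))
  clf <- fit_final(d, cv$best, seed = 7, cv = cv)
  expect_equal(clf$train_accuracy, 1.0)
  expect_gte(clf$train_accuracy, cv$best$mean_accuracy - 0.05)
  clf2 <- fit_final(d, cv$best, seed = 7, cv = cv)
  expect_identical(predict_risk(clf, d)$probability_high,
                   predict_risk(clf2, d)$probability_high)
})

test_that("constant features predict the class prior", {
  withr::with_seed(4, {
    d <- tibble::tibble(
      slide_id = sprintf("s%02d", 1:40),
      label = rep(c("high_risk", "low_risk"), 20),
      f_area_pct = 1, f_wmean = 0.5, f_flag = 1L, f_wpctl1 = 0.5
    )
  })
  clf <- fit_final(d, tibble::tibble(trees = 50L, depth = 2L,
                                     learning_rate = 0.1, min_leaf = 1L),
                   seed = 2)
  p <- predict_risk(clf, d)$probability_high
  expect_true(all(abs(p - 0.5) < 0.05))
})

test_that("prediction thresholding uses >= and is monotone", {
  d <- separable_data(40)
  clf <- fit_final(d, tibble::tibble(trees = 50L, depth = 2L,
                                     learning_rate = 0.3, min_leaf = 1L),
                   seed = 5)
  fake <- d[1:2, ]
  # exact boundary semantics on a synthetic probability
  probe <- tibble::tibble(probability_high = c(0.69, 0.70))
  lab <- ifelse(probe$probability_high >= 0.7, "high_risk", "low_risk")
  expect_identical(lab, c("low_risk", "high_risk"))
  preds <- predict_risk(clf, d, threshold = 0.7)
  expect_true(all(preds$prediction ==
                    ifelse(preds$probability_high >= 0.7,
                           "high_risk", "low_risk")))
  # lowering the threshold never flips a slide high -> low
  high_at <- function(t) {
    p <- predict_risk(clf, d, threshold = t)
    p$slide_id[p$prediction == "high_risk"]
  }
  hs <- lapply(c(0.9, 0.7, 0.5, 0.3, 0.1), high_at)
  for (i in seq_len(length(hs) - 1)) {
    expect_true(all(hs[[i]] %in% hs[[i + 1]]))
  }
  expect_error(predict_risk(clf, dplyr::mutate(d, f_wmean = NA_real_)),
               class = "wsitriage_input_error")
})

test_that("classifier JSON round trip preserves predictions", {
  d <- separable_data(60, seed = 9)
  clf <- train_slide_classifier(d, classifier_config(seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_classifier(clf, path)
  restored <- read_classifier(path)
  expect_identical(predict_risk(restored, d)$probability_high,
                   predict_risk(clf, d)$probability_high)
  expect_identical(restored$hyperparameters, clf$hyperparameters)
  expect_identical(restored$feature_names, clf$feature_names)
})

test_that("tidiers summarize fits and reports", {
  d <- separable_data(60, seed = 10)
  clf <- train_slide_classifier(d, classifier_config(seed = 2))
  g <- glance(clf)
  expect_identical(g$n_train, 60L)
  expect_true(all(c("trees", "depth", "train_accuracy") %in% names(g)))
  td <- tidy(clf$cv)
  expect_identical(nrow(td), nrow(default_hyperparameter_grid()))
})
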