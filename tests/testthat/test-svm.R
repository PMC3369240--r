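# two separable Gaussian blobs dressed up as a feature table
blob_features <- function(n = 30, gap = 6, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    subject_id = sprintf("B%03d", 1:(2 * n)),
    group = rep(c("left", "right"), each = n),
    L5_00000_00250 = c(rnorm(n), rnorm(n) + gap),
    L5_00250_00500 = c(rnorm(n), rnorm(n) + gap)
  )
}

test_that("separable data is fit perfectly and grids degenerate correctly", {
  ft <- blob_features()
  model <- svm_train(ft, C = 1, gamma = 0.5)
  expect_equal(as.character(predict(model, ft)), ft$group)

  gs <- svm_grid_search(ft, C_grid = 2, gamma_grid = 0.25, folds = 3,
                        seed = 5)
  expect_equal(gs$best_C, 2)
  expect_equal(gs$best_gamma, 0.25)
  expect_equal(nrow(gs$grid), 1L)
  expect_equal(gs$cv_accuracy, 1)
})

test_that("grid search is deterministic and breaks ties toward small C then gamma", {
  ft <- small_features()
  sel <- select_features(compare_groups(ft))
  g1 <- svm_grid_search(ft, bands = sel, C_grid = 2^(-2:2),
                        gamma_grid = 2^(-6:-2), folds = 3, seed = 42)
  g2 <- svm_grid_search(ft, bands = sel, C_grid = 2^(-2:2),
                        gamma_grid = 2^(-6:-2), folds = 3, seed = 42)
  expect_identical(g1$best_C, g2$best_C)
  expect_identical(g1$best_gamma, g2$best_gamma)
  expect_identical(g1$grid, g2$grid)
  # the reported best is the lexicographically smallest argmax
  top <- g1$grid[g1$grid$accuracy == max(g1$grid$accuracy), ]
  top <- top[order(top$C, top$gamma), ]
  expect_equal(g1$best_C, top$C[1])
  expect_equal(g1$best_gamma, top$gamma[1])
})

test_that("duplicating every row with C halved leaves predictions unchanged", {
  ft <- small_features()
  m1 <- svm_train(ft, C = 0.5, gamma = 0.0625)
  m2 <- svm_train(dplyr::bind_rows(ft, ft), C = 0.25, gamma = 0.0625)
  probe <- ft
  set.seed(3)
  bk <- feature_bands(ft)
  probe[bk] <- probe[bk] + matrix(rnorm(nrow(ft) * length(bk), 0, 0.05),
                                  nrow(ft))
  expect_equal(predict(m1, probe), predict(m2, probe))
})

test_that("the JSON round-trip reproduces predictions through the explicit decision function", {
  ft <- small_features()
  sel <- select_features(compare_groups(ft))
  model <- svm_train(ft, bands = sel, C = 0.25, gamma = 0.0625)
  restored <- svm_from_json(svm_to_json(model))

  set.seed(9)
  probes <- purrr::map_dfr(1:5, function(i) {
    p <- ft
    bk <- feature_bands(ft)
    p[bk] <- p[bk] + matrix(rnorm(nrow(ft) * length(bk), 0, 0.1), nrow(ft))
    p
  })
  expect_equal(predict(model, probes), predict(restored, probes))

  path <- withr::local_tempfile(fileext = ".json")
  svm_to_json(model, path)
  expect_equal(predict(svm_from_json(path), ft), predict(model, ft))
})

test_that("prediction matches features by band name, not position", {
  ft <- small_features()
  model <- svm_train(ft, C = 0.25, gamma = 0.0625)
  shuffled <- ft[, c(1, 2, sample(3:ncol(ft)))]
  expect_equal(predict(model, shuffled), predict(model, ft))
  expect_error(predict(model, ft[, 1:30]), "lacks band")
})

test_that("evaluation reports recalls, overall accuracy and confusion consistently", {
  ft <- blob_features(n = 20)
  model <- svm_train(ft, C = 1, gamma = 0.5)
  ev <- svm_evaluate(model, ft)
  expect_equal(ev$overall, 1)
  expect_true(all(ev$per_class == 1))
  expect_equal(sum(diag(ev$confusion)), sum(ev$confusion))

  # force total misassignment of one class
  flipped <- ft
  flipped$group <- rev(flipped$group)
  ev2 <- svm_evaluate(model, flipped)
  expect_equal(unname(ev2$per_class), c(0, 0))
  expect_equal(ev2$overall,
               sum(diag(ev2$confusion)) / sum(ev2$confusion))
  expect_equal(glance(ev2)$overall_accuracy, ev2$overall)
  expect_equal(nrow(tidy(ev)), 2L)
})

test_that("undefined feature cells and thin classes are refused", {
  ft <- blob_features(n = 10)
  ft$L5_00000_00250[3] <- NA
  expect_error(svm_train(ft), "undefined feature")
  m <- svm_train(ft, na_policy = "drop_rows")
  expect_s3_class(m, "wpse_svm")
  expect_error(svm_cv(blob_features(n = 3), folds = 5), "fewer samples")
})
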