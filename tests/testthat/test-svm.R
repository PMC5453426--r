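# RBF-SVM head: separable-blob oracle, grid-search contracts, determinism,
# and interchangeability with CNN probabilities.

blob_features <- function(n_per = 20L, d = 6L, sep = 4, seed = 5L,
                          classes = c("normal", "invasive")) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(length(classes) * d), length(classes), d)
  centers <- centers / sqrt(rowSums(centers^2)) * sep
  X <- NULL; y <- c()
  for (ci in seq_along(classes)) {
    X <- rbind(X, sweep(matrix(stats::rnorm(n_per * d, sd = 0.5), n_per, d),
                        2, centers[ci, ], "+"))
    y <- c(y, rep(classes[ci], n_per))
  }
  list(X = abs(X), y = y)   # non-negative, like post-ReLU features
}

test_that("well-separated blobs reach >= 95% CV accuracy and clean predictions", {
  fx <- blob_features()
  svm <- fit_feature_svm(fx$X, fx$y, cost_grid = c(1, 10),
                         gamma_grid = c(0.01, 0.1), folds = 3L, seed = 2)
  expect_gte(max(svm$cv_table$cv_accuracy), 0.95)
  expect_true(svm$cost %in% c(1, 10))                # chosen from the grid
  expect_true(svm$gamma %in% c(0.01, 0.1))

  probs <- predict_svm_probs(svm, fx$X)
  expect_equal(rowSums(probs), rep(1, nrow(fx$X)), tolerance = 1e-6)
  pred <- svm$class_levels[max.col(probs)]
  expect_gte(mean(pred == fx$y), 0.95)
})

test_that("4-class blobs are separated and probabilities feed the fusion rules", {
  fx <- blob_features(n_per = 12L, classes = hepatch_classes(), seed = 8)
  svm <- fit_feature_svm(fx$X, fx$y, cost_grid = 10, gamma_grid = 0.1,
                         folds = 3L, seed = 3, class_levels = hepatch_classes())
  probs <- predict_svm_probs(svm, fx$X)
  pred <- hepatch_classes()[max.col(probs)]
  expect_gte(mean(pred == fx$y), 0.9)
  # downstream interchangeability: every fusion rule accepts SVM output
  for (rule in c("majority", "max", "sum"))
    expect_true(fuse_patches(probs[1:12, ], rule) %in% hepatch_classes())
})

test_that("grid search is seed-reproducible, stratified, and validates input", {
  fx <- blob_features(n_per = 9L)
  fit_twice <- function() fit_feature_svm(fx$X, fx$y, cost_grid = c(1, 10),
                                          gamma_grid = c(0.05, 0.5),
                                          folds = 3L, seed = 11)
  s1 <- fit_twice(); s2 <- fit_twice()
  expect_identical(s1$cost, s2$cost)
  expect_identical(s1$gamma, s2$gamma)
  expect_identical(predict_svm_probs(s1, fx$X), predict_svm_probs(s2, fx$X))

  fold <- hepatch:::stratified_folds(fx$y, 3L, seed = 11)
  for (cl in unique(fx$y))
    expect_true(all(table(fold[fx$y == cl]) == 3L))  # 9 per class over 3 folds

  expect_error(fit_feature_svm(fx$X[1:10, ], c(rep("normal", 8), "invasive",
                                               "invasive"),
                               folds = 3L), "fewer samples")
  expect_error(predict_svm_probs(s1, fx$X[, 1:3]), "dimension")
})

test_that("extract_fc_features reads the designated fc layer deterministically", {
  arch <- tiny_architecture(c(64L, 64L, 3L))
  model <- build_model(arch, seed = 4)
  set.seed(6)
  patches <- lapply(1:3, function(i) array(stats::runif(64 * 64 * 3, 0, 255),
                                           c(64, 64, 3)))
  f <- extract_fc_features(model, patches)           # second fc layer: 8 units
  expect_equal(dim(f), c(3L, 8L))
  expect_true(all(f >= 0))                           # post-ReLU
  expect_identical(extract_fc_features(model, patches), f)
  expect_identical(f[1, ], extract_fc_features(model, patches[c(1, 1)])[2, ])
  expect_error(extract_fc_features(model, patches, fc_index = 5L), "fc layer")

  # the default architecture exposes 128 features at the second fc layer
  n_units <- default_architecture()$layers[[12]]$maps_or_units
  expect_equal(n_units, 128L)
})
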