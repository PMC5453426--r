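# Train/validation splitting and the training loop contracts (cheap parts;
# the end-to-end accuracy criteria live in test-acceptance.R).

test_that("split_train_val partitions at the image level with the floor convention", {
  ids <- sprintf("im%03d", 1:249)
  sp <- split_train_val(ids, fraction = 0.75, seed = 3)
  expect_length(sp$train, 186L)                      # floor(249 * 0.75)
  expect_length(sp$val, 63L)
  expect_length(intersect(sp$train, sp$val), 0L)
  expect_setequal(c(sp$train, sp$val), ids)

  # deterministic under (seed, epoch); epoch changes membership
  sp2 <- split_train_val(ids, 0.75, seed = 3)
  expect_identical(sp, sp2)
  sp3 <- split_train_val(ids, 0.75, seed = 3, epoch = 1L)
  expect_false(identical(sp$train, sp3$train))

  expect_error(split_train_val(ids, 1.2, 1), "fraction")
  expect_error(split_train_val(ids[1:3], 0.75, 1), "at least 4")
})

test_that("stratified splitting keeps every class in the training side", {
  ids <- sprintf("im%02d", 1:16)
  labels <- rep(hepatch_classes(), each = 4)
  sp <- split_train_val(ids, 0.75, seed = 5, labels = labels, stratify = TRUE)
  expect_length(sp$train, 12L)
  got_classes <- unique(labels[match(sp$train, ids)])
  expect_setequal(got_classes, hepatch_classes())
})

# small shared fixture: 64-px synthetic patch records for 2 classes
two_class_fixture <- function(n_per_class = 3L, seed = 101L) {
  suite <- easy_class_suite()
  images <- list(); rows <- list()
  k <- 0
  for (cl in c("normal", "invasive")) {
    for (i in seq_len(n_per_class)) {
      k <- k + 1
      id <- sprintf("%s_%d", cl, i)
      images[[id]] <- render_tissue_image(suite[[cl]], c(128L, 128L),
                                          seed = seed + k)
      rows[[k]] <- data.frame(image_id = id, label = cl)
    }
  }
  tab <- do.call(rbind, rows)
  records <- build_patch_records(tab$image_id,
                                 lapply(tab$image_id, function(i) dim(images[[i]])[1:2]),
                                 tab$label, 64L, 64L, augment = FALSE)
  list(images = images, records = records)
}

test_that("initial loss on balanced classes is ln(4) and history has epoch rows", {
  fx <- two_class_fixture()
  arch <- tiny_architecture(c(64L, 64L, 3L))
  model <- build_model(arch, seed = 7)
  # loss at random init ~ ln 4 (near-uniform softmax by construction)
  losses <- vapply(seq_len(nrow(fx$records)), function(i) {
    x <- get_patch_pixels(fx$images, fx$records[i, ], 64L)
    y <- match(fx$records$label[i], hepatch_classes())
    hepatch:::cross_entropy(model_forward(model, x)$probs, y)
  }, 0)
  expect_equal(mean(losses), log(4), tolerance = 0.1)

  fit <- train_patch_classifier(model, fx$records, fx$images, epochs = 2L,
                                batch_size = 8L, seed = 7, train_fraction = 0.75,
                                stratify_split = TRUE)
  expect_equal(nrow(fit$history), 2L)
  expect_true(all(is.finite(fit$history$loss)))
})

test_that("an easy 2-class patch set is fit to >= 95% training accuracy", {
  fx <- two_class_fixture(n_per_class = 4L)
  arch <- tiny_architecture(c(64L, 64L, 3L), classes = 2L)
  model <- build_model(arch, seed = 3)
  fit <- train_patch_classifier(model, fx$records, fx$images, epochs = 25L,
                                batch_size = 4L, learning_rate = 5e-3, seed = 3,
                                train_fraction = 0.75, stratify_split = TRUE,
                                checkpoint_best = FALSE,
                                class_levels = c("normal", "invasive"))
  # final training-set accuracy on the images actually trained on
  tr_rec <- fx$records[fx$records$image_id %in% fit$split$train, ]
  pred <- hepatch:::predict_patch_records(fit$model, tr_rec, fx$images,
                                          class_levels = c("normal", "invasive"))
  expect_gte(mean(pred$label == tr_rec$label), 0.95)
})

test_that("training is seed-reproducible and rejects degenerate input", {
  fx <- two_class_fixture()
  arch <- tiny_architecture(c(64L, 64L, 3L), classes = 2L)
  run_once <- function() {
    model <- build_model(arch, seed = 9)
    train_patch_classifier(model, fx$records, fx$images, epochs = 1L,
                           batch_size = 8L, seed = 9,
                           class_levels = c("normal", "invasive"))
  }
  f1 <- run_once(); f2 <- run_once()
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$history, f2$history)

  single <- fx$records[fx$records$label == "normal", ]
  expect_error(train_patch_classifier(build_model(arch, 1), single, fx$images),
               "at least 2 classes")
  m4 <- build_model(tiny_architecture(c(64L, 64L, 3L), classes = 3L), 1)
  expect_error(train_patch_classifier(m4, fx$records, fx$images,
                                      class_levels = c("a", "b")),
               "does not match")
})

test_that("predict_patch_probs is a stateless per-patch map", {
  fx <- two_class_fixture(n_per_class = 1L)
  arch <- tiny_architecture(c(64L, 64L, 3L))
  model <- build_model(arch, seed = 21)
  patches <- lapply(1:4, function(i)
    get_patch_pixels(fx$images, fx$records[i, ], 64L, center = FALSE))
  probs <- predict_patch_probs(model, patches)
  expect_equal(dim(probs), c(4L, 4L))
  expect_equal(rowSums(probs), rep(1, 4), tolerance = 1e-6)
  expect_true(all(probs >= 0))
  perm <- c(3, 1, 4, 2)
  expect_equal(predict_patch_probs(model, patches[perm]), probs[perm, ])
})
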