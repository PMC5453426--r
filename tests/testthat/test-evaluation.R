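# Confusion/accuracy/sensitivity arithmetic, pooling, binary grouping.

test_that("metrics match hand computation on a constructed confusion", {
  # 4x4 with known counts: diag (5, 4, 3, 6), off-diag errors
  true <- c(rep("normal", 6), rep("benign", 6), rep("insitu", 5),
            rep("invasive", 7))
  pred <- c(rep("normal", 5), "benign",
            rep("benign", 4), "insitu", "insitu",
            rep("insitu", 3), "invasive", "invasive",
            rep("invasive", 6), "normal")
  rep <- confusion_and_metrics(true, pred)
  expect_equal(rep$n, 24L)
  expect_equal(sum(diag(rep$confusion)), 18L)
  expect_equal(rep$accuracy, 18 / 24 * 100)
  expect_equal(unname(rep$sensitivity),
               c(5 / 6, 4 / 6, 3 / 5, 6 / 7) * 100)

  perfect <- confusion_and_metrics(true, true)
  expect_equal(perfect$accuracy, 100)
  expect_true(all(perfect$sensitivity == 100))

  expect_error(confusion_and_metrics(true, pred[-1]), "length")
  expect_error(confusion_and_metrics(c(true, "cancer"), c(pred, "normal")),
               "unknown label")
})

test_that("for balanced classes accuracy equals the mean sensitivity", {
  set.seed(17)
  true <- rep(hepatch_classes(), each = 25)
  pred <- sample(hepatch_classes(), 100, replace = TRUE)
  rep <- confusion_and_metrics(true, pred)
  expect_equal(rep$accuracy, mean(rep$sensitivity))
})

test_that("count-weighted pooling equals the merged-confusion metric exactly", {
  set.seed(23)
  for (i in 1:20) {
    cm1 <- matrix(sample(0:30, 16, replace = TRUE), 4, 4)
    cm2 <- matrix(sample(0:30, 16, replace = TRUE), 4, 4)
    acc <- function(cm) sum(diag(cm)) / sum(cm) * 100
    pooled <- pool_subset_metrics(c(acc(cm1), acc(cm2)),
                                  c(sum(cm1), sum(cm2)), digits = NULL)
    expect_equal(pooled, acc(cm1 + cm2))
  }
  expect_equal(pool_subset_metrics(c(55.5, 55.5), c(3, 97)), 55.5)  # idempotent
  expect_error(pool_subset_metrics(c(1, 2), c(1, 0)), "> 0")
  expect_error(pool_subset_metrics(c(1, 2), 1), "length")
})

test_that("binary grouping conserves counts and can only raise accuracy", {
  true <- rep(hepatch_classes(), times = c(9, 9, 9, 9))
  bin <- group_labels_binary(true)
  expect_length(bin, 36L)
  expect_equal(sum(bin == "carcinoma"), 18L)
  expect_error(group_labels_binary("tumour"), "unknown label")

  set.seed(29)
  for (i in 1:20) {
    truth <- sample(hepatch_classes(), 40, replace = TRUE)
    pred <- sample(hepatch_classes(), 40, replace = TRUE)
    acc4 <- confusion_and_metrics(truth, pred)$accuracy
    acc2 <- confusion_and_metrics(group_labels_binary(truth),
                                  group_labels_binary(pred),
                                  classes = c("non_carcinoma", "carcinoma"))$accuracy
    expect_gte(acc2, acc4)
  }
})

test_that("percentages present with one-decimal round-half-up", {
  expect_equal(round_half_up(66.65, 1), 66.7)
  expect_equal(round_half_up(77.75, 1), 77.8)
  expect_equal(round_half_up(94.44, 1), 94.4)
  expect_equal(round_half_up(c(0.05, 2.25), 1), c(0.1, 2.3))
})

test_that("evaluate_predictions builds per-subset and pooled reports", {
  truth <- data.frame(
    image_id = sprintf("im%02d", 1:12),
    label = rep(hepatch_classes(), 3),
    subset = rep(c("test_initial", "test_extended"), times = c(8, 4)))
  preds <- data.frame(
    image_id = truth$image_id,
    label_4class = c(truth$label[1:10], "normal", "normal"),
    label_binary = group_labels_binary(c(truth$label[1:10], "normal", "normal")))
  reports <- evaluate_predictions(truth, preds)
  expect_setequal(names(reports),
                  as.vector(outer(c("4class", "binary"),
                                  c("test_initial", "test_extended", "overall"),
                                  paste, sep = ".")))
  expect_equal(reports[["4class.test_initial"]]$accuracy, 100)
  expect_equal(reports[["4class.overall"]]$n, 12L)
  expect_equal(reports[["4class.overall"]]$accuracy, 10 / 12 * 100)
  # pooled equals count-weighted pooling of the subset accuracies
  expect_equal(reports[["4class.overall"]]$accuracy,
               pool_subset_metrics(c(reports[["4class.test_initial"]]$accuracy,
                                     reports[["4class.test_extended"]]$accuracy),
                                   c(8, 4), digits = NULL))
  tab <- eval_reports_table(reports)
  expect_equal(nrow(tab), 6L)
})
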