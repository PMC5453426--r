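# Evaluation: confusion matrices, accuracy and per-class sensitivity for the
# 4-class and grouped binary tasks, with item-count-weighted pooling across
# subsets.  Percentages are presented to one decimal, round-half-up.

#' Round half away from zero (presentation rounding)
#'
#' @param x Numeric vector (percent scale values are non-negative here).
#' @param digits Decimal places (default 1).
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Confusion matrix, accuracy and per-class sensitivity
#'
#' Accuracy is `trace / total * 100`; sensitivity of class c is
#' `diagonal(c) / row-total(c) * 100` (rows = true class, columns =
#' predicted).  Values are stored unrounded; presentation rounding is applied
#' by the print method.
#'
#' @param true,predicted Equal-length label vectors within `classes`.
#' @param classes Class vocabulary.
#' @param task,granularity,subset Optional report metadata strings.
#' @return List of class `eval_report`: `confusion`, `accuracy`,
#'   `sensitivity` (named), `n`, plus the metadata.
#' @export
confusion_and_metrics <- function(true, predicted,
                                  classes = hepatch_classes(),
                                  task = NA_character_,
                                  granularity = NA_character_,
                                  subset = NA_character_) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) != length(predicted))
    stop("true and predicted label lists differ in length", call. = FALSE)
  bad <- setdiff(unique(c(true, predicted)), classes)
  if (length(bad) > 0L)
    stop("unknown label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  cm <- table(factor(true, levels = classes),
              factor(predicted, levels = classes))
  cm <- unclass(cm)
  total <- sum(cm)
  acc <- sum(diag(cm)) / total * 100
  row_tot <- rowSums(cm)
  sens <- ifelse(row_tot > 0, diag(cm) / row_tot * 100, NA_real_)
  names(sens) <- classes
  structure(list(confusion = cm, accuracy = acc, sensitivity = sens,
                 n = total, task = task, granularity = granularity,
                 subset = subset),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> task=%s granularity=%s subset=%s n=%d\n",
              x$task, x$granularity, x$subset, x$n))
  cat(sprintf("accuracy: %.1f%%\n", round_half_up(x$accuracy, 1)))
  cat("sensitivity (%):\n")
  print(round_half_up(x$sensitivity, 1))
  cat("confusion (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Pool subset metrics by item count
#'
#' The item-count-weighted mean of per-subset percentages; this equals the
#' metric of the merged confusion matrices exactly.  E.g. pooling 72.5% over
#' 240 patches with 59.4% over 192 patches gives 66.7%.
#'
#' @param values Percentages per subset.
#' @param weights Item counts per subset (all > 0).
#' @param digits Presentation rounding (default 1 decimal, half-up);
#'   `NULL` for the exact pooled value.
#' @return The pooled percentage.
#' @export
pool_subset_metrics <- function(values, weights, digits = 1) {
  if (length(values) != length(weights))
    stop("values and weights differ in length", call. = FALSE)
  if (any(weights <= 0)) stop("weights must be > 0", call. = FALSE)
  pooled <- sum(values * weights) / sum(weights)
  if (is.null(digits)) pooled else round_half_up(pooled, digits)
}

#' Group 4-class labels into the binary task
#'
#' @param labels 4-class labels.
#' @return Character vector over `non_carcinoma` / `carcinoma`, same length.
#' @export
group_labels_binary <- function(labels) {
  check_labels(labels, "binary grouping")
  unname(hepatch_binary_groups()[as.character(labels)])
}

#' Evaluate predictions across tasks and subsets
#'
#' Builds `eval_report`s for the 4-class and binary tasks per subset present
#' plus the pooled ("overall") rows, mirroring the initial / extended /
#' overall table layout.
#'
#' @param truth Data frame with columns `image_id`, `label`, `subset`.
#' @param predictions Data frame with `image_id`, `label_4class`,
#'   `label_binary`.
#' @param granularity Metadata string (default `"image"`).
#' @return Named list of `eval_report`s, keys like
#'   `"4class.test_initial"`, `"binary.overall"`.
#' @export
evaluate_predictions <- function(truth, predictions, granularity = "image") {
  m <- merge(truth, predictions, by = "image_id", sort = TRUE)
  if (nrow(m) != nrow(predictions))
    stop("predictions contain image ids absent from the truth table", call. = FALSE)
  subsets <- unique(m$subset)
  reports <- list()
  add <- function(key, rep) reports[[key]] <<- rep
  scopes <- c(as.list(subsets), list(subsets))
  names(scopes) <- c(subsets, "overall")
  for (sc in names(scopes)) {
    rows <- m[m$subset %in% scopes[[sc]], , drop = FALSE]
    add(paste0("4class.", sc),
        confusion_and_metrics(rows$label, rows$label_4class,
                              classes = hepatch_classes(), task = "4class",
                              granularity = granularity, subset = sc))
    add(paste0("binary.", sc),
        confusion_and_metrics(group_labels_binary(rows$label),
                              rows$label_binary,
                              classes = c("non_carcinoma", "carcinoma"),
                              task = "binary", granularity = granularity,
                              subset = sc))
  }
  reports
}

#' Flatten evaluation reports to a data frame
#'
#' @param reports Named list of `eval_report`s from [evaluate_predictions()].
#' @return data.frame with one row per report: task, subset, n, accuracy and
#'   per-class sensitivities (1-decimal, half-up).
#' @export
eval_reports_table <- function(reports) {
  rows <- lapply(names(reports), function(k) {
    r <- reports[[k]]
    sens <- round_half_up(r$sensitivity, 1)
    df <- data.frame(task = r$task, subset = r$subset, granularity = r$granularity,
                     n = r$n, accuracy = round_half_up(r$accuracy, 1))
    for (cl in names(sens)) df[[paste0("sens_", cl)]] <- sens[[cl]]
    df
  })
  out <- do.call(rbind, lapply(rows, function(df) {
    # align columns across 4-class and binary reports
    all_cols <- c("task", "subset", "granularity", "n", "accuracy",
                  paste0("sens_", c(hepatch_classes(), "non_carcinoma", "carcinoma")))
    for (cc in setdiff(all_cols, names(df))) df[[cc]] <- NA_real_
    df[all_cols]
  }))
  out
}
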