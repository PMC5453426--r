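# Patch-wise classifier training: image-level train/validation split,
# epoch loop with categorical cross-entropy and Adam, class-balanced
# validation accuracy, best-validation checkpointing.  Fully seed-driven.

#' Split images into training and validation sets
#'
#' The split is at the image level (all patches of an image stay on one
#' side), disjoint and exhaustive, with `floor(fraction * n)` training
#' images.  Deterministic in `(seed, epoch)`: with per-epoch validation
#' resampling the membership changes with `epoch`, otherwise pass the same
#' epoch value.
#'
#' @param image_ids Character vector of image ids.
#' @param fraction Training fraction in (0, 1), default 0.75.
#' @param seed Integer seed.
#' @param epoch Epoch index mixed into the seed (default 0).
#' @param labels Optional label per image; when given and `stratify = TRUE`,
#'   the split draws `floor(fraction * n_c)` per class (with a top-up to keep
#'   the global training count at `floor(fraction * n)`).
#' @param stratify Stratify by class (requires `labels`).
#' @return List with `train` and `val` character vectors (disjoint, union =
#'   all ids).
#' @export
split_train_val <- function(image_ids, fraction = 0.75, seed = 1L, epoch = 0L,
                            labels = NULL, stratify = FALSE) {
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must be in (0, 1)", call. = FALSE)
  n <- length(image_ids)
  if (n < 4L) stop("need at least 4 images to split", call. = FALSE)
  set.seed(as.integer((as.numeric(seed) + 1000003 * epoch) %% 2147483647))
  n_train <- floor(fraction * n)
  if (stratify && !is.null(labels)) {
    stopifnot(length(labels) == n)
    train <- character(0)
    for (cl in unique(labels)) {
      ids_c <- image_ids[labels == cl]
      k <- floor(fraction * length(ids_c))
      train <- c(train, sample(ids_c, k))
    }
    # top up to the global floor count from the remaining pool
    pool <- setdiff(image_ids, train)
    if (length(train) < n_train)
      train <- c(train, sample(pool, n_train - length(train)))
  } else {
    train <- sample(image_ids, n_train)
  }
  list(train = sort(train), val = sort(setdiff(image_ids, train)))
}

# class-balanced accuracy: mean per-class recall over classes present in truth
balanced_accuracy <- function(true, pred, classes) {
  recalls <- vapply(classes, function(cl) {
    sel <- true == cl
    if (!any(sel)) return(NA_real_)
    mean(pred[sel] == cl)
  }, 0)
  mean(recalls, na.rm = TRUE)
}

#' Train the patch-wise classifier
#'
#' Runs the configured number of epochs of Adam on categorical cross-entropy
#' over the training-image patches, validating on the held-out images'
#' unaugmented patches with class-balanced accuracy, and returns the weights
#' of the best validation epoch.  With `resample_validation` the image-level
#' split is redrawn each epoch (as in the reference protocol; a warning is
#' logged because patches of an image may then appear on both sides across
#' epochs).
#'
#' @param model A `cnn_model` whose output dimension matches the class count.
#' @param records A `patch_records` table (train-subset images).
#' @param images Named list of image arrays keyed by `image_id`.
#' @param epochs,batch_size,learning_rate,seed Training protocol.
#' @param train_fraction Image-level training fraction (default 0.75).
#' @param resample_validation Redraw the split each epoch (default `FALSE`).
#' @param stratify_split Stratify the image split by class (default `TRUE`).
#' @param checkpoint_best Return the weights of the best validation epoch
#'   (default `TRUE`, the reference protocol); `FALSE` keeps the final-epoch
#'   weights.
#' @param class_levels Class vocabulary (default [hepatch_classes()]).
#' @param verbose Emit per-epoch messages.
#' @return List: `model` (best-validation weights), `history` (data.frame
#'   `epoch`, `loss`, `val_balanced_accuracy`), `best_epoch`, `split` (the
#'   last split used).
#' @export
train_patch_classifier <- function(model, records, images,
                                   epochs = 50L, batch_size = 16L,
                                   learning_rate = 1e-3, seed = 1L,
                                   train_fraction = 0.75,
                                   resample_validation = FALSE,
                                   stratify_split = TRUE,
                                   checkpoint_best = TRUE,
                                   class_levels = hepatch_classes(),
                                   verbose = FALSE) {
  records <- as.data.frame(records)
  if (length(unique(records$label)) < 2L)
    stop("training requires patches from at least 2 classes", call. = FALSE)
  n_out <- model$spec$layers[[length(model$spec$layers)]]$maps_or_units
  if (length(class_levels) != n_out)
    stop(sprintf("model output dimension (%d) does not match class count (%d)",
                 n_out, length(class_levels)), call. = FALSE)
  if (resample_validation)
    warning("per-epoch validation resampling is enabled: patches of an image ",
            "may cross the train/validation boundary between epochs",
            call. = FALSE)
  patch_size <- model$spec$input[1]
  img_tab <- unique(records[, c("image_id", "label")])
  state <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_balanced_accuracy = numeric(0))
  best <- list(acc = -Inf, params = model$params, epoch = 0L)
  split <- NULL
  for (ep in seq_len(epochs)) {
    if (is.null(split) || resample_validation) {
      split <- split_train_val(img_tab$image_id, train_fraction, seed,
                               epoch = if (resample_validation) ep else 0L,
                               labels = img_tab$label, stratify = stratify_split)
    }
    tr <- records[records$image_id %in% split$train, , drop = FALSE]
    va <- records[records$image_id %in% split$val &
                    records$augmentation_id == 0L, , drop = FALSE]
    if (nrow(tr) == 0L) stop("empty training split", call. = FALSE)
    set.seed(as.integer((as.numeric(seed) + 7919 * ep) %% 2147483647))
    ord <- sample.int(nrow(tr))
    losses <- numeric(nrow(tr))
    pos <- 1L
    while (pos <= nrow(tr)) {
      take <- ord[pos:min(pos + batch_size - 1L, nrow(tr))]
      grad_sum <- NULL
      for (t in take) {
        rec <- tr[t, ]
        x <- get_patch_pixels(images, rec, patch_size, center = TRUE)
        fwd <- model_forward(model, x, keep_cache = TRUE)
        y_idx <- match(rec$label, class_levels)
        losses[match(t, ord)] <- cross_entropy(fwd$probs, y_idx)
        g <- model_backward(model, fwd$caches, fwd$probs, y_idx)
        if (is.null(grad_sum)) grad_sum <- g
        else for (i in seq_along(g)) if (!is.null(g[[i]])) {
          grad_sum[[i]]$W <- grad_sum[[i]]$W + g[[i]]$W
          grad_sum[[i]]$b <- grad_sum[[i]]$b + g[[i]]$b
        }
      }
      for (i in seq_along(grad_sum)) if (!is.null(grad_sum[[i]])) {
        grad_sum[[i]]$W <- grad_sum[[i]]$W / length(take)
        grad_sum[[i]]$b <- grad_sum[[i]]$b / length(take)
      }
      upd <- adam_step(model$params, grad_sum, state, learning_rate)
      model$params <- upd$params
      state <- upd$state
      pos <- pos + batch_size
    }
    epoch_loss <- mean(losses)
    if (!is.finite(epoch_loss))
      stop(sprintf("non-finite training loss at epoch %d; aborting (last batch ",
                   "losses: %s)", ep,
                   paste(signif(utils::tail(losses, 3), 3), collapse = ", ")),
           call. = FALSE)
    val_acc <- NA_real_
    if (nrow(va) > 0L) {
      vp <- predict_patch_records(model, va, images, class_levels)
      val_acc <- balanced_accuracy(va$label, vp$label, class_levels)
    }
    if (!is.na(val_acc) && val_acc > best$acc) {
      best <- list(acc = val_acc, params = model$params, epoch = ep)
    } else if (is.na(val_acc)) {
      best <- list(acc = NA_real_, params = model$params, epoch = ep)
    }
    history <- rbind(history, data.frame(epoch = ep, loss = epoch_loss,
                                         val_balanced_accuracy = val_acc))
    if (verbose)
      message(sprintf("epoch %d/%d  loss %.4f  val balanced acc %s",
                      ep, epochs, epoch_loss,
                      ifelse(is.na(val_acc), "NA", sprintf("%.3f", val_acc))))
  }
  if (checkpoint_best) model$params <- best$params
  list(model = model, history = history,
       best_epoch = if (checkpoint_best) best$epoch else epochs, split = split)
}

#' Predict class probabilities for a list of patches
#'
#' Stateless: permuting the input order permutes the output rows identically.
#'
#' @param model A trained `cnn_model`.
#' @param patches List of patch arrays matching the model input geometry.
#' @param center Apply [center_channels()] first (default `TRUE`; pass
#'   `FALSE` for already-centered patches).
#' @return Numeric matrix `(n, n_classes)`; each row is non-negative and sums
#'   to 1.
#' @export
predict_patch_probs <- function(model, patches, center = TRUE) {
  n_out <- model$spec$layers[[length(model$spec$layers)]]$maps_or_units
  out <- matrix(NA_real_, length(patches), n_out)
  for (i in seq_along(patches)) {
    x <- patches[[i]]
    if (center) x <- center_channels(x)
    out[i, ] <- model_forward(model, x)$probs
  }
  out
}

# predict over a patch-record table; returns probs matrix + argmax labels
predict_patch_records <- function(model, records, images, class_levels = hepatch_classes()) {
  patch_size <- model$spec$input[1]
  probs <- matrix(NA_real_, nrow(records),
                  model$spec$layers[[length(model$spec$layers)]]$maps_or_units)
  for (i in seq_len(nrow(records))) {
    x <- get_patch_pixels(images, records[i, ], patch_size, center = TRUE)
    probs[i, ] <- model_forward(model, x)$probs
  }
  list(probs = probs,
       label = class_levels[apply(probs, 1, argmax_with_priority,
                                  classes = class_levels)])
}
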