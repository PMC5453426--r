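# RBF-kernel SVM head on CNN fully-connected features.
#
# No SVM library exists in the target environment, so a simplified-SMO
# dual solver is implemented here.  Multiclass handling is one-vs-rest with
# per-class Platt-scaled (sigmoid-calibrated) decision values, renormalized
# to a probability vector so the SVM head plugs into the same fusion rules
# as the CNN softmax.  The grid search is exhaustive over logarithmic
# (cost, gamma) grids with stratified k-fold cross-validation.

#' Extract fully-connected-layer activations as feature vectors
#'
#' Returns the post-ReLU activations of the requested fully-connected layer
#' (the second one by default, the 128-unit layer in the default
#' architecture) for each patch.  A pure function of (weights, patch).
#'
#' @param model A trained `cnn_model` with at least `fc_index` fc layers.
#' @param patches List of patch arrays.
#' @param fc_index Which fc layer to read (default 2).
#' @param center Center patch channels first (default `TRUE`).
#' @return Numeric matrix `(n_patches, n_units)`; all entries >= 0.
#' @export
extract_fc_features <- function(model, patches, fc_index = 2L, center = TRUE) {
  n_fc <- sum(vapply(model$spec$layers, `[[`, "", "kind") == "fc")
  if (n_fc < fc_index)
    stop(sprintf("architecture has %d fc layers; cannot read fc layer %d",
                 n_fc, fc_index), call. = FALSE)
  out <- NULL
  for (i in seq_along(patches)) {
    x <- patches[[i]]
    if (center) x <- center_channels(x)
    a <- model_forward(model, x)$fc_activations[[fc_index]]
    if (is.null(out)) out <- matrix(NA_real_, length(patches), length(a))
    out[i, ] <- a
  }
  out
}

rbf_kernel <- function(X, Y, gamma) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-gamma * pmax(d2, 0))
}

# Simplified SMO (Platt's pedagogical variant) for the soft-margin dual with
# a precomputed kernel.  y in {-1, +1}.  The margin vector f = K (alpha * y)
# is maintained incrementally so each working-pair update is O(n).
# Deterministic given the RNG state; adequate for the few-hundred-sample
# problems this head faces.
svm_smo <- function(K, y, C, tol = 1e-3, max_passes = 5L, max_iter = 400L) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  f <- numeric(n)                       # K %*% (alpha * y), kept up to date
  passes <- 0L
  iter <- 0L
  while (passes < max_passes && iter < max_iter) {
    iter <- iter + 1L
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- f[i] + b - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) || (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- sample.int(n - 1L, 1L)
        if (j >= i) j <- j + 1L
        Ej <- f[j] + b - y[j]
        ai_old <- alpha[i]; aj_old <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, alpha[j] - alpha[i]); H <- min(C, C + alpha[j] - alpha[i])
        } else {
          L <- max(0, alpha[i] + alpha[j] - C); H <- min(C, alpha[i] + alpha[j])
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        alpha[j] <- min(max(alpha[j] - y[j] * (Ei - Ej) / eta, L), H)
        if (abs(alpha[j] - aj_old) < 1e-5) next
        alpha[i] <- alpha[i] + y[i] * y[j] * (aj_old - alpha[j])
        di <- (alpha[i] - ai_old) * y[i]
        dj <- (alpha[j] - aj_old) * y[j]
        f <- f + di * K[, i] + dj * K[, j]
        b1 <- b - Ei - di * K[i, i] - dj * K[i, j]
        b2 <- b - Ej - di * K[i, j] - dj * K[j, j]
        b <- if (alpha[i] > 0 && alpha[i] < C) b1
             else if (alpha[j] > 0 && alpha[j] < C) b2
             else (b1 + b2) / 2
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  list(alpha = alpha, b = b)
}

# decision values of a fitted binary machine on new kernel columns
svm_decision <- function(fit, K_new_train, y_train) {
  drop(K_new_train %*% (fit$alpha * y_train)) + fit$b
}

# stratified fold assignment, seed-reproducible
stratified_folds <- function(labels, k, seed) {
  set.seed(as.integer(seed))
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Fit the RBF-SVM head by exhaustive grid search
#'
#' For every `(cost, gamma)` pair, k-fold (default 3) stratified
#' cross-validated one-vs-rest accuracy is measured; the best pair (ties:
#' first in grid order) is refit on the whole training set.  Per-class Platt
#' sigmoids are fitted on the out-of-fold decision values of the winning
#' pair so the head emits calibrated class probabilities.
#'
#' @param features Matrix `(n, d)` of feature vectors.
#' @param labels Class labels (character), each with at least `folds`
#'   samples.
#' @param cost_grid,gamma_grid Logarithmic search grids.
#' @param folds CV folds (default 3).
#' @param seed Seed controlling fold assignment and SMO working-pair draws.
#' @param class_levels Class vocabulary.
#' @return List of class `svm_head`: per-class machines, support features,
#'   Platt coefficients, chosen `(cost, gamma)`, CV table.
#' @export
fit_feature_svm <- function(features, labels,
                            cost_grid = 10^(0:2), gamma_grid = 10^(-2:0),
                            folds = 3L, seed = 1L,
                            class_levels = sort(unique(labels))) {
  features <- as.matrix(features)
  labels <- as.character(labels)
  stopifnot(nrow(features) == length(labels))
  counts <- table(labels)
  if (any(counts < folds))
    stop(sprintf("class '%s' has fewer samples (%d) than folds (%d)",
                 names(counts)[which.min(counts)], min(counts), folds),
         call. = FALSE)
  fold <- stratified_folds(labels, folds, seed)
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_accuracy <- NA_real_
  cv_dec <- vector("list", nrow(grid))   # out-of-fold decisions per pair
  for (g in seq_len(nrow(grid))) {
    K <- rbf_kernel(features, features, grid$gamma[g])
    dec <- matrix(NA_real_, nrow(features), length(class_levels))
    for (f in seq_len(folds)) {
      tr <- which(fold != f); te <- which(fold == f)
      for (ci in seq_along(class_levels)) {
        yb <- ifelse(labels[tr] == class_levels[ci], 1, -1)
        set.seed(as.integer(seed) + 131 * g + 17 * f + ci)
        fit <- svm_smo(K[tr, tr, drop = FALSE], yb, grid$cost[g])
        dec[te, ci] <- svm_decision(fit, K[te, tr, drop = FALSE], yb)
      }
    }
    pred <- class_levels[max.col(dec, ties.method = "first")]
    grid$cv_accuracy[g] <- mean(pred == labels)
    cv_dec[[g]] <- dec
  }
  best <- which.max(grid$cv_accuracy)   # ties: first in grid order
  cost <- grid$cost[best]; gamma <- grid$gamma[best]
  K <- rbf_kernel(features, features, gamma)
  machines <- vector("list", length(class_levels))
  platt <- vector("list", length(class_levels))
  for (ci in seq_along(class_levels)) {
    yb <- ifelse(labels == class_levels[ci], 1, -1)
    set.seed(as.integer(seed) + 9973 + ci)
    machines[[ci]] <- svm_smo(K, yb, cost)
    machines[[ci]]$y <- yb
    d <- cv_dec[[best]][, ci]
    y01 <- as.integer(yb == 1)
    co <- tryCatch(
      suppressWarnings(stats::coef(stats::glm(y01 ~ d, family = stats::binomial()))),
      error = function(e) c(0, 1))
    if (anyNA(co)) co <- c(0, 1)
    platt[[ci]] <- co
  }
  structure(list(machines = machines, platt = platt,
                 features = features, labels = labels,
                 class_levels = class_levels,
                 cost = cost, gamma = gamma, cv_table = grid,
                 folds = folds, seed = as.integer(seed)),
            class = "svm_head")
}

#' Predict calibrated class probabilities with the SVM head
#'
#' One-vs-rest decision values pass through the per-class Platt sigmoids and
#' are renormalized to sum to 1, making the output interchangeable with the
#' CNN softmax for every fusion rule.
#'
#' @param svm An `svm_head` from [fit_feature_svm()].
#' @param features Matrix `(m, d)` of feature vectors (same dimension as at
#'   training).
#' @return Matrix `(m, n_classes)` of probabilities (rows sum to 1).
#' @export
predict_svm_probs <- function(svm, features) {
  features <- as.matrix(features)
  if (ncol(features) != ncol(svm$features))
    stop(sprintf("feature dimension %d does not match training dimension %d",
                 ncol(features), ncol(svm$features)), call. = FALSE)
  Kn <- rbf_kernel(features, svm$features, svm$gamma)
  probs <- matrix(NA_real_, nrow(features), length(svm$class_levels))
  for (ci in seq_along(svm$class_levels)) {
    d <- svm_decision(svm$machines[[ci]], Kn, svm$machines[[ci]]$y)
    co <- svm$platt[[ci]]
    probs[, ci] <- stats::plogis(co[1] + co[2] * d)
  }
  probs <- pmax(probs, 1e-9)
  probs / rowSums(probs)
}
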