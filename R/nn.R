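# Native CNN engine: im2col convolution (BLAS matmul), max-pooling with
# stride equal to pool size, fully-connected layers, softmax/cross-entropy,
# manual backpropagation and Adam updates.  Correctness is established by a
# numeric-gradient oracle in the test suite.
#
# Feature maps are double arrays (h, w, maps); a model is the architecture
# spec plus a per-layer parameter list.  All randomness is seed-controlled.

pad_same <- function(x, k) {
  if (k %% 2L == 0L) stop("'same' padding requires an odd kernel", call. = FALSE)
  p <- (k - 1L) %/% 2L
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  xp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), ] <- x
  xp
}

# im2col by contiguous block slicing: column (ki, kj, ch) of the patch
# matrix is the shifted sub-image, so rows enumerate output positions in
# column-major order (row index fastest) — matching array(z, c(oh, ow, m)).
conv_forward <- function(x, W, b, k, padding) {
  xp <- if (padding == "same") pad_same(x, k) else x
  d <- dim(xp)
  oh <- d[1] - k + 1L; ow <- d[2] - k + 1L
  cols <- matrix(0, oh * ow, k * k * d[3])
  col_i <- 0L
  for (ch in seq_len(d[3])) for (kj in seq_len(k)) for (ki in seq_len(k)) {
    col_i <- col_i + 1L
    cols[, col_i] <- xp[ki:(ki + oh - 1L), kj:(kj + ow - 1L), ch]
  }
  z <- cols %*% W
  z <- z + rep(b, each = nrow(z))
  list(z = array(z, c(oh, ow, ncol(W))),
       cache = list(cols = cols, padded_dim = d, input_dim = dim(x),
                    oh = oh, ow = ow, k = k, padding = padding))
}

conv_backward <- function(dz, cache, W, need_dx = TRUE) {
  m <- ncol(W)
  oh <- cache$oh; ow <- cache$ow; k <- cache$k
  dZ <- matrix(dz, oh * ow, m)
  dW <- crossprod(cache$cols, dZ)
  db <- colSums(dZ)
  if (!need_dx) return(list(dx = NULL, dW = dW, db = db))
  dcols <- tcrossprod(dZ, W)
  dxp <- array(0, cache$padded_dim)
  col_i <- 0L
  for (ch in seq_len(cache$padded_dim[3])) for (kj in seq_len(k)) for (ki in seq_len(k)) {
    col_i <- col_i + 1L
    dxp[ki:(ki + oh - 1L), kj:(kj + ow - 1L), ch] <-
      dxp[ki:(ki + oh - 1L), kj:(kj + ow - 1L), ch] + dcols[, col_i]
  }
  if (cache$padding == "same") {
    p <- (k - 1L) %/% 2L
    d <- cache$input_dim
    dxp <- dxp[(p + 1L):(p + d[1]), (p + 1L):(p + d[2]), , drop = FALSE]
  }
  list(dx = dxp, dW = dW, db = db)
}

maxpool_forward <- function(x, p) {
  d <- dim(x)
  h2 <- d[1] %/% p; w2 <- d[2] %/% p; ch <- d[3]
  if (h2 < 1L || w2 < 1L) stop("pooling window larger than input", call. = FALSE)
  xc <- x[seq_len(h2 * p), seq_len(w2 * p), , drop = FALSE]
  # rows of M enumerate the p*p in-window positions (a + (cc-1)*p)
  M <- matrix(aperm(array(xc, c(p, h2, p, w2, ch)), c(1L, 3L, 2L, 4L, 5L)),
              nrow = p * p)
  best <- M[1L, ]
  bestK <- rep.int(1L, length(best))
  for (kk in seq_len(p * p)[-1L]) {
    s <- M[kk, ]
    gt <- s > best
    best[gt] <- s[gt]; bestK[gt] <- kk
  }
  t <- seq_along(best) - 1L
  b <- t %% h2 + 1L
  dd <- (t %/% h2) %% w2 + 1L
  chI <- t %/% (h2 * w2) + 1L
  a <- (bestK - 1L) %% p + 1L
  cc <- (bestK - 1L) %/% p + 1L
  lin <- (a + (b - 1L) * p) + (cc + (dd - 1L) * p - 1L) * d[1] +
    (chI - 1L) * d[1] * d[2]
  list(z = array(best, c(h2, w2, ch)), cache = list(lin = lin, input_dim = d))
}

maxpool_backward <- function(dz, cache) {
  dx <- numeric(prod(cache$input_dim))
  dx[as.vector(cache$lin)] <- as.vector(dz)   # windows are disjoint
  dim(dx) <- cache$input_dim
  dx
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Build a trainable model from an architecture spec
#'
#' Weights are randomly initialized from the seed: He (fan-in scaled) normal
#' for conv layers, Glorot for hidden fc layers, and a small-scale normal
#' (sd 0.01) for the softmax output layer so the initial output is near
#' uniform.  Inputs are scaled by `input_scale` inside the forward pass to
#' condition the optimization (centered 8-bit patches land roughly in
#' [-1, 1]).
#'
#' @param spec A validated `cnn_architecture`.
#' @param seed Integer seed controlling initialization.
#' @param input_scale Input scaling applied in the forward pass
#'   (default 1/128).
#' @return A list of class `cnn_model`: `spec`, `params`, `input_scale`,
#'   `seed`.
#' @export
build_model <- function(spec, seed = 1L, input_scale = 1 / 128) {
  validate_architecture(spec)
  shapes <- propagate_shapes(spec)
  set.seed(as.integer(seed))
  params <- vector("list", length(spec$layers))
  c_in <- spec$input[3]
  flat_in <- NA_integer_
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$kind == "conv") {
      fan_in <- ly$kernel^2 * c_in
      params[[i]] <- list(
        W = matrix(stats::rnorm(fan_in * ly$maps_or_units, sd = sqrt(2 / fan_in)),
                   fan_in, ly$maps_or_units),
        b = numeric(ly$maps_or_units))
      c_in <- ly$maps_or_units
    } else if (ly$kind == "fc") {
      if (is.na(flat_in)) {
        prev <- shapes[shapes$kind != "fc", ]
        last_sp <- prev[nrow(prev), ]
        flat_in <- last_sp$maps * last_sp$height * last_sp$width
      }
      n_out <- ly$maps_or_units
      sd <- if (identical(ly$activation, "softmax")) 0.01
            else sqrt(2 / (flat_in + n_out))
      params[[i]] <- list(
        W = matrix(stats::rnorm(flat_in * n_out, sd = sd), flat_in, n_out),
        b = numeric(n_out))
      flat_in <- n_out
    }
  }
  structure(list(spec = spec, params = params, input_scale = input_scale,
                 seed = as.integer(seed)),
            class = "cnn_model")
}

#' Forward pass of a model on one patch
#'
#' @param model A `cnn_model`.
#' @param x Input array matching `spec$input` (centered patch).
#' @param keep_cache Keep per-layer caches for backpropagation.
#' @return List: `probs` (softmax output), `fc_activations` (post-activation
#'   vectors of each fc layer, in order), `caches` (if requested).
#' @export
model_forward <- function(model, x, keep_cache = FALSE) {
  d <- dim(x)
  if (is.null(d) || !all(d == model$spec$input))
    stop(sprintf("input geometry %s does not match model input %s",
                 paste(d, collapse = "x"),
                 paste(model$spec$input, collapse = "x")), call. = FALSE)
  cur <- x * model$input_scale
  layers <- model$spec$layers
  caches <- if (keep_cache) vector("list", length(layers)) else NULL
  fc_acts <- list()
  probs <- NULL
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$kind == "conv") {
      fw <- conv_forward(cur, model$params[[i]]$W, model$params[[i]]$b,
                         ly$kernel, ly$padding)
      a <- pmax(fw$z, 0)
      if (keep_cache) caches[[i]] <- c(fw$cache, list(mask = fw$z > 0))
      cur <- a
    } else if (ly$kind == "maxpool") {
      fw <- maxpool_forward(cur, ly$kernel)
      if (keep_cache) caches[[i]] <- fw$cache
      cur <- fw$z
    } else {
      v <- as.vector(cur)
      z <- drop(v %*% model$params[[i]]$W) + model$params[[i]]$b
      if (identical(ly$activation, "softmax")) {
        probs <- softmax(z)
        a <- probs
      } else {
        a <- pmax(z, 0)
      }
      if (keep_cache)
        caches[[i]] <- list(v = v, mask = z > 0, input_dim = dim(cur))
      fc_acts[[length(fc_acts) + 1L]] <- a
      cur <- a
    }
  }
  list(probs = probs, fc_activations = fc_acts, caches = caches)
}

# backward pass: returns per-layer gradient list; y_idx is the 1-based true
# class index; probs from the forward pass.
model_backward <- function(model, caches, probs, y_idx) {
  layers <- model$spec$layers
  grads <- vector("list", length(layers))
  dcur <- probs
  dcur[y_idx] <- dcur[y_idx] - 1        # d loss / d logits of the softmax fc
  at_logits <- TRUE
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$kind == "fc") {
      dz <- if (at_logits) dcur else dcur * caches[[i]]$mask
      at_logits <- FALSE
      grads[[i]] <- list(W = caches[[i]]$v %o% dz, b = dz)
      dcur <- drop(model$params[[i]]$W %*% dz)
      if (!is.null(caches[[i]]$input_dim) && length(caches[[i]]$input_dim) == 3L)
        dim(dcur) <- caches[[i]]$input_dim
    } else if (ly$kind == "maxpool") {
      dcur <- maxpool_backward(dcur, caches[[i]])
    } else {
      dz <- dcur * caches[[i]]$mask
      bw <- conv_backward(dz, caches[[i]], model$params[[i]]$W,
                          need_dx = i > 1L)   # input gradient is never used
      grads[[i]] <- list(W = bw$dW, b = bw$db)
      dcur <- bw$dx
    }
  }
  grads
}

# categorical cross-entropy of one prediction
cross_entropy <- function(probs, y_idx) -log(max(probs[y_idx], 1e-12))

# ---- Adam optimizer ---------------------------------------------------------

adam_init <- function(params) {
  st <- list(t = 0L, m = vector("list", length(params)),
             v = vector("list", length(params)))
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    st$m[[i]] <- list(W = params[[i]]$W * 0, b = params[[i]]$b * 0)
    st$v[[i]] <- list(W = params[[i]]$W * 0, b = params[[i]]$b * 0)
  }
  st
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    if (is.null(params[[i]]) || is.null(grads[[i]])) next
    for (nm in c("W", "b")) {
      g <- grads[[i]][[nm]]
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g^2
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lr * (state$m[[i]][[nm]] / bc1) / (sqrt(state$v[[i]][[nm]] / bc2) + eps)
    }
  }
  list(params = params, state = state)
}
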