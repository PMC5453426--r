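# CNN engine correctness: naive-loop oracles for conv/pool, a numeric
# gradient check of the full backward pass, and the model contracts.

micro_spec <- function() {
  hepatch:::new_architecture(c(12L, 12L, 2L), list(
    hepatch:::conv_layer(3L, 3L, "valid"),
    hepatch:::pool_layer(2L),
    hepatch:::conv_layer(4L, 3L, "same"),
    hepatch:::pool_layer(2L),
    hepatch:::fc_layer(5L),
    hepatch:::fc_layer(4L, activation = "softmax")))
}

test_that("conv_forward agrees with a naive nested-loop convolution", {
  naive_conv <- function(x, W, b, k, padding) {
    if (padding == "same") x <- hepatch:::pad_same(x, k)
    d <- dim(x); m <- ncol(W)
    oh <- d[1] - k + 1L; ow <- d[2] - k + 1L
    out <- array(0, c(oh, ow, m))
    for (i in seq_len(oh)) for (j in seq_len(ow)) {
      patch <- as.vector(x[i:(i + k - 1), j:(j + k - 1), ])
      # weight rows are ordered (ki, kj, ch) with ki fastest = as.vector order
      out[i, j, ] <- drop(patch %*% W) + b
    }
    out
  }
  set.seed(4)
  x <- array(rnorm(10 * 9 * 2), c(10, 9, 2))
  W <- matrix(rnorm(3 * 3 * 2 * 3), 18, 3)
  b <- rnorm(3)
  for (pad in c("valid", "same")) {
    got <- hepatch:::conv_forward(x, W, b, 3L, pad)$z
    expect_equal(got, naive_conv(x, W, b, 3L, pad), tolerance = 1e-12)
  }
})

test_that("maxpool_forward agrees with a naive window maximum", {
  set.seed(5)
  x <- array(rnorm(11 * 9 * 3), c(11, 9, 3))
  p <- 3L
  got <- hepatch:::maxpool_forward(x, p)
  expect_equal(dim(got$z), c(3L, 3L, 3L))
  for (b in 1:3) for (d in 1:3) for (ch in 1:3) {
    win <- x[((b - 1) * p + 1):(b * p), ((d - 1) * p + 1):(d * p), ch]
    expect_equal(got$z[b, d, ch], max(win))
  }
  # the argmax bookkeeping routes gradients to the maximum positions only
  dz <- array(1, dim(got$z))
  dx <- hepatch:::maxpool_backward(dz, got$cache)
  expect_equal(sum(dx != 0), 27L)
  expect_equal(sort(x[which(dx != 0)]),
               sort(as.vector(got$z)))
})

test_that("backpropagation matches numeric gradients everywhere", {
  m <- build_model(micro_spec(), seed = 42, input_scale = 1)
  set.seed(7)
  x <- array(rnorm(12 * 12 * 2), c(12, 12, 2))
  y <- 3L
  fwd <- model_forward(m, x, keep_cache = TRUE)
  gr <- hepatch:::model_backward(m, fwd$caches, fwd$probs, y)
  numeric_grad <- function(li, nm, idx, eps = 1e-5) {
    mp <- m; mp$params[[li]][[nm]][idx] <- mp$params[[li]][[nm]][idx] + eps
    mm <- m; mm$params[[li]][[nm]][idx] <- mm$params[[li]][[nm]][idx] - eps
    (hepatch:::cross_entropy(model_forward(mp, x)$probs, y) -
       hepatch:::cross_entropy(model_forward(mm, x)$probs, y)) / (2 * eps)
  }
  set.seed(1)
  for (li in c(1, 3, 5, 6)) for (nm in c("W", "b")) {
    p <- m$params[[li]][[nm]]
    for (idx in sample(length(p), min(6, length(p)))) {
      expect_equal(gr[[li]][[nm]][idx], numeric_grad(li, nm, idx),
                   tolerance = 1e-5,
                   label = sprintf("layer %d %s[%d]", li, nm, idx))
    }
  }
})

test_that("model contracts: softmax output, determinism, uniform at zero weights", {
  spec <- micro_spec()
  m1 <- build_model(spec, seed = 11)
  m2 <- build_model(spec, seed = 11)
  expect_identical(m1$params, m2$params)            # same seed, same weights
  m3 <- build_model(spec, seed = 12)
  expect_false(identical(m1$params, m3$params))

  x <- array(rnorm(12 * 12 * 2), c(12, 12, 2))
  out <- model_forward(m1, x)
  expect_length(out$probs, 4L)
  expect_equal(sum(out$probs), 1, tolerance = 1e-9)
  expect_true(all(out$probs >= 0))

  # zero final layer -> exactly uniform for any input
  mz <- m1
  mz$params[[6]]$W[] <- 0; mz$params[[6]]$b[] <- 0
  expect_equal(model_forward(mz, x)$probs, rep(0.25, 4), tolerance = 1e-12)

  expect_error(model_forward(m1, array(0, c(8, 8, 2))), "geometry")
})

test_that("model forward shapes agree with propagate_shapes", {
  arch <- tiny_architecture(c(64L, 64L, 3L))
  m <- build_model(arch, seed = 2)
  x <- array(rnorm(64 * 64 * 3), c(64, 64, 3))
  fwd <- model_forward(m, x, keep_cache = TRUE)
  shp <- propagate_shapes(arch)
  # conv caches record output extents
  expect_equal(c(fwd$caches[[1]]$oh, fwd$caches[[1]]$ow),
               c(shp$height[1], shp$width[1]))
  expect_equal(c(fwd$caches[[3]]$oh, fwd$caches[[3]]$ow),
               c(shp$height[3], shp$width[3]))
  # fc activation sizes
  expect_length(fwd$fc_activations[[1]], shp$units[5])
  expect_length(fwd$fc_activations[[2]], shp$units[6])
})
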