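# Shared fixtures.  Everything is generated in code; no binary files.

# deterministic random RGB image
random_rgb <- function(h, w, seed = 1L) {
  set.seed(seed)
  img <- array(sample.int(256, h * w * 3, replace = TRUE) - 1L, c(h, w, 3))
  img
}

# RGB image whose OD cloud is a non-negative mixture of two known unit
# stain vectors plus small noise; returns image and the true vectors
two_stain_image <- function(h = 64L, w = 64L, seed = 1L, noise = 0.01) {
  set.seed(seed)
  s1 <- c(0.65, 0.70, 0.29); s1 <- s1 / sqrt(sum(s1^2))   # hematoxylin-like
  s2 <- c(0.07, 0.99, 0.11); s2 <- s2 / sqrt(sum(s2^2))   # eosin-like
  n <- h * w
  c1 <- stats::runif(n, 0.05, 1.2)
  c2 <- stats::runif(n, 0.05, 1.2)
  od <- outer(c1, s1) + outer(c2, s2) + matrix(abs(stats::rnorm(3 * n, sd = noise)), n, 3)
  rgb <- round(256 * 10^(-od) - 1)
  img <- array(as.integer(pmin(pmax(rgb, 0), 255)), c(h, w, 3))
  list(image = img, s1 = s1, s2 = s2)
}

# principal angle (degrees) between two 2D subspaces given as 3x2 bases
subspace_angle_deg <- function(A, B) {
  qa <- qr.Q(qr(A)); qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  s <- pmin(pmax(s, -1), 1)
  max(acos(s)) * 180 / pi
}

# ---- shared end-to-end smoke run (acceptance criteria 6 and 7) -------------
# Memoised: the CNN smoke pipeline is trained once and reused across tests.
.smoke_env <- new.env(parent = emptyenv())

smoke_dataset <- function() {
  if (is.null(.smoke_env$ds)) {
    .smoke_env$ds <- generate_labeled_dataset(
      n_train = 8L, n_test_initial = 2L, dims = c(384L, 512L),
      seed = 2024L, suite = easy_class_suite())
  }
  .smoke_env$ds
}

smoke_config <- function() {
  pipeline_config(patch_size = 256L, overlap_fraction = 0, augment = FALSE,
                  epochs = 10L, seed = 2024L, fusion_rule = "majority",
                  batch_size = 8L, learning_rate = 2e-3,
                  normalize_stain = TRUE)
}

smoke_run <- function() {
  if (is.null(.smoke_env$run)) {
    ds <- smoke_dataset()
    .smoke_env$run <- run_pipeline(smoke_config(), ds$manifest,
                                   images = ds$images, verbose = FALSE)
  }
  .smoke_env$run
}
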