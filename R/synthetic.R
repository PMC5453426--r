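# Seeded synthetic H&E-like image generator.  Classes differ along the axes
# a pathologist uses at this magnification: nucleus density, nucleus size
# variability, and spatial organization (regular / clustered / disordered),
# rendered as purple anti-aliased ellipses on a textured pink background.
# Purely a stand-in for stained tissue: it emulates the color statistics and
# the density/organization phenotypes, not real histology morphology.

#' Describe one synthetic tissue class
#'
#' @param label Class label (one of [hepatch_classes()]).
#' @param density Nuclei per 10^4 px^2.
#' @param radius_range Min/max nucleus radius in px (the reference imagery
#'   shows nucleus radii of 3--11 px at 0.42 um/px).
#' @param radius_cv Coefficient of variation of the per-nucleus axis radii
#'   (size pleomorphism).
#' @param organization `"regular"` (jittered lattice), `"clustered"`
#'   (parent/offspring process) or `"disordered"` (uniform Poisson).
#' @param nucleus_color,background_color Mean RGB (0--255) of the purple
#'   nucleus family and pink background family.
#' @param color_jitter Per-nucleus RGB jitter SD.
#' @param background_texture Background low-frequency texture amplitude.
#' @return A list of class `synthetic_class_spec`.
#' @export
synthetic_class_spec <- function(label,
                                 density,
                                 radius_range = c(3, 11),
                                 radius_cv = 0.15,
                                 organization = c("regular", "clustered",
                                                  "disordered"),
                                 nucleus_color = c(96, 64, 150),
                                 background_color = c(236, 200, 216),
                                 color_jitter = 12,
                                 background_texture = 10) {
  check_labels(label, "synthetic class spec")
  if (density <= 0) stop("density must be > 0", call. = FALSE)
  if (radius_range[1] < 1) stop("minimum radius must be >= 1 px", call. = FALSE)
  structure(list(label = label, density = density,
                 radius_range = radius_range, radius_cv = radius_cv,
                 organization = match.arg(organization),
                 nucleus_color = nucleus_color,
                 background_color = background_color,
                 color_jitter = color_jitter,
                 background_texture = background_texture),
            class = "synthetic_class_spec")
}

#' Default 4-class suite
#'
#' Mean nucleus density and size variability are ordered
#' invasive > insitu > benign >= normal, and organization degrades from
#' regular (normal) through clustered to disordered (invasive).
#'
#' @return Named list of four `synthetic_class_spec`s.
#' @export
default_class_suite <- function() {
  list(
    normal = synthetic_class_spec("normal", density = 5,
                                  radius_range = c(3, 6), radius_cv = 0.08,
                                  organization = "regular"),
    benign = synthetic_class_spec("benign", density = 7,
                                  radius_range = c(3, 7), radius_cv = 0.12,
                                  organization = "clustered"),
    insitu = synthetic_class_spec("insitu", density = 10,
                                  radius_range = c(4, 9), radius_cv = 0.20,
                                  organization = "clustered"),
    invasive = synthetic_class_spec("invasive", density = 15,
                                    radius_range = c(3, 11), radius_cv = 0.30,
                                    organization = "disordered"))
}

#' Easy-separation 4-class suite for desk-scale smoke tests
#'
#' Same phenotype axes as [default_class_suite()] with wider density and size
#' gaps so a compact network trained for a few epochs on a handful of images
#' can separate the classes; used by the end-to-end smoke test.
#'
#' @return Named list of four `synthetic_class_spec`s.
#' @export
easy_class_suite <- function() {
  list(
    normal = synthetic_class_spec("normal", density = 2,
                                  radius_range = c(3, 5), radius_cv = 0.05,
                                  organization = "regular"),
    benign = synthetic_class_spec("benign", density = 7,
                                  radius_range = c(3, 6), radius_cv = 0.10,
                                  organization = "clustered"),
    insitu = synthetic_class_spec("insitu", density = 16,
                                  radius_range = c(5, 9), radius_cv = 0.20,
                                  organization = "clustered"),
    invasive = synthetic_class_spec("invasive", density = 34,
                                    radius_range = c(4, 11), radius_cv = 0.30,
                                    organization = "disordered"))
}

#' No-signal control suite (all four classes identical)
#'
#' Drives end-to-end accuracy to chance; used to confirm that no label
#' information leaks through the pipeline.
#'
#' @return Named list of four identical-phenotype `synthetic_class_spec`s.
#' @export
flat_class_suite <- function() {
  base <- function(lab) synthetic_class_spec(lab, density = 8,
                                             radius_range = c(3, 8),
                                             radius_cv = 0.15,
                                             organization = "disordered")
  list(normal = base("normal"), benign = base("benign"),
       insitu = base("insitu"), invasive = base("invasive"))
}

# low-frequency value noise: coarse Gaussian grid bilinearly upsampled
value_noise <- function(h, w, cell = 64) {
  gh <- max(2L, ceiling(h / cell) + 1L)
  gw <- max(2L, ceiling(w / cell) + 1L)
  g <- matrix(stats::rnorm(gh * gw), gh, gw)
  ry <- seq(1, gh, length.out = h)
  rx <- seq(1, gw, length.out = w)
  y0 <- pmin(floor(ry), gh - 1L); fy <- ry - y0
  x0 <- pmin(floor(rx), gw - 1L); fx <- rx - x0
  a <- g[cbind(rep(y0, w), rep(x0, each = h))]
  b <- g[cbind(rep(y0 + 1L, w), rep(x0, each = h))]
  cc <- g[cbind(rep(y0, w), rep(x0 + 1L, each = h))]
  d <- g[cbind(rep(y0 + 1L, w), rep(x0 + 1L, each = h))]
  fyv <- rep(fy, w); fxv <- rep(fx, each = h)
  v <- a * (1 - fyv) * (1 - fxv) + b * fyv * (1 - fxv) +
    cc * (1 - fyv) * fxv + d * fyv * fxv
  matrix(v, h, w)
}

# nucleus center placement per organization model; returns matrix (n, 2)
place_nuclei <- function(organization, h, w, density) {
  lambda <- density * h * w / 1e4
  if (organization == "regular") {
    s <- sqrt(1e4 / density)
    ys <- seq(s / 2, h, by = s); xs <- seq(s / 2, w, by = s)
    ctr <- cbind(rep(ys, times = length(xs)), rep(xs, each = length(ys)))
    ctr + matrix(stats::rnorm(length(ctr), sd = 0.18 * s), ncol = 2)
  } else if (organization == "clustered") {
    mu <- 6                                  # mean offspring per cluster
    n_par <- stats::rpois(1, lambda / mu)
    if (n_par == 0L) n_par <- 1L
    par <- cbind(stats::runif(n_par, 1, h), stats::runif(n_par, 1, w))
    kids <- stats::rpois(n_par, mu)
    ctr <- par[rep(seq_len(n_par), kids), , drop = FALSE]
    ctr + matrix(stats::rnorm(length(ctr), sd = 18), ncol = 2)
  } else {
    n <- stats::rpois(1, lambda)
    cbind(stats::runif(n, 1, h), stats::runif(n, 1, w))
  }
}

#' Render one synthetic labeled tissue image
#'
#' Fully determined by `(spec, dims, seed)`.  Nuclei are placed by the
#' organization model and drawn as anti-aliased filled ellipses with
#' per-nucleus color jitter over a textured pink background.
#'
#' @param spec A `synthetic_class_spec`.
#' @param dims `c(height, width)` in px.
#' @param seed Integer seed.
#' @return Integer RGB array with attributes `label`, `n_nuclei`.
#' @export
render_tissue_image <- function(spec, dims = c(768L, 1020L), seed = 1L) {
  h <- dims[1]; w <- dims[2]
  set.seed(as.integer(seed))
  img <- array(0, c(h, w, 3))
  tex <- value_noise(h, w)
  for (ch in 1:3)
    img[, , ch] <- spec$background_color[ch] + spec$background_texture * tex +
      stats::rnorm(h * w, sd = 2)
  ctr <- place_nuclei(spec$organization, h, w, spec$density)
  ctr <- ctr[ctr[, 1] >= 1 & ctr[, 1] <= h & ctr[, 2] >= 1 & ctr[, 2] <= w, ,
             drop = FALSE]
  n <- nrow(ctr)
  r_base <- stats::runif(n, spec$radius_range[1], spec$radius_range[2])
  for (i in seq_len(n)) {
    a <- max(1, r_base[i] * (1 + spec$radius_cv * stats::rnorm(1)))
    b <- max(1, r_base[i] * (1 + spec$radius_cv * stats::rnorm(1)))
    th <- stats::runif(1, 0, pi)
    col_n <- pmin(pmax(spec$nucleus_color + stats::rnorm(3, sd = spec$color_jitter), 0), 255)
    rmax <- ceiling(max(a, b)) + 1L
    y0 <- max(1L, floor(ctr[i, 1] - rmax)); y1 <- min(h, ceiling(ctr[i, 1] + rmax))
    x0 <- max(1L, floor(ctr[i, 2] - rmax)); x1 <- min(w, ceiling(ctr[i, 2] + rmax))
    yy <- y0:y1; xx <- x0:x1
    dy <- outer(yy - ctr[i, 1], rep(1, length(xx)))
    dx <- outer(rep(1, length(yy)), xx - ctr[i, 2])
    u <- (dy * cos(th) + dx * sin(th)) / a
    v <- (-dy * sin(th) + dx * cos(th)) / b
    dd <- sqrt(u^2 + v^2)
    alpha <- pmin(pmax((1 - dd) * min(a, b) + 0.5, 0), 1)  # anti-aliased edge
    if (all(alpha == 0)) next
    for (ch in 1:3)
      img[yy, xx, ch] <- alpha * col_n[ch] + (1 - alpha) * img[yy, xx, ch]
  }
  img <- round(pmin(pmax(img, 0), 255))
  storage.mode(img) <- "integer"
  attr(img, "label") <- spec$label
  attr(img, "n_nuclei") <- n
  img
}

#' Generate a balanced, seeded synthetic dataset
#'
#' @param images_per_class Named vector or single count of images per class
#'   and subset: use `n_train`, `n_test_initial`, `n_test_extended`.
#' @param dims Image dims `c(height, width)` (default the reduced geometry
#'   768 x 1020).
#' @param seed Master seed; each image's seed derives from it.
#' @param suite Class-spec suite (default [default_class_suite()]).
#' @param n_train,n_test_initial,n_test_extended Images per class per subset.
#' @param dir Optional directory: images are written as uncompressed TIFF and
#'   a manifest CSV alongside.
#' @return List: `images` (named list of arrays), `manifest`
#'   (`hepatch_manifest` data frame; `image_path` is populated when `dir` is
#'   given).
#' @export
generate_labeled_dataset <- function(n_train = 8L, n_test_initial = 2L,
                                     n_test_extended = 0L,
                                     dims = c(768L, 1020L), seed = 1L,
                                     suite = default_class_suite(),
                                     dir = NULL) {
  stopifnot(setequal(names(suite), hepatch_classes()))
  plan <- data.frame(subset = rep(c("train", "test_initial", "test_extended"),
                                  times = c(n_train, n_test_initial, n_test_extended)))
  images <- list()
  rows <- list()
  counter <- 0L
  for (cl in hepatch_classes()) {
    for (k in seq_len(nrow(plan))) {
      counter <- counter + 1L
      id <- sprintf("%s_%s_%02d", cl, plan$subset[k], k)
      img_seed <- (as.numeric(seed) * 131071 + counter * 2654435761) %% 2147483647
      img <- render_tissue_image(suite[[cl]], dims, seed = as.integer(img_seed))
      images[[id]] <- img
      path <- if (is.null(dir)) paste0(id, ".tif") else file.path(dir, paste0(id, ".tif"))
      rows[[counter]] <- data.frame(image_id = id, image_path = path,
                                    label = cl, subset = plan$subset[k],
                                    stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  class(manifest) <- c("hepatch_manifest", "data.frame")
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(images))
      write_image(images[[id]], file.path(dir, paste0(id, ".tif")))
    write_manifest(manifest, file.path(dir, "manifest.csv"))
  }
  list(images = images, manifest = manifest)
}
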