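# H&E stain normalization in optical-density space.
#
# Pipeline: RGB -> optical density (decadic log), SVD of the foreground OD
# cloud to find the 2D stain plane, robust extreme angles within the plane to
# estimate the two stain vectors, per-pixel stain concentrations by least
# squares, then a histogram stretch so that the stretch_coverage quantile
# (default the 90th percentile) of each concentration channel maps to the top
# of the output dynamic range; values above are clipped.

#' Stain-normalization parameters
#'
#' @param reference_intensity White point of the 8-bit input (default 255).
#' @param background_od_threshold Pixels with OD vector norm below this are
#'   treated as background (default 0.15 OD).
#' @param extreme_angle_percentile Robust trim for the extreme stain angles
#'   within the SVD plane, as a fraction (default 0.01, i.e. the 1st and 99th
#'   angle percentiles).
#' @param stretch_coverage Fraction of the data covered by the output dynamic
#'   range (default 0.90).
#' @param min_foreground Minimum number of foreground pixels required to fit a
#'   stain basis (default 100).
#' @param stretch_mode `"per_channel"`: stretch each stain-concentration
#'   channel independently (default); `"magnitude"`: one common scale from the
#'   OD-magnitude distribution.
#' @param log_eps Guard against log(0): OD = -log10((v + log_eps) /
#'   (reference_intensity + log_eps)).  Default 1.
#' @return A list of class `stain_norm_params`.
#' @export
stain_norm_params <- function(reference_intensity = 255,
                              background_od_threshold = 0.15,
                              extreme_angle_percentile = 0.01,
                              stretch_coverage = 0.90,
                              min_foreground = 100L,
                              stretch_mode = c("per_channel", "magnitude"),
                              log_eps = 1) {
  if (reference_intensity <= 0) stop("reference_intensity must be > 0", call. = FALSE)
  if (background_od_threshold <= 0) stop("background_od_threshold must be > 0", call. = FALSE)
  if (stretch_coverage <= 0 || stretch_coverage >= 1)
    stop("stretch_coverage must be in (0, 1)", call. = FALSE)
  structure(list(reference_intensity = reference_intensity,
                 background_od_threshold = background_od_threshold,
                 extreme_angle_percentile = extreme_angle_percentile,
                 stretch_coverage = stretch_coverage,
                 min_foreground = as.integer(min_foreground),
                 stretch_mode = match.arg(stretch_mode),
                 log_eps = log_eps),
            class = "stain_norm_params")
}

#' Convert an 8-bit RGB image to optical density
#'
#' Decadic log transform: `OD = -log10((v + eps) / (I0 + eps))` per channel,
#' where `I0` is the white reference and `eps` guards against `log(0)`.
#' The guard is applied to numerator and denominator so the map is strictly
#' monotone decreasing and OD is exactly 0 at the white point, never negative.
#'
#' @param img Integer array `(h, w, 3)`, values in `[0, reference_intensity]`.
#' @param reference_intensity White point (default 255).
#' @param eps Log guard (default 1).
#' @return A list of class `od_image`: `values` (double array, same shape,
#'   all finite and >= 0) and `reference_intensity`.
#' @export
rgb_to_od <- function(img, reference_intensity = 255, eps = 1) {
  check_rgb_image(img)
  if (reference_intensity <= 0) stop("reference_intensity must be > 0", call. = FALSE)
  od <- -log10((img + eps) / (reference_intensity + eps))
  structure(list(values = od, reference_intensity = reference_intensity,
                 eps = eps),
            class = "od_image")
}

#' Invert the optical-density transform back to 8-bit RGB
#'
#' @param od An `od_image` from [rgb_to_od()], or a plain OD array (then
#'   `reference_intensity` and `eps` apply).
#' @param reference_intensity,eps Used when `od` is a plain array.
#' @return Integer RGB array, values clamped to 0--255.
#' @export
od_to_rgb <- function(od, reference_intensity = 255, eps = 1) {
  if (inherits(od, "od_image")) {
    reference_intensity <- od$reference_intensity
    eps <- od$eps %||% 1
    od <- od$values
  }
  v <- (reference_intensity + eps) * 10^(-od) - eps
  v <- round(pmin(pmax(v, 0), 255))
  storage.mode(v) <- "integer"
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# flatten an OD array to an n x 3 matrix of pixel tuples
od_matrix <- function(od_values) {
  d <- dim(od_values)
  matrix(od_values, nrow = d[1] * d[2], ncol = 3L)
}

#' Fit the two-stain basis of an H&E image
#'
#' Applies SVD (via the 3x3 scatter eigendecomposition) to the foreground OD
#' tuples to find the 2D plane with highest variance, then takes the stain
#' vectors at the percentile-trimmed extreme angles within that plane.
#'
#' @param od An `od_image` (or plain OD array).
#' @param params [stain_norm_params()].
#' @return A list of class `stain_basis`: `plane` (3x2 orthonormal columns),
#'   `stain_vectors` (3x2 unit columns, non-negative components, ordered by
#'   angle), `angles` (the two extreme angles), `n_foreground`.
#' @export
fit_stain_basis <- function(od, params = stain_norm_params()) {
  values <- if (inherits(od, "od_image")) od$values else od
  M <- od_matrix(values)
  norms <- sqrt(rowSums(M^2))
  fg <- M[norms > params$background_od_threshold, , drop = FALSE]
  if (nrow(fg) < params$min_foreground)
    stop(sprintf("insufficient foreground: %d pixels above OD %.3g (need >= %d)",
                 nrow(fg), params$background_od_threshold, params$min_foreground),
         call. = FALSE)
  sc <- crossprod(fg)                      # 3x3 scatter (uncentered, as in SVD of OD)
  eg <- eigen(sc, symmetric = TRUE)
  if (eg$values[2] < 1e-8 * eg$values[1])
    stop("rank-deficient OD cloud: image appears to contain a single color",
         call. = FALSE)
  plane <- eg$vectors[, 1:2, drop = FALSE]
  # orient plane columns so projections are predominantly positive
  proj <- fg %*% plane
  for (j in 1:2) if (mean(proj[, j]) < 0) { plane[, j] <- -plane[, j]; proj[, j] <- -proj[, j] }
  phi <- atan2(proj[, 2], proj[, 1])
  p <- params$extreme_angle_percentile
  a <- stats::quantile(phi, c(p, 1 - p), names = FALSE, type = 7)
  sv <- cbind(plane %*% c(cos(a[1]), sin(a[1])),
              plane %*% c(cos(a[2]), sin(a[2])))
  # OD components are non-negative for physical stains; clamp numeric dust
  sv[sv < 0] <- 0
  sv <- sweep(sv, 2, sqrt(colSums(sv^2)), "/")
  structure(list(plane = plane, stain_vectors = sv, angles = a,
                 n_foreground = nrow(fg)),
            class = "stain_basis")
}

# per-pixel least-squares stain concentrations; M n x 3, S 3 x 2 -> n x 2
stain_concentrations <- function(M, S) {
  C <- M %*% S %*% solve(crossprod(S))
  C[C < 0] <- 0
  C
}

#' Normalize the stain appearance of an H&E image
#'
#' Transforms the image into the fitted stain-concentration space and
#' stretches the histogram so the `stretch_coverage` quantile of the
#' (foreground) data maps to the top of the output dynamic range; larger
#' values are clipped.  The output is reconstructed as 8-bit RGB with each
#' stain at a fixed target optical density, giving images from different
#' acquisitions a common appearance.
#'
#' @param img 8-bit RGB array.
#' @param params [stain_norm_params()].
#' @param target_od Optical density assigned to a concentration at the stretch
#'   quantile (default 1.0).
#' @param details Return diagnostics alongside the image.
#' @return The normalized RGB image; if `details = TRUE`, a list with
#'   `image`, `basis`, `stretch_scale` (the per-channel quantiles that map to
#'   full range) and `concentrations_raw` (foreground quantile check data).
#' @export
normalize_image <- function(img, params = stain_norm_params(),
                            target_od = 1.0, details = FALSE) {
  od <- rgb_to_od(img, params$reference_intensity, params$log_eps)
  basis <- fit_stain_basis(od, params)
  M <- od_matrix(od$values)
  C <- stain_concentrations(M, basis$stain_vectors)
  fg <- sqrt(rowSums(M^2)) > params$background_od_threshold
  if (params$stretch_mode == "per_channel") {
    q <- vapply(1:2, function(j)
      stats::quantile(C[fg, j], params$stretch_coverage, names = FALSE), 0)
  } else {
    q <- rep(stats::quantile(sqrt(rowSums(C[fg, , drop = FALSE]^2)),
                             params$stretch_coverage, names = FALSE), 2)
  }
  q[q < 1e-8] <- 1e-8
  Cs <- sweep(C, 2, q, "/")
  Cs[Cs > 1] <- 1                           # clip the upper tail
  od_out <- Cs %*% t(basis$stain_vectors) * target_od
  out <- od_to_rgb(array(od_out, dim(img)), params$reference_intensity,
                   params$log_eps)
  if (!details) return(out)
  list(image = out, basis = basis, stretch_scale = q,
       concentrations_raw = C, concentrations_stretched = Cs,
       foreground = fg)
}
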