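# Declarative CNN architecture: layer specs, output-shape propagation, and
# effective receptive-field tracing (px and um).
#
# Conventions: conv layers stride 1 with "valid" or "same" padding; max-pool
# layers use stride equal to the pooling size; conv/fc activation is ReLU
# except the final fc, which is softmax.

conv_layer <- function(maps, kernel = 3L, padding = c("valid", "same"),
                       activation = "relu") {
  list(kind = "conv", maps_or_units = as.integer(maps),
       kernel = as.integer(kernel), stride = 1L,
       padding = match.arg(padding), activation = activation)
}

pool_layer <- function(kernel) {
  # pool stride equals the pooling size by design
  list(kind = "maxpool", maps_or_units = NA_integer_, kernel = as.integer(kernel),
       stride = as.integer(kernel), padding = "valid", activation = "none")
}

fc_layer <- function(units, activation = "relu") {
  list(kind = "fc", maps_or_units = as.integer(units), kernel = NA_integer_,
       stride = NA_integer_, padding = NA_character_, activation = activation)
}

new_architecture <- function(input, layers) {
  spec <- structure(list(input = as.integer(input), layers = layers),
                    class = "cnn_architecture")
  validate_architecture(spec)
}

#' The default 13-layer multi-scale architecture
#'
#' Five conv/max-pool pairs followed by three fully-connected layers, designed
#' so that successive depths cover nuclei-scale, nuclei-organization and
#' tissue-structure scales on 512x512 inputs at 0.42 um/px: conv16/pool3,
#' conv32/pool2, conv64/pool2, conv64/pool3, conv32/pool3, fc256, fc128, fc4.
#' All conv kernels are 3x3, stride 1; pool stride equals pool size; ReLU
#' activations except the softmax output of 4 units.  The padding schedule is
#' mixed (valid at conv layers 1, 3 and 9; same at conv layers 5 and 7), the
#' only schedule consistent with the published per-layer output sizes.
#'
#' @return A `cnn_architecture` with input `(512, 512, 3)` and 13 layers.
#' @export
default_architecture <- function() {
  new_architecture(c(512L, 512L, 3L), list(
    conv_layer(16L, 3L, "valid"),
    pool_layer(3L),
    conv_layer(32L, 3L, "valid"),
    pool_layer(2L),
    conv_layer(64L, 3L, "same"),
    pool_layer(2L),
    conv_layer(64L, 3L, "same"),
    pool_layer(3L),
    conv_layer(32L, 3L, "valid"),
    pool_layer(3L),
    fc_layer(256L),
    fc_layer(128L),
    fc_layer(4L, activation = "softmax")))
}

#' A compact architecture for reduced-geometry (256-px patch) runs
#'
#' Same multi-scale design idea at desk scale: three conv/pool pairs and
#' three fc layers on 256x256 inputs.  Used by the synthetic smoke pipeline
#' so CPU training finishes in minutes.
#'
#' @param input Input dims, default `c(256, 256, 3)`.
#' @return A `cnn_architecture`.
#' @export
compact_architecture <- function(input = c(256L, 256L, 3L)) {
  new_architecture(input, list(
    conv_layer(8L, 3L, "valid"),
    pool_layer(4L),
    conv_layer(16L, 3L, "valid"),
    pool_layer(4L),
    conv_layer(16L, 3L, "valid"),
    pool_layer(4L),
    fc_layer(32L),
    fc_layer(16L),
    fc_layer(4L, activation = "softmax")))
}

#' A minimal architecture for very small (e.g. 64-px) test patches
#'
#' @param input Input dims, default `c(64, 64, 3)`.
#' @param classes Output units, default 4.
#' @return A `cnn_architecture`.
#' @export
tiny_architecture <- function(input = c(64L, 64L, 3L), classes = 4L) {
  new_architecture(input, list(
    conv_layer(4L, 3L, "valid"),
    pool_layer(4L),
    conv_layer(8L, 3L, "valid"),
    pool_layer(4L),
    fc_layer(16L),
    fc_layer(8L),
    fc_layer(classes, activation = "softmax")))
}

#' Validate an architecture spec
#'
#' Checks the structural invariants: pool stride equals pool size; hidden
#' conv/fc activations are ReLU and the final layer is a softmax fc; fc
#' layers only appear after all spatial layers.
#'
#' @param spec A `cnn_architecture`.
#' @return The spec, invisibly usable, or an error.
#' @export
validate_architecture <- function(spec) {
  stopifnot(inherits(spec, "cnn_architecture"))
  if (length(spec$input) != 3L) stop("input must be (h, w, channels)", call. = FALSE)
  kinds <- vapply(spec$layers, `[[`, "", "kind")
  if (kinds[length(kinds)] != "fc")
    stop("final layer must be fully-connected", call. = FALSE)
  last_fc <- spec$layers[[length(spec$layers)]]
  if (!identical(last_fc$activation, "softmax"))
    stop("final fc layer must use softmax activation", call. = FALSE)
  seen_fc <- FALSE
  for (ly in spec$layers) {
    if (ly$kind == "fc") seen_fc <- TRUE
    else if (seen_fc) stop("spatial layer after fc layer", call. = FALSE)
    if (ly$kind == "maxpool" && ly$stride != ly$kernel)
      stop("max-pool stride must equal the pooling size", call. = FALSE)
    if (ly$kind %in% c("conv", "fc") && !identical(ly, last_fc) &&
        !identical(ly$activation, "relu"))
      stop("hidden conv/fc layers must use ReLU activation", call. = FALSE)
  }
  spec
}

#' Propagate per-layer output shapes
#'
#' Shapes follow each layer's padding and stride: valid conv shrinks by
#' `kernel - 1`, same conv preserves size, pooling takes `floor(size / pool)`
#' (stride equal to pool size).  When `expected` shapes are supplied,
#' mismatches are reported per layer in the `note` column rather than raised —
#' this is how the known print inconsistency at the tenth layer of the
#' reference table (12x12 printed where the stride rule gives 4x4) is
#' surfaced.
#'
#' @param spec A validated `cnn_architecture`.
#' @param expected Optional list of `c(h, w)` per layer to compare against.
#' @return data.frame: `layer`, `kind`, `maps`, `height`, `width`, `units`,
#'   `note`.
#' @export
propagate_shapes <- function(spec, expected = NULL) {
  validate_architecture(spec)
  h <- spec$input[1]; w <- spec$input[2]; maps <- spec$input[3]
  units <- NA_integer_
  rows <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    note <- ""
    if (ly$kind == "conv") {
      if (ly$padding == "valid") { h <- h - ly$kernel + 1L; w <- w - ly$kernel + 1L }
      maps <- ly$maps_or_units
    } else if (ly$kind == "maxpool") {
      h <- h %/% ly$kernel; w <- w %/% ly$kernel
    } else {
      units <- ly$maps_or_units
      h <- NA_integer_; w <- NA_integer_; maps <- NA_integer_
    }
    if (ly$kind != "fc" && (is.na(h) || h < 1L || w < 1L))
      stop(sprintf("layer %d: non-positive output dimension; spec infeasible", i),
           call. = FALSE)
    if (!is.null(expected) && !is.null(expected[[i]]) && ly$kind != "fc") {
      exp_hw <- expected[[i]]
      if (exp_hw[1] != h || exp_hw[2] != w)
        note <- sprintf("computed %dx%d differs from expected %dx%d",
                        h, w, exp_hw[1], exp_hw[2])
    }
    rows[[i]] <- data.frame(layer = i, kind = ly$kind, maps = maps,
                            height = h, width = w, units = units, note = note,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Trace effective receptive fields through an architecture
#'
#' Standard recursive propagation: starting from `rf = 1`, `stride = 1`,
#' each spatial layer updates `rf <- rf + (kernel - 1) * stride_cum` and
#' `stride_cum <- stride_cum * layer_stride` (padding-independent).  Fully
#' connected layers see the full input extent.  The micrometre column is the
#' pixel column times `pixel_size_um`, stored exact (unrounded).
#'
#' @param spec A validated `cnn_architecture`.
#' @param pixel_size_um Physical pixel size (default 0.42 um/px).
#' @return data.frame: `layer`, `kind`, `receptive_field_px`,
#'   `cumulative_stride`, `receptive_field_um`.
#' @export
compute_receptive_field_trace <- function(spec, pixel_size_um = 0.42) {
  validate_architecture(spec)
  rf <- 1L; stride_cum <- 1L
  rows <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$kind == "fc") {
      rf_i <- max(spec$input[1], spec$input[2])   # full input extent
    } else {
      rf <- rf + (ly$kernel - 1L) * stride_cum
      stride_cum <- stride_cum * ly$stride
      rf_i <- rf
    }
    rows[[i]] <- data.frame(layer = i, kind = ly$kind,
                            receptive_field_px = rf_i,
                            cumulative_stride = if (ly$kind == "fc") NA_integer_ else stride_cum,
                            receptive_field_um = rf_i * pixel_size_um)
  }
  do.call(rbind, rows)
}

#' Combined shape and receptive-field report
#'
#' @param spec A `cnn_architecture`.
#' @param pixel_size_um Pixel size in um (default 0.42).
#' @return data.frame merging [propagate_shapes()] and
#'   [compute_receptive_field_trace()], plus a 1-decimal rounded um column for
#'   display.
#' @export
architecture_report <- function(spec, pixel_size_um = 0.42) {
  shp <- propagate_shapes(spec)
  rft <- compute_receptive_field_trace(spec, pixel_size_um)
  out <- cbind(shp[, c("layer", "kind", "maps", "height", "width", "units")],
               rft[, c("receptive_field_px", "cumulative_stride",
                       "receptive_field_um")])
  out$receptive_field_um_rounded <- round_half_up(out$receptive_field_um, 1)
  out
}

#' @export
print.cnn_architecture <- function(x, ...) {
  cat(sprintf("<cnn_architecture> input %s, %d layers\n",
              paste(x$input, collapse = "x"), length(x$layers)))
  print(architecture_report(x), row.names = FALSE)
  invisible(x)
}
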