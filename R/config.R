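# Pipeline configuration.  Defaults are the published protocol values:
# 512-px patches at 50% overlap, 0.42 um/px, 75% training fraction, 50 epochs.

#' Build a pipeline configuration
#'
#' All stages of [run_pipeline()] are driven by this object.  Defaults follow
#' the reference protocol; reduced-geometry runs override `patch_size`,
#' `epochs` and the architecture.
#'
#' @param patch_size Patch edge in pixels (default 512).
#' @param overlap_fraction Fractional overlap of the training patch grid
#'   (default 0.5, i.e. stride = patch_size/2).  Must be in `[0, 1)`.
#' @param pixel_size_um Physical pixel size in micrometres (default 0.42).
#' @param augment Enable 8-fold dihedral augmentation of training patches.
#' @param normalize_stain Run stain normalization before patching.
#' @param fusion_rule One of `"majority"`, `"max"`, `"sum"`.
#' @param binary_mode `"label"` (group the fused 4-class label) or `"prob"`
#'   (group probabilities per patch, then fuse).
#' @param train_fraction Image-level training fraction of the train subset
#'   (default 0.75); the remainder validates.
#' @param epochs Training epochs (default 50).
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Master seed; all stage seeds derive from it.
#' @param resample_validation Re-draw the train/validation split each epoch
#'   (as in the reference protocol).  Default `FALSE`: a fixed split avoids
#'   cross-epoch leakage; enabling it logs a warning.
#' @param stratify_split Stratify the train/validation split by class
#'   (default `TRUE`; guarantees class coverage in small runs).
#' @param classifier `"cnn"` or `"cnn_svm"` (SVM head on fc features).
#' @param svm_cost_grid,svm_gamma_grid Logarithmic grids for the RBF SVM
#'   exhaustive search.
#' @param svm_folds Cross-validation folds for the SVM grid search (default 3).
#' @param stretch_coverage Stain-normalization histogram-stretch coverage
#'   (default 0.90: the 90th percentile maps to full range).
#' @return A validated list of class `hepatch_config`.
#' @export
pipeline_config <- function(patch_size = 512L,
                            overlap_fraction = 0.5,
                            pixel_size_um = 0.42,
                            augment = TRUE,
                            normalize_stain = TRUE,
                            fusion_rule = c("majority", "max", "sum"),
                            binary_mode = c("label", "prob"),
                            train_fraction = 0.75,
                            epochs = 50L,
                            batch_size = 16L,
                            learning_rate = 1e-3,
                            seed = 1L,
                            resample_validation = FALSE,
                            stratify_split = TRUE,
                            classifier = c("cnn", "cnn_svm"),
                            svm_cost_grid = 10^(0:2),
                            svm_gamma_grid = 10^(-2:0),
                            svm_folds = 3L,
                            stretch_coverage = 0.90) {
  cfg <- list(
    patch_size = as.integer(patch_size),
    overlap_fraction = as.numeric(overlap_fraction),
    pixel_size_um = as.numeric(pixel_size_um),
    augment = isTRUE(augment),
    normalize_stain = isTRUE(normalize_stain),
    fusion_rule = match.arg(fusion_rule),
    binary_mode = match.arg(binary_mode),
    train_fraction = as.numeric(train_fraction),
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    learning_rate = as.numeric(learning_rate),
    seed = as.integer(seed),
    resample_validation = isTRUE(resample_validation),
    stratify_split = isTRUE(stratify_split),
    classifier = match.arg(classifier),
    svm_cost_grid = as.numeric(svm_cost_grid),
    svm_gamma_grid = as.numeric(svm_gamma_grid),
    svm_folds = as.integer(svm_folds),
    stretch_coverage = as.numeric(stretch_coverage))
  class(cfg) <- "hepatch_config"
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg A `hepatch_config` list.
#' @return The config, invisibly usable, after range checks.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "hepatch_config"))
  if (cfg$patch_size < 8L) stop("patch_size must be >= 8 px", call. = FALSE)
  if (cfg$overlap_fraction < 0 || cfg$overlap_fraction >= 1)
    stop("overlap_fraction must be in [0, 1): overlap 1.0 gives a degenerate ",
         "zero stride", call. = FALSE)
  if (cfg$pixel_size_um <= 0) stop("pixel_size_um must be > 0", call. = FALSE)
  if (cfg$train_fraction <= 0 || cfg$train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  if (cfg$epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (cfg$batch_size < 1L) stop("batch_size must be >= 1", call. = FALSE)
  if (cfg$learning_rate <= 0) stop("learning_rate must be > 0", call. = FALSE)
  if (cfg$stretch_coverage <= 0 || cfg$stretch_coverage >= 1)
    stop("stretch_coverage must be in (0, 1)", call. = FALSE)
  if (length(cfg$svm_cost_grid) == 0L || length(cfg$svm_gamma_grid) == 0L)
    stop("SVM parameter grids must be non-empty", call. = FALSE)
  cfg
}

#' Serialize a configuration to JSON
#'
#' Round-trips losslessly through [read_config()].
#'
#' @param cfg A `hepatch_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a configuration from JSON
#'
#' @param path JSON path written by [write_config()].
#' @return A validated `hepatch_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}
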