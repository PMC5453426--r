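# End-to-end orchestration: normalize -> patchify -> train -> predict ->
# fuse -> evaluate, with artifacts (config, patch manifest, training log,
# predictions, evaluation tables) written under a run directory so any run is
# regenerable from its recorded config and seed.

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[hepatch] ", fmt), ...))
}

#' Run the full classification pipeline
#'
#' Executes every stage on the images of a manifest: optional stain
#' normalization, augmented patch-record construction for the training
#' subset, patch-wise CNN training, per-test-image inference-grid prediction,
#' probability fusion to the 4-class and binary image labels, and
#' evaluation reports per subset and pooled.  Identical `(config, seed)`
#' produce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param manifest A `hepatch_manifest` (or data frame with `image_id`,
#'   `image_path`, `label`, `subset`).
#' @param images Optional named list of in-memory image arrays keyed by
#'   `image_id`; when `NULL`, images are read from `manifest$image_path`.
#' @param architecture A `cnn_architecture`; default chosen from
#'   `config$patch_size` ([default_architecture()] at 512,
#'   [compact_architecture()] at 256, [tiny_architecture()] otherwise).
#' @param out_dir Optional run directory for artifacts.
#' @param verbose Per-stage INFO logging (default `TRUE`).
#' @return List of class `hepatch_run`: `predictions` (data frame),
#'   `reports` (named `eval_report` list), `model`, `history`, `svm`
#'   (if the SVM head was used), `config`.
#' @export
run_pipeline <- function(config, manifest, images = NULL, architecture = NULL,
                         out_dir = NULL, verbose = TRUE) {
  validate_config(config)
  manifest <- validate_manifest(as.data.frame(manifest),
                                check_paths = is.null(images))
  for (cl in hepatch_classes()) {
    has_train <- any(manifest$label == cl & manifest$subset == "train")
    has_test <- any(manifest$label == cl & manifest$subset != "train")
    if (!has_train || !has_test)
      stop(sprintf("manifest needs >= 1 train and >= 1 test image for class '%s'",
                   cl), call. = FALSE)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(out_dir, "config.json"))
    write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  }

  run_stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    stage_log(verbose, "stage %-10s done in %.1fs", name,
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  images <- run_stage("load", {
    if (is.null(images)) {
      im <- lapply(manifest$image_path, read_image)
      names(im) <- manifest$image_id
      im
    } else {
      missing <- setdiff(manifest$image_id, names(images))
      if (length(missing) > 0L)
        stop("no in-memory image for id(s): ", paste(missing, collapse = ", "))
      images[manifest$image_id]
    }
  })

  if (config$normalize_stain) {
    images <- run_stage("normalize", {
      params <- stain_norm_params(stretch_coverage = config$stretch_coverage)
      lapply(images, normalize_image, params = params)
    })
  }

  if (is.null(architecture)) {
    architecture <- if (config$patch_size >= 512L) default_architecture()
    else if (config$patch_size >= 256L)
      compact_architecture(c(config$patch_size, config$patch_size, 3L))
    else tiny_architecture(c(config$patch_size, config$patch_size, 3L))
  }
  if (architecture$input[1] != config$patch_size)
    stop("architecture input size does not match config patch_size", call. = FALSE)

  train_man <- manifest[manifest$subset == "train", ]
  test_man <- manifest[manifest$subset != "train", ]
  stride <- max(1L, as.integer(round(config$patch_size *
                                       (1 - config$overlap_fraction))))
  records <- run_stage("patchify", {
    dims <- lapply(train_man$image_id, function(id) dim(images[[id]])[1:2])
    build_patch_records(train_man$image_id, dims, train_man$label,
                        patch_size = config$patch_size, stride = stride,
                        edge_anchor = TRUE, augment = config$augment)
  })
  if (!is.null(out_dir))
    write_patch_manifest(records, file.path(out_dir, "train_patches.csv"))
  stage_log(verbose, "patchify: %d records from %d training images",
            nrow(records), nrow(train_man))

  model <- build_model(architecture, seed = config$seed)
  trained <- run_stage("train", {
    train_patch_classifier(model, records, images,
                           epochs = config$epochs,
                           batch_size = config$batch_size,
                           learning_rate = config$learning_rate,
                           seed = config$seed,
                           train_fraction = config$train_fraction,
                           resample_validation = config$resample_validation,
                           stratify_split = config$stratify_split,
                           verbose = verbose)
  })
  if (!is.null(out_dir))
    utils::write.csv(trained$history, file.path(out_dir, "training_log.csv"),
                     row.names = FALSE)

  svm <- NULL
  if (config$classifier == "cnn_svm") {
    svm <- run_stage("svm", {
      patch_list <- lapply(seq_len(nrow(records)), function(i)
        get_patch_pixels(images, records[i, ], config$patch_size, center = TRUE))
      f <- extract_fc_features(trained$model, patch_list, center = FALSE)
      fit_feature_svm(f, records$label,
                      cost_grid = config$svm_cost_grid,
                      gamma_grid = config$svm_gamma_grid,
                      folds = config$svm_folds, seed = config$seed,
                      class_levels = hepatch_classes())
    })
  }

  predictions <- run_stage("predict", {
    rows <- vector("list", nrow(test_man))
    for (i in seq_len(nrow(test_man))) {
      id <- test_man$image_id[i]
      img <- images[[id]]
      grid <- inference_grid(dim(img)[1], dim(img)[2], config$patch_size)
      patches <- lapply(seq_len(nrow(grid$offsets)), function(j)
        center_channels(extract_patch(img, grid$offsets$row[j],
                                      grid$offsets$col[j], config$patch_size)))
      probs <- if (is.null(svm)) {
        predict_patch_probs(trained$model, patches, center = FALSE)
      } else {
        predict_svm_probs(svm, extract_fc_features(trained$model, patches,
                                                   center = FALSE))
      }
      lab4 <- fuse_patches(probs, rule = config$fusion_rule)
      labb <- if (config$binary_mode == "label") to_binary(label = lab4)
              else to_binary(patch_probs = probs, mode = "prob",
                             rule = config$fusion_rule)
      rows[[i]] <- data.frame(
        image_id = id, n_patches = nrow(probs),
        label_4class = lab4, label_binary = labb,
        mean_prob_normal = mean(probs[, 1]), mean_prob_benign = mean(probs[, 2]),
        mean_prob_insitu = mean(probs[, 3]), mean_prob_invasive = mean(probs[, 4]),
        stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  if (!is.null(out_dir))
    utils::write.csv(predictions, file.path(out_dir, "predictions.csv"),
                     row.names = FALSE)

  reports <- run_stage("evaluate", {
    evaluate_predictions(test_man[, c("image_id", "label", "subset")],
                         predictions)
  })
  if (!is.null(out_dir))
    utils::write.csv(eval_reports_table(reports),
                     file.path(out_dir, "evaluation.csv"), row.names = FALSE)

  structure(list(predictions = predictions, reports = reports,
                 model = trained$model, history = trained$history,
                 svm = svm, config = config),
            class = "hepatch_run")
}
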