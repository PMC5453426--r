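# Dataset manifest: delimited text (CSV with header), one image per row.
# Columns: image_path, label, subset.  image_id is derived from the file name.

MANIFEST_SUBSETS <- c("train", "test_initial", "test_extended")

#' Load and validate a dataset manifest
#'
#' The manifest is a CSV file with header columns `image_path`, `label` and
#' `subset`.  Labels must be in [hepatch_classes()]; subsets in
#' `train`, `test_initial`, `test_extended`.  Duplicate image paths are
#' rejected.  Errors name the offending row.
#'
#' @param path Manifest CSV path.
#' @param check_paths Require every image file to exist (default `TRUE`).
#' @param check_images Additionally load each image and verify it is 8-bit
#'   3-channel RGB (default `FALSE`; expensive for large datasets).
#' @return A `data.frame` of class `hepatch_manifest` with columns
#'   `image_id`, `image_path`, `label`, `subset`.
#' @export
load_manifest <- function(path, check_paths = TRUE, check_images = FALSE) {
  if (!file.exists(path)) stop("manifest file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("image_path", "label", "subset")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  validate_manifest(df, check_paths = check_paths, check_images = check_images)
}

#' Validate manifest entries held in a data frame
#'
#' @param df Data frame with columns `image_path`, `label`, `subset` and
#'   optionally `image_id`.
#' @inheritParams load_manifest
#' @return The validated manifest (class `hepatch_manifest`).
#' @export
validate_manifest <- function(df, check_paths = FALSE, check_images = FALSE) {
  if (nrow(df) == 0L) stop("manifest has no entries", call. = FALSE)
  for (i in seq_len(nrow(df))) {
    if (!(df$label[i] %in% hepatch_classes()))
      stop(sprintf("manifest row %d: unknown label token '%s' (allowed: %s)",
                   i, df$label[i], paste(hepatch_classes(), collapse = ", ")),
           call. = FALSE)
    if (!(df$subset[i] %in% MANIFEST_SUBSETS))
      stop(sprintf("manifest row %d: unknown subset tag '%s' (allowed: %s)",
                   i, df$subset[i], paste(MANIFEST_SUBSETS, collapse = ", ")),
           call. = FALSE)
  }
  dup <- duplicated(df$image_path)
  if (any(dup))
    stop("manifest contains duplicate image path(s): ",
         paste(unique(df$image_path[dup]), collapse = ", "), call. = FALSE)
  if (is.null(df$image_id))
    df$image_id <- tools::file_path_sans_ext(basename(df$image_path))
  if (anyDuplicated(df$image_id))
    stop("manifest derives duplicate image ids from file names", call. = FALSE)
  if (check_paths) {
    gone <- !file.exists(df$image_path)
    if (any(gone))
      stop(sprintf("manifest row %d: image file not found: %s",
                   which(gone)[1], df$image_path[which(gone)[1]]), call. = FALSE)
  }
  if (check_images) {
    for (i in seq_len(nrow(df))) {
      ok <- tryCatch({ read_image(df$image_path[i]); TRUE },
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok))
        stop(sprintf("manifest row %d: unreadable image %s (%s)",
                     i, df$image_path[i], ok), call. = FALSE)
    }
  }
  df <- df[, c("image_id", "image_path", "label", "subset")]
  class(df) <- c("hepatch_manifest", "data.frame")
  df
}

#' Write a manifest to CSV
#'
#' @param manifest A manifest data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(
    as.data.frame(manifest)[, c("image_path", "label", "subset")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
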