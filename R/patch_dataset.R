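# Overlapping patch grids, dihedral augmentation, per-patch channel centering,
# and the augmented patch dataset.  Coordinates are 0-based, row-major,
# half-open windows [r, r + size) x [c, c + size).

# per-axis offsets of a regular stride lattice, optionally edge-anchored
axis_offsets <- function(dim, patch, stride, edge_anchor) {
  base <- seq.int(0L, dim - patch, by = stride)
  if (edge_anchor && (dim - patch) %% stride != 0L)
    base <- c(base, dim - patch)
  as.integer(base)
}

#' Plan a patch grid over an image
#'
#' Offsets form the regular stride lattice; with `edge_anchor` an extra
#' offset anchored at `dim - patch_size` is appended per axis whenever the
#' lattice does not reach the far edge.  This edge anchoring is what makes a
#' 2040x1536 image yield 35 training offsets (stride 256) and 12 inference
#' offsets (stride 512); for the stride-512 grid the anchored last column
#' overlaps its neighbour by 8 px (4 x 512 = 2048 > 2040), which is
#' intentional.
#'
#' @param height,width Image dimensions in px.
#' @param patch_size Patch edge in px.
#' @param stride Grid stride in px (`patch_size` for non-overlapping,
#'   `patch_size/2` for 50% overlap).
#' @param edge_anchor Append edge-anchored offsets (default `TRUE`).
#' @return A list of class `patch_grid`: `offsets` (data.frame `row`, `col`
#'   in row-major order), `patch_size`, `stride`, `edge_anchored`.
#' @export
plan_patch_grid <- function(height, width, patch_size, stride,
                            edge_anchor = TRUE) {
  if (patch_size > min(height, width))
    stop(sprintf("patch (%d px) larger than image (%d x %d)",
                 patch_size, height, width), call. = FALSE)
  if (stride < 1L || stride > patch_size)
    stop("stride must satisfy 1 <= stride <= patch_size", call. = FALSE)
  rows <- axis_offsets(height, patch_size, stride, edge_anchor)
  cols <- axis_offsets(width, patch_size, stride, edge_anchor)
  offsets <- data.frame(row = rep(rows, each = length(cols)),
                        col = rep(cols, times = length(rows)))
  structure(list(offsets = offsets, patch_size = as.integer(patch_size),
                 stride = as.integer(stride), edge_anchored = isTRUE(edge_anchor),
                 n_rows = length(rows), n_cols = length(cols)),
            class = "patch_grid")
}

#' The inference patch grid (contiguous non-overlapping, edge-anchored)
#'
#' Stride equals the patch size; on the reference 2040x1536 geometry this is
#' the 12-patch grid used for image-wise classification.
#'
#' @inheritParams plan_patch_grid
#' @return A `patch_grid`.
#' @export
inference_grid <- function(height, width, patch_size) {
  plan_patch_grid(height, width, patch_size, stride = patch_size,
                  edge_anchor = TRUE)
}

#' Extract one patch from an image
#'
#' @param img Image array `(h, w, channels)`.
#' @param row,col 0-based offset of the patch's top-left corner.
#' @param patch_size Patch edge in px.
#' @return The `(patch_size, patch_size, channels)` window.
#' @export
extract_patch <- function(img, row, col, patch_size) {
  d <- dim(img)
  if (row < 0L || col < 0L || row + patch_size > d[1] || col + patch_size > d[2])
    stop("patch window falls outside the image", call. = FALSE)
  img[(row + 1L):(row + patch_size), (col + 1L):(col + patch_size), , drop = FALSE]
}

# rotate an (h, w, c) array 90 degrees clockwise
rot90_cw <- function(a) {
  b <- aperm(a, c(2L, 1L, 3L))
  b[, dim(b)[2]:1, , drop = FALSE]
}

# reflect vertically (reverse row order, i.e. flip upside-down)
flip_vertical <- function(a) a[dim(a)[1]:1, , , drop = FALSE]

#' Apply one dihedral transform to a square patch
#'
#' Augmentation ids 0--7 enumerate the 8 symmetries of the square in a fixed
#' order: ids 0--3 are k = 0..3 clockwise quarter-turn rotations; ids 4--7 are
#' a vertical reflection followed by k = 0..3 rotations.
#'
#' @param patch Square `(s, s, c)` array.
#' @param augmentation_id Integer 0--7.
#' @return The transformed patch.
#' @export
apply_augmentation <- function(patch, augmentation_id) {
  d <- dim(patch)
  if (d[1] != d[2]) stop("augmentation requires a square patch", call. = FALSE)
  if (!(augmentation_id %in% 0:7)) stop("augmentation_id must be 0..7", call. = FALSE)
  out <- if (augmentation_id >= 4L) flip_vertical(patch) else patch
  k <- augmentation_id %% 4L
  for (i in seq_len(k)) out <- rot90_cw(out)
  out
}

#' Generate all 8 dihedral augmentations of a square patch
#'
#' @param patch Square `(s, s, c)` array.
#' @return List of 8 patches, named by augmentation id `"0"`..`"7"`.
#' @export
augment_patch <- function(patch) {
  out <- lapply(0:7, function(id) apply_augmentation(patch, id))
  names(out) <- as.character(0:7)
  out
}

#' Center the channels of a patch
#'
#' Subtracts the per-channel mean (computed over this patch) from each of the
#' red, green and blue channels separately; output is double with channel
#' means 0.
#'
#' @param patch `(h, w, 3)` array.
#' @return Double array, per-channel mean 0.
#' @export
center_channels <- function(patch) {
  d <- dim(patch)
  if (length(d) != 3L || d[3] != 3L)
    stop("center_channels expects an (h, w, 3) patch", call. = FALSE)
  out <- patch * 1.0
  for (ch in 1:3) out[, , ch] <- out[, , ch] - mean(out[, , ch])
  out
}

#' Build the augmented patch record table for a set of images
#'
#' One record per (image, grid offset, augmentation id); pixel data is not
#' materialized here (use [get_patch_pixels()]), so the record table scales to
#' the full 70000-record geometry.  Records inherit the source image label and
#' are emitted in deterministic order (images in input order, offsets
#' row-major, augmentation ids ascending).
#'
#' @param image_dims Named list or data.frame giving each image's `height`
#'   and `width`, keyed/ordered by `image_id`.
#' @param image_ids Character vector of image ids.
#' @param labels Labels (one per image, from [hepatch_classes()]).
#' @param patch_size,stride,edge_anchor Grid parameters.
#' @param augment Emit all 8 dihedral augmentations per patch (default
#'   `TRUE`); otherwise only augmentation id 0.
#' @return A data.frame of class `patch_records`: `image_id`, `row`, `col`,
#'   `augmentation_id`, `label`.
#' @export
build_patch_records <- function(image_ids, image_dims, labels,
                                patch_size, stride, edge_anchor = TRUE,
                                augment = TRUE) {
  stopifnot(length(image_ids) == length(labels))
  check_labels(labels, "patch records")
  aug_ids <- if (augment) 0:7 else 0L
  pieces <- vector("list", length(image_ids))
  for (i in seq_along(image_ids)) {
    hd <- image_dims[[i]]
    grid <- plan_patch_grid(hd[1], hd[2], patch_size, stride, edge_anchor)
    off <- grid$offsets
    n <- nrow(off)
    pieces[[i]] <- data.frame(
      image_id = image_ids[i],
      row = rep(off$row, each = length(aug_ids)),
      col = rep(off$col, each = length(aug_ids)),
      augmentation_id = rep(aug_ids, times = n),
      label = labels[i],
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, pieces)
  class(records) <- c("patch_records", "data.frame")
  records
}

#' Materialize the pixels of one patch record
#'
#' @param images Named list of image arrays, keyed by `image_id`.
#' @param record One row of a `patch_records` table (list or data.frame row).
#' @param patch_size Patch edge in px.
#' @param center Apply [center_channels()] (default `TRUE`).
#' @return The (augmented, optionally centered) patch array.
#' @export
get_patch_pixels <- function(images, record, patch_size, center = TRUE) {
  img <- images[[record$image_id]]
  if (is.null(img)) stop("no image with id ", record$image_id, call. = FALSE)
  p <- extract_patch(img, record$row, record$col, patch_size)
  if (record$augmentation_id != 0L) p <- apply_augmentation(p, record$augmentation_id)
  if (center) p <- center_channels(p)
  p
}

#' Write a patch-record manifest to CSV
#'
#' @param records A `patch_records` table.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_patch_manifest <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
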