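# Patch-to-image probability fusion: majority vote, maximum probability, or
# sum of probabilities, with draws resolved by malignancy priority
# (invasive > in situ > benign > normal), and the grouped binary label.

FUSION_TIE_EPS <- 1e-9

#' Argmax with malignancy-priority tie-breaking
#'
#' @param scores Numeric vector of per-class scores, named or ordered as
#'   `classes`.
#' @param classes Class vocabulary (default [hepatch_classes()]).
#' @param priority Priority order for ties (default [hepatch_priority()]).
#' @return The 1-based index (into `classes`) of the winning class.
#' @export
argmax_with_priority <- function(scores, classes = hepatch_classes(),
                                 priority = hepatch_priority()) {
  stopifnot(length(scores) == length(classes))
  cand <- which(scores >= max(scores) - FUSION_TIE_EPS)
  rank <- match(classes, priority)
  cand[which.min(rank[cand])]
}

check_patch_probs <- function(patch_probs, classes) {
  if (is.null(dim(patch_probs)))
    patch_probs <- matrix(patch_probs, nrow = 1)
  if (nrow(patch_probs) < 1L) stop("need at least one patch", call. = FALSE)
  if (ncol(patch_probs) != length(classes))
    stop("probability columns do not match the class set", call. = FALSE)
  if (any(patch_probs < -1e-9)) stop("negative probabilities", call. = FALSE)
  sums <- rowSums(patch_probs)
  if (any(abs(sums - 1) > 1e-6))
    stop("patch probabilities must sum to 1 (within 1e-6)", call. = FALSE)
  patch_probs
}

#' Fuse patch probabilities by majority voting
#'
#' Each patch votes with its argmax label (within-patch ties resolved by
#' malignancy priority); the modal label wins, with count draws also resolved
#' by priority.
#'
#' @param patch_probs Matrix `(n_patches, n_classes)` of probability vectors.
#' @param classes,priority Class vocabulary and draw-resolution order.
#' @return The fused class label (character).
#' @export
fuse_majority <- function(patch_probs, classes = hepatch_classes(),
                          priority = hepatch_priority()) {
  patch_probs <- check_patch_probs(patch_probs, classes)
  votes <- apply(patch_probs, 1, argmax_with_priority, classes = classes,
                 priority = priority)
  counts <- tabulate(votes, nbins = length(classes))
  classes[argmax_with_priority(counts, classes, priority)]
}

#' Fuse patch probabilities by maximum probability
#'
#' The single patch whose maximum class probability is globally largest
#' decides the image label; ties (across patches or classes) resolve by
#' malignancy priority.
#'
#' @inheritParams fuse_majority
#' @return The fused class label (character).
#' @export
fuse_max <- function(patch_probs, classes = hepatch_classes(),
                     priority = hepatch_priority()) {
  patch_probs <- check_patch_probs(patch_probs, classes)
  best_per_class <- apply(patch_probs, 2, max)
  classes[argmax_with_priority(best_per_class, classes, priority)]
}

#' Fuse patch probabilities by sum of probabilities
#'
#' Element-wise sum over patches, then argmax with priority tie-breaking.
#'
#' @inheritParams fuse_majority
#' @return The fused class label (character).
#' @export
fuse_sum <- function(patch_probs, classes = hepatch_classes(),
                     priority = hepatch_priority()) {
  patch_probs <- check_patch_probs(patch_probs, classes)
  classes[argmax_with_priority(colSums(patch_probs), classes, priority)]
}

#' Fuse with a named rule
#'
#' @param patch_probs Matrix of per-patch probabilities.
#' @param rule One of `"majority"`, `"max"`, `"sum"`.
#' @inheritParams fuse_majority
#' @return The fused class label.
#' @export
fuse_patches <- function(patch_probs, rule = c("majority", "max", "sum"),
                         classes = hepatch_classes(),
                         priority = hepatch_priority()) {
  switch(match.arg(rule),
         majority = fuse_majority(patch_probs, classes, priority),
         max = fuse_max(patch_probs, classes, priority),
         sum = fuse_sum(patch_probs, classes, priority))
}

#' Group per-patch 4-class probabilities into binary probabilities
#'
#' Sums normal+benign into non-carcinoma and insitu+invasive into carcinoma;
#' mass is conserved per patch.
#'
#' @param patch_probs Matrix `(n, 4)` in canonical class order.
#' @return Matrix `(n, 2)` with columns `non_carcinoma`, `carcinoma`.
#' @export
group_probs_binary <- function(patch_probs) {
  patch_probs <- check_patch_probs(patch_probs, hepatch_classes())
  out <- cbind(non_carcinoma = patch_probs[, 1] + patch_probs[, 2],
               carcinoma = patch_probs[, 3] + patch_probs[, 4])
  out
}

#' Derive the binary carcinoma / non-carcinoma label
#'
#' `mode = "label"` maps a fused 4-class label through the grouping
#' (normal/benign to non-carcinoma, insitu/invasive to carcinoma).
#' `mode = "prob"` first groups the per-patch probabilities and then fuses
#' the two-class vectors with the given rule; ties resolve to carcinoma.
#'
#' @param label Fused 4-class label (for `mode = "label"`).
#' @param patch_probs Matrix of 4-class patch probabilities (for
#'   `mode = "prob"`).
#' @param mode `"label"` (default) or `"prob"`.
#' @param rule Fusion rule for `mode = "prob"`.
#' @return `"carcinoma"` or `"non_carcinoma"`.
#' @export
to_binary <- function(label = NULL, patch_probs = NULL,
                      mode = c("label", "prob"),
                      rule = c("majority", "max", "sum")) {
  mode <- match.arg(mode)
  if (mode == "label") {
    groups <- hepatch_binary_groups()
    if (is.null(label) || !(label %in% names(groups)))
      stop("unknown label: ", label, call. = FALSE)
    return(unname(groups[label]))
  }
  gp <- group_probs_binary(patch_probs)
  bin_classes <- c("non_carcinoma", "carcinoma")
  bin_priority <- c("carcinoma", "non_carcinoma")   # ties -> carcinoma
  fuse_patches(gp, rule = match.arg(rule), classes = bin_classes,
               priority = bin_priority)
}
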