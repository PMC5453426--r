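---
title: "Methods: patch-based multi-scale CNN classification of H&E breast histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: patch-based multi-scale CNN classification of H&E breast histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepatch)
```

## The problem

Hematoxylin & eosin (H&E) stained breast-biopsy images are diagnosed into
four classes of increasing concern: **normal** tissue, **benign** lesion,
**in situ carcinoma** (malignant cells confined to the ductal–lobular
system) and **invasive carcinoma** (malignant cells spreading beyond it).
A grouped binary task — carcinoma vs non-carcinoma — follows by merging
normal with benign and in situ with invasive.  The discriminating evidence
spans scales: single-nucleus color and shape (nucleus radii of roughly
3–11 px at 0.42 µm/px), local nuclear density and pleomorphism, and
tissue-level architecture.  `hepatch` implements a complete pipeline for
this problem: stain normalization, overlapping-patch extraction with
dihedral augmentation, a multi-scale CNN trained patch-wise, patch-to-image
probability fusion, an optional RBF-SVM head on CNN features, and
structured evaluation.

## Stain normalization

Stained-tissue color is modelled in optical-density (OD) space, where stain
absorbances combine approximately linearly.  The decadic transform is

$$ OD = -\log_{10}\!\frac{v + \varepsilon}{I_0 + \varepsilon}, $$

with white reference $I_0 = 255$ and guard $\varepsilon = 1$.  The guard is
applied to numerator *and* denominator: the numerator-only variant makes OD
negative at the white point, violating the non-negativity and strict
monotonicity that downstream code relies on; with the symmetric guard the
map is exactly 0 at $v = I_0$, strictly decreasing, and invertible to
within one gray level.

Foreground pixels (OD norm above 0.15) are decomposed by the scatter-matrix
eigendecomposition (equivalent to SVD of the OD tuples) into the 2-D plane
of highest variance; the two stain vectors are taken at the 1%/99%
percentile-trimmed extreme angles within that plane.  Per-pixel stain
concentrations follow by least squares (clamped at zero), and the histogram
stretch maps the `stretch_coverage` quantile (default 0.90, i.e. "the lower
90% of the data") of each concentration channel to the top of the output
range, clipping the upper tail.  Output RGB is reconstructed with each
stain at a fixed target OD, so images from different acquisitions share one
appearance.

Open choices resolved here: the 90% stretch is applied **per concentration
channel** (a `stretch_mode = "magnitude"` switch applies one common scale
instead); normalization is approximately idempotent (documented tolerance:
mean per-pixel change below 6 gray levels on double application, dominated
by 8-bit quantization and basis re-estimation); constant-color images raise
a rank-deficiency error rather than returning silently.

## Patch dataset

Training images are tiled with `patch_size` = 512 px and 50% overlap
(stride 256).  Grids are **edge-anchored**: when the stride lattice does
not reach the far edge, one extra offset anchored at `dim − patch` is
appended per axis.  This is the only reading under which the reference
2040×1536 geometry yields 35 training offsets per image (and hence
70 000 = 250 × 35 × 8 augmented records) and 12 inference patches per
image; for the stride-512 inference grid the anchored last column overlaps
its neighbour by 8 px (4 × 512 = 2048 > 2040), which is intentional and
documented.  Coordinates are 0-based, row-major, half-open windows.

Each patch is expanded to the 8 symmetries of the square (k·π/2 rotations,
k = 0…3, with and without vertical reflection), in a fixed order so
`augmentation_id` 0–7 is reproducible.  Patch normalization subtracts the
per-patch mean of each RGB channel separately (per-patch, not
dataset-global, as stated in the source protocol).  Patch records are
metadata (image id, offset, augmentation id, inherited label); pixels are
materialized lazily, so the full-scale record arithmetic runs without
touching pixel data.

## Network architecture

The default 13-layer stack interleaves five 3×3 convolutions (16, 32, 64,
64, 32 maps) with five max-pools (sizes 3, 2, 2, 3, 3; stride equal to pool
size) and ends with fully-connected layers of 256, 128 and 4 units; hidden
activations are ReLU, the output is a softmax over the four classes.
Output shapes and effective receptive fields are propagated declaratively:

$$ rf \leftarrow rf + (k - 1)\,s_{cum}, \qquad s_{cum} \leftarrow s_{cum}\,s_{layer}. $$

```{r rf}
architecture_report(default_architecture(), pixel_size_um = 0.42)
```

Two print inconsistencies in the source table are handled explicitly:

* the published per-layer sizes force a **mixed padding schedule** (valid at
  conv layers 1, 3, 9; same at conv layers 5, 7), which is encoded per
  layer (receptive-field math is padding-independent);
* the tenth layer's printed 12×12 output contradicts the stated
  stride-equals-pool-size rule (3×3 stride-3 pooling of 12×12 gives 4×4);
  the text rule wins, and `propagate_shapes()` reports the discrepancy
  instead of hiding it.  The µm column is stored exact (px × 0.42); the
  printed table rounds inconsistently (10.92 → "11" but 63.84 → "63.8"), so
  presentation rounding is kept separate from the trace.

The engine itself is written natively (no deep-learning framework exists in
the supported environment): im2col by contiguous block slicing feeding BLAS
matrix products, max-pooling with argmax bookkeeping, manual
backpropagation verified against numeric gradients (relative error ~1e-9 in
the test suite), and Adam as the "adaptive learning rate gradient descent"
— a standard per-parameter adaptive scheme chosen because the cited
original is under-specified.  Weights initialize from a seed: He for conv
layers, Glorot for hidden fc layers, and small-scale normal (sd 0.01) for
the output layer so the initial loss sits at ln 4.  Inputs are scaled by
1/128 inside the forward pass so centered 8-bit patches land near [−1, 1];
this is numeric conditioning only and does not change the model class.

## Training protocol

Training follows the published protocol: a 75%/25% split **at the image
level** (all patches of an image stay on one side — a patch-level split
would leak augmented copies of the same tissue into validation), 50 epochs
by default, categorical cross-entropy, class-balanced validation accuracy,
and checkpointing of the best-validation weights.  Per-epoch validation
resampling is implemented as stated but **off by default** (it lets patches
cross the train/validation boundary between epochs; enabling it logs a
warning).  The unstratified split uses the floor convention
(249 × 0.75 → 186 training images); a stratification switch guarantees
class coverage in tiny runs and is on in the pipeline default.  Batch size
(16) and learning rate (1e-3) are exposed with documented defaults, as the
source leaves them unspecified.

## Fusion and the binary label

A test image is tiled with the non-overlapping edge-anchored inference
grid, each patch is classified, and the per-patch probability vectors are
fused by one of three rules: **majority** voting over per-patch argmax
labels, **maximum** probability (the single most confident patch decides),
or **sum** of probabilities.  All draws — within-patch argmax ties, modal
ties, global maxima ties — resolve by the malignancy priority *invasive >
in situ > benign > normal*, which deliberately trades non-carcinoma
specificity for carcinoma sensitivity.  The binary label is derived from
the fused 4-class label by grouping (default); a `binary_mode = "prob"`
alternative first sums grouped probabilities per patch and re-fuses, with
grouped ties resolving to carcinoma.  The source does not say which of the
two the authors used; label grouping is the simpler reading and is the
default.

## SVM head

The CNN+SVM variant uses the post-ReLU activations of the **second
fully-connected layer** (128 features in the default architecture) with an
RBF kernel, tuned by exhaustive search over logarithmic (cost, γ) grids
with stratified 3-fold cross-validation and refit on the full training set.
No SVM library is available in the supported environment, so the dual is
solved by a simplified SMO with an incrementally maintained margin cache —
adequate and deterministic at the few-hundred-sample scale of this head.
Because fusion consumes probabilities, per-class Platt sigmoids are fitted
on out-of-fold decision values and renormalized; one-vs-rest is used
(rather than one-vs-one with pairwise coupling) because it yields
fusion-compatible probabilities directly with far less machinery.  Whether
the original SVM saw augmented or original patches is unstated; the head
accepts either (the smoke suite trains it on unaugmented patches for
runtime).

## Evaluation

Reports contain the confusion matrix (rows = truth), accuracy
(trace/total), and per-class sensitivity (recall), for the 4-class and
binary tasks, per subset (initial / extended test sets) and pooled.
"Overall" is the **item-count-weighted mean** of subset metrics, which is
algebraically identical to the metric of the merged confusion matrices and
reproduces the published pooled values (66.7, 77.8, 94.4) from the printed
subset entries.  Percentages are presented to one decimal with
round-half-up; internal values stay unrounded.

## Synthetic data: what it does and does not establish

The generator renders purple anti-aliased ellipses (nuclei) over a textured
pink background (cytoplasm/stroma), with class controlled by three axes a
pathologist actually uses: nucleus **density** (per 10⁴ px²), **size
variability**, and **spatial organization** (jittered lattice, clustered
parent–offspring process, or uniform Poisson).  The default suite orders
density and variability invasive > in situ > benign ≥ normal and degrades
organization from regular to disordered; nucleus radii default to the
3–11 px range of the reference imagery.  An `easy_class_suite()` widens the
gaps for desk-scale smoke tests, and a `flat_class_suite()` makes all four
classes identical as a no-leakage control.

A green end-to-end test on this data establishes that the pipeline wiring,
seeding, fusion and evaluation are correct and that the network can learn
density/organization phenotypes — it does **not** establish clinical
performance, which requires the real dataset and full-scale training and is
explicitly out of scope.  Reduced geometry is used throughout testing
(384×512 images, 256-px patches, 8 train / 2 test images per class,
10 epochs, batch 8, learning rate 2e-3) purely to fit a single-CPU time
budget; the full 2040×1536/512 geometry remains available and is exercised
for the count arithmetic.

Image I/O is binary PPM and uncompressed baseline TIFF (validated against
an independent TIFF implementation in the test suite); PNG is rejected with
an informative error because no codec is available in the supported
environment and bundling one is out of scope.

## Known limitations

* CPU-bound native engine: full-scale (512-px, 70 000-patch, 50-epoch)
  training is possible but slow; the package's verified scope at full scale
  is the architecture/grid arithmetic, not headline accuracy.
* The SMO solver targets small feature sets (hundreds to a few thousand
  patches); it is not an industrial SVM.
* The synthetic generator does not attempt ductal geometry, so the
  in-situ/invasive distinction rests on density/size/organization rather
  than true architectural confinement.
* Whole-slide pyramid formats, learned fusion, and architecture search are
  non-goals.
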