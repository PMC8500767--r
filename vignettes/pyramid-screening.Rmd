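---
title: "Hierarchical pyramid screening of whole-slide images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical pyramid screening of whole-slide images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Digitized lymph-node sections are gigapixel images stored as multiresolution
pyramids: level 0 holds the full-resolution scan (pixels of roughly
0.23–0.26 µm in modern scanners) and each coarser level halves both spatial
dimensions while doubling the physical pixel size. Metastatic lesions range
over four orders of magnitude in extent — from macrometastases larger than
2 mm down to isolated tumor cell clusters (ITCs) of a handful of cells — so
neither a single-resolution segmentation nor an exhaustive fine-level scan is
practical. This package implements a coarse-to-fine screening pipeline:

1. **Tissue-level search** (`search_pyramid()`): a per-level patch classifier
   is evaluated on a grid of patches at the coarsest level; every
   above-threshold patch becomes a region of interest (RoI) whose four
   quadrant children are examined at the next finer level, while
   sub-threshold patches are pruned with their whole subtree. Each patch is
   addressed by a quadtree *location code* over the alphabet {0=NW, 1=NE,
   2=SW, 3=SE}, so a code of length d addresses one patch d levels below the
   start level.
2. **Cell-level detection** (`points_to_density()`, `nms_peaks()`,
   `cluster_points()`): inside surviving sub-macro candidates, a density
   regression network estimates a nonnegative map whose integral estimates
   the cell count; non-maximum suppression extracts per-cell positions, and
   single-linkage clustering groups them into candidate regions.
3. **Staging** (`classify_slide()`): the slide is assigned one of
   {negative, itc, micro, macro} from the physical extent of connected RoI
   components and the cell-level evidence.

## Model and losses

Both levels share one encoder–decoder backbone (`build_deconvnet()`): three
blocks of 3×3 convolution + ReLU + 2×2 max-pooling, mirrored by three blocks
of 2× nearest-neighbour upsampling + 3×3 convolution, and a final 1×1
convolution that produces a single-channel density map at input resolution.
Because pooling and upsampling are symmetric, any input whose sides are
divisible by `2^3` is accepted and the output matches the input size. The
patch classifier head replaces the decoder by global average pooling of the
bottleneck features, one fully connected layer and a logistic squashing to a
confidence in [0, 1].

Training minimizes mean-squared error with Adam; the learning rate decays
from 1e-3 to 1e-5 by an equal step per epoch, and data are split 70/30 into
train and test. For a patch sequence the composite loss is

* density loss `L_t = (1/2N) Σ_i Σ_p (F_i(p) − F⁰_i(p))²`,
* count loss `L_lstm = (1/2N) Σ_i (T_i − T⁰_i)²` with
  `T_i = R_i + Σ_p F_i(p)`,
* total `L = L_t + α·L_lstm` (default `α = 0.1`, configurable).

`R_i` is a residual count produced by a 10-cell LSTM with a fully connected
readout. Its input is the *dimension shuffle* of the predicted maps: each map
is summed over a 4×4 spatial partition, giving a 16-vector per patch whose
entries sum to the map integral; sequence order is row-major over the tiling
grid. With `α = 0` the LSTM provably receives zero gradient (tested).
Sequences at desk scale are short (≤ 16 patches), so backpropagation through
time runs over the full sequence.

### Numerical choices

* The final 1×1 convolution is linear; negative responses are clamped at
  zero at prediction time. (Training through a terminal ReLU starves the
  gradient whenever the target map is mostly background — one wide run
  collapsed to the all-zero map before this change.)
* Density targets are scaled by 100 during training (`density_scale`) purely
  for numerical conditioning of the sum-form loss; predicted integrals are
  divided back.
* Weights use He-normal initialization; the LSTM forget-gate bias starts
  at 1.
* Adam state and all shuffling are governed by one seed, so training is
  bit-reproducible on a single device.

## Cell-level labels and detection

Point labels (bounding-box centers via `bbox_to_point()`) are rendered as
bivariate Gaussian kernels (Eq. form `(2π)^(−1)|Σ|^(−1/2) exp(−½ (x−μ)ᵀ Σ⁻¹
(x−μ))`, default isotropic σ = 3 px), truncated at Mahalanobis distance 3 and
rescaled to unit mass after truncation, so the map integral equals the number
of interior points exactly. A `peak_normalized` mode reproduces 0–1 float
maps for visualization; counting is then only valid by peak enumeration.
NMS returns strict local maxima within a Euclidean radius (default σ), with
plateau ties broken toward the lexicographically lowest pixel; a constant map
therefore has no peaks. Clustering is single linkage with a 50 µm cutoff
(equivalently, connected components of the ≤cutoff distance graph), chosen
for determinism.

## Staging rules

The clinical TNM node-lesion cut-offs are adopted because the source
framework invokes the TNM area threshold without printing numbers: macro
above 2.0 mm Feret extent, micro from 0.2 mm to 2.0 mm *or* above 200 cells,
ITC at most 0.2 mm and at most 200 cells. All values are `staging_thresholds()`
fields. A slide with no RoI at any level finer than level 2 is negative (the
search "broke" before reaching it); connected-RoI extent at level 2 decides
macro; cell-level evidence decides micro versus ITC. Feret diameter rather
than area is compared against the millimetre cut-offs, matching the clinical
definitions; areas are still reported. The larger class always wins when
regions disagree.

## The synthetic-slide generator

`generate_slide()` renders, at level 0: a near-white background (gray
≥ 240/255, so Otsu separates tissue exactly as on real H&E), a wobbly
elliptical tissue blob with two-octave smooth texture, planted lesions as
darker/denser star-shaped disks of controlled physical diameter, and nuclei
as 3–5 px dark ellipses (three-fold density inside lesions). Ground truth
per slide: per-level lesion masks (any-positive downsampling), nuclei points
and bounding boxes, and the slide label derived from the planted lesions via
the staging cut-offs. ITC-scale lesions are specified by an explicit cell
count (< 200) rather than area. Nuclei counts are deterministic
(`round(density × area)`): this keeps the derived label stable and makes the
diameter-monotonicity property well defined.

Class-typical slides (`slide_spec_for_class()`) use 1 µm level-0 pixels —
the upper edge of the supported [0.1, 1] µm range — because a > 2 mm
macrometastasis cannot fit any desk-scale canvas at scanner resolution;
macro slides use a 4.096 mm (4096 px) canvas, the other classes 1024 px.
Lesion diameters are drawn well inside their class bands (macro 2.3–3.1 mm,
micro 0.3–0.7 mm, ITC < 0.2 mm) so that patch-grid quantization of RoI
extents (up to ~2 patch diagonals at level 2) cannot cross a class boundary.

What the generator does *not* emulate: stain variability and stain physics,
nuclear pleomorphism, tissue folds, pen marks, blur, or any appearance
feature adversarial to a classifier. Passing tests therefore demonstrate
that the search, detection, counting and staging machinery is correct and
trainable — not clinical performance on real slides.

## Desk-scale experiment sizes

All experiment helpers run on one CPU core:

* `experiment_tissue_classifier()`: 200 patches of 64×64 (100 tumor /
  100 normal), 70/30 split, ≤ 50 epochs, encoder width 8.
* `experiment_cell_counting()`: 240 patches of 48×48 with 3–12 nuclei each —
  a realistic nuclear density for H&E lymph-node fields (~1500 nuclei per
  2200² px image) — and σ = 3
  kernels. The model uses two stacked convolutions per block
  (`convs_per_block = 2`; a single-conv block cannot fit even the training
  set) with decoupled weight decay 2 (the deeper net otherwise memorizes its
  training patches). The count estimator layers four standard stabilizers on
  the raw density integral, each fixed a priori or fit on the training split
  only: (i) maps from an ensemble of 2 independently initialized runs are
  averaged (single runs of so small a network vary visibly across seeds);
  (ii) maps are additionally averaged over the four rotation replicas of the
  input; (iii) integration is restricted to pixels above 5 % of a clean
  kernel's peak and divided by the analytic retained-mass fraction of a
  thresholded kernel, which removes diffuse background mass without biasing
  isolated kernels; (iv) an affine recalibration of counts, fit by least
  squares on the *training* patches, corrects the regression-toward-the-mean
  shrinkage that plain MSE training induces. NMS peak enumeration is
  reported alongside; at this nucleus spacing (down to ~7 px, i.e. closer
  than 4σ) merged peaks make enumeration the weaker counter, so the integral
  is the headline count.
* `experiment_lstm_fusion()`: sequences of 4 patches of 32×32 with planted
  tumor masses, joint encoder+LSTM training.
* `experiment_oracle_staging()`: 40 class-typical slides (10 per class)
  screened with ground-truth detectors.

## Known limitations

* The search assumes an approximately monotone classifier (a positive child
  should have a positive parent). For non-monotone real classifiers a lesion
  whose coarse appearance is benign can be pruned early; the `t` threshold is
  per-level configurable so coarse levels can be run more permissively.
* Patch-grid extents quantize Feret diameters upward by up to about two
  patch diagonals; staging near the 2 mm boundary inherits this bias.
* The density network is trained per magnification; no cross-level weight
  sharing is attempted.
* Histogram matching stands in for the (uncited) colour equalization of the
  source framework and is explicitly replaceable.
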