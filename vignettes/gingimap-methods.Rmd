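---
title: "Measuring and mapping gingival thickness: models and methods"
author: "gingimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and mapping gingival thickness: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Gingival thickness (GT) — the bucco-lingual width of the gingival soft
tissue — drives treatment planning in implant dentistry: a band thinner
than about 1 mm is the accepted threshold for a "thin" phenotype with
elevated recession risk. Point probing gives isolated values;
cross-sectional imaging (CBCT registered against an intraoral surface
scan) can in principle give the full spatial distribution, but turning a
stack of segmented cross-sections into a quantitative, visualizable
thickness map requires a chain of image-analysis steps. `gingimap`
implements that chain end to end:

1. **Phantoms** (`make_slice_phantom()`, `make_series_phantom()`,
   `make_registration_pair()`) — synthetic cross-sections and mesh pairs
   with analytic ground truth, so every stage below can be scored
   exactly.
2. **Registration** (`register_meshes()`) — feature-based rigid
   alignment of two surface meshes of the same dentition.
3. **Segmentation** (`build_segmentation_network()`, `train_staged()`)
   — a lightweight encoder–decoder network labelling each pixel as
   background, bone/tooth, or gingiva.
4. **Measurement** (`measure_slice()`) — a vertical pixel scan
   converting a colorized segmentation into a per-column thickness
   profile.
5. **Reconstruction** (`merge_tables()`, `grid_mesh()`) — merging
   profiles across slices into a CSV table and a triangulated, color-mapped
   3-D thickness surface.

## Slice phantoms and what they do (and do not) emulate

A slice phantom is a cropped cross-section of an edentulous ridge: a
bone/tooth slab entering from the top of the crop, whose gingiva-facing
edge is a per-column profile `bone_profile(x)`; directly below it a
gingival band of `round(thickness_fn(x))` pixels; background below that.
Base intensities (background 30, gingiva 90, bone 200 on the 8-bit
scale) mimic the soft/hard-tissue contrast of CBCT; additive Gaussian
noise is seeded and reproducible. Because the band is constructed by
counting pixels, the per-column gingiva count *is* the ground truth the
scan must recover — an exact oracle rather than an approximate one.

The training dataset generator (`make_phantom_dataset()`) draws, per
slice, a ridge level in 25–45 % of the image height, a sinusoidal ridge
undulation, and a band amplitude of 6–18 px. At the default measurement
scale of 0.1 mm/px this spans 0.25–1.8 mm — deliberately straddling the
1 mm thin/thick threshold — with noise sd 6. What the phantoms do *not*
emulate: CBCT scatter and beam hardening, lip/cheek soft-tissue
confounders adjacent to the gingiva, arch-curve reformatting geometry,
and annotation noise. A network that segments phantoms perfectly has
only been shown to separate three well-contrasted tissue classes under
additive noise; clinical performance claims require clinical data.

## Registration

The 3-D landmark-detection problem is reduced to 2-D. Both meshes are
rendered as orthographic depth maps from nine azimuths (step 2π/9) about
the vertical axis; orthographic projection makes back-projection exact
(pixel + depth → 3-D point). On each height-normalized depth map we
detect keypoints as the union of difference-of-Gaussians extrema (the
SIFT detector; tooth cusps and surface bumps are blobs) and Harris
corners, describe them with upright SIFT-style gradient-orientation
histograms (4×4 cells × 8 bins over a 32 px patch — all views share one
pixel scale, and cross-modality rotation is assumed mild, so no
orientation normalization), and match mutual nearest neighbours screened
by RANSAC under a 2-D similarity model (inlier threshold 2 px, 1000
seeded iterations, scale constrained to [0.8, 1.25] since both renders
share the pixel scale).

Matched pixels are back-projected to 3-D on both meshes, pooled into at
most 55 landmark candidates by greedy proximity clustering (radius 2 px
in length units), and scored by geometric stability

  stability = (#views detected) / (1 + RMS spread),

where the spread is the *larger* of the source-side and target-side
scatter: with repetitive dentition a match that is consistently one
tooth off clusters tightly on the source but scatters on the target, and
this definition demotes it. The 10 most stable candidates give
corresponding centroids; a closed-form Kabsch fit — made robust by a
consensus search over candidate triples — initializes point-to-point ICP
restricted to source vertices within a tooth-sized neighbourhood
(default 20 px at the default rendering resolution of ~256 px per mesh
extent) of the landmarks. The ICP objective (mean nearest-neighbour
distance) is recorded per iteration and is non-increasing by
construction; iteration stops at relative change < 1e-6 or 50
iterations.

Design notes: projections use 9 views by default; matching is restricted
to same-azimuth view pairs (neighbouring azimuths are 40° apart and
contribute mostly false matches). "Geometric stability" has no standard
definition; the formula above is this package's interpretation. The
modality difference between the two meshes is emulated by independent
vertex noise; isosurface extraction from CBCT volumes is out of scope.

## Segmentation network

The network follows the DeepLabV3+ layout with a MobileNetV2 backbone,
written against this package's own reverse-mode autodiff over 4-D
arrays (no deep-learning framework is used; convolution kernels are
C++). The encoder's inverted-residual stages follow the standard
MobileNetV2 table with channel widths scaled by `width_multiplier` and
an output stride of 16 (later stages switch stride for dilation). Two
taps feed the head: a low-level map at 1/4 resolution (nominally 24
channels) and the deep map at 1/16 (nominally 320). We standardize on
the strict 1/16 reduction (a 512 input gives a 32×32 deep map; published
descriptions sometimes print 30×30, which is not consistent with a /16
stride on a 512 input). The ASPP head has exactly five branches — 1×1
convolution, three 3×3 dilated convolutions at rates 6/12/18, and global
average pooling — concatenated and fused by a 1×1 projection. The
decoder upsamples the ASPP output ×4, concatenates projected low-level
features, refines, and maps to the three class scores at full input
resolution. The 3×3 convolutions in the ASPP branches and the decoder
refinement are depthwise-separable by default (`aspp_separable`,
`decoder_separable`), consistent with the backbone's design principle;
dense variants are one flag away.

**Loss.** `L = α·L_CE + β·L_Dice` with α = β = 1 by default (no
published values exist for the weights). Cross-entropy carries per-class
weights, by default inverse pixel frequency on the training split
normalized to mean 1, so the thin gingival band is not drowned out.
The Dice term is `1 − (2Σpy + ε)/(Σp² + Σy² + ε)` with ε = 1e-6 and the
sums running jointly over pixels and classes (micro aggregation; this is
the form whose hand-worked binary value for p = (0.5, 0.5) against
y = (1, 0) is 1/3). A macro (per-class averaged) variant is available
via `dice_loss(average = "macro")`. The log argument in the
cross-entropy is clamped at 1e-12.

**Training schedule.** SGD with momentum 0.9 and weight decay 1e-4 (on
convolution weights only), staged: backbone frozen with batch size 8 for
the first phase, then unfrozen with batch size 4. Freezing stops
gradient updates for backbone parameters — bit-identical across the
phase — while batch-norm running statistics continue to track the data
(with a from-scratch backbone the statistics must adapt even while
weights are fixed). The learning rate is anchored by the batch-adaptive
rule `lr = min(max(batch/16 · lr_init, lr_min), lr_max)` with lr_init
7e-3 and lr_min = 0.01·lr_init, and decays along a *single* cosine over
all epochs (the alternative — restarting the cosine at unfreezing — is
not used; one schedule keeps the unfreeze phase at an already-lowered
rate, which is what fine-tuning wants). Validation mIoU is computed
every 5 epochs and the best-scoring state is retained alongside the
final one.

**Preprocessing and augmentation.** Window/clip to the [p1, p99]
intensity percentiles (no standard window values exist for these
crops; the percentile window is per-image and CLI-overridable), rescale
to [0, 1], CLAHE (clip 2.0, 8×8 tiles), bilateral filter (d = 5, range
σ 25 on the 8-bit scale, spatial σ 5), then resize to the square input.
Degenerate constant images map to zero. Augmentation applies one
geometric transform to image and mask together — rotation uniform in
±15°, horizontal flip with probability 0.5, nearest-neighbour mask
resampling — plus brightness/contrast factors uniform in [0.9, 1.1] on
the image only. Dataset splits are patient-disjoint at ratios 7:1:2
(largest-remainder rounding on patient counts).

**Desk scale.** The tested configuration is width multiplier 0.25 at
128×128 input: 200 phantom slices split 140/20/40, 30 epochs (10
frozen), evaluation every 5. One training run takes a few minutes on one
CPU; the acceptance checks train three seeds and require a median
held-out mIoU of at least 0.80 (majority-class baseline ≈ 0.2 mIoU on
the same data). Gingiva is the limiting class: its IoU is bounded by
±1 px boundary ambiguity on a band only ~10 px wide.

## Thickness measurement

The measurement operates on colorized segmentations (gingiva pure red,
bone/tooth pure green — `colorize_labels()` emits exactly the colors the
thresholds expect). Binary masks come from exact thresholds (red:
R > 75, G < 30, B < 30; green: G > 75, R < 30, B < 30; mutually
exclusive by construction). The tooth mask is closed (3×3 box, 1
iteration), the largest connected component's contour is traced,
contour points at y = 0 are discarded as crop-edge artifacts, duplicate
x positions keep the smallest y, and the points are sorted by x.

The scan then walks each image column: start one pixel past the
boundary point for that column (the boundary pixel itself is tooth;
columns without a boundary point use the nearest boundary x, ties to
the smaller x), step in the scan direction (default "down"; "auto"
picks, per slice, the direction with more gingiva within 10 rows of the
boundary), skip non-gingiva pixels until entering the band, count
consecutive gingiva pixels, and stop at the first exit or the image
edge. Interior gaps therefore terminate the count — the measured value
is the first contiguous run, not the total. A configurable `max_skip`
bounds the approach distance on pathological masks (default unlimited).

Raw profiles are smoothed with a 1-D Gaussian (reflected ends, support
4σ, σ = 0 is the identity); smoothing preserves constants exactly and
cannot produce negative thickness. Pixel counts convert to mm by
`pixel_spacing`, default 0.1 mm/px — the package's working measurement
resolution. Note the tension left explicit rather than resolved: typical
CBCT voxels are 0.3 mm, so a 0.1 mm/px cross-section implies resampled
slices; `pixel_spacing` should be set from the actual image metadata.

Thickness is measured strictly along image columns ("vertical lines"),
not along the local surface normal; for steeply sloped boundaries the
vertical chord overestimates the perpendicular thickness. Surface-normal
measurement is a possible extension, not implemented.

## Reconstruction and visualization

Per-slice rows (image name, slice number, x, thickness in px and mm,
direction) are merged in natural filename order (numeric substrings
compared as integers, so slice2 < slice10) and written as CSV that
round-trips losslessly. The surface places one vertex per measured grid
cell at `(slice · slice_mm, x · pixel_mm, thickness_mm)` — slice spacing
defaults to 0.3 mm (the typical CBCT voxel), column spacing to
`pixel_mm` — and splits every complete quad into two triangles along the
(i,j)→(i+1,j+1) diagonal. Quads with missing corners are omitted rather
than interpolated (a full M×N grid yields exactly M·N vertices and
2(M−1)(N−1) triangles). Colors follow a piecewise-linear map through
blue → green → yellow → red anchored at 0, 1/3, 2/3 and 1 of the value
range (the anchor positions are this package's choice; only the color
order is prescribed by convention), shared between the 3-D surface and
the 2-D scatter "heatmap". Optional Laplacian (umbrella) smoothing
relaxes z toward neighbour means with factor λ ∈ (0, 1]; x/y stay
fixed, planes are fixed points, and the z range never expands. Export is
binary little-endian PLY with per-vertex uchar RGB (or ASCII PLY, or
OBJ with vertex-color extension); re-import preserves counts, float32
vertex precision and exact colors.

The mesiodistal axis is raw slice index scaled to mm; mapping image
columns back to anatomical arch-circumference coordinates would require
the arch curve used during reformatting, which is outside this package's
scope.

## Numerical choices and degenerate inputs

* Thickness values are rounded with R's `round()` when the phantom band
  is constructed and when analytic counts are compared; defaults avoid
  exact .5 thicknesses.
* Softmax is computed with row-max subtraction; class ties in the
  argmax resolve to the lowest class index.
* Batch-norm uses ε = 1e-5, running-statistic momentum 0.1, biased
  batch variance for normalization and unbiased running variance.
* Confusion-matrix classes absent from both prediction and truth are
  reported NA, excluded from mIoU, and warned about; mIoU averages over
  all present classes including background.
* Empty tooth masks, masks that vanish under closing, and contours
  confined to y = 0 all raise a "no tooth surface" error naming the
  slice.
* All stochastic stages (phantom noise, augmentation, shuffling, RANSAC,
  weight init) draw from R's RNG under explicit seeds; reruns of the
  measurement pipeline with one seed are byte-identical, and training
  reruns are identical given identical checkpoints.

## Problem sizes used by the test-suite

Unit tests run the network at 32×32 with width 0.25 (seconds); the
acceptance checks use 256×256 thickness phantoms, ten ~1,600-vertex
registration pairs with vertex noise sd 0.05, and three desk-scale
trainings (128×128, width 0.25, 200 slices, 30 epochs). These sizes were
chosen so the full chain — including three complete trainings — runs on
a single CPU in well under half an hour while still exercising every
stage at realistic signal-to-noise.

## Known limitations

* Phantom realism is intentionally limited (see above); passing tests
  demonstrate algorithmic correctness, not clinical accuracy.
* The registration assumes mild misalignment (rotations within ~15°);
  larger rotations about the vertical axis would need azimuth-offset
  view matching (`match_window > 0`), and arbitrary large rotations are
  out of scope.
* The scan measures the first contiguous gingival run below the
  boundary; detached red islands (segmentation artifacts) are ignored by
  design.
* Training from scratch on phantoms does not use pretrained backbone
  weights; the freeze phase therefore protects only the random
  initialization. A flag for loading locally available pretrained
  weights exists at the API level (`network_restore()`), but no weights
  ship with the package.
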