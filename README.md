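# gingimap

Quantify and visualize **gingival thickness (GT)** — the bucco-lingual
width of the gingival soft tissue — from segmented dental
cross-sections, end to end: synthetic phantoms with analytic ground
truth, rigid CBCT/intraoral-scan mesh registration, semantic
segmentation of gingiva and bone, a vertical pixel-scan thickness
measurement, and triangulated 3-D thickness surfaces with gradient
color mapping.

GT is a key component of the periodontal phenotype: a band thinner than
1 mm marks the "thin" phenotype with elevated recession risk, and the
thickness at specific sites drives incision and grafting decisions in
implant surgery. Point probing yields isolated numbers; `gingimap`
turns a stack of segmented cross-sectional images into the full spatial
thickness distribution.

## What is inside

| stage | functions | method |
|---|---|---|
| phantoms | `make_slice_phantom()`, `make_series_phantom()`, `make_phantom_dataset()`, `make_registration_pair()` | cross-sections with a bone slab, a gingival band of known per-column thickness, and seeded noise; mesh pairs under known rigid motions |
| registration | `register_meshes()` and its stages (`render_projections()`, `detect_and_match()`, `backproject()`, `select_landmarks()`, `estimate_rigid()`, `icp_refine()`) | multi-view orthographic depth maps (step 2π/9), DoG + Harris keypoints, SIFT-style descriptors, RANSAC screening, stability-ranked landmarks (55 → 10), Kabsch fit, local ICP |
| segmentation | `build_segmentation_network()`, `train_staged()`, `predict_segmentation()` | DeepLabV3+-style encoder–decoder on a MobileNetV2 backbone (output stride 16, five-branch ASPP at rates 6/12/18), composite loss `α·L_CE + β·L_Dice`, staged freeze/unfreeze SGD with a batch-adaptive cosine learning rate `min(max(b/16·lr₀, lr_min), lr_max)` |
| evaluation | `confusion_counts()`, `class_metrics()` | per-class IoU = TP/(TP+FP+FN), precision, recall, F1, mIoU, row-normalized confusion matrices |
| measurement | `measure_slice()`, `scan_thickness()`, `smooth_profile()` | exact color thresholds (red R>75,G<30,B<30; green G>75,R<30,B<30), largest-contour tooth boundary, per-column enter/exit scan, 1-D Gaussian smoothing, annotated overlays |
| reconstruction | `merge_tables()`, `grid_mesh()`, `laplacian_smooth()`, `export_surface()`, `plot_distribution()` | natural-sort slice merging, CSV tables, triangulated (slice × column) surfaces, blue→green→yellow→red color map, PLY/OBJ export |
| pipeline | `run_pipeline()`, `inst/cli/gingimap` | staged end-to-end runs with a YAML config, seed control and a JSON manifest |

The segmentation network and its training loop are implemented in
R + Rcpp (a small reverse-mode autodiff over 4-D arrays with C++
convolution kernels); no external deep-learning framework is required.

## Worked example

Generate a 5-slice phantom series, measure it, and reconstruct the
thickness surface (this is `run_pipeline()` in five lines):

```r
library(gingimap)

base  <- slice_phantom_spec(128, 128,
                            bone_profile = function(x) 40,
                            thickness_fn = function(x) 8, noise_sd = 0)
field <- function(k, x) 6 + 3 * sin(pi * (k + 1) / 6) *
                        (0.7 + 0.3 * cos(2 * pi * x / 128))
series <- make_series_phantom(series_phantom_spec(5, base, field))

rows <- lapply(names(series), function(nm)
  measure_slice(colorize_labels(series[[nm]]$mask),
                measure_config(sigma = 0), image_name = nm)$rows)
names(rows) <- names(series)

tab  <- merge_tables(rows)
surf <- grid_mesh(tab, slice_mm = 0.3, pixel_mm = 0.1)
surf
#> thickness surface: 640 vertices, 1016 triangles, z in [0.7, 0.9] mm
export_surface(surf, "surface.ply")
```

Each of the 5 × 128 grid cells became a vertex at
`(slice · 0.3 mm, x · 0.1 mm, GT mm)`; every complete quad split into
two triangles (a full M×N grid gives exactly 2(M−1)(N−1) = 1016 here),
and vertex colors run blue (0.7 mm, thinnest) to red (0.9 mm,
thickest). On noise-free phantoms the measured per-column counts equal
the analytic band thickness exactly, so the surface z-values reproduce
the generating field to within rounding.

Registration of a noisy mesh pair under a known rigid motion:

```r
mesh <- make_arch_mesh(seed = 1)
tr   <- rigid_transform(rotation_about(8 * pi / 180, c(0.2, 0.3, 1)),
                        c(1.5, -1, 0.8))
pair <- make_registration_pair(mesh_pair_spec(mesh, tr,
                                              surface_noise_sd = 0.05))
res  <- register_meshes(pair$source, pair$target, register_config(seed = 3))
transform_error(res$transform, tr)
#> $rotation_deg
#> [1] 0.2409011
#> $translation
#> [1] 0.02515091
```

i.e. an 8° misalignment with per-vertex noise sd 0.05 is recovered to
~0.24° and ~1/3 of a projection pixel (pixel scale 0.078 length units)
of translation.

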