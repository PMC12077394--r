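---
title: "Registration of serial histology sections and spatial multi-omics fusion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Registration of serial histology sections and spatial multi-omics fusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(histofuse)
```

## The problem

Spatial omics assays that cannot share a tissue section — Visium-style
spatial transcriptomics (circular ~55 µm capture spots on a hexagonal
lattice) and mass spectrometry imaging (square ~30 µm pixels) — are run on
*serial* sections of the same block. Every section also receives a routine
histology stain, so the stained scans provide a common visual currency:
once the stained images are registered, the registration carries every
spatial data type (images, masks, pointsets, polygon annotations, omics
geometries) from one section's coordinate system into another's, and
measurements from the source modality can be fused into the target
modality's spatial organization.

`histofuse` implements both halves: a self-contained registration engine
for stained fresh-frozen serial sections, and an integration layer that
projects omics geometries into label rasters, registers them across
sections and fuses them by area-weighted statistics. Everything is
validated against seeded synthetic data generated by the package itself; no
external data is required anywhere.

## Conventions

One convention is used everywhere: pixel indices are 0-based with
(x, y) = (column, row); pixel centers sit at integer coordinates; image
bounds are the half-open box [0, W) × [0, H); physical coordinates are
pixel coordinates times the raster's resolution in µm/pixel (default
1 µm/px, the export resolution assumed for stained scans). Displacement
fields store per-pixel *offsets*; the backward field gives, for each
fixed-space pixel, its source coordinate in moving space (used for
resampling), the forward field maps moving-space points into fixed space
(used for pointsets).

## Preprocessing

`prepare_pair()` builds the registration-ready pair:

1. **Tissue segmentation** (`segment_tissue()`): resample to 640 × 640,
   grayscale, total-variation denoising (Chambolle's dual projection, 40
   iterations, weight 8), Otsu threshold with tissue taken darker than the
   slide background (a flag flips the polarity), morphological closing with
   a 5 px disk, and removal of 8-connected regions below 10,000 µm²
   (configurable). The mask is resampled back to the original grid. A
   learned segmenter is deliberately not used; user-supplied masks are
   accepted everywhere and take precedence.
2. **Masking and cropping**: the background is blanked to white, each image
   is cropped to its mask bounding box, and both crops are padded to a
   common square so the later resample applies the same scale to both.
3. **Denoising** (affine stage only, `denoise_mean_shift()`): resample to
   512 × 512, convert to HSV, joint spatial/range mean-shift filtering
   (spatial radius 20 px, color radius 15 intensity units, ≤ 10 iterations,
   termination when the combined shift drops below 1), convert back. The
   nonrigid stage skips denoising: local matching benefits from the full
   feature content.
4. **Downscaling**: Gaussian smoothing (σ = 2) against aliasing, resample
   to the 1024 × 1024 working resolution, grayscale (luminance weights
   0.299/0.587/0.114), and a 100 px border pad to leave room for
   deformations (working grid 1224 × 1224).

Every geometric step (crop offset, pad amounts, scale) is recorded as an
exact affine map, so original-space coordinates round-trip through the
working space to machine precision and the final transform chain acts
between the *original* image spaces.

## Similarity: windowed NCC

All optimization uses the mean windowed normalized cross-correlation: in a
box window of radius 10 px (1% of the working resolution) around each
pixel, the correlation of the two images' intensities; windows with zero
variance contribute 0; the score is the mean over all pixels. Local NCC is
invariant to local linear intensity maps — appropriate for differently
stained, differently faded sections. The window sums are computed with
summed-area tables, so cost is independent of the radius.

## Affine stage

`affine_register()` first runs a seeded random search over rigid
candidates at the coarsest pyramid level: rotations uniform in
[−180°, 180°) and translations within ±10% of the width around the
center-of-mass initialization (mask centroids aligned); half the trials
probe rotation only at the centroid translation, half probe joint
perturbations; 64 trials by default, reproducible from the mandatory seed.
The best candidate seeds a per-level quasi-Newton (bounded L-BFGS-B)
ascent of the 6 affine parameters (translation, rotation, two log-scales,
shear), coarse to fine over pyramid factors 8, 4, 2, 1. Bounds around the
incoming parameters (±25°, ±0.3 log-scale, ±6% translation) keep the
ascent inside the basin the search found. A 3-parameter rigid restriction
of the same machinery serves the omics-to-stain registration.

## Nonrigid stage

`nonrigid_register()` implements a greedy diffeomorphic scheme. Per
pyramid level it iterates:

1. warp the moving image through the current total backward field composed
   with the affine initialization (evaluated as function composition — no
   intermediate resampling);
2. compute the windowed-NCC gradient force (the analytic local-correlation
   gradient times the warped image gradient);
3. smooth the update with a Gaussian, σ = 5 (*pre-sigma*);
4. scale the update so the maximum displacement per iteration is 1 px;
5. compose it into the total field;
6. smooth the total field with σ = 4 (*post-sigma*).

Only similarity-improving steps are accepted (the recorded similarity
trace is non-decreasing by construction); a level stops at 100 iterations
or when the relative similarity gain falls below 10⁻⁵. The small-step /
smooth-total regime keeps the map diffeomorphic in practice; tests assert
a positive Jacobian determinant on ≥ 99% of tissue pixels. The forward
field is obtained by fixed-point inversion of the backward field (20
iterations, tolerance 0.05 px), and every result self-reports its
forward/backward round-trip error (a warning attribute above 2 px).

## Chains, compositing, application

A registration result is a `transform_chain`: bookkeeping affine →
working-space affine → working-space displacement field → inverse
bookkeeping. `composite()` materializes the chain once, at full fixed-image
resolution, by evaluating the backward composition on the fixed grid — so
applying a chain to an image costs exactly one interpolation regardless of
how many stages it contains. Images use bilinear interpolation, masks and
label rasters nearest-neighbor (no invented labels), pointsets and GeoJSON
polygons the forward map. `rescale_transform()` moves affines (by
conjugation with the pixel-center scaling map) and fields (bilinear vector
resampling with per-axis scaling) between resolutions.

## Groupwise mode

For an ordered series registered to one fixed section (by default the
last): neighbor affine registrations are chained section-by-section
(damaged sections can be bridged via a skip list), then each moving
section is nonrigidly registered *directly* against the fixed section with
its chained affine as initialization. After the affine chain the sections
are independent, so the per-section work runs through a pluggable map
function (sequential by default) with order-independent results. The
chained-affine initialization is what rescues distant pairs whose direct
coarse alignment fails; the final nonrigid stage is identical in both
modes.

## Omics integration

*Grid projection.* Spot geometries (center, 55 µm diameter default) and
pixel geometries (30 µm square grid default) are rasterized into
*reference matrices* — integer label rasters at stained-image resolution,
0 = background — by pixel-center inclusion. The integer raster is what
makes nonrigid warping of omics geometry exact-to-the-pixel; the fusion
weights recover sub-spot precision. On the spot size the package follows
the 55 µm *diameter* convention of the Visium assay (the diameter/radius
wording is ambiguous in parts of the literature); it is configurable.

*MSI-to-stain registration.* A feature image is built from the first
principal component of the pixel spectra (mean-centered, min-max scaled,
sign fixed so interior tissue scores above the grid border), rescaled to
the stained resolution and rigidly registered (rotation + translation
only, to spare the pixel geometry from deformation) against the segmented,
cropped stained image; masks are used directly when supplied.

*Fusion.* For each target spot the co-labeled raster cells per source data
point are counted; weights are the area fractions of the spot's covered
area (summing to 1). Each measure is fused by weighted statistics:
weighted mean, *population* weighted standard deviation (no bias
correction — the paperless choice documented here), lower weighted median
(smallest value at cumulative weight ≥ 0.5), and unweighted extremes.
Spots without overlap are emitted flagged rather than dropped, so joins
stay aligned.

*Filters.* Spots with tissue coverage below 80% are removed (a spot at
exactly 80% survives). Tissue-type matching assigns each spot its
majority-fraction annotation label (threshold 0.5, else unassigned) in
both the target and the registered source annotation and keeps spots whose
labels agree. The negative control (`sham_rotate()`) appends a 180°
rotation about the fixed-image center to an otherwise correct chain.

*Evaluation.* Landmark accuracy uses the target registration error
(Euclidean distance per landmark pair), its per-pair median, and the
median (MM-TRE) and mean (AM-TRE) of per-pair medians over a set of
registration pairs; at 1 µm/px all errors are in µm. Even-count medians
take the midpoint of the central order statistics.

## Synthetic data: what it emulates, and what it does not

`make_tissue_image()` renders a smooth random tissue blob on a white slide
filled with textured stroma and non-overlapping elliptical glands (dark
rim, light lumen) in an H&E-like palette; mask, label raster, gland table
and texture are all exposed as ground truth. `make_deformation()` builds
smooth invertible fields by integrating a sum-of-Gaussian-bumps velocity
field with scaling-and-squaring (exact inverse from the negated velocity;
the generator refuses amplitude/smoothness combinations whose Jacobian
would collapse). `make_serial_sections()` emulates a sectioning series:
per step, accumulated smooth drift, morphological churn (each gland
rescaled or removed with probability `morph_rate`), AR(1) decorrelation of
the stromal micro-texture (ρ = 0.75 per step) and a random rigid slide
placement (±15°, ±3% shift) — the latter two because identical texture
and identical mounting would make distant sections unrealistically easy to
register directly, contradicting the growing heterogeneity the series is
meant to display. Landmarks are carried through the exact ground-truth
chains; landmarks inside churned glands are flagged, mirroring how
annotators replace landmarks lost between real sections.
`make_omics_layers()` lays a hexagonal spot lattice (row pitch
100·√3/2 µm, alternate rows offset 50 µm, so nearest centers are exactly
100 µm apart) and a 30 µm pixel grid over the tissue and draws molecular
values as baseline + effect · gland-fraction + Gaussian noise on both
layers, so the true cross-layer correlation structure is known.

What the generator does **not** emulate: realistic stain variation and
batch effects, mass spectra (values are already-normalized intensities),
out-of-plane tissue loss and folds, scanner artifacts. Passing tests
therefore demonstrate correctness of the algorithms under controlled
deformation, heterogeneity and noise — not performance on any particular
real dataset.

## Numerical choices and default problem sizes

- Mean-shift filtering samples its spatial window on a stride lattice
  (stride = radius/10, i.e. 2 px at the default radius 20): at these
  smoothing scales the subsampled window mean is indistinguishable and the
  filter is ~4× faster; the window radii themselves are unchanged.
- Image resampling uses clamped-border bilinear sampling with the
  pixel-center convention `x_src = (x + 0.5)·scale − 0.5`; out-of-bounds
  *warping* sources take a fill value (0 by default, 255 for stained
  backgrounds).
- Gland-in-circle and pixel-in-square rasterization use strict
  center-inclusion; ties between overlapping spots go to the
  lower-indexed id with a warning.
- The rigid random search and every stochastic generator derive child
  seeds from a single user seed by fixed integer arithmetic; identical
  inputs and seed give bit-identical results, including under a parallel
  map in the groupwise mode.
- Unit and property tests exercise the engine at reduced working
  resolutions (128–256 px working size, correspondingly smaller border
  pads, and 400–500 px scenes), which the accuracy contracts tolerate; the
  known-transform recovery checks additionally run at the full
  1024 + 2·100 working resolution on 1500 px scenes. The
  groupwise-vs-pairwise and integration-ordering experiments use 10
  seeded replicates at 450 px and 1200 px scene sizes respectively. These
  sizes are the package's desk-scale validation conditions; all of them
  are plain options.

## Known limitations

- The engine is 2-D, single-channel-similarity, CPU-only; mutual
  information or learned similarities are out of scope, so strongly
  multimodal image pairs (e.g. fluorescence vs brightfield) rely on the
  mask-based registration path.
- Greedy update-then-smooth schemes guarantee invertibility only softly
  (via small steps and smoothing); the Jacobian and round-trip are checked
  and reported rather than enforced by construction.
- The groupwise mode assumes the caller has identified damaged sections;
  there is no automatic quality estimation.
- Whole-slide pyramid formats and full OME-XML metadata are not parsed;
  plain TIFF/PNG with caller-supplied resolution is the I/O contract.
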