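---
title: "Mapping myocardial innervation from immunostained slides: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping myocardial innervation from immunostained slides: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(innervmap)
```

## The problem

Nerve fibers in the ventricular myocardium can be visualised by
immunostaining against the pan-neuronal marker UCHL-1 (PGP9.5): fibers
take up the brown DAB chromogen against a blue hematoxylin counterstain.
Classical histology, however, destroys the three-dimensional context:
each 4 mm transverse ring of ventricle is cut open, split into cassette
sized fragments, sectioned and scanned separately. `innervmap`
implements the full computational chain that undoes this fragmentation:
per-slide fiber quantification, virtual reassembly of complete rings,
landmark registration onto a reference anatomical volume (e.g. a
post-mortem MRI), fusion into a 3D innervation map, and spatial
statistics along the apex-to-base axis.

## Per-slide quantification

**Working resolution.** Slides are downscaled by an integer factor
(default 16) using box/area resampling. Area resampling is the only
choice consistent with the downstream metric: density is a pixel-count
fraction, and box filtering preserves mean stain fraction exactly. The
effective resolution is `mpp_base * downscale` microns per pixel; the
native `mpp` must come from the file or the caller — scanners differ and
the package never assumes a constant.

**Tissue mask.** Grayscale conversion (BT.601 luma), Gaussian blur
(`blur_sigma`, default 2 px), then a pixel is tissue if it is darker
than `brightness_max` (default 220) *or* its Sobel gradient magnitude
reaches `gradient_min` (default 10). The OR combination is the default
because pale but textured regions (stretched subendocardium, fat
borders) should not be discarded; an AND mode is available. Components
smaller than `min_area_px` (default 500 px at downscale 16, about
0.03 mm²) are dropped — they are almost always debris — and the mask is
dilated by `dilate_radius` (default 3 px) so that tissue edges, where
nerve trunks often run, are not clipped. None of these numbers is
canonical; all sit in the `tissue_mask:` config block and should be
reviewed per staining batch.

**Fiber classification.** A pixel is a fiber pixel iff it lies in the
tissue mask and its HSV coordinates fall inside an inclusive box range.
The package uses the 8-bit convention (H on 0–179 half-degrees, S and V
on 0–255), which matches the magnitude of the default range
`H (0,80), S (12,125), V (31,162)` — a working range for UCHL-1 DAB
staining. Because hue, antibody dilution and counterstain intensity vary
between laboratories, the range is a required configuration parameter
with these values only as the default. Bounds are inclusive at both ends
(simplest testable contract) and hue wraparound is not supported — DAB
brown does not cross the hue origin under this convention. Stain
deconvolution and learned detectors are deliberately out of scope.

**Density map.** The binary fiber mask is tiled into non-overlapping
square windows whose side is `floor(sqrt(window_mm2) * 1000 / mpp_eff)`
pixels; 1 mm² is the conventional window. Each window's density is
fiber pixels divided by window pixel area. Two decisions matter:

* *Non-overlapping tiling* (stride = window) is the default because the
  rendered grid then corresponds one-to-one to the analysis windows; a
  `stride_px` parameter exists for overlapping maps.
* *Partial edge windows* are normalized by their true pixel count, not
  padded — padding would fabricate low densities along every section
  border.

The density map retains the integer per-window counts and areas, so the
conservation identity (sum of density x area = total fiber count) holds
exactly, not merely to rounding.

**Rendering.** A fixed logarithmic colour scale (default 8 bins spanning
1e-4 to 1 with constant edge ratio) keeps maps comparable across slides;
densities below the lowest edge render as background. The overlay is
alpha-blended at `alpha = 0.3` (round-half-up to integers) so the
histology stays visible, with grid lines at window boundaries and an
optional legend strip. Exact bin edges and palette are a package
convention — comparability is only guaranteed within one configured
style.

## Ring reassembly

Fragment placement maps are explicit JSON documents (`fragment_layout`):
per fragment a flip, a rotation about the fragment centre, an integer
translation and a z-order. Assembly is rigid placement with
nearest-neighbour resampling (value-preserving for masks and densities),
later z-order winning overlaps.

Seam correction (`refine_boundaries`) is landmark-free: facing fragment
boundaries within a band (default 10 px) are paired by nearest-neighbour
correspondence, but a pair only counts as gap evidence when the pixels
are at least 2 px apart and the segment between them crosses empty
canvas — this distinguishes true seam gaps from touching seams and from
facing arc contours. Pairs of fragments with fewer than 8 such
correspondences are left alone (a handful of accidental matches is
noise). The correction itself is a regularized thin-plate-spline warp
whose targets put the two edges half a pixel to either side of the seam
midline, applied by *forward splatting*: the steep part of the
displacement field lives in the empty gap, so tissue is only gently
displaced and does not fold; isolated rounding holes (empty pixels with
at least six tissue neighbours) are filled from their neighbourhood,
with fiber pixels never duplicated. The relative change of tissue area
is measured before committing; if it would exceed `max_area_change`
(default 1%), the composite is returned unchanged with a warning flag.
Closing a gap necessarily adds roughly the gap's area, so the bound is a
real constraint, not a formality: sections whose processing damage
exceeds it are flagged rather than silently deformed.

## Registration

Landmarks are human-supplied `(x_src, y_src, x_dst, y_dst)` CSV files in
0-based pixel coordinates, x = column, y = row. The linear stage is
closed-form Procrustes (rotation + translation, optional uniform scale,
reflections off by default with a flag for flipped sections). The
deformable stage is a single regularized thin-plate spline: with
`lambda = 0` it interpolates the landmarks exactly; as `lambda` grows it
approaches the best affine fit (the bending penalty does not act on the
affine part). The TPS solve uses block elimination of the bordered
system, which stays numerically stable for any `lambda`. TPS was chosen
as the standard landmark-driven smooth warp; per-ring `lambda` is a
config value because deformation severity genuinely varies between
rings and no universal default exists.

Grids are resampled by inverse mapping with an explicit fill value
(default 0) and nearest-neighbour interpolation by default, so binary
and density grids keep their value range. A forward TPS has no closed
form inverse; `apply_transform` approximates it by refitting on swapped
landmark pairs, the standard backward-warping practice. Forward point
evaluation (`transform_points`) is exact and is what the recovery tests
check.

## 3D fusion

Registered per-slice density surfaces are stacked apex-to-base (slice 1
= apex) at `dz = 4` mm, the ring thickness; the implementation assumes
one ring per reference slice. In-plane spacing comes from the reference
volume header when present, else from the effective mpp. Missing
interior slices are filled by inverse-distance linear interpolation
between the nearest present neighbours; missing terminal slices copy
their nearest neighbour; both are marked `"interpolated"` in the
per-slice provenance sidecar. Volumes export to NIfTI with correct
pixdim; the fill value is −1, a sentinel outside the valid density
range.

## Spatial statistics

Per slice, four metrics summarize the innervation pattern:

* **Shannon entropy** (natural log) of the per-window density histogram
  over the heatmap's logarithmic bins, tissue-covered windows only.
  Zero means all windows share a bin; `ln k` means `k` bins equally
  occupied. The bin set matters as much as the data; the package ties it
  to the rendering bins so one configuration governs both.
* **Moran's I** with binary contiguity weights on the window lattice
  (queen adjacency by default, rook available), restricted to
  tissue-covered windows. Positive = clustered, ~0 = random, negative =
  alternating.
* **Mean nearest-neighbour distance** over fiber-mask pixels treated as
  points at their centres (values near 1 px mean near-contiguous
  fibers). Computed exactly: a Chebyshev-2 local search resolves every
  pixel with a neighbour within distance 2·√2 (anything outside that
  window is at distance ≥ 3), and isolated pixels fall back to a scan.
* **Hotspot volume**: total pixel area of windows whose density strictly
  exceeds a threshold. The default threshold is the lowest edge of the
  top logarithmic bin; it is exposed as `stats.hotspot_threshold`
  because no canonical value exists.

Region summaries report the mean and a Student-t 95% confidence
interval over the slices of each named region; single-slice regions
report the value with an undefined interval.

## The phantom generator

Every stage is testable without any external data through seeded
phantoms:

* `make_phantom_slide` draws each tissue pixel as a fiber pixel
  independently with probability given by a fiber-fraction field
  (Bernoulli truth model — the density metric is pixel-count based, so
  per-pixel sampling is the natural ground truth). Stain colours default
  to values strictly inside (fiber: RGB 120,108,82) or outside (tissue:
  190,185,220; background: white) the default HSV range, so phantom
  classification is exact by construction and any pipeline discrepancy
  is a genuine defect.
* `make_phantom_ring` cuts an annulus into angular sectors displaced by
  known rigid placements. Default placements use 90-degree rotations and
  integer translations so the create/reassemble round trip through
  nearest-neighbour resampling is exact; an integer seam jitter
  (random or explicit per fragment) emulates processing deformation and
  opens seam gaps for the correction stage.
* `make_phantom_heart` builds a stack of annular slides whose fiber
  fraction follows a chosen apex-to-base gradient (default linear,
  0.01 to 0.10 over 8 slices) and whose annulus tapers from apex to
  base, as ventricular rings do — so the hotspot profile reflects both
  rising fiber fraction and growing ring size, like the real
  longitudinal gradient. Each slide carries a known integer in-plane
  shift relative to the reference volume, encoded in four outer-contour
  landmarks, giving the registration stage real work with an exactly
  known answer. The reference volume is a blurred rendering of the
  unshifted tissue geometry at 4 mm spacing.

What the phantoms do *not* emulate: curvilinear fiber morphology (an
optional visual mode aside, truth is per-pixel), staining variability
and background signal, fixation shrinkage, scanner artefacts, and
pyramidal file formats. Tests passing on phantoms therefore validate
the *computational* contract — geometry, counting, registration,
statistics — not the biological calibration of the HSV range or mask
thresholds, which remain per-laboratory choices.

## Study conditions used by the tests and the acceptance script

Phantom hearts use 8 slices of 192x192 px at 8 µm/px effective
resolution (a 0.5 µm/px scan downscaled 16x), annulus outer radius
growing from about 38 to 81 px, fiber fractions 0.01 to 0.10, analysis
windows of 0.04 mm² (25 px), and a hotspot threshold of 0.005 — half
the apical fiber fraction, so even the sparsest slice registers
hotspots and the profile is sensitive to density and ring size jointly.
Ring phantoms use 240–300 px canvases with 2–3 fragments. These sizes
keep every property exercised (partial windows, multi-window lattices,
multi-fragment seams) at desk scale.

## Known limitations

* No pyramidal/whole-slide (SVS) reader: slides enter as plain PNG/TIFF
  rasters (with `mpp` supplied when the file lacks resolution tags).
  For gigapixel scans, export a downscaled level first.
* Seam correction handles gaps and small overlaps driven by rigid
  misplacement; it does not model large elastic tears, and it refuses
  (flagging instead) corrections that would move more than the
  configured share of section area.
* The TPS image inverse is approximate (swapped-pair refit); exactness
  holds for the linear stages and for forward point mapping.
* Metrics depend on convention (bin edges, adjacency, thresholds,
  working downscale); absolute values are only comparable within one
  configuration.
* One ring per reference slice is assumed when fusing; slice-thickness
  mismatch between histology and the reference volume is not modelled.
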