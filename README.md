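# innervmap

Quantitative mapping of myocardial innervation from immunostained
whole-slide images, and its reconstruction into a 3D model.

## The problem

The spatial organisation of nerve fibers inside the heart wall is still
poorly characterised, largely because histology — the only way to see
the fibers — destroys the organ's geometry: each 4 mm transverse
ventricular ring is cut open, split into cassette-sized fragments,
sectioned, stained (UCHL-1/PGP9.5 with brown DAB chromogen on blue
hematoxylin) and scanned as independent slides. `innervmap` is the
computational counterpart of that dissection. It

1. **quantifies** nerve-fiber density per slide: tissue/background
   segmentation, HSV colour classification of DAB-positive pixels
   inside the tissue mask, and sliding-window density mapping with a
   fixed logarithmic heatmap overlay;
2. **reassembles** complete myocardial rings from fragment images using
   explicit layout maps, with a bounded elastic seam correction (the
   tissue area may change by at most 1%, otherwise the correction is
   refused and flagged);
3. **registers** each ring onto the matching slice of a reference
   anatomical volume (e.g. post-mortem MRI) via landmark-based
   Procrustes (rigid/similarity) and regularized thin-plate-spline
   transforms;
4. **fuses** the registered density maps into a 3D innervation volume
   (NIfTI export, missing-slice interpolation); and
5. **profiles** the result: per-slice Shannon entropy, Moran's I, mean
   nearest-neighbour distance and hotspot volume along the apex-to-base
   axis, with region summaries (mean and 95% t-interval).

The per-window density is simply

```
density(w) = (# fiber pixels in w) / (# pixels in w)
```

for non-overlapping windows of a fixed physical area (conventionally
1 mm²), with windows converted to pixels through the slide's
microns-per-pixel resolution. Moran's I uses binary contiguity weights
on the window lattice,

```
I = (N / W) * sum_ij w_ij (x_i - x̄)(x_j - x̄) / sum_i (x_i - x̄)²,
```

and entropy is the natural-log Shannon entropy of the window-density
histogram over the heatmap's logarithmic bins.

A seeded phantom generator produces synthetic slides (Bernoulli
per-pixel fiber truth), fragmented rings and tapered, apex-to-base
graded heart stacks with exact ground truth, so the entire pipeline is
testable with no external data.

## Worked example

```r
library(innervmap)

# an 8-slice phantom heart with a linear innervation gradient
ph <- make_phantom_heart(n_slices = 8, seed = 7)
sl <- ph$slides[[5]]

tissue <- compute_tissue_mask(sl$slide)
fibers <- classify_fibers(sl$slide, tissue)          # default UCHL-1 DAB HSV range
dm     <- compute_density_map(fibers, window_mm2 = 0.04, tissue = tissue)

print(tissue); print(fibers); print(dm)
#> <tissue_mask 192 x 192, 13665 tissue px (37.1%)>
#> <fiber_mask 'phantom_seed12' 192 x 192, 555 fiber px, 8 um/px>
#> <density_map 8 x 8 windows of 25 px (0.04 mm^2), mean density 0.02467>

shannon_entropy(dm)                  # 1.197 — heterogeneity of the window densities
morans_i(dm$density, dm$covered)     # -0.045 — no spatial clustering (field is uniform)
mean_nnd(fibers)                     # 2.142 px — mean spacing between fiber pixels
hotspot_volume(dm, 0.005)            # 13750 px — area of windows above threshold
```

The slice carries 555 fiber pixels in 13,665 tissue pixels (slice 5 of
the 0.01→0.10 gradient), the 25 px analysis windows average 2.5%
density, and Moran's I near zero correctly reports that the phantom's
uniform field has no spatial structure. `run_pipeline()` chains the
same steps over a whole stack (plus ring assembly, registration, fusion
and the profile CSV/plots) from one YAML/JSON config; a thin
command-line front-end lives at `inst/cli/innervmap.R`:

```sh
Rscript inst/cli/innervmap.R phantom --out ph --seed 3 --slices 8
Rscript inst/cli/innervmap.R run --config cfg.yaml
```

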