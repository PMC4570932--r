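---
title: "Quantifying mitochondrial membrane potential and network morphology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying mitochondrial membrane potential and network morphology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The two readouts

`mitomorph` quantifies two complementary aspects of mitochondrial state in
single cells carrying a dual fluorescent reporter:

1. **Membrane potential (MMP)** — a green marker is imported into
   mitochondria regardless of the inner-membrane proton gradient and marks
   mitochondrial structure; a red marker is imported in proportion to the
   gradient and redistributes to the cytosol when the potential collapses
   (uncoupler treatment, loss of mtDNA, some fission/fusion mutants). The
   readout is the per-cell Pearson correlation coefficient (PCC) of the two
   channels over the cell's voxels, optionally accompanied by the
   R-squared of the least-squares fit of red on green (`r2 = pcc^2` for a
   single predictor, asserted in the tests).

2. **Network morphology** — from the green channel of a 3D stack the
   package extracts connected mitochondrial objects and computes volume,
   surface area, five shape descriptors and the fragmentation index *f*.

Both readouts run on multi-channel TIFF z-stacks with user-supplied voxel
spacing `(dz, dy, dx)` in micrometres; the axial spacing may differ from
the (isotropic) in-plane spacing.

# Membrane potential by co-localisation

For each cell ROI the analysis mask is built by summing the two
fluorescence channels, blurring each z-slice with a Gaussian of
`sigma = 5` pixels, and applying Otsu's threshold. The PCC is then computed
in 3D over all masked voxels of the cropped cell. Decisions behind that
default, where the procedure was genuinely open:

* *Which channel defines the mask?* The green + red sum: the sum stays
  informative when the red marker is delocalised, whereas a red-only mask
  would collapse exactly in the condition of interest.
* *2D or 3D blur?* Per-slice 2D by default, matching the display-based
  convention of slice-wise image analysis; `mode = "3d"` additionally
  convolves along z with sigma scaled by `dx/dz` so the physical smoothing
  radius is isotropic.
* *Background subtraction?* None by default. Background present in both
  channels contributes a correlation floor; that floor is part of the
  measurement's behaviour, and whole-cell (`mask_mode = "all"`) analysis
  reproduces it. The Otsu mask mode largely removes it.
* Cells whose masked intensities have zero variance are reported with an
  error flag rather than silently dropped; cells with more than 1% of
  voxels at the detector ceiling are flagged as saturated but retained.

`min_cells_power()` estimates, from two groups of per-cell PCCs, the
smallest per-group n at which a two-sample t-test reaches a requested
power at the observed pooled-SD effect size. The default uses the
normal-approximation formula `n = 2 ((z_{1-a/2} + z_power) / d)^2`;
`method = "exact"` searches `stats::power.t.test()`.

# Morphology

## Object extraction

The green channel is thresholded by Otsu's method: a 256-bin histogram
over `[min, max]`, the threshold maximising the between-class variance,
ties broken toward the lowest threshold (deterministic, and exactly
scale-equivariant: multiplying all intensities by a positive constant
scales the threshold). Foreground is `intensity > threshold`. 32-bit input
stacks are linearly rescaled to the 16-bit range before thresholding.

Connected components are labelled with 26-connectivity by default: thin
tubules sampled at coarse z-spacing stay connected through voxel corners
where 6-connectivity would fragment them. Objects smaller than
0.1 µm³ are excluded as likely artefacts (an object exactly at the
threshold is retained); objects touching the ROI border are kept, since
ROIs are drawn around whole cells.

## Surface area

Surface voxels are those with at least one face not shared with another
voxel of the same object. Each exposed-face configuration is assigned to
one of 15 classes, invariant under the grid symmetries that preserve the
z axis so the classification remains valid for anisotropic sampling. Of
the 17 symmetry orbits of exposed-face configurations, two pairs of rare,
geometrically equivalent configurations are merged (the two five-face
configurations; the two one-voxel-thick rod shafts) to give exactly 15
classes.

A class's weight is a function of the spacing:
`w = alpha * (exposed lateral-face area) + beta * (exposed z-face area)`.
Summing raw exposed-face areas overestimates smooth surfaces by ~50% (the
staircase effect), while flat axis-aligned faces are exact, so no single
multiplicative factor per class can serve both regimes. The shipped
`alpha`/`beta` coefficients were calibrated once — non-negative least
squares on relative residuals, refined toward the minimax solution by
p-norm continuation — against the analytic areas of digitised spheres
(radii 5–40 voxels at z anisotropies 1.0 and 1.6) and isotropic
axis-aligned boxes, then frozen; `calibrate_surface_weights()` reproduces
the procedure. The worst relative error over the calibration shapes is
3.9%, and the tests hold spheres (r = 5, 10, 20, 40 voxels, both
anisotropies) and boxes to 5%. **Limitations:** accuracy degrades outside
the calibrated anisotropy range (above ~1.6, e.g. coarse widefield
z-sampling of high-NA data) and for very small objects (radius below
~8 voxels at intermediate anisotropies), where digitisation is erratic;
those regimes may exceed 5%.

## Shape descriptors

With voxel centres at `(index - 0.5) * spacing` in physical coordinates
and `d(k)` the distance of voxel `k` from the object centroid:

* **Compactness** `= var(d) / V` (1/µm) — low for balls, high for tubes;
  the tubularity axis.
* **Distribution isotropy** — for each grid axis, the population variance
  of the voxels' distances from that axis through the centroid; the
  descriptor is the sum over the three axis pairs of `max/min` moment
  ratios. It is always ≥ 3 and equals 3 when the three moments coincide.
  The ratios are deliberately oriented `max/min` (not a fixed order) so
  the minimum is attained by rotationally symmetric objects regardless of
  whether they are prolate or oblate. An object with a zero moment (e.g.
  a perfect one-voxel-wide line, or any rod whose cross-section places
  every voxel equidistant from the long axis) is reported as `Inf` with a
  `degenerate` attribute rather than an error.
* **Isoperimetric quotient** `= V / ((4/3) pi (A / 4 pi)^(3/2))` and
  **sphericity** `= pi^(1/3) (6V)^(2/3) / A`, both 1 for a perfect sphere;
  algebraically `sphericity^3 = IPQ^2`. Because `A` is an estimate,
  discretisation can push these slightly above 1 for near-spherical
  objects.
* **Radius variance** (µm²) — the population variance of surface-voxel
  distances from the centroid, approaching 0 for a sphere. Its decrease
  toward 0 with sphere radius, normalised by the squared mean surface
  radius, is what `scripts/acceptance.R` recomputes.

All variances are population variances (divide by n), matching the
descriptors' defining sums over all n voxels.

Per-cell feature summaries weight each object by its surface area before
averaging: small fragments are inherently compact and spherical, and
unweighted means would over-represent them.

## Fragmentation

Each object's relative volume `Vs` is its percentage of the cell's total
mitochondrial volume (post-filter; the values sum to 100). The
fragmentation index `f` is the sum of `Vs` over objects with
`Vs <= 20`: the percentage of mitochondrial volume held in small
fragments. The threshold is inclusive (`<= 20`, configurable), following
the defining formula. Population summaries report mean ± SEM of per-cell
`f` over cells (30 cells is the conventional population size) and pool all
objects' `Vs` into a width-10 histogram (`[0,10), ..., [90,100]`), the
population "footprint".

# The synthetic scene generator

Real validation images cannot ship with the package, so every pipeline
stage is exercised on ground-truthed synthetic scenes. A scene is an
ellipsoidal "cell" (92% of each grid half-extent) containing spherical or
capsule-shaped (tubular, aspect ratio ~6, mostly in-plane) mitochondrial
objects on a 24 × 64 × 64 grid at `(0.16, 0.1, 0.1)` µm spacing — yeast-like
cell dimensions, 1.6-fold z anisotropy. Channels are composed as:

* green = background (10 counts) + foreground (200 counts) on the objects;
* red = background + `(1 - phi)` of the foreground on the objects, with the
  delocalised fraction `phi` of the mitochondrial signal spread uniformly
  over the cytosol (total red signal conserved) — `phi = 0` is an intact
  potential, `phi = 1` a fully collapsed one;
* a Gaussian PSF of 1 in-plane pixel (z sigma scaled by `dx/dz`), then
  Poisson shot noise and Gaussian read noise (SD 2% of foreground). The
  noise level keeps Otsu segmentation stable; seeds are mandatory and
  identical specs produce identical stacks.

`make_fragmentation_series()` designs each cell's `Vs` partition
analytically *before* rasterisation so the designed `f` is exact: a
non-fragment remainder (kept well above the 20% cutoff) plus equal
fragments kept well below it (at most 16%), realised as non-overlapping
objects (0.35 µm surface gap, so the PSF cannot merge neighbours) with a
total volume of 3 µm³ per cell. Targets whose remainder would itself fall
at or below the cutoff (e.g. 90) are rejected as infeasible. Validation
uses 30-cell series at targets 0, 20, 45 and 100 and requires the
measured `f` within ±5 of the design — margins chosen so that a fragment's
measured `Vs` never crosses the 20% cutoff under blur and noise.

What the generator does **not** emulate: structured-illumination
reconstruction artefacts, depth-dependent PSF widening, autofluorescence,
cell-to-cell expression variability, or realistic branched network
topology. Passing round-trip tests therefore demonstrates correctness of
the measurement chain on idealised geometry, not robustness to every
property of real microscopy data.

# Workflows, configuration, provenance

`run_morphology()`, `run_coloc()` and `run_simulate()` (and the
`exec/mitomorph` command-line wrapper with sub-commands `morph`, `coloc`,
`simulate`) tie the stages together. All tunable parameters live in
`run_config()` — mask blur sigma (5 px), minimum object volume (0.1 µm³),
fragmentation cutoff (Vs ≤ 20%), Vs bin width (10), connectivity (26) —
and the resolved configuration is serialised as JSON next to every output,
so a run can be reproduced bit-for-bit (the morphology chain is fully
deterministic; simulation outputs embed their seed). Per-cell failures are
logged and flagged while the run continues; only run-level failures exit
non-zero.

# Numerical conventions

* Coordinates are `(z, y, x)`; ROIs are 0-based half-open boxes in the
  sidecar files (unambiguous composition), converted to R's 1-based
  indexing internally.
* Otsu uses 256 bins over `[min, max]`, lowest-threshold tie break;
  constant volumes are an error ("no separable classes").
* Distances use voxel centres times spacing; centroids are arithmetic
  means of voxel centres.
* Surface-area coefficients are frozen constants; no randomness exists
  anywhere in the morphology chain.
* Validation problem sizes: spheres up to r = 40 voxels (84³ grids),
  30-cell synthetic populations on 24 × 64 × 64 grids — sizes at which
  every structural property above is measurable in minutes on a laptop.
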