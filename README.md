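# mitomorph

Quantification of mitochondrial membrane potential and network morphology
in single cells, from multi-channel 3D fluorescence microscopy stacks.

Mitochondria form networks whose shape and whose inner-membrane potential
(MMP) respond — sometimes independently — to stress, metabolic state and
fission/fusion genetics. `mitomorph` measures both in the same cells
carrying a dual reporter: a green marker imported into mitochondria
independently of the MMP (structure), and a red marker imported in
proportion to the MMP (function). It is written for microscopists and
yeast cell biologists who want numerical, comparable readouts instead of
visual categorisation of network morphologies.

## What it computes

**Membrane potential.** Per cell, the Pearson correlation coefficient of
the red and green channels over an Otsu-defined cell mask (channels
summed, Gaussian blur σ = 5 px per slice). An intact potential gives
near-perfect co-localisation; a collapsed one delocalises the red marker
into the cytosol and the PCC drops. `min_cells_power()` estimates the
cells-per-group needed to resolve a difference between conditions.

**Network morphology.** From the green channel: Otsu segmentation, 3D
connected components (26-connectivity), exclusion of objects < 0.1 µm³,
and for every object `p(k)` with centroid `c`, volume `V` and surface
area `A`:

| Descriptor | Definition |
|---|---|
| Compactness | `var(d(k)) / V`, `d(k) = ‖p(k) − c‖` |
| Distribution isotropy | Σ over axis pairs of max/min second-moment ratios (≥ 3) |
| Isoperimetric quotient | `V / ((4/3)π (A/4π)^{3/2})` |
| Sphericity | `π^{1/3} (6V)^{2/3} / A` |
| Radius variance | `var(r(j))` over surface voxels `j` (0 for a sphere) |
| Fragmentation index | `f = Σ { Vs : Vs ≤ 20 }`, `Vs = 100·V_object/V_total` |

Surface area comes from a 15-class surface-voxel classification
(exposed-face configurations, valid for anisotropic z sampling) with
correction weights calibrated against analytic spheres and boxes. Per-cell
feature means are surface-area-weighted; populations are summarised as
mean f ± SEM plus a Vs-decile volume histogram. A seeded synthetic scene
generator (`scene_spec()`, `make_fragmentation_series()`,
`delocalisation_series()`) produces ground-truthed dual-channel stacks for
validation.

## Worked example

Six synthetic cells designed at fragmentation index f = 45, analysed by
the full morphology chain, plus an MMP series at increasing delocalised
fractions of the red marker:

```r
library(mitomorph)

series <- make_fragmentation_series("spherical", target_f = 45,
                                    n_cells = 6, seed = 42)
cells <- lapply(seq_along(series), function(i)
  cell_morphology(segment_mitochondria(series[[i]]$scene$stack),
                  cell_label = paste0("cell_", i)))
pop <- population_summary(cells)
sprintf("mean f = %.1f +/- %.1f (SEM, n = %d cells)",
        pop$mean_f, pop$sem_f, pop$n_cells)
#> mean f = 44.6 +/- 0.1 (SEM, n = 6 cells)

print(cells[[1]])
#> cell_morphology: 4 object(s), total volume 3.093 um^3, f = 44.9%
round(cells[[1]]$weighted_features, 4)
#>      volume_um3     surface_um2     compactness        isotropy
#>          1.0318          4.8603          0.0157          3.0325
#>             ipq      sphericity radius_variance
#>          0.9799          0.9863          0.0011

dl <- delocalisation_series(phis = c(0, 0.5, 1), seed = 7)
for (s in dl) {
  stk <- s$scene$stack
  pcc <- pearson_cc(get_channel(stk, "gfp"), get_channel(stk, "mcherry"),
                    cell_mask(stk))
  cat(sprintf("phi = %.2f  ->  PCC = %.3f\n", s$phi, pcc))
}
#> phi = 0.00  ->  PCC = 0.979
#> phi = 0.50  ->  PCC = 0.957
#> phi = 1.00  ->  PCC = 0.017
```

The measured population f (44.6) recovers the designed 45 within the
rasterisation/noise error; the per-cell weighted descriptors show
near-spherical fragments (sphericity ≈ 0.99, isotropy ≈ 3); and the PCC
falls from 0.98 (intact potential) to ~0 (fully delocalised red marker)
— on real images a background-driven floor around 0.5 appears instead
when correlating over whole cells rather than the Otsu mask.

Real stacks enter through `read_stack()` (TIFF + spacing + channel
names) with ROI sidecar CSVs, or through the CLI:
`exec/mitomorph morph|coloc|simulate --stack s.tif --rois r.csv --out dir`.

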