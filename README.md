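# spinemesh

Cytoskeleton network morphometrics for electron tomograms of dendritic
spines.

Dendritic spines are sub-micron protrusions whose shape is maintained by a
dense mesh of actin filaments and cross-linking proteins. `spinemesh` turns
a 3D tomogram volume (≈2 nm voxel pitch) plus a compartment label mask
(cytosol / membrane / ER / PSD / mitochondria) into a network graph of
filament branches and junctions, and computes the morphometrics that
characterize such meshes. It is written for microscopists and modellers who
want reproducible, automated mesh statistics — and for anyone who needs a
fully synthetic, ground-truthed test bed for skeletonization pipelines.

## What it computes

The pipeline is: mask the cytosol → Gaussian smoothing (σ = 2 nm) → local
adaptive threshold (Niblack form, `T = m − k·s` over a 20 nm window,
k = 0.1) → exact Euclidean distance transform → distance-ordered,
connectivity-preserving thinning → stub pruning (4 nm) → attributed
multigraph. On the graph:

* branch arc lengths (smoothed curves, sliding weights (1,2,3,2,1)/9) and
  tortuosity `t = arc/chord`, with the isosceles-triangle reading
  `θ = acos(1/t)`;
* junction ranks and densities (rank ≥ 3 nodes per µm³ of cytosol);
* branching-angle triples at rank-3 nodes (PCA tangents, sorted angles,
  standardized near-planar frames);
* orientations relative to the membrane via the gradient of the distance
  transform, folded to [0°, 90°];
* elementary loops (per node, Dijkstra between incident-branch ends),
  loop planarity/elongation by PCA, and the pore-size estimate
  `c/(π·ε) − d_filament`;
* minimum spanning trees under 1/length weights with rank-2 merging
  (cross-link removal);
* analytic/Monte-Carlo null models: sin(α) random orientations
  (mean 57.3°), random branching-angle triples
  (53.6°/95.3°/121.1°, SDs 24.4°/27.1°/30.9°), rigid rods near a wall,
  Euler buckling `F = π²κ/L²`, and random branch-end placement.

A synthetic spine phantom generator (`spine_phantom_spec()`,
`generate_spine_geometry()`, `grow_network()`, `render_tomogram()`)
produces spine-shaped masks with a known, contact-resolved filament
network and tomogram-like volumes, so the whole chain is testable against
ground truth.

## Worked example

```r
library(spinemesh)

spec <- spine_phantom_spec(head_radius = 100, neck_length = 120,
                           neck_radius = 40)
mask <- generate_spine_geometry(spec, seed = 2)
net  <- grow_network(mask, spec, seed = 1)      # ground truth
network_summary(net, mask)
#>   n_junctions junction_density_per_um3 mean_branch_length mean_tortuosity
#> 1         627                 131306.9           15.13433        1.211922
#>   rank3_fraction
#> 1      0.4704944

vol <- render_tomogram(net, mask, psf_sigma = 1.2, noise_sd = 0.15,
                       z_drift_amplitude = 0.1, seed = 101)
out <- run_pipeline(analysis_config(), vol, mask)
out$summary[, c("n_nodes", "mean_branch_length_nm",
                "junction_density_per_um3", "mean_loop_length_nm")]
```

The ground-truth summary above says the phantom carries 627 junctions
(131×10³ µm⁻³ — inside the 91–181×10³ band observed in spine tomograms)
with a mean inter-junction branch length of 15.1 nm. The
pipeline bundle reports the same quantities measured from the rendered
volume; on phantoms like this one the junction count is recovered within
about 15 %, the mean branch length within about 15 %, and the rank-3
fraction within a few percentage points (see the test suite).

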