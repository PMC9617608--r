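---
title: "Cytoskeleton network morphometrics from spine tomograms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cytoskeleton network morphometrics from spine tomograms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemesh)
```

## The problem

Dendritic spines are sub-micron protrusions of neuronal dendrites whose
shape is maintained by a dense mesh of actin filaments and associated
proteins. Electron tomography can image this mesh *in situ* at a binned
voxel pitch of about 2 nm, where an 8 nm actin filament is a few voxels
wide. `spinemesh` turns such a tomogram, plus a co-registered compartment
mask (cytosol, membrane, ER, PSD, mitochondria), into a network graph of
filament branches and junctions, and computes the morphometric descriptors
that characterize the mesh: branch lengths and tortuosity, junction ranks
and densities, branching-angle geometry at bifurcations, orientations
relative to the membrane, elementary loops (the "pores" of the mesh), and
minimum-spanning-tree reductions of the network.

Because the package cannot ship tomograms, it also contains a first-class
synthetic-data module: a spine phantom generator with a known ground-truth
filament network and a forward imaging model. Every stage of the pipeline
is validated against these phantoms.

## The pipeline

1. **Masking.** Voxels outside the cytosol are set to `NA` and excluded
   from all statistics (`mask_intracellular()`). Organelle and PSD voxels
   count as boundary everywhere.
2. **Smoothing.** Isotropic Gaussian smoothing with `sigma_smooth = 2` nm
   (one voxel at the default pitch). Masked voxels are excluded through a
   renormalized convolution, so no intensity bleeds across the membrane.
   Smaller kernels leave too much voxel noise; larger ones start erasing
   8 nm filaments.
3. **Local-threshold binarization.** For every voxel the mean `m` and SD
   `s` of its 20 nm cubic window are computed (masked voxels excluded);
   the voxel is foreground iff its absorption intensity strictly exceeds
   `T = m - k*s` with `k = 0.1`. The threshold is local because tomogram
   luminance drifts on a scale of tens of nanometres along z. Positive `k`
   lowers the threshold below the local mean, which protects dim stretches
   of filament from being cut. A `"mean-offset"` form (`T = m - k`, with
   `k` in intensity units) is also available. Constant windows produce no
   foreground (strict inequality), and windows with fewer than 8 valid
   voxels classify as background.
4. **Distance-transform-ordered thinning.** The Euclidean distance
   transform of the foreground is computed (exact, via the separable
   lower-envelope algorithm), and voxels are deleted in ascending distance
   order. A voxel survives if it is an endpoint (at most one foreground
   neighbour) or if its removal would break the foreground locally: the
   default rule demands that the foreground in its 26-neighbourhood stay
   in one 26-connected component. This keep rule preserves every filament
   cycle exactly — a cycle voxel's two neighbours are locally disconnected,
   so it can never be removed — while collapsing membrane-like voxel
   sheets (which arise where tube halos merge) into curves. The stricter
   classical (26,6) simple-point test, which additionally preserves
   tunnels and cavities of the voxel set, is available as
   `rule = "simple-point"`. Ties in the distance ordering are broken in a
   fixed lexicographic scan order, so the skeleton is deterministic.
   Out-of-volume voxels count as foreground, so filaments exiting the
   imaged block can never be detached from its faces.
5. **Stub pruning.** Terminal chains whose own extent is below 4 nm are
   removed once; they are almost exclusively noise artifacts.
6. **Graph conversion.** Voxels with more than two neighbours are junction
   voxels; 26-adjacent junction voxels are clustered into a single node at
   their centre of mass. Maximal chains of degree-2 voxels become branches;
   their polylines are smoothed with the sliding kernel (1,2,3,2,1)/9
   (truncated and renormalized near the ends, end points pinned to the
   node positions). Branches touching the bounding-box faces are flagged
   `excluded` and are kept for connectivity but skipped by length and
   tortuosity statistics, since they are artificial cuts.

Everything downstream operates on the graph: `node_rank_distribution()`,
`node_density()`, `branching_angles_rank3()`, `branch_orientations()`,
`elementary_loops()`, `minimum_spanning_tree_prune()` +
`merge_rank2_nodes()`, and the distance-resolved profiles
(`profile_vs_distance()`).

## Reference (null) models

Measured distributions are interpreted against analytic or Monte-Carlo
references in `null_models`:

* uniformly random 3D orientations folded to [0°, 90°] have density
  sin(α) and mean exactly 1 rad = 57.2958° (median 60°);
* three independent uniform unit vectors give sorted pairwise angles with
  means ≈ 53.6°, 95.3°, 121.1° and SDs ≈ 24.4°, 27.1°, 30.9°
  (`random_branching_angle_reference()`; uniform directions are sampled as
  normalized Gaussian triples, which is exactly uniform on the sphere);
* a rigid rod of length L whose centre sits at distance d from a flat wall
  has mean folded angle `(1 - sin a0 + a0 cos a0)/cos a0` rad with
  `a0 = acos(min(1, 2d/L))`, rising to 90° at the wall;
* the Euler force to buckle a filament of length L is `pi^2 kappa / L^2`
  (κ = 0.040 pN µm² for F-actin: 0.4 pN at 1 µm);
* a branch of tortuosity t, drawn as an isosceles triangle whose equal
  sides sum to the arc length, has base angle `acos(1/t)` (30° at 1.15);
* the mesh pore estimate treats the typical elementary loop as an ellipse
  of circumference c and axis ratio ε: short-axis diameter
  `c/(pi ε) - filament_diameter`.

## The synthetic phantom and what it emulates

`generate_spine_geometry()` builds a spherical head on a cylindrical neck
opening onto a flat dendrite face, with a one-voxel membrane shell and
optional ER-like inclusions; head and neck voxels carry domain tags.
`grow_network()` then grows filaments as persistent random walks (3 nm
steps; turning noise calibrated once, by simulation, to the target mean
tortuosity). Three processes shape the network:

* **branching** into 3-way junctions at a Poisson rate along the filament,
  beyond a refractory spacing of one filament diameter (8 nm) — junctions
  closer together than the filament width are not physically separable
  objects; outgoing directions follow the chosen angle law
  (`planar-70-110-180`, `isotropic`, or `empirical` sorted-angle normals);
* **fusion**: a growing tip that comes within the contact-capture radius
  (default 1.75 filament diameters = 14 nm) of an existing filament
  terminates on it, creating a junction — or attaches directly to an
  existing junction when the contact lands next to one. This is what makes
  the ground truth a *contact-resolved* network: at tomogram resolution,
  two filaments passing within a dilated tube diameter are one connected
  object, and a crosslinked gel really is connected at such contacts;
* **membrane deflection**: a filament reaching the membrane continues
  parallel to it with probability 0.6 and anchors otherwise, so branch
  ends concentrate near the membrane, as observed in spine meshes. Higher
  deflection probabilities overweight the cortical shell relative to the
  bulk mesh.

Growth stops when the junction-density budget is met; unfinished tips are
retracted (their rank-2 remnants merged away) so the laid filament length
tracks the branch census. Because branching, fusion and the junction
budget interact, the generator measures its own output and recalibrates
the branch rate and budget once or twice against the requested
branch-length mean and node density; defaults land within a few percent
of the targets (15.4 nm, 1.3×10⁵ µm⁻³). Cross-links — short extra edges
from a junction to a nearby filament — are added at a per-junction rate
of 0.35 afterwards.

The forward model (`render_tomogram()`) draws filaments as solid tubes of
8 nm diameter and unit absorption contrast, blurs them with a Gaussian
PSF, adds a sinusoidal luminance drift along z and i.i.d. voxel noise, and
clips. A `"luminance"` polarity flag negates the volume to mimic raw EM
(dark fibrils); the pipeline negates it back on entry.

### What the phantoms do and do not show

Passing the recovery tests shows the chain
binarize→thin→graph→statistics is faithful when its assumptions hold:
tube-like filaments of known diameter, windows that always contain some
filament, and junctions separated by at least about a filament width. The
phantoms do not emulate stain granularity, missing-wedge anisotropy,
section-interface artifacts, or molecular identity; tests on them say
nothing about segmentation quality on such data.

Two honest limitations surfaced during phantom calibration and are worth
stating:

* **Junction rank mix.** A contact-resolved network at 1.3×10⁵
  junctions/µm³ with 8 nm tubes necessarily contains many rank-4/5
  junctions (nearby contacts coalesce); the generator's junction mix is
  roughly 45–50% rank-3, versus the ~72% reported for spine meshes. Rank
  mix and contact completeness cannot both be imposed at this density;
  the package prioritizes contact completeness because it is what makes
  ground truth recoverable — and measurable rank fractions comparable
  between truth and reconstruction.
* **Branch splitting at the resolution limit.** Voxel noise toggles the
  halo surface of the binarized tubes, and the resulting skeleton splits
  some branches at sub-filament scale. The cumulative branch length is
  recovered to a few percent, but the *mean* branch length is diluted by
  these sub-8 nm splinters: about −14% at SNR 8 and −15% at SNR 5.5 on the
  default phantom. Junction counts and rank fractions are much less
  sensitive.
* **Threshold form in structure-free regions.** With `T = m - k*s` and
  k > 0, a window containing only noise marks ~54% of its voxels as
  foreground no matter how small the noise is (the threshold scales with
  s). The method therefore presupposes filaments within every window —
  true of real spine cytosol and of phantoms at tissue-like densities,
  but a sweep of k over [-0.1, 0.4] dilates the foreground until
  neighbouring tubes merge, so the skeleton's cumulative branch length is
  stable only over a narrower k band (about [-0.1, 0.1] on phantoms) than
  the full range reported for tissue data.

## Numerical choices

* Coordinates: arrays are (x, y, z) with voxel centres at
  `origin + (index - 0.5) * pitch`; lengths in nm, angles in degrees,
  densities in µm⁻³.
* The distance transform is the exact Euclidean distance to the nearest
  background voxel centre (a lone foreground voxel reads one pitch).
* Thinning tie-breaks are lexicographic and fixed; the pipeline is
  deterministic given `rng_seed`.
* Tangents at a junction use the first principal direction of the first
  three polyline points, oriented away from the node; the standardized
  rank-3 frame sends the vector with the largest summed angle to
  (-1,0,0), places the intermediate-angle vector in the z = 0 plane with
  positive y, and reflects the third vector to non-negative elevation.
  Ties are broken by branch id; collinear frames are excluded.
* Elementary loops follow the removed-node construction: for each node,
  Dijkstra (weights = branch arc length) between the far ends of each
  pair of its incident branches, plus the two incident branches;
  deduplication is by branch-id set, so the loop list is independent of
  iteration order. Parallel edges between a node pair are handled by
  path-finding on the full multigraph; self-loops count as 1-node loops.
* Loop elongation ε is the axis-length (SD) ratio of the first two
  principal components; `use_sd_ratio = FALSE` gives the raw variance
  ratio.
* The MST uses weights 1/arc-length per connected component, so short
  branches (putative cross-links) are removed preferentially.
* The spine neck width is estimated automatically as twice the minimum
  distance-transform value over the medial axis of the neck domain — a
  replacement for manual minimum-diameter measurements.
* Degenerate inputs have defined behaviour: constant volumes binarize to
  empty foreground; zero-span branches have undefined tortuosity and are
  excluded and counted; masks without cytosol raise structured errors
  before any output is written.

## Problem sizes

The test-suite phantoms use heads of 70–100 nm radius and necks of
30–40 nm radius at 2 nm pitch (volumes of roughly 10⁶ voxels,
500–650 junctions), which exercise every stage in minutes on one CPU.
These sizes are a deliberate scaling-down of tissue-scale spines
(0.01–0.07 µm³); all statistics are intensive (densities, fractions,
means), so they transfer across sizes.
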