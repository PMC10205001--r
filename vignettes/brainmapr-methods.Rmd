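---
title: "brainmapr: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{brainmapr: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

brainmapr maps labeled cells in cleared-brain light-sheet stacks onto a
hierarchical reference atlas and quantifies them as region counts and
densities, voxel-level heatmaps and group statistics, and cortical
flatmap/depth profiles. This vignette documents the models behind each
stage, the tunable parameters and their defaults, the numerical choices,
and what the synthetic test bed does and does not demonstrate about real
data.

## Coordinate conventions

Every coordinate tuple in the API and in every CSV the package reads or
writes is `(x, y, z)` in physical micrometres of a *named* space
(`"stack"`, `"atlas"`, `"flatmap"`). Volumes are stored as R arrays with
`dim = c(nx, ny, nz)`; the physical position of voxel `(i, j, k)` (1-based)
is `origin + (i-1, j-1, k-1) * spacing`, and a voxel *owns* the half-open
box `[center - spacing/2, center + spacing/2)` on each axis, so every point
belongs to exactly one voxel and region lookup is unambiguous. Cell tables
carry their space as an attribute and every consumer checks it; a table of
raw stack coordinates can never be silently treated as atlas coordinates.

Missing spacing metadata is always an error, never a default of 1 µm:
densities are reported in cells/mm³ and silently wrong spacing would
corrupt them by orders of magnitude. TIFF has no trustworthy spacing tag,
so TIFF input requires explicit spacing (or the JSON sidecar the package
itself writes); NRRD carries spacing in its header.

## Synthetic data: what it emulates

The generator exists so that every downstream stage has exactly known
ground truth with no downloads. It emulates:

* **A reference atlas** as a hemispherical cortical shell (outer radius
  400 µm, inner 250 µm, 10 µm voxels by default) partitioned into
  azimuthal sectors × radial layers under an "Isocortex" parent, plus
  optional spherical subcortical nuclei. The hemisphere is deliberately
  chosen over a realistic cortex because its Laplace depth potential has
  the closed form $\varphi(r) = \frac{1/R_o - 1/r}{1/R_o - 1/R_i}$, and a
  rectangular-slab variant (`make_slab_masks()`) has the exactly linear
  solution — both serve as analytic oracles for the flatmap stage.
* **Cell populations** as homogeneous Poisson processes per region: count
  ~ Poisson(density × region volume), positions uniform inside the
  region's voxels, true region id recorded per cell.
* **Light-sheet stacks**: each soma is a 3D Gaussian (default σ = 5 µm,
  about half a soma diameter); the background is a constant (100 counts)
  plus a smooth linear gradient emulating slowly varying tissue
  autofluorescence; noise is Poisson on the expected counts plus Gaussian
  read noise (sd 2). The default amplitude of 82 gives peak SNR ≈ 8 over
  the background noise (√100 + read), comfortably detectable but
  degradable for stress tests. The stack lives in its own space related to
  atlas space by a configurable, known affine warp.
* **Clicked landmarks**: moving points sampled in the brain, fixed points
  = warp(moving) + per-axis Gaussian jitter emulating human clicking
  error; coplanar configurations are rejected by construction.

Not modeled: light-sheet stripe artifacts, depth-dependent attenuation,
anisotropic PSFs, autofluorescent vasculature, or tissue deformation
beyond an affine/TPS warp. Passing tests therefore demonstrate the
correctness of the *computational* chain, not robustness to every
real-world imaging artifact; detection parameters will always need
per-dataset tuning on real stacks.

All stochastic calls take an explicit seed; identical inputs give
bit-identical outputs.

## Cell detection

The intensity-based chain is: grayscale opening (ball structuring element,
radius 15 µm) subtracted from the stack to remove slowly varying
background; difference-of-Gaussians band-pass (σ 3/9 µm); h-maxima seed
detection (via morphological reconstruction); marker-controlled watershed
on the negated band-passed image above a global threshold; size and
intensity filtering; intensity-weighted centroids in physical µm.

All length parameters are µm and are converted per axis by the stack
spacing, so anisotropic acquisitions (e.g. 2.95/2.95/3 µm) are handled
correctly. Defaults were calibrated once on the synthetic fixtures: the
band-passed noise floor at the default noise model measures ≈1.6 intensity
units (SD), so the seed depth and watershed threshold default to 8 ≈ 5
noise SDs, and the size window [20, 3000] voxels brackets the ≈180-voxel
suprathreshold footprint of a default cell at 3 µm spacing. On real data
these are starting points, nothing more.

Determinism is guaranteed by explicit tie-breaks: seed plateaus reduce to
their lexicographically first voxel in (z, y, x) order; conflicting seeds
within the minimum distance keep the brighter one (same order on ties);
watershed flooding breaks equal priorities first-queued-first-assigned.
Filters use reflected boundaries; note that grayscale opening cannot track
a monotone intensity ramp within one ball radius of the volume border —
background removal is least reliable there.

Machine-learning segmentations from external tools enter through the CSV
import path (`read_cell_csv()`), with explicit column mapping, pixel-to-µm
scaling and optional axis flips; rejected rows are always counted and
reported.

## Landmark registration

Transforms map points *forward*, sample → atlas (the natural direction for
moving cell coordinates; the opposite of the resampling convention used by
intensity-based registration tools), and every artifact records its
from/to spaces.

* `fit_affine()` solves the least-squares 3×4 matrix; ≥ 4 non-coplanar
  active pairs are required and degeneracy is refused with the design
  matrix's condition number.
* `fit_tps()` fits a 3D thin-plate spline with kernel $U(r) = r$ (the
  biharmonic fundamental solution in 3D — *not* the 2D $r^2 \log r$),
  solving the standard augmented system with smoothing weight λ on the
  kernel diagonal. λ = 0 interpolates exactly; affine-generated landmarks
  yield numerically zero kernel weights (polynomial reproduction); as
  λ → ∞ the map converges to the least-squares affine. Fitted weights are
  re-projected onto the side-condition space to remove round-off drift.
* The default pipeline mode is affine-then-TPS-on-residuals with
  λ = 0.001 · n · (mean squared pairwise distance), damping isolated
  clicking errors without stiffening the whole field.

`registration_report()` gives per-landmark residuals and RMS/median/max in
µm — the QC artifact to inspect before trusting any downstream count.
`downsample_stack()` returns a grid whose *physical* coordinates are
unchanged (block-mean for integer factors, Gaussian-prefiltered trilinear
otherwise), so landmarks clicked on the downsampled stack are already
full-resolution physical positions and an entire class of off-by-scale
bugs is eliminated.

## Region assignment and aggregation

Assignment is categorical nearest-voxel lookup under the half-open
ownership rule; there is no interpolation at label boundaries. Cells
outside the volume or in background voxels get region id 0 and their own
"unassigned" row — they are a registration-quality signal and are never
dropped. An exclusion list (e.g. a structure that saturated the detector)
zeroes a region and all its descendants before assignment.

Counts roll up the ontology tree: `n_cells_total(parent) =
n_cells_direct(parent) + Σ n_cells_total(children)`, exactly, in integers.
Volumes come from voxel counts × voxel volume (µm³ → mm³). The density of
a merged region is total cells over total volume — deliberately *not* the
mean of child densities, which would weight small regions incorrectly.

## Voxel heatmaps and group statistics

Voxelization is a point splat (each cell increments its owning voxel;
out-of-bounds cells are counted and reported), so raw counts sum exactly
to the in-bounds cells and the pipeline is linear: the heatmap of a union
of cell sets is the sum of their heatmaps. Smoothing is a separable
Gaussian with σ in µm (default 3 atlas voxels) using zero-padded
boundaries, which conserves total mass for interior-supported data —
important when comparing heatmaps across animals.

Group comparison is per-voxel and two-sided; Welch's unequal-variance t is
the default, with a rank-based alternative (Mann–Whitney, normal
approximation with tie and continuity corrections). Voxels with zero
variance and zero effect in both groups are untestable and carry an `NA`
sentinel. Raw p is the primary output; Benjamini–Hochberg q-values are
opt-in.

A known limitation worth stating plainly: at the group sizes typical of
animal studies (n ≈ 5 per group), Welch's test is intrinsically
conservative — its true size at nominal α = 0.05 is ≈ 0.043 even for
perfectly normal data, as R's own `t.test()` reproduces in simulation.
The package's null-calibration check measures exactly this rate; anyone
requiring exact finite-sample size should use permutation inference, which
is out of scope here.

## Cortical depth field and flatmap

The depth coordinate is the harmonic potential φ solving Laplace's
equation on the cortical mask with φ = 0 on the pia, φ = 1 on the
white-matter boundary, and zero-flux (insulating) lateral faces — the
"streamlines" construction. The solver is a 6-neighbor finite-difference
stencil with anisotropic spacing weights, iterated by SOR (ω from the
largest grid dimension) until the maximum per-voxel residual falls below
`tol` (default 1e-6); non-convergence is an error, and disconnected
cortical components solve independently by construction.

Discretization note: Dirichlet values are imposed on whole voxel *bands*
(the outermost/innermost shell layers), so the effective boundary radii
sit at the band centers (≈ R ± spacing/2) and the voxel staircase of a
sphere puts the largest deviations from the smooth-geometry formula at the
boundary voxels. At 10 µm spacing on the toy shell the mean absolute
deviation from the analytic radial solution (using the effective radii) is
well under 1%, while the pointwise maximum at staircase voxels is a few
percent — an inherent property of the stencil, shrinking with spacing.

Cells project to the flatmap by tracing the streamline along −∇φ
(first-order Euler, step = min(spacing)/2, trilinear gradients) from the
cell to the pia; `depth_um` is the integrated path length plus a
first-order endpoint correction (φ/|∇φ| at the stopping point), which
removes the systematic ε-stop bias, and `depth_frac` is φ interpolated at
the cell. The (u, v) coordinate is the parameterization of the
streamline's pia endpoint: azimuth/polar angles for the toy shell,
(x, y) for slabs, or any user-supplied per-voxel lookup for a real
atlas's butterfly projection. The flatmap inherits the projection's
anisotropic area distortion; no equal-area correction is attempted.
Cells outside the cortex masks are excluded and counted; streamlines that
leave the mask flag their cell and are excluded from depth statistics, so
projected + excluded + flagged always equals the input count.

Depth profiles are histograms of `depth_um` divided by the bin width
(cells per µm of depth, from the pial surface, in atlas-space µm);
`Σ density · bin_width` equals the cell count in scope exactly. Layer
bands are expressed as `depth_frac` windows because the toy atlas's layers
are radial shells; with a layer-resolved annotation, membership can come
from the labels instead.

## Pipeline, configuration and provenance

One declarative YAML config drives the full run; `validate_config()`
checks every stage's preconditions up front and reports all violations at
once. The run writes every intermediate artifact (stack-space cells,
transform JSON, QC residuals, atlas-space cells, region table, heatmap,
optional flatmap outputs) plus a manifest with the config hash, package
version, seed, and cell counts at every stage, which obey the obvious
conservation identities. Reruns with the same config and seed are
bit-identical. A thin command-line dispatcher
(`system.file("cli", "brainmapr", package = "brainmapr")`) exposes each
stage as a subcommand for shell use.

## Problem sizes used by the test suite

The self-tests run on sizes chosen to exercise every code path at desktop
scale: a 128³-voxel stack with 200 planted cells for detection accuracy, a
10 µm toy shell (≈90k cortical voxels) for the depth field, 1000-cell
brute-force oracles for region assignment, 20 × 2000-cell replicates for
profile calibration, and 200 Monte-Carlo repeats (5 vs 5 samples, 512
voxels) for the null-rate check. The same computations, from scratch, are
reproduced by `scripts/acceptance.R`.

## Known limitations

* Intensity-based detection needs per-dataset parameter tuning on real
  stacks; the defaults are calibrated on the synthetic noise model only.
* No intensity-based (image-to-image) registration: transforms come from
  landmarks. TPS has no closed-form inverse; fit the reverse direction if
  needed.
* Welch small-sample conservatism, as discussed above.
* The flatmap's toy-shell parameterization is exact only for the
  synthetic geometry; real-atlas butterfly projections must be supplied
  as an external per-voxel lookup.
* Volumes are processed in memory; stacks beyond a few GB need chunking
  upstream.
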