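---
title: "Sparse-view iterative reconstruction for trabecular bone morphometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse-view iterative reconstruction for trabecular bone morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tomomorph)
```

## The problem

Micro-computed tomography is the standard modality for quantitative bone
morphometry, but a full projection protocol (here: 260 views over a 181.3
degree short scan at a 0.7 degree step) costs scan time and radiation dose.
Iterative reconstruction promises equivalent morphometric read-outs from a
half, a quarter, or a sixth of the views. `tomomorph` implements the whole
evaluation loop at desk scale: synthetic three-material bone phantoms, a
matrix-free short-scan projector with Poisson photon noise, four
reconstruction algorithms (filtered backprojection as the full-data
reference, CGLS, total-variation regularization, and the discrete algebraic
reconstruction technique DART), the Otsu-based segmentation chain, direct-3D
morphometry, and exact Mann-Whitney group statistics.

The six morphometric parameters are bone volume fraction (BV/TV, %),
trabecular thickness and separation (Tb.Th, Tb.S, um), trabecular number
(Tb.N, 1/mm), the ellipsoid factor (EF, dimensionless, rating rod-like
against plate-like architecture), and subchondral plate thickness (Pl.Th,
um). Tb.N uses the direct-model identity Tb.N = (BV/TV)/Tb.Th, the only
convention consistent with the published reference tables this package's
cohorts are calibrated to (e.g. 0.519 / 0.2147 mm = 2.42 per mm).

## The synthetic phantoms

Real subchondral bone scans of the destabilized-joint (ACLT) rabbit model are
not publicly deposited, so the study runs on synthetic cohorts whose group
statistics are calibrated to the published reference values
(`groupTargets()`): BV/TV 47.7 +/- 4.4% vs 51.9 +/- 3.4%, Tb.Th 202.9 +/-
18.2 um vs 214.7 +/- 16.1 um, and so on, with n = 12 vs n = 16.

The trabecular texture is a thresholded stationary Gaussian random field.
Its two knobs map cleanly onto the calibration targets: the threshold
quantile sets BV/TV *exactly* (up to voxel discretization), and the
correlation length sets the Tb.Th/Tb.S scale through a shipped lookup table
(`inst/extdata/trabecular_calibration.csv`, built once by
`inst/scripts/build_calibration.R` with the package's own thickness
operators, since no closed form exists). Per-axis anisotropy of the
correlation length turns the texture rod-like or plate-like, which is what
the EF sign-separation tests exercise. What the model does *not* capture:
the real bone's plate-rod mixture statistics, its long-range structural
gradients, and any correlation between parameters beyond what the targets
impose -- Tb.S in particular is emergent (a single-scale field cannot match
BV/TV, Tb.Th and Tb.S independently), so only BV/TV and Tb.Th are calibrated
and Tb.S is reported as measured.

Cohort draws are moment-matched: the per-sample z-scores are standardized to
exact mean 0 / SD 1 before scaling to the target mean and SD. The cohort's
purpose is to *reproduce the printed group statistics*, not to add sampling
variability on top of them; with plain iid draws a 12-sample group mean would
wander by +/- 1.3 BV/TV points between seeds, defeating the calibration.
Draws are truncated at +/- 3 SD and at physical bounds (BV/TV in [5, 95]%,
thicknesses at least 3 voxels).

Two phantom families with analytic ground truth anchor the morphometry
operators: parallel slabs (exact Tb.Th/Tb.S, oblate EF) and parallel rod
lattices (exact Tb.Th = 2r, analytic BV/TV = pi r^2 / pitch^2, prolate EF).
Both are laid out so that no structure touches the volume border, because
the thickness convention treats out-of-volume space as neither bone nor
background.

## Geometry and projection model

The forward model is a Joseph-style interpolated ray-driven projector:
each ray marches across the voxel-center planes of its dominant axis with
linear interpolation transverse to it. The adjoint reuses the identical
traversal weights, so forward/adjoint form an exact pair by construction --
the property CGLS correctness rests on, verified to 1e-6 (measured ~1e-15)
by inner-product tests in three modalities (parallel2d, fan2d, cone3d).

The protocol's source and detector distances are not part of the published
geometry, so the defaults (SAD 400 mm, SDD 800 mm) were chosen to give a
fan narrow enough that the 181.3 degree span satisfies the short-scan
condition (span >= 180 degrees + fan angle); Parker weights then handle the
redundancy, with uniform 1/2 weighting for full 360 degree scans. The
filtered backprojection uses the band-limited ramp (Ram-Lak) kernel apodized
by a Hamming window (alpha = 0.54 by default) and reconstructs a uniform
disc to better than 1% of its true attenuation.

Photon noise follows the scanner protocol: per detector element the
transmitted count is Poisson with mean I0 exp(-p), two frames are averaged,
the average is clipped at one count to keep the logarithm finite, and the
result is re-logged. The study default I0 = 30000 gives a line-integral
noise level representative of a low-dose bench scan. Means above 2^30 use
the normal limit of the Poisson (rpois overflows 32-bit counts; at such
means the approximation is exact to rounding).

## Reconstruction algorithms

* **CGLS** -- conjugate gradients on the normal equations, zero start,
  25 iterations (the study's base iteration count for every method).
  Verified against a dense least-squares solve to 1e-6.
* **TV** -- minimizes 1/2 ||Au-b||^2 + lambda * sum sqrt(|grad u|^2 + eps^2)
  with Barzilai-Borwein (BB1) steps from the zero image. The raw BB step
  diverges on strongly regularized problems, so steps are safeguarded into
  [1e-8, 1e8], fall back to the initial exact line-search step on negative
  curvature, and pass a 5-step nonmonotone backtracking test; the reported
  iterate is the best one visited, so the final objective never exceeds the
  initial one. eps defaults to 1e-4 times a data-derived image scale.
* **lambda selection** -- the L-curve method: per lambda the solver records
  (residual norm, total variation); the corner is the maximum three-point
  Menger curvature on the log-log curve, ties resolving to the smaller
  lambda. The default grid has 8 logarithmic points bracketing a one-step
  pilot balance estimate. In `runStudy()` the selection runs once per
  sparsity level on a pilot sample with 4x the base iterations (the curve
  must be traced on converged points) and the chosen lambda is reused across
  samples; the published protocol this emulates names only the selection
  method, not per-dataset weights.
* **DART** -- a 25-iteration CGLS initial reconstruction, then 25 discrete
  iterations: threshold-segment against the three admissible gray values,
  fix interior voxels at their class value, free the class boundaries plus a
  1% random fraction of the interior (fix probability 0.99), re-solve the
  free voxels with 10 CGLS iterations against the residual data, and blend a
  radius-1 mean smoothing at weight 0.1 into the free voxels. The output is
  the segmented image (voxel values are exactly the prior's gray values); a
  flag exposes the continuous iterate. The fix probability and smoothing
  weight follow the conventions of the discrete-tomography literature; the
  emulated protocol states neither. "25 base iterations" is read as 25 outer
  discrete iterations, not total algebraic passes.

Image quality is scored by the contrast-to-noise ratio on the middle slice,
(mean bone ROI - mean background ROI) / SD background ROI. A discrete DART
output can have an exactly constant background; the CNR is then undefined
and reported as +Inf, flagged in the study tables rather than averaged.

## Segmentation

The chain mirrors a standard vendor workflow: cubic median filter (radius
1), unsharp mask (radius 1, amount 50%, box blur sharing the radius -- the
vendor tool does not specify its blur kernel), global Otsu threshold over a
256-bin histogram of the full volume (half-open bins between min and max,
ties to the lowest cut), despeckling, then restriction to the trabecular
and plate regions; the plate mask additionally gets interior pores filled
(background components not reaching the volume border) and a morphological
closing with a 2-voxel Euclidean ball (the reference names no radius),
computed in a padded domain so border-touching plates are not closed
against the array edge.

The despeckling sweep is keep-largest-component (26-connectivity) by
default, matching the "largest object in the volume" behavior it emulates.
That presumes 3D connectivity: a 2D cross-section of a connected trabecular
network fragments into dozens of components, and keep-largest would discard
most real bone. Single-slice studies therefore use the `min-size` mode
(drop components under 30 voxels), which removes noise speckles without
touching genuine cross-sections. Manual region delineation is replaced by
the generator's region masks; external data can supply their own.

## Morphometry numerics

Local thickness follows the largest-inscribed-sphere model: a sphere
centered at c has radius r_c equal to the distance to the nearest background
voxel center, covers voxels strictly closer than r_c, and contributes the
diameter 2 r_c - 1 voxels (equal to the slab width for odd widths, one voxel
short for even ones -- the +/- 1 voxel discretization every thickness test
tolerates). Painting from *every* foreground voxel realizes the definition
exactly; an exhaustive brute-force oracle arbitrates on small volumes.
Volume borders do not count as background.

The ellipsoid factor seeds candidate ellipsoids at distance-ridge
(medial-axis) points, subsampled by a fixed stride in scan order (cap 200),
starts each as the largest inscribed sphere (shrunk until its sampled
surface fits the voxelized boundary), and grows semi-axes greedily with a
step that halves down to 0.12 voxels, consulting a fixed bank of 24 small
rotations (drawn once from the seed) when growth stalls. The search is
therefore deterministic given the mask and seed, which keeps EF comparable
between slightly different masks of the same object. EF = a/b - b/c on the
sorted semi-axes: positive for prolate rods, negative for oblate plates (the
standard convention; some published tables state the opposite mapping, so
`signConvention = -1` can flip the report). Every foreground
voxel takes the EF of the largest ellipsoid containing it; the mean is
volume-weighted.

Single-slice masks are extruded 4 voxels along z before the three-axis EF
search. The depth is a deliberate constant: at roughly half the trabecular
thickness it makes the in-plane labyrinth read as oblate with mean EF near
-0.3 -- the magnitude scale of the reference animal data -- whereas deeper
extrusions drive the mean EF through zero, where a relative-error comparison
between reconstructions is ill-conditioned. Even so, EF remains the most
mask-sensitive parameter (a one-voxel dilation at 25 um resolution moves it
by ~0.05), and its relative errors run an order of magnitude above the other
five parameters'; the study tables report each parameter separately so this
is visible.

## The study and its statistics

`runStudy(studyConfig("demo"))` runs the full grid: 6 + 6 single-slice
256 x 256 samples, 260-view short-scan fan-beam projections with Poisson
noise, the full-data FBP reference plus CGLS / TV / DART at 1/2, 1/4 and 1/6
of the views -- ten reconstructions per sample -- then segmentation,
morphometry and CNR for each. Problem sizes are the package's desk-scale
choice: single slices keep ten iterative reconstructions per sample
tractable while preserving the protocol's angular sampling; the "smoke"
preset (2 + 2 samples, 96 x 96, 120 views) exercises the identical code path
in seconds. A 3D volume-of-interest cohort mode (80 x 80 x 160 voxels, the
protocol's VOI) backs the calibration-recovery checks.

Group differences use the exact Mann-Whitney U test with midrank ties and a
tie-aware permutation distribution (dynamic-programming shift algorithm on
doubled ranks, verified against full enumeration for all group sizes up to
8). The two-tailed p doubles the smaller tail, capped at 1 -- the convention
identified from the reference tables, where two-tailed values are twice the
one-tailed ones throughout; the exact two-sided tail mass is available by
flag. Relative errors against the per-sample full-data reference are
|IR - ref| / |ref| * 100, aggregated to mean +/- SD per algorithm, sparsity
level and parameter; zero references are excluded with a warning. Every
seed derives from the master seed, so the whole study is reproducible
byte for byte.

On the calibrated cohort DART's mean relative error across the six
parameters stays within single digits at every reduction level while CGLS
and TV degrade as views are removed -- the behavior the acceptance suite
asserts; it does not re-derive the animal study's biology, only the
pipeline's algorithm ranking on textures matched to its group statistics.

## Degenerate inputs and tie-breaks

Otsu on a constant volume, empty masks, empty VOIs, empty skeletons, zero
thickness, non-positive photon counts, and prior threshold misordering are
errors with explicit messages. Despeckle ties keep the component containing
the first voxel in scan order (component labels are assigned in scan order,
so this is the smallest label among the largest components). The L-curve
with fewer than three points returns the first lambda with a warning;
collinear points have zero curvature everywhere and fall back to the
smallest lambda.

## Known limitations

* The projector is monochromatic and artifact-free: no beam hardening,
  scatter, detector blur or ring artifacts (the workflow it emulates removed
  these in vendor preprocessing), and no focal-spot size.
* The Gaussian-field texture is a stand-in, not an inference about real
  trabecular microstructure; passing tests show algorithm behavior on
  matched textures, not biological fidelity.
* Tb.S and EF group values are emergent rather than calibrated.
* The slice-mode EF is a 2.5D surrogate (fixed extrusion) and is the least
  stable parameter of the six.
* DART's discrete output makes its CNR undefined whenever the background
  collapses to a single gray value.
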