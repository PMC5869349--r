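---
title: "Methods: mask agreement, coverage margins, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mask agreement, coverage margins, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segmargin)
```

## Scope and data model

`segmargin` quantifies how well candidate tumor segmentations agree with a
reference ("truth") volume on a common voxel grid, and what isotropic
safety margin a candidate needs to cover the truth entirely. Everything
operates on two containers: `binary_mask` (3D logical lattice, axes x/y/z,
positive mm spacing per axis, world origin at the centre of the first
voxel) and `scalar_image` (same grid, finite float intensities). The grid
model is deliberately minimal: NIfTI affines are reduced to spacing +
origin and oblique or rotated affines are rejected, because the intended
workflow registers all volumes to one axis-aligned analysis grid (1 mm
isotropic by default) before any comparison. Binary operations require
exact grid compatibility; regridding is only ever explicit
(`resample_nearest()`), never silent.

Volumes are voxel counts times the voxel volume at 1000 mm³/mL. This makes
volume additive over disjoint masks and invariant under axis permutation,
which the test suite checks as properties.

## Agreement metrics

Dice and Jaccard are computed on voxel counts. The surface metrics need a
definition of "surface" and of point-to-point distance, neither of which is
canonical for voxel data; the package uses:

- **surface voxels**: TRUE voxels with at least one FALSE 6-neighbour
  (lattice-boundary voxels included);
- **distances**: Euclidean, between voxel centres, spacing-aware, via an
  exact separable distance transform (Felzenszwalb–Huttenlocher lower
  envelope, implemented in C++ with per-axis spacing weights).

Centre-to-centre distances keep the fast implementation and the
brute-force O(n²) oracle in the tests numerically identical (agreement to
1e-9 mm is asserted on random masks up to 12³). The cost is a consistent
discretization bias of at most half a voxel diagonal relative to a
sub-voxel surface model; no sub-voxel interpolation is attempted. The
Hausdorff distance is the full maximum (no percentile variant), and MDA is
symmetrised by pooling both directed distance sets, so every surface point
of either mask contributes once with equal weight — the alternative
(averaging the two directed means) weights the two surfaces equally
regardless of their point counts. Comparisons of two empty masks raise an
error rather than returning a sentinel: the analysis never compares empty
VOIs, and a silent 0 or 1 would corrupt summaries.

## Margin analysis

`expand_mask(m, margin)` thresholds the distance transform of the mask at
the margin, i.e. it contains every voxel centre within `margin` mm of a
TRUE voxel centre. `min_coverage_margin(truth, candidate)` is the maximum
over truth voxels of the distance to the candidate. Because both use the
same distance field, dilation by the returned margin yields exactly zero
missed volume, and dilation by one voxel diagonal less leaves missed volume
positive whenever the margin is positive — asserted as an acceptance
property. The margin is returned as a continuous mm value; rounding to
integer millimetres is left to presentation. Expansions are clipped at the
lattice boundary with a warning; synthetic grids are sized so the margins
of interest (up to 15 mm) do not clip. An optional `allowed_region` mask is
intersected after expansion for anatomy-limited margins (e.g. near the
sphincter); the default is unrestricted.

## Ellipsoid volume estimate

`max_extents()` measures the full voxel-width extent per lattice axis
((max − min + 1) × spacing), so a single voxel has a 1-voxel extent; the
caliper-style estimate is extents × 0.52 / 1000 mL. The constant 0.52
approximates π/6 ≈ 0.5236, so for a digitized ellipsoid in generic lattice
position the estimate converges to ≈ 0.993 × the voxel-count volume. The
one subtlety is lattice coincidence: if a semi-axis is an exact multiple of
the voxel size, voxel centres lie exactly on the analytic surface and the
inclusive digitization inflates that extent by a full voxel (~7% in volume
at 0.5 mm voxels for a 20 mm sphere). Calibration tests therefore place
phantom semi-axes at half-voxel offsets, the generic configuration; real
lesions never sit on the lattice. For irregular, non-convex masks the
bounding box grows faster than the enclosed volume and the formula
systematically overestimates — the direction of bias the cohort pipeline
reports.

## Gradient-based PET segmentation

The segmenter reconstructs a proprietary, one-sentence-documented clinical
algorithm in spirit: spatial derivatives along tumor radii, edge placement
by derivative level, continuity of the edge surface. Every constant is an
explicit parameter:

- **directions**: icosphere vertices, default 3 subdivisions = 642
  quasi-uniform rays (configurable via `subdivisions`);
- **profile step**: half the smallest voxel spacing, trilinear
  interpolation, samples beyond the lattice clamped and flagged;
- **edge rule**: most negative centred finite difference along the ray,
  parabolic sub-sample refinement; a falling edge must exceed 5%/mm of the
  profile's global intensity range (`threshold_frac`), which makes the
  segmenter invariant under positive intensity rescaling; numerically flat
  profiles carry no edge;
- **curvature correction** (default on): for a convex boundary of local
  radius r blurred with an isotropic Gaussian σ, the steepest radial
  gradient sits at ≈ r − σ²/r, not at r. Each ray's σ is estimated from
  the FWHM of its derivative trough with the finite-difference stencil
  width (2 steps) removed in quadrature, so a sharp step yields σ = 0 and
  no correction; the outward shift σ²/r is capped at σ. Without this
  correction a 6 mm sphere at 4.1 mm FWHM is under-segmented by ~24% in
  volume; with it, phantom recovery across 6–15 mm radii and 4:1–20:1
  contrasts stays within the 15% band the tests assert;
- **continuity**: an iterated neighbour-median filter on the icosphere
  adjacency imputes rays with no detected edge and replaces radii deviating
  more than 50% (`continuity_bound`) from their neighbour median. A
  diffusion smoother was rejected: iterated to convergence it has no fixed
  point short of a constant field and erodes genuine lesion anisotropy,
  while the median filter leaves smooth radius fields untouched (uniform
  fields are exact fixed points) and removes only discontinuous outliers;
- **rasterization**: a voxel is inside if its distance to the seed is at
  most the radius interpolated from the 3 nearest direction nodes
  (inverse-angular-distance weights); the output is the 26-connected
  component containing the seed.

The segmenter is deterministic given image, seed and parameters. It does
not attempt bit-compatibility with the commercial tool, partial-volume
correction, or multi-focal lesions.

## Shape-based slice interpolation

Histology contours exist only every 3 mm. Each 2D slice becomes a signed
Euclidean distance field (negative inside), fields are interpolated
linearly between consecutive slices and re-thresholded at zero. At knot
positions the interpolation weight is exactly 0 or 1 and the input slice is
returned bit-exactly. Fields are capped at 2× the largest gap
(`cap_factor`) so a component present in one slice and absent in the next
grows from the nearest boundary at a bounded rate instead of appearing
instantaneously; the cap also determines how far past the last non-empty
slice the reconstruction extends. Nearest-slab replication is available as
`method = "nearest"` for comparison — its net volume error can cancel by
luck, but its per-slice shape error is strictly larger on ball phantoms,
which a test demonstrates.

Linear interpolation of signed distances is chord-like: it under-fills
convex caps between slices, which is the geometric content of the 3 mm
slice-level uncertainty of interval sectioning. On 1 mm grids,
reconstructing balls sectioned at 3 mm recovers the analytic sphere volume
within 5% for diameters ≥ 12 mm (asserted in the acceptance suite);
against the digitized ball the deficit can reach ~6% at unfavourable
sectioning phases, and in the continuous limit the cap loss is larger
still — sub-5% round-trips for small lesions are partly a property of the
favourable discretization, not of linear interpolation per se.

## Synthetic cohort generator

The generator is first-class, tested code: it produces the statistical
structure the analysis assumes, so every pipeline stage runs without
patient data.

- **Truth tumors**: star-convex blobs — a base ellipsoid with mild random
  volume-preserving axis anisotropy, radius modulated by a band-limited
  random spherical field (low-order polynomials in cosines to a few random
  axes, amplitude `irregularity` = 0.25), rescaled by bisection to a drawn
  target volume within 2%. Volumes are lognormal with median 1.37 mL and
  sdlog 0.9, truncated to 0.15–6.31 mL: the clinical series reports only
  the median and range, and ±2 SD of this law reproduce the range at the
  observed sample size. Single connected lesions only (the study required
  a solitary focus).
- **Readers**: the truth is shrunk about its deepest interior point,
  translated by a Gaussian decentring of 3 mm SD, and perturbed by a
  smooth boundary noise field (0.75 mm SD); the shrink factor is calibrated
  by bisection so the candidate covers the target fraction of the truth
  (0.21/0.20 by default, i.e. ~79/80% missed) within ±0.03. Reader error
  is deliberately decomposed into shrinkage + decentring + boundary noise,
  because required margins are driven by both under-segmentation and
  mis-centring. The two readers' decentrings share 70% of their variance
  (`reader_offset_shared_frac`): readers looking at the same images
  mis-centre toward the same conspicuous subregion, and with fully
  independent 3 mm offsets the simulated inter-reader Dice falls to ~0.2,
  well below observed inter-reader agreement; with the shared component it
  sits in the observed 0.25–0.55 bracket while each reader's marginal
  decentring SD stays 3 mm.
- **PET**: piecewise-constant activity (tumor 8, background 2, SUV-like)
  convolved with an isotropic Gaussian PSF of 4.1 mm FWHM plus 5% Gaussian
  noise, clipped at zero.
- **Reproducibility**: each case draws from its own substream derived from
  the master seed, so cohorts are bit-reproducible and enlarging a cohort
  does not change earlier cases.

What the generator does *not* emulate matters for interpreting green
tests. The phantom PET assigns uptake to the entire histologic truth
volume, so the simulated gradient segmentation (seg3) recovers most of the
truth (~12% missed in cohort runs), whereas clinically the tracer-avid
region covers only part of the tumor and the PET segmentation missed ~58%.
Consequently simulated minimum-coverage margins for seg3/seg4 are far
smaller than clinical ones. The tests therefore validate the *machinery*
(metrics, margins, calibration, union dominance — which holds by set
algebra in every case) and the qualitative ordering
missed(seg4) < missed(seg3) < missed(seg1/seg2), not the clinical
magnitudes for PET-derived candidates. Fixation shrinkage, MRI appearance,
multi-focality and registration error are likewise out of scope.

## Statistics

Candidate comparisons use the two-sided Wilcoxon signed-rank test (paired
across cases) or rank-sum test (unpaired), via `stats::wilcox.test`: exact
distribution for n ≤ 20 without ties, normal approximation with continuity
and tie correction otherwise. Zero differences are dropped first (the
classical signed-rank rule); all-zero differences return p = 1 with a
flag, and comparisons with fewer than 5 observations are flagged as
underpowered but still computed. Exactness is verified in the tests
against full enumeration of all sign patterns up to n = 10. No
multiple-testing correction is applied by default, matching the source
analysis convention; summaries report mean, SD, median and range per
candidate and metric, and cases whose candidate is empty are excluded from
that candidate's summaries while still contributing to the union.

## Problem sizes and numerical choices

Tests run on 64³ grids at 1 mm for cohort-level checks (200 simulated
cases for the cohort-sanity property; 60 for the acceptance script),
12³ grids for oracle-equivalence suites (where O(n²) brute force is
feasible), and 40–54³ phantoms for the PET segmenter. Volume calibration
tolerances: 2% (truth rescaling), ±0.03 (reader coverage, relaxed to 0.1
with a flag for truths under 30 voxels). Expansion uses a 1e-9 mm slack
when thresholding distances so that dilation by the computed minimum
coverage margin is never defeated by floating-point rounding. Ties in the
edge detector resolve to the first (innermost) steepest-descent sample.

## Known limitations

Distances are centre-to-centre on the voxel lattice (no mesh extraction);
HD/MDA inherit up to half a voxel diagonal of discretization. The
minimum coverage margin assumes isotropic expansion; direction-dependent
margins are out of scope. The PET segmenter assumes a star-convex lesion
around the seed and a falling edge along each ray; necrotic cores or
adjacent avid structures violate these assumptions. The generator's reader
model is geometric (shrink/shift/noise of the truth), not an appearance
model of reader perception.
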