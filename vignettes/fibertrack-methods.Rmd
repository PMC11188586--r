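---
title: "Models, parameters and design choices in fibertrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in fibertrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fibertrack)
```

## The problem

Serial block-face microscopy of peripheral nerve yields long stacks of
aligned transverse sections: thousands of slices, each showing fascicles as
clusters of bright fiber cross-sections in a darker connective-tissue
background. Single axons are not resolvable, but fiber *groups* are, and
their trajectories — how bundles drift, split and merge along the nerve —
can be recovered by treating the stack axis like the time axis of a video
and tracking image texture from slice to slice. `fibertrack` implements
this microscopic tractography: orientation estimation, streamline
propagation, anatomical constraints, evaluation metrics, and a synthetic
phantom generator that makes each stage testable against exact ground
truth.

This vignette records the models, the tunable parameters with their
defaults and units, the numerical choices, and the places where the design
was genuinely open — and what was decided there and why.

## Orientation models

### Lucas–Kanade optic flow

Brightness constancy between consecutive slices gives, per pixel,
`Ix Vx + Iy Vy = −Iz`, with `Ix, Iy` spatial derivatives (central
differences after Gaussian blur) and `Iz` the blurred inter-slice
difference. Flow is assumed constant over an `n × n` window, and the
resulting overdetermined system is solved through the 2 × 2 normal
equations. We compute flow densely (at every pixel, not only at tracked
points) so that propagation can interpolate anywhere; at desk-scale image
sizes the cost is negligible.

Numerical choices:

* **Window (`window`, default 50 px).** Matches full-scale nerve stacks
  where fascicles span hundreds of pixels. An even window is incremented
  by one so it has a center pixel. On small phantoms the same
  *window-to-fascicle ratio*, not the absolute window, is what matters:
  the examples and tests use ~1/3 of the fascicle diameter (11 px for
  32-px fascicles), mirroring the full-scale ratio.
* **Pyramid levels (`levels`, default 2).** Downsampling by 2 per level;
  flow estimated coarse-to-fine with bilinear upsampling (corner-aligned),
  doubling, warping of the second slice (bilinear, replicated borders) and
  residual re-estimation. If the coarsest level would be smaller than
  twice the window per side, the level count is reduced with a warning.
* **Blur (`blur_sigma`, default 2 px).** Applied to both slices before
  gradient computation; reflect boundaries.
* **Validity.** Pixels whose normal matrix has smaller eigenvalue below
  `1e-4 · n²` are aperture-degenerate: flow is set to zero and flagged
  invalid. The constant is scaled by window area so the rule is
  window-size invariant.
* **Window weighting.** The window sum is unweighted (no Gaussian taper),
  matching the plain least-squares formulation.

### 3D structure tensor

The local fiber direction minimizes the displaced-intensity difference
`D(u) = Σ (V(p′+u) − V(p′))²` over the neighborhood of a voxel; to second
order this is the quadratic form `uᵀJu` with
`J = Σ w ∇V ∇Vᵀ`. We take the eigenvector of the smallest eigenvalue of
`J` as the orientation.

* **Noise scale (`sigma_n`, default 1 px)** — Gaussian-derivative
  gradients; **neighborhood scale (`sigma_nb`, default 5 px)** — Gaussian
  smoothing of the six tensor components. The Gaussian neighborhood is a
  soft version of a hard windowed sum; the test-suite oracle uses matching
  Gaussian weights in an explicit loop.
* **Isotropization.** Tensor analysis runs on near-isotropic voxels: the
  stack is block-averaged in XY by `round(slice_thickness /
  pixel_size_xy)` (e.g. factor 3 for 0.9 µm pixels and 3 µm slices).
  Orientation lookups during tracking account for the half-pixel origin
  shift of block averaging.
* **Chunking (`step_size`, default 64 slices).** Chunks are loaded with an
  overlap margin of `ceil(3(σn + σnb))` slices per side. Because every
  kernel is truncated at `ceil(3σ)`, the margin covers the full filter
  support and chunked output is *bit-identical* to a single-pass run —
  this is asserted, not approximated. If the chunk plus margins exceeds
  the stack, processing falls back to a single chunk with a warning.
* **Eigen-analysis.** A vectorized closed-form solver for symmetric 3 × 3
  matrices (trigonometric eigenvalues; eigenvector from the largest cross
  product of rows of `A − λI`), validated against base `eigen()` in the
  tests. Signs are fixed canonically (`uz ≥ 0`, ties toward `uy ≥ 0`, then
  `ux ≥ 0`).
* **Degeneracy.** Voxels with negligible tensor trace (`< 1e-8`, i.e. no
  gradient energy) or with the two smallest eigenvalues equal within
  `1e-4` of the largest (direction undefined) are flagged invalid rather
  than given an arbitrary tie-break.

## Tracking

One point per crossed slice plane; coordinates are physical micrometers
(`x = col · pixel_size_xy`, `y = row · pixel_size_xy`,
`z = slice · slice_thickness`, voxel indices 0-based). Optic-flow steps
interpolate the flow field bilinearly at the current sub-pixel position;
tensor steps use nearest-neighbor orientation lookup (the tensor field
lives on the coarse isotropized grid) scaled so each step crosses exactly
one slice.

Termination rules, in the order tested: invalid flow at the location
(tensor mode first bridges up to 2 consecutive invalid voxels with the
previous direction — enough to cross isolated degenerate voxels without
letting tracks wander); step angle to the stack axis exceeding
`max_angle` (default 75°; the stack axis is the anatomical long axis of a
transversely sectioned nerve); exit from the image bounds (positions are
not clamped); end of stack.

Anatomically constrained tracking takes a per-slice fascicle mask stack:
`truncate` cuts each streamline at its last consecutive in-mask point from
the seed; `remove` deletes any streamline that ever leaves the mask. Both
modes are provided because both behaviors are useful in practice
(truncation preserves the in-fascicle prefix; removal gives a clean
subset), and after either, every surviving point lies inside the mask.

Seeding enumerates each ROI's pixels in row-major order, permutes them
with a generator re-seeded per component (`rng_seed + label`, so editing
one ROI never disturbs another's seeds), and takes
`max(1, floor(count · density))` of them — the floor-with-minimum-1 rule
guarantees every ROI is tracked. Connected components use 8-connectivity,
the safer choice for hand-drawn masks whose strokes may touch only
diagonally.

## Metrics

**Normalized Dice.** The tractogram's points on a slice are rasterized to
their nearest pixels and compared with the ground-truth fiber-group mask
by Dice overlap, normalized by the same overlap at the seeding slice.
Normalization removes the strong dependence of the raw value on seed
density; the metric rests on the assumption that the group's
cross-sectional area is roughly conserved along the stack. Values slightly
above 1 are possible (e.g. when the group's outline tightens). A Dice
against an empty reference, or a zero Dice at the seeding slice, raises an
error rather than silently returning a convention — such cases indicate
evaluation mistakes.

**Mean closest-neighbor distance.** Both tractograms are reduced to
cluster centroids by an incremental QuickBundles-style pass: streamlines
resampled to `K = 12` points, minimum-direct-flip (MDF) distance to
existing centroids, threshold `theta = 50 µm`, running flip-aligned mean
as centroid, processed in stored order (the inherent order dependence of
incremental clustering is pinned by the stored order, and provenance makes
it reproducible). `mcn_dist` is the symmetrized mean over centroids of the
distance to the closest same-ROI centroid in the other tractogram. ROIs
present in only one tractogram are skipped with a warning; no shared ROI
is an error.

## The phantom generator

Phantoms emulate the imaging geometry of block-face nerve stacks —
defaults 0.9 µm pixels, 3 µm slices, bright fibers (intensity 200) on a
dark background (30), anti-aliased disk rendering so sub-pixel drift is
expressible, optional additive Gaussian noise, and a contrast-inversion
flag for absorptive-stain appearance. Centerline models: straight, tilted,
constant drift, helical, bend (straight then tilted past a set slice), and
smoothstep migration for split/merge scenes. Fibers are placed by
deterministic dart throwing inside each fascicle; everything is a pure
function of the spec and its seed, down to the written PNG bytes.

The bundled split/merge scene sends subsets of fibers from four fascicles
into one merged fascicle. Its geometry was chosen to reproduce, at desk
scale, the *ratios* that matter in real stacks: analysis windows well
below fascicle diameter, migration angles ~15° (bounded at 45°, inside
the 75° tracking envelope), and fiber spacing roughly conserved during
migration, consistent with the conserved-area assumption behind the
normalized Dice. Ground-truth fiber-group masks are the smallest enclosing
disk of each group's fiber sections — the filled group outline a rater
would trace — not single-fiber disks; overlapping outlines assign each
pixel to the group it is deepest inside.

What the phantoms do *not* emulate: stain and illumination gradients,
sectioning artifacts, tile-stitching seams, myelin texture, and fascicles
hundreds of pixels across. Passing phantom tests therefore demonstrates
the correctness of the machinery (estimators, propagation, termination,
metrics, determinism) and its behavior under noise and downsampling — not
the end-to-end accuracy on any particular real dataset.

## Problem sizes in tests and the acceptance study

The test suite and `scripts/acceptance.R` use phantoms between
`48 × 48 × 40` and `160 × 160 × 90` voxels with 100–250 streamlines;
brute-force oracles (explicit Gaussian-weighted tensor sums, 0.01-px flow
grids, 1000-direction eigen-minimality checks) run on 11³ volumes and 5×5
windows. These sizes keep every check exact or tightly toleranced while
the whole suite runs in about a minute on one CPU; the algorithms
themselves are written for stacks that do not fit in memory (virtual
slice reader with a bounded cache of 8 decoded slices, chunked tensor
processing).

## Known limitations

* Tracking is one direction per run; forward and backward tractograms are
  not merged into single streamlines.
* The optic-flow tracker degrades when in-plane motion per slice
  approaches the fiber spacing (the texture decorrelates); the structure
  tensor degrades when isotropization leaves fascicles only a few coarse
  voxels wide. Both effects appear in the downsampling-robustness numbers
  on small phantoms well before they would on full-scale stacks.
* `dice_norm` is only computed at slices where ground truth exists, and
  inherits the conserved-area assumption discussed above.
* The QuickBundles reduction is an approximation for tractogram
  comparison, not a biological clustering of the nerve.
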