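---
title: "Methods: quantifying basal-ganglia connectivity from tractograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying basal-ganglia connectivity from tractograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgtract)
```

## The problem and the model

A tractogram is a set of streamlines — ordered 3D polylines in world
millimetres — reconstructed from diffusion MRI as proxies for white-matter
fiber paths. Given such a tractogram and a label volume segmenting the
five core basal-ganglia nuclei (STN, SNc, SNr, GPe, GPi) plus auxiliary
ROIs, `bgtract` quantifies three things:

* **Seed–target connectivity**: for each nucleus, the percentage of the
  tracks through it that also reach each projection site, counting both
  direct and indirect connections.
* **Direct connectivity**: tracks are cut into segments that join two
  core nuclei with no third core nucleus along the way; the segment
  counts are normalized per structure, so each column of the percentage
  matrix describes how one structure's direct connections distribute over
  the other four.
* **Voxel projection maps**: within a nucleus, the per-voxel percentage
  of traversing tracks that reach a given target, localizing where in the
  structure a projection originates.

The underlying assumptions are those of streamline tractography itself:
tracks are direction-blind (no efferent/afferent distinction — direct
segments are unordered pairs), a reconstructed track is evidence of a
possible anatomical connection rather than proof, and counts measure
reconstruction support, not synapse counts.

## Decision rules

Several counting rules are fixed by the table semantics of the reference analysis the
package mirrors; the rest are documented package decisions.

**Visit = vertex membership.** A track visits a structure iff at least
one vertex maps into it, via nearest-voxel-centre lookup. With tracking
steps (0.05 mm) an order of magnitude finer than voxels (0.5 mm), a
segment cannot cross a voxel without placing a vertex in it, so the rule
is lossless there. For coarser tractograms `densify()` interpolates to a
chosen spacing first; without it, a diagonal corner-cut with no interior
vertex is *not* a visit — documented behaviour, configurable nowhere.
The alternative (geometric segment–voxel intersection) was rejected as
needless at the native step size. A single-vertex touch counts
(`min_visit_vertices = 1`); no dwell criterion is defined in the reference analysis, and the
parameter is exposed for sensitivity analyses.

**Directness.** Visits are filtered to the five core labels; every
consecutive pair of *distinct* labels emits one segment. Hence a path
STN→SNc→SNr yields (STN,SNc) and (SNc,SNr) but never (STN,SNr);
auxiliary ROIs such as the internal capsule — which demonstrably lies
between directly connected pairs — never block directness; and a track
re-entering the same structure emits nothing (the percentage table has
no diagonal). Repeated pairs on one track all count: the unit is the
track *segment*, not the track. `dedupe_per_track = TRUE` switches to
once-per-track counting for comparison; whether the original custom code
deduplicated is not documented, so the segment-counting
default was chosen as the more literal reading of "cut into single track
segments".

**Seed–target counting.** The unit here *is* the track: each track
counts once per (seed, target) pair regardless of how often it enters
either — including tracks leaving a seed at two different borders. One
track usually reaches several targets, so seed columns legitimately sum
to more than 100 %. Composite structures (SN = SNc ∪ SNr, GP = GPe ∪
GPi, structure halves) use union semantics: a track touching both parts
counts once — which is why the SN percentage is below the SNc + SNr sum.
The ≥ 1 % inclusion rule drops a target only if it is below threshold for
*every* seed, and is applied to seed–target reporting only, never to the
direct-connection matrix (the reference analysis states the rule in the
seed–target context only). Rows that are NA against every seed (pure
self-overlaps) are retained; dropping them would conflate "no evidence"
with "below threshold".

**Voxel maps.** Denominator = selected tracks with ≥ 1 vertex in the
voxel; numerator = those also intersecting the target; a track crossing
a voxel twice counts once in both. Zero-track voxels are NaN, never 0,
so downstream statistics are unbiased; whether the denominator should
instead count *all* tracks is left open by the reference semantics — the
seed-selected default is configurable via the `ids` argument.

**Coordinates.** TCK streamline coordinates and the NIfTI affine are
taken to share one world space (scanner mm, RAS) with no implicit flips —
both formats define world-space semantics, unlike TrackVis TRK, which is
deliberately unsupported. Voxel lookup rounds to the nearest voxel
centre (the NIfTI affine maps indices to centres), with ties at .5
rounded half away from zero — `base::round()`'s round-half-even would
assign boundary points by parity. Indices are 0-based at the API surface
to match the affine convention.

**Splitting.** The anteromedial/posterolateral split of the pallidal
segments has no canonical construction. The default plane passes through
the structure's voxel-centre centroid, normal to its first principal
axis, with the positive side oriented anteriorly (+y; ties toward −x,
then +z) and on-plane voxels assigned to the anteromedial half. An
axis-aligned rule (`plane_rule = "x"/"y"/"z"`) is provided; for
elongated structures like the pallidum the principal axis is stable, but
for near-spherical structures the axis, and hence the split, is
ill-conditioned — use the axis-aligned rule there.

## The phantom: what it does and does not emulate

No specimen data are deposited, so validation uses synthetic phantoms
with closed-form ground truth. The "paper-like" preset emulates the
study conditions: a 0.5 mm isotropic grid (64×64×48), five ellipsoidal
nuclei whose analytic volumes equal the reported segmentation volumes
(STN 100.5, SNc 138.8, SNr 142.6, GPe 611.9, GPi 271.8 mm³ — the
rasterized ratios land within a few percent), a box "capsule" obstacle
between the pallidum and the STN/SN block, streamline vertices stepped
at 0.05 mm, and one bundle per connection class: straight within-block
bundles, arcs circling anteriorly (+y) around the capsule, bundles
crossing straight through it, a pass-through path (STN–SNc–SNr), a
double-exit path (GPe–STN–GPe), and background streamlines touching
nothing. The nucleus positions, bundle mix and counts are package
inventions — the reference analysis had no synthetic data — so their realism is
aesthetic, not contractual.

Ground truth is closed-form from the bundle specs: a visit path
contributes one direct segment per consecutive distinct core pair after
dropping non-core names, and one seed–target count per (seed,
other-visited) pair; through-obstacle routes count the obstacle as
visited. Every synthesized streamline is validated against its intent
(realized visit sequence, obstacle constraints); boundary aliasing at a
jagged rasterized surface can make a track exit and immediately re-enter
the same structure, which changes no table and is the one tolerated
deviation. Arc detours are polylines routed over the obstacle's bounding
box with 2 mm clearance and 1.5 mm lateral margin; if no corridor
remains inside the grid, generation fails loudly rather than bending the
route. Waypoint jitter is Gaussian (default sd 0.3 mm), truncated at 2
sd and clamped to 80 % of the structure's extent so the intended visit
path cannot be broken by jitter.

What the phantom does **not** emulate: curving anatomy, fanning and
kissing fibers, partial-volume boundaries, tracking noise, false
positives/negatives of the tracking algorithm, or realistic track-count
proportions. Passing the phantom tests therefore shows the *counting
machinery* is exact under known geometry — it says nothing about
tractography's anatomical validity on real data, where the upstream
reconstruction dominates the error budget.

## Numerical and scale choices

* TCK I/O is Float32; round-trips agree to ≤ 1e-6 mm (float32
  quantization of mm-scale coordinates), and the second round-trip is
  bit-exact. Payloads are Float32LE on write; LE/BE accepted on read.
* All integer comparisons in validation are exact; no tolerance hides a
  counting bug.
* All randomness (waypoint jitter, background offsets, subsampling)
  funnels through explicit seeds; reruns are byte-identical. The
  subsample default mirrors the full-scale analysis' 9000-track
  compute-budget choice, but the recommended phantom mode is the full
  population — subsampling exists for scale parity, not necessity.
* Degenerate inputs: empty tractograms select nothing and write valid
  zero-count files; zero-total structures yield flagged all-zero
  percentage columns rather than division errors; structures with < 3
  voxels refuse to split; absent labels give volume 0 with a warning.
* Test problem sizes: routine tests use 0.2 mm-step phantoms with tens
  to hundreds of tracks (the counting rules are step-invariant once
  sampling is finer than voxels — verified by the densification
  property test); the scale rehearsal runs the preset at 9000 tracks
  and the native 0.05 mm step, completing in a few minutes on one CPU;
  ground-truth recovery is checked across 20 randomized bundle mixes.

## Limitations

* Vertex-based intersection undercounts corner-cutting crossings for
  tractograms with steps comparable to the voxel size unless densified.
* Direction, laterality and synaptic sign are out of reach of the data
  model; segments are unordered.
* Descriptive projection regions ("inferior of SN"-style) are supported
  only as user-supplied ROI labels; the package does not invent their
  geometry, and anatomical bundle identification remains expert work.
* The principal-axis split is coordinate-frame-dependent for
  near-isotropic structures.
* Phantom realism is limited as described above; conclusions about real
  tissue require real tractograms.
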