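# bgtract

Post-tractography connectivity quantification for the basal ganglia.

High-resolution diffusion-MRI tractography of the subthalamic nucleus
(STN), substantia nigra (SNc/SNr) and globus pallidus (GPe/GPi) produces
hundreds of thousands of streamlines. Turning that tractogram into
interpretable connectivity numbers is a post-processing problem: which
tracks touch which nuclei, which portions of a track connect two nuclei
*directly*, and what fraction of the fibers through each structure — and
through each voxel of it — reach each projection site. `bgtract`
implements that post-processing as a tested R package, aimed at anyone
analysing tractograms of deep-brain nuclei (e.g. for deep-brain-stimulation
targeting research) who has a `.tck` tractogram and a NIfTI label volume
and wants reproducible connectivity tables rather than one-off scripts.

## What it computes

Starting from a tractogram `T` (streamlines in world mm) and an integer
label volume with the five core nuclei `C = {STN, SNc, SNr, GPe, GPi}`:

1. **Selection.** Keep the tracks intersecting a seed structure
   (STN, SN = SNc ∪ SNr, or GP = GPe ∪ GPi). Intersection is vertex-based:
   a track visits a structure iff ≥ 1 vertex maps into it (nearest voxel
   centre; at a 0.05 mm step against 0.5 mm voxels this is lossless).
2. **Visit sequences.** Each track is compressed to its ordered maximal
   runs of in-structure vertices (background omitted) — the object all
   counting operates on.
3. **Direct segments.** Each track is cut into segments that join two
   distinct nuclei of `C` with no third member of `C` in between.
   Auxiliary ROIs (internal capsule, named fiber paths, …) are transparent
   and never break directness. Counts are symmetric,
   `n(a,b) = #{segments with endpoints {a,b}}`, and the percentage matrix
   normalizes each column by its structure's total:
   `p(a | b) = 100 · n(a,b) / Σₓ n(x,b)`, so every nonzero column sums to
   100 and the matrix is asymmetric even though counts are symmetric.
4. **Seed–target table.** For each seed `s` and target `t`:
   `p(s,t) = 100 · |{tracks through s and t}| / |{tracks through s}|`,
   each track counted once per (s,t) pair even if it leaves `s` at two
   borders; composite targets use union semantics. Targets below the
   inclusion threshold (1 % for every seed) are dropped.
5. **Voxel projection maps.** For every voxel of a structure, the
   percentage of traversing tracks that also reach a target; untraversed
   voxels are NaN, never 0.
6. **Geometry utilities.** Structure volumes (voxels × voxel volume) and
   the anteromedial/posterolateral split of a structure by a
   principal-axis plane.

Because no post-mortem tractogram is publicly deposited, the package
ships a **phantom generator**: analytic nuclei rasterized at 0.5 mm with
the reported volume proportions, a capsule obstacle, and streamline
bundles with known visit paths (straight, arcing around the obstacle,
crossing through it, pass-through and double-exit classes) whose expected
tables are known in closed form — so every stage is verified by exact
integer comparison against ground truth.

## Worked example

```r
library(bgtract)

spec <- paper_like_spec(n_tracks = 110, rng_seed = 42, step = 0.2)
ph   <- make_phantom(spec)          # label volume + tractogram + truth

sel <- select_seed_tracks(ph$tract, ph$volume, ph$structures)
cat(length(sel$selected), "of", sel$n_total, "tracks intersect a seed\n")
#> 110 of 121 tracks intersect a seed

direct <- direct_connectivity(sel$sequences, ph$structures)
direct$counts
#>     STN SNc SNr GPe GPi
#> STN   0  20  13  20   9
#> SNc  20   0  22   0   7
#> SNr  13  22   0   9   0
#> GPe  20   0   9   0  20
#> GPi   9   7   0  20   0
round(direct$percent, 1)
#>      STN  SNc  SNr  GPe  GPi
#> STN   NA 40.8 29.5 40.8 25.0
#> SNc 32.3   NA 50.0  0.0 19.4
#> SNr 21.0 44.9   NA 18.4  0.0
#> GPe 32.3  0.0 20.5   NA 55.6
#> GPi 14.5 14.3  0.0 40.8   NA
```

The 11 background tracks never touch a seed and are rejected. The counts
are the symmetric direct-segment tallies; the percentages read per
*column*: of all direct connections of the STN, 40.8 % go to the SNc —
each column sums to 100, and the matrix is asymmetric because each
structure has its own total. The same sequences feed the seed–target
table (both direct and indirect connections, ≥ 1 % rule):

```r
tab <- apply_inclusion_threshold(
  seed_target_table(sel$sequences, ph$structures), 1)
round(tab$percent["SN", ], 1)
#>  STN  SNc  SNr  GPe  GPi
#> 55.9   NA   NA 19.6 19.4
```

55.9 % of the tracks through the STN reach the SN (union of SNc and SNr —
less than the SNc and SNr rows summed, because many tracks touch both).
`identical(direct$counts, ph$truth$direct_counts)` is `TRUE`: the
pipeline recovers the phantom's closed-form ground truth exactly.

## The analysis workflow

`analysis/01_build_phantom.R` … `04_seed_tables_maps.R` run the stages
as a narrative: build the full-scale phantom (9000 bundle tracks at the
0.05 mm step), select seed tracks, build the direct-connection matrices,
and produce the seed–target table, voxel projection maps and pallidal
split. Tables land in `results/`, heavy intermediates (TCK/NIfTI) in
`scratch/`. Run them in order from the repository root.

## Scope

The package starts at (tractogram, label volume): image acquisition,
preprocessing, spherical deconvolution and the tracking itself are
upstream (MRtrix parameters such as the 0.05 mm step are carried only as
provenance and phantom defaults). TRK files, DICOM, endpoint-only
connectivity modes and anatomical bundle naming are out of scope; see the
methods vignette (`vignettes/bgtract-methods.Rmd`) for the full design
rationale and limitations.
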