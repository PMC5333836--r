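---
title: "Methods: 3D morphometry of arterial trees with vasctree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D morphometry of arterial trees with vasctree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vasctree)
```

`vasctree` quantifies the 3D architecture of arterial trees imaged by
contrast-perfused microCT. This vignette explains the models and procedures
behind each stage, the tunable parameters and their defaults, the numerical
choices, what the synthetic-tree generator does and does not emulate, and
the known limitations. Every number quoted here is computed by the package's
test suite or by `scripts/acceptance.R`; nothing is asserted beyond what the
code demonstrates.

## From attenuation volume to centerline

A `voxel_volume` holds attenuation values (Hounsfield-like) on an isotropic
grid; the default spacing of 16 µm per axis matches typical whole-kidney
microCT. Segmentation proceeds in four steps.

**Thresholding.** Foreground is the closed attenuation window
`[hu_low, hu_high]`. The window has no default on purpose: contrast-agent
filling differs between preparations, so the window is a per-study choice.
`suggest_hu_window()` computes an Otsu split of the histogram and *reports*
a candidate window; it is never applied silently.

**Closing.** Inhomogeneous contrast filling leaves interior background
cavities that would puncture the skeleton. Morphological closing with a
Euclidean ball (default radius 1 voxel — the size of the cavities the
generator emulates; larger radii risk fusing adjacent vessels whose gap is
under two radii) heals them. The volume is padded before the operation so
closing is extensive: original foreground is never removed, and closing is
idempotent.

**Component cleanup.** 26-connected foreground components below
`min_component_voxels` (default 50, i.e. specks below ~0.2 nL at 16 µm) are
removed as contrast debris.

**Skeletonization.** A sequential 3D thinning peels simple voxels — simple
in the (26, 6) sense: exactly one 26-connected foreground component among
the 26 neighbours and exactly one 6-connected background component touching
a face neighbour — from six directions in turn, preserving curve endpoints
(voxels with at most one foreground neighbour). Every deletion is
individually topology-preserving, so the skeleton has exactly as many
connected components as the mask. Tube ends retract by roughly one vessel
radius before the endpoint lock engages; this is shared by thinning schemes
of this class and is the main source of the few-percent underestimate of
total length at the tips (partly offset by the lattice zig-zag, which
overestimates arc length by a few percent).

One degenerate input deserves mention: a tube of exactly even voxel width
whose axis is axis-aligned and falls exactly between voxel planes has no
central voxel column, and its free end can retract much further. The
reference 3D thinning in scikit-image (Lee's algorithm) loses the same
branch on the identical volume, so we regard this as a property of the
algorithm class; real vessels, with their oblique orientations and
irregular surfaces, do not present it.

**Radius estimation.** Vessel cross-sections are not circles after
discretisation, so the distance `s_min` from a skeleton voxel to its
nearest surface voxel (foreground with a background 6-neighbour)
underestimates the radius. Instead, all surface voxels within
`radius_factor * s_min` (default 1.5) of the skeleton voxel are collected
and their own nearest distances to the skeleton are averaged. Two
numerical details: distances are Euclidean in physical units, and half a
voxel edge is added to the average because surface voxel *centres* sit
about half a voxel inside the continuous vessel surface. With the offset,
axis-voxel estimates on digital cylinders of radii 3–15 voxels are within
one voxel of truth for 100% of axis voxels (the acceptance script
recomputes this). An empty neighbourhood (possible only in degenerate
masks) falls back to `s_min` and is logged.

The stage ends in the ASCII interchange format — one `x y z D` record per
skeleton point, in micrometres, comments prefixed `#` — readable and
writable with `read_centerline()` / `write_centerline()`.

## Reconstruction by staged nearest-neighbour linking

The exported points carry no connectivity. Three linking stages rebuild it,
each calibrated by the point cloud itself through the mean distances to the
2nd, 5th and 10th nearest neighbours (`nn2 ≤ nn5 ≤ nn10`, computed once on
the raw points):

1. **Chain formation (`nn2`).** Nodes are visited in ascending id (file)
   order. Node *i* connects to its nearest *suitable* neighbour *j*:
   degree of *j* below 2, distance below `nn2`, and no existing path
   between *i* and *j*. Distance ties break toward the lower id. We read
   "not already connected" in the network sense — no path — rather than
   merely "no direct edge": with the weaker reading, three mutually close
   points can close a triangle, and the reconstruction is expected to be
   acyclic (stage 2's explicit reachability check makes that expectation
   plain). With the path check, the whole protocol is acyclic by
   construction.
2. **Endpoint completion (`nn5`).** Every node of degree 0 or 1 (ascending
   id, degrees re-evaluated after each accepted edge) connects to the
   nearest node it has no path to, if closer than `nn5`. The reachability
   condition is what keeps a folded chain from biting its own tail;
   without it the nearest node of a chain end is almost always its own
   neighbour and the stage would do nothing.
3. **Sub-network bridging (`nn10`).** Remaining components are labelled;
   each degree-1 node bridges to the nearest node of a *different*
   component when closer than `nn10`, labels updated after every accepted
   bridge.

Reachability and component queries use union–find; the result is
deterministic given the input point order. A literal O(n²) replay of the
three rules — recomputing every distance and reachability naively — serves
as the test oracle; on 100 random point sets (n ≤ 300) the edge sets are
identical and no cycles exist after stage 2.

**Pruning.** In one pass over the post-linking degrees: isolated nodes are
dropped; every spur — a degree-1 node with at most one intermediate
degree-2 node before the nearest bifurcation — is removed whole (tip plus
intermediate); all components except the largest are discarded. The pass
is not iterated to a fixpoint: removing a whole short spur leaves no
dangling remnant, and longer side branches are genuine anatomy.

**Segments.** Edges are partitioned into maximal paths whose interior nodes
have degree 2. A segment's length is the sum of its inter-node Euclidean
distances and its diameter the mean of the embedded node diameters (the
junction node, owned by the parent, contributes the parent's local
diameter — a deliberate convention that leaves per-generation diameter
statistics exact on synthetic trees). Nodes of degree above 3 are treated
as coincident bifurcations. The root is the degree-1 node with the largest
diameter (the injection inlet is the widest entry), overridable in the
configuration.

## Strahler and diameter-defined ordering

Classic Strahler ordering starts at the terminals (order 0) and moves
rootward: a parent takes the maximum of its daughters' orders, incremented
only when at least two daughters tie at the maximum. A second convention —
parent always one above the largest daughter, which counts branching depth
— is implemented behind `convention = "literal"` because descriptions of
stream ordering sometimes state the rule that way; classic is the default
and is validated against an independent recursive oracle on 1000 random
trees. We ship both rather than guess which was intended, since they
genuinely differ on caterpillar-like topologies.

Classic Strahler can give a parent an order different from daughters of
essentially the same calibre. Diameter-defined Strahler ordering (DDSO)
repairs this by alternating until a fixpoint: (i) compute the mean `D_n`
and SD `Δ_n` of segment diameters per current order; (ii) reassign each
segment to the order whose diameter interval

$$\left(\tfrac{(D_{n-1}+\Delta_{n-1}) + (D_n-\Delta_n)}{2},\;
       \tfrac{(D_n+\Delta_n) + (D_{n+1}-\Delta_{n+1})}{2}\right]$$

contains its diameter, with ±∞ replacing the missing neighbour at the
boundary orders. Numerical choices: a segment matching no interval (possible
when intervals invert) keeps its order for that iteration; when overlapping
intervals both match, the lower order wins (the criterion is strict below,
inclusive above); orders are relabelled contiguous from 0 each iteration;
the SD convention defaults to sample SD (n−1), configurable to population
SD; singleton orders have SD 0. The iteration cap is 100 — in practice the
default tree converges in a single iteration — and non-convergence returns
the last state flagged rather than failing. The number of DDSO levels is a
data property: it grows with the diameter span, which the test suite checks
by widening the generator's taper.

## Metrics

* **Fractal dimension** by box counting: boxes of edge `x` anchored at the
  bounding-box minimum; `D_f` is the negative slope of the least-squares
  line through `(ln x, ln N(x))`. The default ladder is geometric with
  factor 2 from twice the voxel spacing to a quarter of the largest
  bounding-box edge — below twice the spacing, counts saturate at the point
  count; above a quarter of the extent, too few boxes remain. The fit's
  `r²` is reported so users can restrict `fit_range`. Analytic checks: a
  sampled line gives 1.00, a solid lattice cube 3.00, a level-4 Menger
  sponge 2.727 (log 20 / log 3), the latter exactly because the ladder of
  powers of 3 aligns with the construction.
* **Totals**: `l = Σ l_k`; `V = Σ π l_k (D_k/2)²`, a cylinder-sum that
  ignores tapering within a segment (the bias is a few percent on tapered
  trees and documented in the tests).
* **Distributions**: half-open bins `[v, v+bin)` with `dD = 10` µm and
  `dl = 50` µm defaults (about half a voxel and three voxels at 16 µm —
  fine enough to resolve the terminal diameter mode without empty-bin
  noise). Relative histograms divide each sample's counts by its own
  segment count, so group averages weigh samples equally regardless of
  size; group averaging uses the union of the samples' bins with missing
  bins as zero.
* **Resistance**: `R = ⟨l⟩ / (n ⟨D⟩⁴)` per order, in arbitrary units —
  the `128 μ / π` Poiseuille constants are deliberately dropped because
  only relative comparisons across orders and groups are meaningful here.
* **Bifurcation angles**: at each branch node, for every daughter pair,
  the angle between vectors from the node toward each daughter's
  `lookahead`-th path node; rigid motions of the input change nothing.
  The default lookahead of 1 (immediate neighbour) is right for analytic
  centerlines, but on skeletons the immediate step is quantised to the 26
  lattice directions: on the default voxelized tree the mean angle reads
  113.7° at lookahead 1 and converges to 92.3° with the segment-endpoint
  vector. `run_sample()` therefore uses `lookahead = "endpoint"` for
  volume inputs; the residual +2° comes from the junction voxel sitting
  slightly inside the branching wedge after thinning.
* **Terminal spacing**: for each degree-1 node except the root, the
  distance to the nearest other terminal. The mean gauges the density of
  the pre-capillary arterioles the network feeds; the variance their
  spatial homogeneity.

## The synthetic generator: what it emulates, and what it does not

`tree_spec()` defines a strictly bifurcating tree: each generation-`g`
segment has length `root_length · length_ratio^g` and diameter
`root_diameter · 2^(−g/m)` with taper exponent `m = 3` (Murray's law for a
symmetric bifurcation: the parent's cubed diameter equals the daughters'
summed cubes); daughters leave each junction at `branching_angle` to each
other, symmetric about the parent, in a branching plane of seeded random
azimuth. The defaults — depth 4, 90° branching, length ratio 0.8, 160 µm
root, 800 µm root length, seed 1 — produce 31 segments with terminal
arterioles of ~64 µm and exactly five diameter-defined order levels, a
realistic small-organ arterial hierarchy at 16 µm resolution. (Terminal
vessels a quarter this calibre exist in real kidneys but are barely one
voxel wide at this resolution; the generator stays above one voxel so that
every stage remains testable, and `voxelize_tree()` refuses sub-voxel
diameters with advice.) Voxelization rasterises the tree as a union of
capsules at 3000 HU over a 0 HU background, adds Gaussian attenuation noise
(SD 100 — wide enough to be visible, narrow enough that a [1000, 4000]
window never misclassifies), and flips interior voxels to background at 0.5
per 1000 foreground voxels to exercise the closing operator.
`tree_to_centerline()` samples the analytic axes directly, with optional
Gaussian jitter and dropout for robustness tests. All randomness hangs off
one seed; identical seeds give bit-identical outputs.

What the generator does *not* emulate: anastomoses (loops), asymmetric
bifurcations, within-segment tapering and curvature, beam-hardening and
reconstruction artifacts, partial contrast filling of whole branches, and
organ-boundary effects. Passing the end-to-end checks therefore shows the
pipeline is correct on clean tree-like data at the stated noise levels —
not that it is robust to every pathology of real microCT. On the default
voxelized tree the pipeline recovers the segment count and the five DDSO
levels exactly, total length within 8%, total volume within 6%, the mean
bifurcation angle within 2.5°, and the skeleton point count within 1% of
the expected 26-connected digitisation of the true axes.

## Problem sizes and runtime

The shipped validation uses volumes of roughly 2.4 M voxels (the default
tree at 16 µm), 100 random point sets of up to 300 points for the linking
oracle, and 1000 random trees of up to 50 segments for the Strahler oracle;
the full test suite runs in under a minute and `scripts/acceptance.R` in
about half a minute on one core. All stages scale to larger volumes
(thinning is linear in foreground voxels; the spatial queries use a uniform
grid index), with the exact k-nearest-neighbour scale computation — O(n²)
by design, since the linking thresholds must be exact — the practical limit
around a few tens of thousands of centerline points.

## Known limitations

* The method targets arterial *trees*; anastomotic (looping) networks are
  outside its scope — cycles surviving to the ordering stage are an error
  by design.
* Thinning retracts tube ends by about one radius, so terminal segment
  lengths are slightly underestimated; the even-width axis-aligned
  degeneracy above is inherited from the algorithm class.
* The cylinder-sum volume ignores within-segment taper.
* `R` per order is proportional, not absolute: no viscosity, no units of
  pressure over flow.
* Group statistics (`run_group()`) provide descriptive means, SDs and
  averaged distributions; hypothesis testing is left to the exported
  tables and the user's statistical environment.
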