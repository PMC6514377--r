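---
title: "Methods: multi-view LiDAR phenotyping of maize row spacing and plant height"
author: "phenolidar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-view LiDAR phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A ground robot carrying a 64-line annular LiDAR drives along the cement
path beside a maize parcel and stops roughly every meter to record a
side-view scan. Each scan is a sensor-centric point cloud; the goal is two
stand-level traits: the spacing between adjacent crop rows, and the height
of individual plants. Side-view observation avoids driving between rows,
but no single viewpoint sees the whole parcel well — self-occlusion and
the growing beam spacing with range starve deep rows of returns — so the
scans from several observation spots must be fused into one cloud before
any trait is measured.

The coordinate convention used throughout: X points into the field, Y
along the robot travel direction (left positive), Z up. The global frame
is the sensor frame at the last observation spot.

## Sensor geometry and the ground blind zone

The scanner's vertical field of view is [-24.8, +2] degrees. Mounted
`H = 0.91` m up a bracket, with `h = 0.25` m between the scanner base and
its optical origin, the steepest beam first reaches the ground at

D = (H + h) / tan(alpha),   alpha = 24.8 degrees,

about 2.5 m (`blindZoneDiameter()`). Ground nearer than `D` is invisible,
so the region of interest starts at that stand-off range. ROI abstraction
(`abstractRoi()`) keeps the half annulus facing the parcel (sign of the
dot product with the heading; boundary points kept), clips the horizontal
range to `[rMin, rMax]` with `rMin` defaulting to `D`, and applies
optional manual x/y windows. `removeGroundSlice()` then finds the minimum
elevation `zMin` and deletes the 5 mm bottom slice; `zMin + 0.005` becomes
the ground reference `heightMin` for plant height.

## Landmark detection

Registration does not align the raw vegetation clouds. Rectangular
0.40 m x 0.30 m metal plates on tripods stand along the path with their
lower border at least 0.1 m above the canopy. Cutting every point below
the canopy threshold leaves plate returns plus sparse residue;
octree-backed DBSCAN (`dbscan()`, `E = 0.52` m — the plate diagonal, so
one plate is always density-connected — and `minPts = 5`) clusters them.
Clusters flatter than `ch = 0.1` m of vertical extent are canopy residue
and are dropped (`filterLandmarkCandidates()`), which also guards against
merged structures via a horizontal-extent cap of twice the plate diagonal.

Each surviving cluster yields one upper corner (`extractCorner()`: max z,
min y, mean x — the plate faces the robot, so x is essentially constant
across the cluster) and a *virtual landmark* (`makeVirtualLandmark()`): a
regular grid interpolated on the plate plane, assumed vertical and
parallel to the travel direction, extending `plateW` along +Y and
`plateH` along -Z from the corner. Grid steps default to 0.01 m. The
virtual clouds, not the raw scans, are what registration aligns — they
are small (a few thousand points), noise-free by construction, and shared
between any two viewpoints that see the same plates.

## Registration

`registerViaLandmarks()` is a two-stage estimate of the rigid transform
between consecutive observation spots, applied afterwards to the full
scans:

1. **Coarse** (`coarseAlign()`): sample-consensus initial alignment over
   FPFH descriptors of the voxel-downsampled virtual clouds. Two
   properties of this target type shaped the implementation. First, a
   perfect plane makes all three Darboux angles vanish identically, so
   the 33-bin histograms alone cannot tell a corner from the interior;
   the matching descriptor therefore appends the normalized neighbour
   count (`fpfhFeatures()$support`), which is exactly the quantity that
   still varies along plate borders. Sample triples are drawn from the
   most distinctive descriptors (plate borders/corners). Second, the
   plate grids are nearly symmetric under half-turns and the corners are
   nearly collinear along the path, so unconstrained fits admit 180-degree
   flip solutions that no residual can reject; candidate rotations are
   therefore capped (30 degrees by default), which encodes the
   acquisition regime — consecutive stops differ by a large translation
   and a small heading change. Candidates are scored by inlier count,
   then inlier RMS, and the best is polished by closed-form re-fits on
   its inliers. A deterministic corner-correspondence alternative
   (`cornerAlign()`, mutual nearest neighbours after centroid shift,
   closed-form Kabsch, degrading to translation-only when the corner set
   is near-collinear) competes with the consensus result under the same
   score, and the better one seeds ICP.
2. **Fine** (`icpRefine()`): point-to-point ICP with closed-form updates,
   correspondence rejection beyond 0.5 m, tolerance 1e-4 m, at most 50
   iterations. The reported residual trace is non-increasing by
   construction: a step that would raise the RMS is not taken.

Scans selected with an incremental step (`selectPlots()`; step 3 by
default, balancing point density against accumulated registration error)
are chained consecutively and composed into the frame of the last
selected plot, then concatenated (`mergeClouds()`).

## Row spacing

On the merged, ground-sliced, sub-canopy cloud, all points are projected
to the horizontal plane — deliberately keeping duplicates, because
projected density is the signal: a vertical stem stacks all its returns
into one or two histogram bins, while leaves spread thinly. The ROI is
divided into 1 m depth bands parallel to the travel direction; each band
is histogrammed along Y with 0.02 m bins (the sensor's range accuracy).
Local maxima over a +/-2 bin window with both an absolute floor (5
counts) and a per-band relative floor (20 % of the band maximum) become
candidate in-row points; the relative floor is what keeps the detector
scale-free when merged densities vary by an order of magnitude between
the nearest and farthest bands. A Hough transform constrained to
[75, 105] degrees (line direction measured from the Y axis, so 90 degrees
means a row perpendicular to travel) votes over the peaks; lines are
extracted greedily with at least 3 supporting peaks, each accepted line
is refined by a total-least-squares fit to its supporters, and all peaks
within 3 accumulator cells of the refined line are retired, so one dense
row cannot spawn near-duplicates. Adjacent-row spacings are evaluated at
the ROI depth midline to tolerate slightly non-parallel lines. Estimates
are compared to reference values by RMSE and the coefficient of
determination (`evalRegression()`).

## Plant height

For each detected row, the cloud within `rowMargin` (0.25 m) of the line
is meshed on the horizontal plane with square cells of `BL = 0.1` m
(half-open, anchored at the neighbourhood bounding-box corner). Cells
whose count exceeds a depth-dependent threshold — 80 for x <= 5 m, 30 for
5 < x <= 8 m, 10 beyond — seed plant detections; 8-connected
super-threshold cells merge into one detection (one plant can straddle a
cell boundary), seeded at the densest cell. The plant height is the
maximum elevation over the 3 x 3 cell neighbourhood of the seed minus the
global ground reference `heightMin = zMin + 0.005`. The ground reference
is global, as the processing chain defines it; on sloped terrain this
biases heights, which is a known limitation. Evaluation groups plants by
depth (0 <= x < 5, 5 <= x < 8, x >= 8) and reports per-plant absolute
errors, error ratios, and per-group RMSE (`heightErrorTable()`).

## The synthetic field and scanner

No field recordings ship with the package, so every claim is exercised
against a simulator whose ground truth is exact by construction.

`buildField()` plants `nRows` rows (default 20) perpendicular to the
path, spaced 0.60 m with 0.02 m Gaussian jitter, starting 3 m from the
path and extending 8 m deep at 0.25 m in-row spacing. A plant is a dense
vertical stem (700 points per meter of height, 1.5 cm radius) topped at a
truncated-Gaussian height (0.60 m +/- 0.04, clipped at 2.5 s.d.) plus
three sparse arched leaves (15 points each — an order of magnitude
sparser per projected bin than stems, which is the assumption the row
detector rests on). The ground is a 25 points/m^2 carpet at z = 0. Five
plates stand at x = 2.7 m at uniformly random path positions at least 1 m
apart — random placement matters: near-regular plate layouts make the
plate-to-plate correspondence ambiguous under translation by one plate
interval. Plate tops sit `clearance = 0.12` m above the tallest plant.

`simulateScan()` transforms the world into a spot's sensor frame
(`spotPoses()`: spots 1 m apart, 1.16 m above ground, heading jitter 0.3
degrees s.d.) and applies, in order: vertical-FOV and blind-radius
culling; discrete-beam elevation gating — a point survives only within
0.06 degrees of one of the 64 beam elevations, which reproduces the
real vertical line structure whose spacing grows from ~2 cm at 3 m to
~7 cm at 10 m and is the mechanism by which plate-corner and stem-top
estimates degrade with range; 1/range azimuthal thinning beyond 4 m;
geometric occlusion by nearer plants (rays grazing within 3 stem radii
below a nearer plant's top are lost; the factor 3 stands in for the leaf
sheath and foliage around the bare stem); 10 % dropout; and Gaussian
range noise (sigma = 0.02 m) along the ray. Everything is deterministic
given the seed.

What the simulator does **not** model: beam divergence and multi-return
behaviour, wind deformation, terrain relief, reflectance, and real leaf
geometry. Plates are sampled at 0.02 m horizontally but 0.004 m
vertically — fine enough that every beam crossing the plate face returns
points, as it would from a continuous surface; coarser vertical sampling
aliases against the beam grid and produces spurious corner errors of
tens of centimeters. A consequence of modelling only the parcel surfaces
is that a simulated scan holds ~4 x 10^4 points rather than the ~1.3
million of a full 360-degree field frame; the in-parcel return densities
per stem and per plate, which are what the pipeline actually consumes,
are matched to the beam geometry instead.

## Numerical choices and degenerate inputs

- Half-open binning `[lo, hi)` everywhere (grid cells, histograms);
  boundary points go up. Peak ties resolve to the lower-y bin.
- Hough member collection spans 1.5 accumulator cells around the winning
  cell because a peak population straddling two cells can sit up to 1.5
  cells from the winner's center depending on bin phase.
- DBSCAN neighbourhoods include the point itself; border points reachable
  from two clusters keep the first-discovered cluster. The octree
  (leaf size E/2) returns exactly the points within the radius —
  verified against all-pairs scans in the tests.
- `kabsch()` refuses fewer than 3 pairs or collinear sources;
  `cornerAlign()` degrades to translation-only below a 0.05 m second
  singular value; `icpRefine()` falls back to all correspondences if
  rejection leaves fewer than 3.
- Empty results are legal values (empty ROI, no landmarks, no lines), not
  errors, except where the contract requires data (ground slice of an
  empty cloud, height of an empty footprint).

## Validation scales

The test suite validates each stage against brute-force oracles and the
whole chain end to end. The end-to-end study runs the default 20-row
parcel (about 3 x 10^5 world points, 10 spots, merge step 3) in a few
seconds; registration accuracy is assessed over 20 independently seeded
two-spot trials on a reduced parcel with a fixed irregular plate layout.
Group RMSEs of plant height are estimates with sampling error of roughly
`rmse / sqrt(2 n)`; the expectation that accuracy does not *improve* with
depth is therefore asserted up to one such standard error — with ~150
plants per group that is about 1 mm — rather than as a strict ordering of
point estimates.

## Known limitations

- The global ground reference assumes flat terrain.
- Row detection assumes nearly straight rows within the constrained angle
  range; curved rows are out of scope.
- Landmark identity is not tracked across more than two views; chaining
  accumulates pairwise error linearly with the number of merged spots.
- DSR accounting in the evaluation report counts a plate as "in view"
  from pose geometry alone (range window and FOV), not from per-point
  provenance.
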