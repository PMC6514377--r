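# phenolidar

Field phenotyping of maize from multi-view ground LiDAR: **crop row
spacing** and **single-plant height** extracted from side-view 3D scans
collected by a robot that stops about every meter along the path beside a
parcel.

The package is aimed at people building or evaluating ground-based
phenotyping pipelines: it implements the full processing chain from raw
per-viewpoint point clouds to trait tables, and ships a synthetic
field/scanner simulator with exact ground truth so that every stage — and
the chain end to end — can be validated without field recordings.

## The method

A 64-line annular scanner (vertical field of view [-24.8°, +2°], ~2 cm
range accuracy) sits `H + h = 1.16` m above ground and cannot see the
ground annulus of radius

```
D = (H + h) / tan(α),   α = 24.8°  →  D ≈ 2.5 m
```

so scans are taken beyond that stand-off. The chain is:

1. **ROI abstraction** — keep the half annulus facing the parcel, clip
   range to `[D, 120 m]` and manual x/y windows, delete the bottom 5 mm
   slice above the minimum elevation `z_min` (the ground reference
   downstream is `z_min + 0.005`).
2. **Landmark detection** — 0.40 m × 0.30 m plates raised ≥ 0.1 m above
   the canopy serve as fiducials. Points above the canopy cut are
   clustered with octree-backed DBSCAN (`E = 0.52` m, the plate diagonal;
   `MinPts = 5`); clusters flatter than `ch = 0.1` m are discarded; each
   plate yields an upper corner (max z, min y, mean x) from which a
   *virtual landmark* — a regular grid on the assumed-vertical plate
   plane — is interpolated.
3. **Registration & fusion** — the pooled virtual landmark clouds of two
   viewpoints are aligned coarsely (FPFH/SAC-IA with a deterministic
   corner-correspondence competitor) and refined with point-to-point ICP;
   the resulting `R′, T′` is applied to the full scans. Every third spot
   is merged by default, chained into the frame of the last one.
4. **Row spacing** — project the merged sub-canopy cloud onto the ground
   plane, histogram each 1 m depth band along Y (0.02 m bins), take
   stem-dominated peaks, and fit row lines with a Hough transform
   constrained to [75°, 105°] with ≥ 3 supporting peaks; row spacing
   `RS` is the distance between adjacent lines.
5. **Plant height** — around each row line, mesh the plane with
   `BL = 0.1` m cells; cells whose count exceeds a depth-dependent
   threshold (`PtsThre` = 80 / 30 / 10 for x ≤ 5 / ≤ 8 / > 8 m) seed
   plants; `PH = Height_max − Height_min` with `Height_max` the top of
   the 3 × 3 cell neighbourhood and `Height_min = z_min + 0.005`.

The methods vignette (`vignettes/phenolidar-methods.Rmd`) documents the
model, every tunable parameter, and the simulator's assumptions and
limits.

## Worked example

```r
library(phenolidar)

blindZoneDiameter(mountGeometry(H = 0.91, h = 0.25, alphaDeg = 24.8))
#> [1] 2.51047
packetRate(1333440, 384)        # scanner data stream, packets per second
#> [1] 3472.5

# a 20-row synthetic parcel observed from 10 spots, with ground truth
ds <- simulateDataset(fieldSpec(), landmarkSpec(), scanSpec(),
                      nSpots = 10, seed = 0)
ds$scans[[3]]
#> PointCloud with 16275 points in frame 'sensor'
#>   x: [2.482, 11.198]  y: [-2.498, 9.697]  z: [-1.172, -0.040] m

res <- runPipeline(ds, pipelineConfig())
res$report
#> Evaluation report
#>   landmark DSR: mean 100.0% over 3 scans
#>   rows: 20 detected / 20 true; spacing RMSE 0.0055 m, R^2 0.9226
#>   height RMSE by depth group:
#>     0<=x<5   0.017 m (n=122)
#>     5<=x<8   0.017 m (n=150)
#>     x>=8     0.018 m (n=171)

round(head(res$spacings, 5), 3)        # estimated row spacings (m)
#> [1] 0.627 0.597 0.615 0.630 0.609
round(head(ds$truth$spacings, 5), 3)   # true row spacings (m)
#> [1] 0.625 0.593 0.627 0.625 0.608
```

Reading the report: all 20 rows were recovered and their spacings agree
with the generated truth to ~6 mm RMSE; every selected scan detected all
5 plates in view (DSR 100 %); per-plant height errors are grouped by
depth into the field, where accuracy degrades as beam spacing and
occlusion grow.

`inst/extdata/` carries two small published evaluation tables (per-plant
height measurements and landmark detection counts from a field
acquisition of this design) used by the tests to verify the evaluation
arithmetic — group RMSEs, detection success rates — against printed
values.

A thin command-line front end over these functions is installed at
`inst/scripts/phenolidar` with subcommands `simulate`, `roi`,
`landmarks`, `register`, `rows`, `run`.

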