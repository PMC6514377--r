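Package: phenolidar
Title: Field-Based Maize Phenotyping from Multi-View Ground LiDAR Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for extracting crop row spacing and single-plant heights
    of field-grown maize from side-view 3D LiDAR point clouds collected by a
    ground robot at multiple observation spots. Scans are merged through
    fiducial landmark plates detected with octree-accelerated DBSCAN, turned
    into virtual planar landmarks, and registered by feature-based coarse
    alignment (FPFH/SAC-IA) followed by iterative closest point refinement.
    Row spacing is measured with depth-band point histograms and an
    angle-constrained Hough transform; plant height with horizontal grid
    point density seeding and 3x3 neighbourhood maximum elevation. A
    synthetic field and scanner simulator with full ground truth supports
    end-to-end validation. Readers and writers for PCD, PLY and XYZ point
    cloud files are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
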