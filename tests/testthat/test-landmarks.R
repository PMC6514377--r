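test_that("canopy cut keeps exactly the points above the threshold", {
  set.seed(2)
  m <- cbind(runif(400, 0, 5), runif(400, 0, 5), runif(400, 0, 1.2))
  out <- cutAboveCanopy(pointCloud(m), 0.75)
  expect_equal(unname(coords(out)), unname(m[m[, 3] > 0.75, , drop = FALSE]))
  expect_equal(nPoints(cutAboveCanopy(pointCloud(m), 2)), 0L)

  plate <- makePlateCloud(2, 1, 0.8)
  plants <- cbind(runif(200, 0, 4), runif(200, 0, 4), runif(200, 0, 0.7))
  mix <- pointCloud(rbind(plate, plants))
  expect_equal(nPoints(cutAboveCanopy(mix, 0.75)), nrow(plate))
})

test_that("plate candidates are filtered by vertical extent", {
  plate <- makePlateCloud(2, 0, 0.8)                   # extent 0.30
  flat <- cbind(runif(30, 4, 4.3), runif(30, 4, 4.3),
                runif(30, 0.80, 0.82))                 # extent 0.02
  pc <- pointCloud(rbind(plate, flat))
  cl <- dbscan(pc, dbscanParams())
  expect_equal(nClusters(cl), 2L)
  keep <- filterLandmarkCandidates(cl, pc, landmarkFilterParams())
  expect_length(keep, 1L)
  expect_equal(keep, cl$labels[1])                     # the plate cluster
})

test_that("five plates among noise blobs yield exactly five candidates", {
  set.seed(8)
  plates <- do.call(rbind, lapply(seq(0, 8, by = 2), function(y0)
    makePlateCloud(2.5, y0, 0.9)))
  # flat canopy-residue blobs (all near one elevation so that chance
  # merges of nearby blobs still stay below the 0.1 m extent threshold)
  blobs <- do.call(rbind, lapply(1:20, function(i) {
    ctr <- c(runif(1, 5, 15), runif(1, -5, 15), 0.9)
    t(ctr + t(matrix(runif(36, -0.02, 0.02), ncol = 3)))
  }))
  pc <- pointCloud(rbind(plates, blobs))
  cl <- dbscan(pc, dbscanParams())
  keep <- filterLandmarkCandidates(cl, pc, landmarkFilterParams())
  expect_length(keep, 5L)
})

test_that("corner extraction follows the max-z / min-y / mean-x rule", {
  g <- expand.grid(y = seq(1.0, 1.4, by = 0.05), z = seq(0.8, 1.1, 0.05))
  m <- cbind(2, g$y, g$z)
  expect_equal(unname(extractCorner(m)), c(2.0, 1.0, 1.1))
  expect_equal(unname(extractCorner(matrix(c(1, 2, 3), 1))), c(1, 2, 3))
  # invariant to order and duplication
  expect_equal(extractCorner(m[sample(nrow(m)), ]), extractCorner(m))
  expect_equal(extractCorner(rbind(m, m)), extractCorner(m))
  expect_error(extractCorner(matrix(numeric(0), 0, 3)), "empty")
})

test_that("virtual landmark grids have the documented geometry", {
  corner <- c(2, 1, 1.1)
  p <- landmarkFilterParams()
  four <- makeVirtualLandmark(corner, p, hStep = 0.40, vStep = 0.30)
  expect_equal(nPoints(four), 4L)
  fine <- makeVirtualLandmark(corner, p, hStep = 0.01, vStep = 0.01)
  expect_equal(nPoints(fine), 41L * 31L)
  xyz <- coords(fine)
  expect_true(all(xyz[, 1] == corner[1]))
  expect_equal(min(xyz[, 2]), corner[2])
  expect_equal(max(xyz[, 3]), corner[3])
  # steps larger than the plate degenerate to a single row/column
  expect_equal(nPoints(makeVirtualLandmark(corner, p, 1, 1)), 1L)
})

test_that("landmark detection finds the plates of a simulated scan", {
  ds <- smallDataset(seed = 4, nSpots = 2)
  cfg <- pipelineConfig()
  roi <- abstractRoi(ds$scans[[1]], cfg$roi)
  zMin <- min(coords(roi)[, 3])
  det <- detectLandmarks(roi, cfg$dbscan,
                         landmarkFilterParams(canopyCutZ = zMin + 0.72))
  expect_gte(length(det), 3L)   # working minimum for registration
  truthC <- applyTransform(ds$truth$corners,
                           invertTransform(ds$poses[[1]]))
  dc <- do.call(rbind, lapply(det, `[[`, "corner"))
  nn <- phenolidar:::nearestNeighborCpp(truthC, dc)
  expect_true(all(nn$distance[seq_len(min(3, nrow(truthC)))] <= 0.05))

  empty <- detectLandmarks(pointCloud(cbind(1, 1, 0.1)), cfg$dbscan,
                           landmarkFilterParams(canopyCutZ = 0.5))
  expect_length(empty, 0L)
})

test_that("detection success rate is the DNL/NLV percentage", {
  expect_equal(detectionSuccessRate(4, 6), 66.7, tolerance = 0.05)
  expect_equal(detectionSuccessRate(5, 5), 100)
  expect_equal(detectionSuccessRate(0, 4), 0)
  expect_error(detectionSuccessRate(1, 0), "NLV")
  expect_error(detectionSuccessRate(5, 4), "DNL")
})
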