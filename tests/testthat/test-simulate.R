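test_that("field generation honours the specification and its truth", {
  one <- buildField(fieldSpec(parcelDepth = 0.1, nRows = 1,
                              groundPointsPerM2 = 0),
                    landmarkSpec(nPlates = 0), seed = 1)
  expect_equal(nrow(one$truth$plants), 1L)
  expect_equal(max(coords(one$world)[, 3]), one$truth$plants$height[1],
               tolerance = 1e-9)

  nj <- buildField(fieldSpec(rowSpacingSd = 0), landmarkSpec(), seed = 2)
  expect_true(all(abs(nj$truth$spacings - 0.6) < 1e-12))

  # determinism: identical seed, bit-identical world and truth
  a <- buildField(seed = 7)
  b <- buildField(seed = 7)
  expect_identical(coords(a$world), coords(b$world))
  expect_identical(a$truth, b$truth)

  # plate corners sit above the canopy with the required clearance
  f <- buildField(seed = 3)
  expect_gte(min(f$truth$corners[, "z"]) - 0.30 - f$truth$canopyTop,
             0.1)
})

test_that("noise-free scans are subsets of the transformed world", {
  f <- buildField(fieldSpec(parcelDepth = 2, nRows = 4),
                  landmarkSpec(plateYs = c(0.2, 1.3)), seed = 4)
  pose <- rigidTransform(diag(3), c(0, 1, 1.16))
  sc <- simulateScan(f$world, pose, scanSpec(rangeNoiseSd = 0, dropout = 0,
                                             occlusion = FALSE), seed = 5)
  expect_gt(nPoints(sc), 100)
  back <- applyTransform(coords(sc), pose)   # sensor -> world
  nn <- phenolidar:::nearestNeighborCpp(back, coords(f$world))
  expect_lt(max(nn$distance), 1e-9)
})

test_that("scans respect the blind radius and vertical field of view", {
  f <- buildField(seed = 4)
  pose <- rigidTransform(diag(3), c(0, 2, 1.16))
  sc <- simulateScan(f$world, pose, scanSpec(occlusion = FALSE), seed = 6)
  m <- coords(sc)
  rh <- sqrt(m[, 1]^2 + m[, 2]^2)
  blind <- blindZoneDiameter(mountGeometry())
  expect_gte(min(rh), blind - 0.1)          # 0.1 m slack for range noise
  elev <- atan2(m[, 3], rh) * 180 / pi
  expect_gte(min(elev), -24.8 - 0.5)
  expect_lte(max(elev), 2 + 0.5)
})

test_that("range noise has the configured half-normal magnitude", {
  f <- buildField(seed = 4)
  pose <- rigidTransform(diag(3), c(0, 3, 1.16))
  spec0 <- scanSpec(rangeNoiseSd = 0, dropout = 0, occlusion = FALSE)
  specN <- scanSpec(rangeNoiseSd = 0.02, dropout = 0, occlusion = FALSE)
  clean <- coords(simulateScan(f$world, pose, spec0, seed = 8))
  noisy <- coords(simulateScan(f$world, pose, specN, seed = 8))
  expect_equal(dim(clean), dim(noisy))
  disp <- sqrt(rowSums((noisy - clean)^2))
  expect_gt(length(disp), 1e4)
  # mean |N(0, 0.02)| = 0.02 * sqrt(2/pi) = 0.016
  expect_gt(mean(disp), 0.015)
  expect_lt(mean(disp), 0.025)
})

test_that("scan simulation is deterministic given the seed", {
  f <- buildField(seed = 4)
  pose <- rigidTransform(rotationZ(0.2), c(0, 1, 1.16))
  a <- simulateScan(f$world, pose, scanSpec(), seed = 9,
                    stems = f$truth$stems)
  b <- simulateScan(f$world, pose, scanSpec(), seed = 9,
                    stems = f$truth$stems)
  expect_identical(coords(a), coords(b))
})

test_that("occlusion only removes points and spares the foreground", {
  f <- buildField(seed = 4)
  pose <- rigidTransform(diag(3), c(0, 2, 1.16))
  off <- simulateScan(f$world, pose, scanSpec(occlusion = FALSE), seed = 10)
  on <- simulateScan(f$world, pose, scanSpec(occlusion = TRUE), seed = 10,
                     stems = f$truth$stems)
  expect_lt(nPoints(on), nPoints(off))
  # removal rate grows with depth
  xs <- function(pc) coords(pc)[, 1]
  lossNear <- 1 - sum(xs(on) < 5) / sum(xs(off) < 5)
  lossFar <- 1 - sum(xs(on) > 8) / sum(xs(off) > 8)
  expect_gt(lossFar, lossNear)
})

test_that("written datasets are reproducible and complete", {
  dir <- withr::local_tempdir()
  field <- fieldSpec(parcelDepth = 1.5, nRows = 5)
  lm <- landmarkSpec(plateYs = c(0.4, 1.4, 2.3))
  ds <- makeDataset(field, lm, scanSpec(), nSpots = 3, outDir = dir,
                    seed = 11)
  expect_true(all(file.exists(unlist(ds$files))))
  expect_length(ds$files$spots, 3L)
  back <- readCloud(ds$files$spots[2])
  expect_equal(nPoints(back), nPoints(ds$scans[[2]]))
  expect_lt(max(abs(coords(back) - coords(ds$scans[[2]]))), 1e-6)
  tj <- jsonlite::read_json(ds$files$truth, simplifyVector = FALSE)
  expect_length(tj$poses, 3L)
  expect_equal(length(tj$rows$rho), 5L)
  # truth spacing statistics follow the field specification
  big <- buildField(fieldSpec(nRows = 40), landmarkSpec(), seed = 12)
  rs <- big$truth$spacings
  expect_lt(abs(mean(rs) - 0.6), 2 * 0.02 / sqrt(length(rs)))
})
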