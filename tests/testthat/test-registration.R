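test_that("kabsch inverts synthetic rigid motions exactly", {
  set.seed(12)
  src <- matrix(rnorm(60), ncol = 3)
  expect_equal(rotation(kabsch(src, src)), diag(3), tolerance = 1e-9)
  expect_equal(translation(kabsch(src, src)), c(0, 0, 0), tolerance = 1e-9)

  shifted <- sweep(src, 2, c(1, 2, 3), `+`)  # dst = src + (1,2,3)
  tr <- kabsch(src, shifted)
  expect_equal(translation(tr), c(1, 2, 3), tolerance = 1e-9)
  expect_equal(rotation(tr), diag(3), tolerance = 1e-9)

  R <- rotationZ(10); t <- c(0.3, -1, 2)
  dst <- applyTransform(src, rigidTransform(R, t))
  rec <- kabsch(src, dst)
  expect_lt(max(abs(rotation(rec) - R)), 1e-9)
  expect_lt(max(abs(translation(rec) - t)), 1e-9)
  # returned rotations honour the orthonormality/determinant invariants
  expect_lt(max(abs(crossprod(rotation(rec)) - diag(3))), 1e-9)
  expect_lt(abs(det(rotation(rec)) - 1), 1e-9)

  expect_error(kabsch(src[1:2, ], src[1:2, ]), "3 matched")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "collinear")
})

test_that("rigid transform algebra composes and inverts", {
  a <- rigidTransform(rotationZ(20), c(1, 0, 0))
  b <- rigidTransform(rotationZ(-5), c(0, 2, -1))
  p <- matrix(rnorm(30), ncol = 3)
  expect_equal(applyTransform(applyTransform(p, b), a),
               applyTransform(p, composeTransforms(a, b)))
  ident <- composeTransforms(a, invertTransform(a))
  expect_equal(rotation(ident), diag(3), tolerance = 1e-12)
  expect_equal(translation(ident), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(rotationAngle(rotationZ(33)), 33)
})

test_that("coarse alignment recovers offsets between plate sets", {
  p <- landmarkFilterParams()
  vl <- function(corners) concatClouds(lapply(corners, function(cc)
    makeVirtualLandmark(cc, p, 0.01, 0.01)))
  corners <- list(c(2.7, 0.2, 1.1), c(2.7, 1.7, 1.1), c(2.7, 4.3, 1.1))
  src <- vl(corners)
  # identical clouds: identity within tolerance, flagged converged
  same <- coarseAlign(src, src, nSamples = 300, seed = 1)
  expect_true(attr(same, "converged"))
  expect_lt(sqrt(sum(translation(same)^2)), 0.05)

  dst <- vl(lapply(corners, function(cc) cc + c(0, 1, 0)))
  tr <- coarseAlign(src, dst, seed = 2)
  expect_lt(max(abs(translation(tr) - c(0, 1, 0))), 0.05)
  # determinism under a fixed seed
  tr2 <- coarseAlign(src, dst, seed = 2)
  expect_identical(rotation(tr), rotation(tr2))
  expect_identical(translation(tr), translation(tr2))
})

test_that("corner alignment is exact on clean corners and guards flips", {
  A <- rbind(c(2.7, 0.2, 1.1), c(2.7, 1.7, 1.15), c(2.7, 4.3, 1.05),
             c(2.7, 6.1, 1.1))
  B <- sweep(A, 2, c(0.01, -3, 0.002), `+`)
  tr <- cornerAlign(A, B)
  expect_lt(max(abs(translation(tr) - c(0.01, -3, 0.002))), 1e-9)
  # near-collinear corners: rotation must stay small (no flip solutions)
  expect_lt(rotationAngle(rotation(tr)), 30)
  expect_error(cornerAlign(A[1:2, ], B[1:2, ]), ">= 3")
})

test_that("ICP refines to the optimum and never increases the residual", {
  set.seed(33)
  m <- matrix(rnorm(900), ncol = 3)
  src <- pointCloud(m)
  truth <- rigidTransform(rotationZ(3), c(0.1, -0.15, 0.05))
  dst <- applyTransform(src, truth)

  atTruth <- icpRefine(src, dst, init = truth)
  expect_lte(atTruth$nIterations, 2L)
  expect_lt(atTruth$rmsResidual, 1e-6)

  # noisy target, rough init: recovered translation within sensor noise
  noisy <- pointCloud(coords(dst) + matrix(rnorm(900, sd = 0.02), ncol = 3))
  rough <- rigidTransform(diag(3), translation(truth) + c(0.1, -0.1, 0.05))
  res <- icpRefine(src, noisy, init = rough)
  expect_lt(max(abs(translation(res$transform) - translation(truth))), 0.03)

  # monotone residual trace on arbitrary input
  junk <- pointCloud(matrix(runif(300, -2, 2), ncol = 3))
  res2 <- icpRefine(junk, dst, init = rigidTransform())
  expect_true(all(diff(res2$residuals) <= 1e-12))
  expect_lte(res2$rmsResidual, res2$residuals[1])
  expect_error(icpRefine(pointCloud(), dst), "non-empty")
})

test_that("scan self-registration through landmarks is the identity", {
  ds <- smallDataset(seed = 6, nSpots = 2)
  cfg <- pipelineConfig()
  roi <- abstractRoi(ds$scans[[1]], cfg$roi)
  zMin <- min(coords(roi)[, 3])
  res <- registerViaLandmarks(
    roi, roi, lmParams = landmarkFilterParams(canopyCutZ = zMin + 0.72),
    seed = 3)
  expect_lt(sqrt(sum(translation(res$transform)^2)), 0.01)
  expect_lt(rotationAngle(rotation(res$transform)), 0.2)
  expect_error(
    registerViaLandmarks(pointCloud(cbind(1, 1, 0.2)), roi,
                         lmParams = landmarkFilterParams(canopyCutZ = 0.5)),
    "landmark")
})

test_that("merging preserves point counts and applies the transforms", {
  a <- pointCloud(matrix(runif(300), ncol = 3))
  b <- pointCloud(matrix(runif(300), ncol = 3) + 5)
  tr <- rigidTransform(diag(3), c(1, 0, 0))
  merged <- mergeClouds(list(a, b), list(rigidTransform(), tr))
  expect_equal(nPoints(merged), 200L)
  expect_equal(frameId(merged), "global")
  expect_equal(coords(merged)[101:200, 1], coords(b)[, 1] + 1)

  one <- mergeClouds(list(a), list(rigidTransform()), frameId = "sensor")
  expect_equal(coords(one), coords(a))
  expect_error(mergeClouds(list(a, b), list(tr)), "one transform per")
})

test_that("merging simulated views at true poses reconstructs the world", {
  ds <- smallDataset(seed = 9, nSpots = 4, occlusion = FALSE)
  merged <- mergeClouds(ds$scans, ds$poses, frameId = "world")
  set.seed(1)
  sub <- coords(merged)[sample(nPoints(merged), 3000), ]
  nn <- phenolidar:::nearestNeighborCpp(sub, coords(ds$world))
  expect_lte(unname(quantile(nn$distance, 0.95)), 2 * 0.02)
})

test_that("plot selection follows the incremental step rule", {
  expect_equal(selectPlots(30, 1), 1:30)
  expect_equal(selectPlots(30, 2), seq(2, 30, by = 2))
  expect_length(selectPlots(30, 2), 15L)
  expect_equal(selectPlots(30, 3), seq(3, 30, by = 3))
  expect_length(selectPlots(30, 3), 10L)
  expect_equal(selectPlots(5, 9), 5L)
})
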