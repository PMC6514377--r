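test_that("blind zone formula matches the mount geometry", {
  # default mount: printed working value ~2.49 m (alpha quoted coarsely);
  # analytic value 2.511, agreement within 1 %
  D <- blindZoneDiameter(mountGeometry(H = 0.91, h = 0.25, alphaDeg = 24.8))
  expect_lt(abs(D - 2.49) / 2.49, 0.01)
  expect_equal(blindZoneDiameter(mountGeometry(0.5, 0.5, 45)), 1.0)
  # tan(26.565 deg) = 0.5 to 5 digits
  expect_equal(blindZoneDiameter(mountGeometry(0.7, 0.3, 26.565)), 2.0,
               tolerance = 1e-4)
  expect_error(mountGeometry(alphaDeg = 0), "strictly between")
  expect_error(mountGeometry(alphaDeg = 95), "strictly between")
})

test_that("blind zone is monotone in depression angle and mount height", {
  alphas <- seq(5, 85, by = 5)
  D <- vapply(alphas, function(a)
    blindZoneDiameter(mountGeometry(0.9, 0.3, a)), numeric(1))
  expect_true(all(diff(D) < 0))
  hs <- seq(0.2, 2, by = 0.2)
  D2 <- vapply(hs, function(h)
    blindZoneDiameter(mountGeometry(h, 0.25, 24.8)), numeric(1))
  expect_true(all(diff(D2) > 0))
})

test_that("packet rate is the exact quotient", {
  expect_equal(packetRate(1333440, 384), 3472.5)
  expect_equal(packetRate(384, 384), 1.0)
  expect_equal(packetRate(266880, 384), 695.0)
  expect_error(packetRate(1000, 0), "positive")
})

test_that("ROI abstraction equals the brute-force point filter", {
  set.seed(42)
  m <- cbind(runif(1000, -20, 20), runif(1000, -20, 20), runif(1000, -2, 2))
  roi <- roiSpec(headingDeg = 30, rMin = 2.5, rMax = 15,
                 xRange = c(-10, 12), yRange = c(-8, 14))
  got <- coords(abstractRoi(pointCloud(m), roi))
  u <- c(cos(30 * pi / 180), sin(30 * pi / 180))
  r <- sqrt(m[, 1]^2 + m[, 2]^2)
  keep <- (m[, 1] * u[1] + m[, 2] * u[2]) >= 0 & r >= 2.5 & r <= 15 &
    m[, 1] >= -10 & m[, 1] <= 12 & m[, 2] >= -8 & m[, 2] <= 14
  expect_equal(unname(got), unname(m[keep, , drop = FALSE]))
})

test_that("ROI removes the opposite half annulus and the blind zone", {
  roi <- roiSpec(headingDeg = 0, rMin = 2.5, rMax = 120)
  pc <- pointCloud(rbind(c(-5, 0, 0),    # opposite the heading
                         c(1.25, 0, 0),  # inside the blind zone
                         c(0, 3, 1),     # boundary: dot product zero, kept
                         c(5, 0, 0)))
  out <- coords(abstractRoi(pc, roi))
  expect_equal(nrow(out), 2L)
  expect_true(all(out[, 1] >= 0))
  # idempotent, never adds points
  again <- abstractRoi(abstractRoi(pc, roi), roi)
  expect_equal(coords(again), out)
})

test_that("ground slice removes exactly the bottom 5 mm band", {
  pc <- pointCloud(cbind(0, 0, c(0, 0.004, 0.006)))
  gs <- removeGroundSlice(pc, 0.005)
  expect_equal(gs$zMin, 0)
  expect_equal(unname(coords(gs$cloud)[, 3]), 0.006)

  flat <- pointCloud(cbind(runif(10), runif(10), 0))
  gsf <- removeGroundSlice(flat)
  expect_equal(nPoints(gsf$cloud), 0L)
  expect_equal(gsf$zMin, 0)

  set.seed(5)
  m <- cbind(runif(500), runif(500), runif(500, -1, 1))
  gsr <- removeGroundSlice(pointCloud(m), 0.1)
  zmin <- min(m[, 3])
  expect_equal(unname(coords(gsr$cloud)),
               unname(m[m[, 3] > zmin + 0.1, , drop = FALSE]))
  expect_error(removeGroundSlice(pointCloud()), "empty")
})

test_that("octree radius queries equal the all-pairs scan", {
  set.seed(9)
  m <- matrix(runif(6000, 0, 4), ncol = 3)
  idx <- octreeIndex(m, leafSize = 0.3)
  for (q in 1:50) {
    ctr <- runif(3, 0, 4)
    r <- runif(1, 0.05, 1.5)
    expect_identical(radiusQuery(idx, ctr, r),
                     sort(bruteRadiusQuery(m, ctr, r)))
  }
  # radius covering everything returns all ids
  expect_identical(radiusQuery(idx, c(2, 2, 2), 10), seq_len(nrow(m)))
  expect_error(radiusQuery(idx, c(0, 0, 0), 0), "radius")
})

test_that("tiny radius returns only the query point itself", {
  m <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  idx <- octreeIndex(m, leafSize = 0.5)
  expect_identical(radiusQuery(idx, c(0, 0, 0), 0.5), 1L)
})
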