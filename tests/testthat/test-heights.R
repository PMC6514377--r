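test_that("grid meshing conserves counts and matches brute-force binning", {
  set.seed(18)
  m <- cbind(runif(800, 0, 3.3), runif(800, -1, 1.4), runif(800))
  mesh <- meshDensity(m, BL = 0.1)
  expect_equal(sum(mesh$counts), 800L)
  ci <- floor((m[, 1] - min(m[, 1])) / 0.1) + 1
  cj <- floor((m[, 2] - min(m[, 2])) / 0.1) + 1
  for (k in sample(800, 25))
    expect_equal(mesh$counts[ci[k], cj[k]],
                 sum(ci == ci[k] & cj == cj[k]))
  # half-open cells: boundary points go to the higher-index cell
  mb <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.2, 0.1, 0))
  meshb <- meshDensity(mb, BL = 0.1)
  expect_equal(meshb$cellIndex[, "i"], c(1L, 2L, 3L))
  expect_equal(meshb$cellIndex[, "j"], c(1L, 1L, 2L))
  # ten points in one cell
  ten <- meshDensity(cbind(runif(10, 0, 0.09), runif(10, 0, 0.09), 0), 0.1)
  expect_equal(ten$counts, matrix(10L, 1, 1))
  empty <- meshDensity(matrix(numeric(0), 0, 3), 0.1)
  expect_equal(dim(empty$counts), c(0L, 0L))
})

test_that("density thresholds step down with depth", {
  expect_equal(ptsThreForX(3), 80)
  expect_equal(ptsThreForX(5), 80)    # closed upper bound of the near band
  expect_equal(ptsThreForX(6), 30)
  expect_equal(ptsThreForX(8), 30)
  expect_equal(ptsThreForX(9), 10)
  expect_equal(ptsThreForX(c(3, 6, 9)), c(80, 30, 10))
  expect_error(ptsThreForX(-1), "non-negative")
})

test_that("row neighbourhood selection is a perpendicular distance filter", {
  row <- data.frame(theta = 90, rho = 1.0)
  pc <- pointCloud(rbind(c(5, 1.0, 0.3),     # on the line
                         c(5, 1.09, 0.3),    # within margin
                         c(5, 1.25, 0.3)))   # at 2x margin. removed
  out <- selectRowNeighborhood(pc, row, margin = 0.12)
  expect_equal(nPoints(out), 2L)
  set.seed(19)
  m <- cbind(runif(500, 0, 10), runif(500, 0, 2), 0)
  got <- coords(selectRowNeighborhood(pointCloud(m), row, 0.3))
  expect_equal(unname(got), unname(m[abs(m[, 2] - 1) <= 0.3, , drop = FALSE]))
})

test_that("plant detection seeds on dense cells and merges components", {
  mk <- function(counts) {
    structure(list(origin = c(0, 0), BL = 0.1, counts = counts,
                   cellIndex = matrix(integer(0), 0, 2)),
              class = "gridMesh")
  }
  counts <- matrix(0L, 9, 9)
  counts[4, 5] <- 120L
  one <- detectPlants(mk(counts))
  expect_length(one, 1L)
  expect_equal(unname(one[[1]]$seed), c(4L, 5L))

  counts[4, 8] <- 90L   # second dense cell two empty cells away
  expect_length(detectPlants(mk(counts)), 2L)

  counts2 <- matrix(0L, 9, 9)
  counts2[4, 5] <- 120L; counts2[5, 6] <- 100L   # diagonal neighbours merge
  expect_length(detectPlants(mk(counts2)), 1L)
})

test_that("a noise-free simulated row yields one detection per plant", {
  # 12 stems 0.25 m apart, dense enough to pass the near-range threshold
  set.seed(20)
  stems <- do.call(rbind, lapply(0:11, function(i)
    cbind(3 + 0.25 * i + runif(200, -0.01, 0.01),
          1 + runif(200, -0.01, 0.01),
          runif(200, 0, 0.6))))
  mesh <- meshDensity(stems, BL = 0.1)
  dets <- detectPlants(mesh)
  expect_length(dets, 12L)
  sx <- vapply(dets, function(d)
    mesh$origin[1] + (d$seed[1] - 0.5) * 0.1, numeric(1))
  expect_equal(sort(sx), 3 + 0.25 * (0:11), tolerance = 0.06)

  # translation equivariance: shifting by one full cell shifts detections
  mesh2 <- meshDensity(cbind(stems[, 1] + 0.1, stems[, 2], stems[, 3]), 0.1)
  dets2 <- detectPlants(mesh2)
  expect_equal(vapply(dets2, function(d) d$seed[1], integer(1)),
               vapply(dets, function(d) d$seed[1], integer(1)))
})

test_that("plant height is the neighbourhood maximum above the reference", {
  det <- list(seed = c(i = 2L, j = 2L), pts = 100L,
              footprint = list(x = c(0, 0.3), y = c(0, 0.3)))
  cloud <- pointCloud(rbind(c(0.15, 0.15, 0.651), c(0.1, 0.2, 0.3),
                            c(2, 2, 5)))
  expect_equal(plantHeight(cloud, det, 0), 0.651)
  # flat ground at the reference height has zero plant height
  flat <- pointCloud(cbind(runif(20, 0, 0.29), runif(20, 0, 0.29), 0.005))
  expect_equal(plantHeight(flat, det, 0.005), 0)
  # monotone: adding a higher point never decreases the height
  taller <- pointCloud(rbind(coords(cloud), c(0.2, 0.2, 0.9)))
  expect_gte(plantHeight(taller, det, 0), plantHeight(cloud, det, 0))
  outside <- pointCloud(matrix(c(5, 5, 5), 1))
  expect_error(plantHeight(outside, det, 0), "footprint")
})

test_that("height error tables reproduce printed per-plant arithmetic", {
  tab <- heightErrorTable(manual = c(0.510, 0.500),
                          computed = c(0.651, 0.500),
                          xGroup = c("0<=x<5", "0<=x<5"))
  expect_equal(tab$perPlant$error, c(0.141, 0))
  expect_equal(tab$perPlant$errorRatio[1], 27.6, tolerance = 0.05)
  expect_equal(tab$groupRmse$rmse, sqrt(mean(c(0.141, 0)^2)))

  t6near <- c(0.007, 0.089, 0.055, 0.061, 0.012, 0.033, 0.091, 0.056)
  tab6 <- heightErrorTable(rep(0.5, 8), 0.5 + t6near, rep("0<=x<5", 8))
  expect_equal(round(tab6$groupRmse$rmse, 3), 0.058)

  same <- heightErrorTable(c(0.5, 0.6), c(0.5, 0.6), c("a", "b"))
  expect_equal(same$perPlant$error, c(0, 0))
  expect_equal(same$groupRmse$rmse, c(0, 0))
  expect_error(heightErrorTable(c(0, 1), c(1, 1), c("a", "a")), "positive")
})
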