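test_that("horizontal projection preserves count and duplicates", {
  pc <- pointCloud(rbind(c(1, 2, 3), c(1, 2, 7), c(4, 5, 6)))
  p <- projectToPlane(pc)
  expect_equal(nrow(p), 3L)
  expect_equal(unname(p[1, ]), c(1, 2))
  expect_equal(p[1, ], p[2, ])   # same (x, y) from different z kept
})

test_that("band histograms tile the depth range and conserve counts", {
  set.seed(14)
  m <- cbind(runif(2000, 0, 4.7), runif(2000, -1, 9), 0)
  h <- bandHistograms(m[, 1:2], bandWidth = 1, binWidth = 0.05)
  expect_length(h, 5L)
  expect_equal(sum(vapply(h, function(b) sum(b$counts), numeric(1))), 2000)
  for (b in h) expect_equal(sum(b$counts),
                            sum(m[, 1] >= b$xLo - 1e-12 &
                                (m[, 1] < b$xHi | b$xHi >= 4.7)))
  one <- bandHistograms(cbind(runif(50), runif(50)), 10, 0.1)
  expect_length(one, 1L)
  expect_equal(sum(one[[1]]$counts), 50)
  expect_length(bandHistograms(matrix(numeric(0), 0, 2), 1, 0.1), 0L)
})

test_that("two stems dominate their band histogram as two peaks", {
  set.seed(15)
  stem1 <- cbind(runif(200, 0, 1), rnorm(200, 1.0, 0.005))
  stem2 <- cbind(runif(200, 0, 1), rnorm(200, 1.6, 0.005))
  leaves <- cbind(runif(80, 0, 1), runif(80, 0.5, 2.1))
  h <- bandHistograms(rbind(stem1, stem2, leaves), 2, 0.02)[[1]]
  pks <- findPeaks(h, minCount = 50, window = 2)
  expect_equal(nrow(pks), 2L)
  expect_equal(sort(pks$y), c(1.0, 1.6), tolerance = 0.03)
})

test_that("peak finding handles degenerate histograms", {
  h <- list(xCenter = 0.5, mids = seq(0.05, 0.95, by = 0.1),
            counts = c(0, 0, 7, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(findPeaks(h, minCount = 5)$y, 0.25)
  ramp <- list(xCenter = 0, mids = 1:10, counts = 1:10)
  expect_equal(findPeaks(ramp, minCount = 1)$y, 10)      # end of the ramp
  expect_equal(nrow(findPeaks(ramp, minCount = 11)), 0L)
})

test_that("constrained Hough transform recovers collinear peak lines", {
  peaks <- data.frame(x = 1:5, y = rep(1, 5), count = 10)
  lines <- houghRows(peaks)
  expect_equal(nrow(lines), 1L)
  expect_equal(lines$theta, 90)
  expect_equal(lines$support, 5L)
  expect_equal(lines$rho, 1)

  expect_equal(nrow(houghRows(peaks[1:2, ])), 0L)  # below minimum support

  # 20 parallel rows, peaks from 8 depth bands
  truthY <- cumsum(c(0, rep(0.6, 19)))
  grid <- expand.grid(x = seq(0.5, 7.5, by = 1), y = truthY)
  det <- houghRows(data.frame(x = grid$x, y = grid$y))
  expect_equal(nrow(det), 20L)
  expect_equal(sort(det$rho), truthY, tolerance = 0.02)
  expect_true(all(abs(det$theta - 90) <= 1))
})

test_that("hough detection is invariant to y translation up to rho", {
  set.seed(16)
  grid <- expand.grid(x = seq(0.5, 5.5, by = 1), y = c(0, 0.62, 1.19))
  peaks <- data.frame(x = grid$x, y = grid$y + rnorm(nrow(grid), 0, 0.005))
  a <- houghRows(peaks)
  b <- houghRows(transform(peaks, y = y + 3))
  expect_equal(b$rho - a$rho, rep(3, nrow(a)), tolerance = 0.02)
  expect_equal(a$support, b$support)
})

test_that("row spacings are adjacent perpendicular distances", {
  two <- data.frame(theta = c(90, 90), rho = c(1.0, 1.6), support = 5L)
  expect_equal(rowSpacings(two), 0.6)
  three <- data.frame(theta = 90, rho = c(0, 0.5, 1.2), support = 5L)
  expect_equal(rowSpacings(three), c(0.5, 0.7))
  expect_length(rowSpacings(three[1, ]), 0L)
  # near-parallel rows: spacings sum to the rho span within 1 %
  tilted <- data.frame(theta = c(88, 91, 89.5, 92), rho = c(0, 0.6, 1.3, 1.9),
                       support = 4L)
  rs <- rowSpacings(tilted, xMid = 0)
  expect_true(all(rs > 0))
  expect_lt(abs(sum(rs) - 1.9) / 1.9, 0.01)
})

test_that("regression metrics match an independent implementation", {
  expect_equal(evalRegression(c(1, 2, 3), c(1, 2, 3)),
               list(rSquared = 1, rmse = 0))
  tab5 <- c(0.141, 0.098, 0.267, 0.272, 0.019, 0.185, 0.093, 0.191)
  expect_lt(abs(sqrt(mean(tab5^2)) - 0.178), 1e-3)
  set.seed(17)
  tru <- runif(40, 0.4, 0.8)
  est <- tru + rnorm(40, 0, 0.05)
  got <- evalRegression(est, tru)
  ref <- refRegression(est, tru)
  expect_equal(got$rSquared, ref$rSquared, tolerance = 1e-9)
  expect_equal(got$rmse, ref$rmse, tolerance = 1e-12)
  expect_error(evalRegression(1:3, 1:4), "equal length")
})
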