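#' Project a cloud onto the horizontal plane
#'
#' Drops z; duplicates arising from different elevations are kept, since
#' projected point density is the row signal (stems concentrate returns).
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @return n x 2 matrix with columns x, y.
#' @export
projectToPlane <- function(cloud) {
  coords(cloud)[, 1:2, drop = FALSE]
}

#' Depth-band Y histograms
#'
#' Splits the projected points into equal-width depth bands along X
#' (bands parallel to the robot travel direction) tiling
#' \code{[min x, max x]}, and histograms each band's points along Y with a
#' fixed bin width. Counts are conserved: each band's bins sum to its point
#' count.
#'
#' @param points2d n x 2 matrix from [projectToPlane()].
#' @param bandWidth depth band width (m), default 1.0.
#' @param binWidth Y bin width (m), default 0.02 (the sensor range
#'   accuracy).
#' @return list of band histograms, each a list with \code{xLo}, \code{xHi},
#'   \code{xCenter}, \code{breaks}, \code{mids}, \code{counts}. Empty input
#'   gives an empty list.
#' @export
bandHistograms <- function(points2d, bandWidth = 1.0, binWidth = 0.02) {
  stopifnot(bandWidth > 0, binWidth > 0)
  if (!nrow(points2d)) return(list())
  x <- points2d[, 1]; y <- points2d[, 2]
  x0 <- min(x)
  nBands <- max(1L, ceiling((max(x) - x0) / bandWidth - 1e-9))
  band <- pmin(pmax(floor((x - x0) / bandWidth), 0), nBands - 1)
  y0 <- min(y)
  nBins <- max(1L, ceiling((max(y) - y0) / binWidth - 1e-9))
  bin <- pmin(pmax(floor((y - y0) / binWidth), 0), nBins - 1)
  breaks <- y0 + (0:nBins) * binWidth
  mids <- y0 + (seq_len(nBins) - 0.5) * binWidth
  lapply(seq_len(nBands) - 1L, function(b) {
    counts <- tabulate(bin[band == b] + 1L, nBins)
    list(xLo = x0 + b * bandWidth, xHi = x0 + (b + 1) * bandWidth,
         xCenter = x0 + (b + 0.5) * bandWidth,
         breaks = breaks, mids = mids, counts = counts)
  })
}

#' Peaks of a band histogram
#'
#' Local maxima over a +/- \code{window} bin neighbourhood with a minimum
#' count; each peak becomes a candidate in-row point at (band center,
#' bin center). Ties between equal-count adjacent bins resolve to the
#' lower-y bin.
#'
#' @param hist one element of [bandHistograms()].
#' @param minCount minimum peak count, default 5.
#' @param window half-width of the comparison neighbourhood in bins,
#'   default 2.
#' @return data frame with columns \code{x}, \code{y}, \code{count}
#'   (zero rows if no peaks).
#' @export
findPeaks <- function(hist, minCount = 5, window = 2L) {
  counts <- hist$counts
  n <- length(counts)
  isPeak <- logical(n)
  for (i in seq_len(n)) {
    if (counts[i] < minCount) next
    lo <- max(1L, i - window); hi <- min(n, i + window)
    nb <- counts[lo:hi]
    if (counts[i] < max(nb)) next
    # ties: only the lowest-y bin of a flat run is the peak
    if (i > lo && any(counts[lo:(i - 1)] == counts[i])) next
    isPeak[i] <- TRUE
  }
  data.frame(x = rep(hist$xCenter, sum(isPeak)), y = hist$mids[isPeak],
             count = counts[isPeak])
}

# line at angle theta (deg, from the Y axis) has direction
# (sin t, cos t) and unit normal (-cos t, sin t); rho = normal . (x, y).
# theta = 90 deg <=> row perpendicular to travel, rho = y.
.lineNormal <- function(thetaDeg) {
  t <- thetaDeg * pi / 180
  c(-cos(t), sin(t))
}

#' Hough-transform crop-row detection
#'
#' Accumulates votes of the peak points over a constrained angle range
#' (default [75, 105] degrees measured from the Y axis, i.e. rows nearly
#' perpendicular to robot travel) and extracts lines greedily: the
#' strongest accumulator cell is refined by a total-least-squares fit to
#' its supporting peaks, those peaks are removed, and the scan repeats
#' while lines reach the minimum support (default 3 peaks).
#'
#' @param peaks data frame with columns x, y (rbind of [findPeaks()]
#'   outputs).
#' @param thetaRange numeric length-2 angle range (degrees).
#' @param thetaRes accumulator angle resolution (degrees), default 1.
#' @param rhoRes accumulator offset resolution (m), default 0.02.
#' @param minSupport minimum supporting peaks per line, default 3.
#' @param assignDist peaks within this distance (m) of an accepted line are
#'   assigned to it and removed from further voting, default 3x
#'   \code{rhoRes}; this absorbs the lateral jitter of stem peaks and
#'   prevents one dense row from spawning near-duplicate lines.
#' @return data frame of lines with columns \code{theta} (degrees),
#'   \code{rho} (m), \code{support}, ordered by \code{rho}; zero rows when
#'   fewer than \code{minSupport} peaks remain.
#' @export
houghRows <- function(peaks, thetaRange = c(75, 105), thetaRes = 1,
                      rhoRes = 0.02, minSupport = 3,
                      assignDist = 3 * rhoRes) {
  out <- data.frame(theta = numeric(0), rho = numeric(0),
                    support = integer(0))
  if (is.null(peaks) || nrow(peaks) < minSupport) return(out)
  thetas <- seq(thetaRange[1], thetaRange[2], by = thetaRes)
  pts <- as.matrix(peaks[, c("x", "y")])
  active <- rep(TRUE, nrow(pts))
  repeat {
    idx <- which(active)
    if (length(idx) < minSupport) break
    best <- NULL
    for (th in thetas) {
      nvec <- .lineNormal(th)
      rho <- pts[idx, 1] * nvec[1] + pts[idx, 2] * nvec[2]
      cell <- round(rho / rhoRes)
      tab <- table(cell)
      top <- as.integer(names(tab)[which.max(tab)])
      # absorb votes split across adjacent cells: a peak in the next cell
      # can lie up to 1.5 cells from this cell's center
      members <- idx[abs(rho - top * rhoRes) <= 1.5 * rhoRes + 1e-12]
      supp <- length(members)
      if (is.null(best) || supp > best$support) {
        best <- list(theta = th, rho = top * rhoRes, support = supp,
                     members = members)
      }
    }
    if (is.null(best) || best$support < minSupport) break
    # refine by total least squares over the member peaks
    mm <- pts[best$members, , drop = FALSE]
    ctr <- colMeans(mm)
    ev <- eigen(stats::cov(mm), symmetric = TRUE)
    dir <- ev$vectors[, 1]                     # dominant direction
    th <- atan2(dir[1], dir[2]) * 180 / pi     # angle from Y axis
    if (th < 0) th <- th + 180
    if (th > thetaRange[2] || th < thetaRange[1]) th <- best$theta
    nvec <- .lineNormal(th)
    rho <- sum(ctr * nvec)
    # assign every remaining peak near the refined line to it
    rhoAll <- pts[idx, 1] * nvec[1] + pts[idx, 2] * nvec[2]
    assigned <- idx[abs(rhoAll - rho) <= assignDist]
    assigned <- union(assigned, best$members)
    out <- rbind(out, data.frame(theta = th, rho = rho,
                                 support = length(assigned)))
    active[assigned] <- FALSE
  }
  out[order(out$rho), , drop = FALSE]
}

#' Adjacent crop-row spacings
#'
#' Lines are sorted by signed normal offset and the spacing RS_i is the
#' perpendicular distance from line i (evaluated at the ROI x midline, so
#' slightly non-parallel lines are handled) to line i+1.
#'
#' @param lines data frame from [houghRows()].
#' @param xMid x coordinate of the ROI midline (m); defaults to 0 and only
#'   matters for non-parallel lines.
#' @return numeric vector of n-1 spacings (m), empty if fewer than 2 lines.
#' @export
rowSpacings <- function(lines, xMid = 0) {
  if (is.null(lines) || nrow(lines) < 2) return(numeric(0))
  lines <- lines[order(lines$rho), , drop = FALSE]
  n <- nrow(lines)
  rs <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    n1 <- .lineNormal(lines$theta[i])
    # point on line i at the midline: x = xMid, n1 . p = rho_i
    y1 <- (lines$rho[i] - n1[1] * xMid) / n1[2]
    n2 <- .lineNormal(lines$theta[i + 1])
    rs[i] <- abs(n2[1] * xMid + n2[2] * y1 - lines$rho[i + 1])
  }
  rs
}

#' Regression evaluation of estimates against reference values
#'
#' RMSE is the root mean squared difference; R squared is the coefficient
#' of determination of the least-squares line of estimates on the
#' reference values.
#'
#' @param estimates,truths equal-length numeric vectors (length >= 2).
#' @return list with \code{rSquared} and \code{rmse}.
#' @export
evalRegression <- function(estimates, truths) {
  if (length(estimates) != length(truths))
    stop("estimates and truths must have equal length")
  stopifnot(length(estimates) >= 2)
  fit <- stats::lm(estimates ~ truths)
  ssTot <- sum((estimates - mean(estimates))^2)
  rsq <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot
         else NA_real_
  list(rSquared = rsq,
       rmse = sqrt(mean((estimates - truths)^2)))
}
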