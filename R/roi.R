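#' Region-of-interest specification
#'
#' The ROI keeps the half annulus facing the parcel, clipped to a horizontal
#' range window and optional manual x/y windows. \code{rMin} defaults to the
#' blind zone extent of the default mount, since scans are taken beyond it.
#'
#' @param headingDeg azimuth (degrees, 0 = +X, counter-clockwise) of the
#'   direction facing the parcel.
#' @param rMin,rMax horizontal range window (m); \code{rMin} may be the
#'   string \code{"auto"} to use [blindZoneDiameter()] of \code{geom}.
#' @param xRange,yRange optional numeric length-2 manual windows (m), NULL
#'   to skip.
#' @param groundSliceM thickness of the ground slice removed by
#'   [removeGroundSlice()] (m).
#' @param geom mount geometry used when \code{rMin = "auto"}.
#' @return a \code{roiSpec} list.
#' @export
roiSpec <- function(headingDeg = 0, rMin = "auto", rMax = 120,
                    xRange = NULL, yRange = NULL, groundSliceM = 0.005,
                    geom = mountGeometry()) {
  if (identical(rMin, "auto")) rMin <- blindZoneDiameter(geom)
  stopifnot(is.numeric(rMin), is.numeric(rMax), rMin < rMax,
            groundSliceM > 0)
  if (!is.null(xRange)) stopifnot(length(xRange) == 2, xRange[1] <= xRange[2])
  if (!is.null(yRange)) stopifnot(length(yRange) == 2, yRange[1] <= yRange[2])
  structure(list(headingDeg = headingDeg, rMin = rMin, rMax = rMax,
                 xRange = xRange, yRange = yRange,
                 groundSliceM = groundSliceM),
            class = "roiSpec")
}

#' Abstract the region of interest from a sensor-centric scan
#'
#' Removes (i) the half annulus opposite the parcel heading (sign test on
#' the dot product with the heading unit vector; boundary points with zero
#' dot product are kept), (ii) points with horizontal range below
#' \code{rMin} (the blind zone) or above \code{rMax}, and (iii) points
#' outside the manual \code{xRange}/\code{yRange} windows.
#'
#' @param cloud a \linkS4class{PointCloud} in the sensor frame.
#' @param roi a [roiSpec()].
#' @return the filtered \linkS4class{PointCloud} (possibly empty).
#' @export
abstractRoi <- function(cloud, roi) {
  xyz <- coords(cloud)
  if (!nrow(xyz)) return(cloud)
  a <- roi$headingDeg * pi / 180
  u <- c(cos(a), sin(a))
  dotp <- xyz[, 1] * u[1] + xyz[, 2] * u[2]
  r <- sqrt(xyz[, 1]^2 + xyz[, 2]^2)
  keep <- dotp >= 0 & r >= roi$rMin & r <= roi$rMax
  if (!is.null(roi$xRange))
    keep <- keep & xyz[, 1] >= roi$xRange[1] & xyz[, 1] <= roi$xRange[2]
  if (!is.null(roi$yRange))
    keep <- keep & xyz[, 2] >= roi$yRange[1] & xyz[, 2] <= roi$yRange[2]
  cloud[keep]
}

#' Remove the bottom slice of a cloud
#'
#' Finds the minimum elevation \code{zMin} and deletes every point with
#' z inside \code{[zMin, zMin + delta]}. This suppresses noise from uneven
#' terrain before histogramming and height extraction; the ground reference
#' used downstream is \code{zMin + delta}.
#'
#' @param cloud non-empty \linkS4class{PointCloud}.
#' @param delta slice thickness (m), default 0.005.
#' @return list with elements \code{cloud} (survivors) and \code{zMin}.
#' @export
removeGroundSlice <- function(cloud, delta = 0.005) {
  xyz <- coords(cloud)
  if (!nrow(xyz)) stop("cannot ground-slice an empty cloud")
  stopifnot(delta > 0)
  zMin <- min(xyz[, 3])
  keep <- xyz[, 3] > zMin + delta
  list(cloud = cloud[keep], zMin = zMin)
}
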