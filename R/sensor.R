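#' Scanner configuration
#'
#' Describes the annular multi-beam scanner. Defaults correspond to a
#' 64-line scanner with a vertical field of view of [-24.8, +2] degrees,
#' 0.09 degree azimuth resolution, 2 cm one-sigma range accuracy, 5 Hz scan
#' rate, 1,333,440 points per second and 384 points per data packet.
#'
#' @param nLines number of laser lines.
#' @param vfovDeg numeric length-2 vertical field of view (degrees),
#'   lower bound first.
#' @param azimuthResDeg horizontal angular resolution (degrees).
#' @param rangeAccuracyM one-sigma range accuracy (m).
#' @param scanRateHz scan rate (Hz).
#' @param pointsPerSecond total point rate (1/s).
#' @param pointsPerPacket points per data packet.
#' @return a \code{sensorConfig} list.
#' @export
sensorConfig <- function(nLines = 64L,
                         vfovDeg = c(-24.8, 2.0),
                         azimuthResDeg = 0.09,
                         rangeAccuracyM = 0.02,
                         scanRateHz = 5,
                         pointsPerSecond = 1333440,
                         pointsPerPacket = 384) {
  stopifnot(length(vfovDeg) == 2, vfovDeg[1] < vfovDeg[2],
            nLines > 0, azimuthResDeg > 0, rangeAccuracyM >= 0,
            scanRateHz > 0, pointsPerSecond > 0, pointsPerPacket > 0)
  structure(list(nLines = as.integer(nLines), vfovDeg = as.numeric(vfovDeg),
                 azimuthResDeg = azimuthResDeg,
                 rangeAccuracyM = rangeAccuracyM, scanRateHz = scanRateHz,
                 pointsPerSecond = pointsPerSecond,
                 pointsPerPacket = pointsPerPacket),
            class = "sensorConfig")
}

#' Sensor mount geometry
#'
#' Height of the mounting bracket above ground (\code{H}), vertical offset
#' from the scanner base to its optical origin (\code{h}), and the maximum
#' depression angle \code{alpha} of the lowest beam. These determine the
#' ground blind zone around the robot.
#'
#' @param H bracket height (m), default 0.91.
#' @param h scanner origin-to-base offset (m), default 0.25.
#' @param alphaDeg maximum depression angle (degrees), default 24.8.
#' @return a \code{mountGeometry} list.
#' @export
mountGeometry <- function(H = 0.91, h = 0.25, alphaDeg = 24.8) {
  stopifnot(H > 0, h > 0)
  if (!is.finite(alphaDeg) || alphaDeg <= 0 || alphaDeg >= 90)
    stop("alphaDeg must lie strictly between 0 and 90 degrees")
  structure(list(H = H, h = h, alphaDeg = alphaDeg), class = "mountGeometry")
}

#' Diameter of the ground blind zone
#'
#' The lowest beam, depressed by \code{alpha} from a scanner origin
#' \code{H + h} above ground, first hits the ground at horizontal distance
#' \deqn{D = (H + h) / \tan(\alpha).} Ground closer to the robot than
#' \code{D} receives no returns; scans are therefore taken at stand-off
#' distances larger than \code{D}. With the default mount (H = 0.91 m,
#' h = 0.25 m, alpha = 24.8 deg) this is about 2.5 m.
#'
#' @param geom a [mountGeometry()].
#' @return blind zone extent D in meters.
#' @examples
#' blindZoneDiameter(mountGeometry(H = 0.91, h = 0.25, alphaDeg = 24.8))
#' @export
blindZoneDiameter <- function(geom = mountGeometry()) {
  (geom$H + geom$h) / tan(geom$alphaDeg * pi / 180)
}

#' Packet rate of the scanner data stream
#'
#' Exact quotient of the point rate and the packet payload, e.g.
#' 1,333,440 points/s over 384 points/packet gives 3472.5 packets/s.
#'
#' @param pointsPerSecond point rate (1/s).
#' @param pointsPerPacket points per packet.
#' @return packets per second.
#' @export
packetRate <- function(pointsPerSecond, pointsPerPacket) {
  if (!isTRUE(pointsPerSecond > 0) || !isTRUE(pointsPerPacket > 0))
    stop("both rates must be positive")
  pointsPerSecond / pointsPerPacket
}
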