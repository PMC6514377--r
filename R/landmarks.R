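#' Landmark filtering parameters
#'
#' @param ch minimum cluster height (vertical extent) in meters; clusters
#'   flatter than this are treated as canopy residue, default 0.1.
#' @param canopyCutZ elevation threshold (m, in the cloud frame) above which
#'   points are kept before clustering; plates are raised above the canopy,
#'   so cutting at canopy height leaves plate returns plus sparse noise.
#' @param plateW,plateH landmark plate width and height (m), defaults
#'   0.40 x 0.30.
#' @param maxHorizontalExtent optional guard: clusters wider than this (m)
#'   are rejected as merged rows / non-plate structures. Default
#'   \code{2 * sqrt(plateW^2 + plateH^2)}.
#' @return a \code{landmarkFilterParams} list.
#' @export
landmarkFilterParams <- function(ch = 0.1, canopyCutZ = 0,
                                 plateW = 0.40, plateH = 0.30,
                                 maxHorizontalExtent = NULL) {
  stopifnot(ch > 0, plateW > 0, plateH > 0)
  if (is.null(maxHorizontalExtent))
    maxHorizontalExtent <- 2 * sqrt(plateW^2 + plateH^2)
  structure(list(ch = ch, canopyCutZ = canopyCutZ, plateW = plateW,
                 plateH = plateH,
                 maxHorizontalExtent = maxHorizontalExtent),
            class = "landmarkFilterParams")
}

#' Keep only points above the canopy
#'
#' @param cloud a \linkS4class{PointCloud} with Z up.
#' @param canopyCutZ elevation threshold (m); points with z strictly above
#'   it survive.
#' @return the filtered cloud (possibly empty).
#' @export
cutAboveCanopy <- function(cloud, canopyCutZ) {
  cloud[coords(cloud)[, 3] > canopyCutZ]
}

#' Filter plate candidates among clusters
#'
#' Keeps clusters whose vertical extent (max z - min z) is at least
#' \code{ch}, rejecting flat canopy-residue clusters, and drops clusters
#' whose horizontal extent exceeds the plate-diagonal guard.
#'
#' @param clusters a \code{clusterResult} from [dbscan()].
#' @param cloud the clustered \linkS4class{PointCloud}.
#' @param params a [landmarkFilterParams()].
#' @return integer vector of surviving cluster ids.
#' @export
filterLandmarkCandidates <- function(clusters, cloud,
                                     params = landmarkFilterParams()) {
  xyz <- coords(cloud)
  ids <- setdiff(sort(unique(clusters$labels)), 0L)
  keep <- vapply(ids, function(k) {
    m <- xyz[clusters$labels == k, , drop = FALSE]
    vext <- max(m[, 3]) - min(m[, 3])
    hext <- sqrt(diff(range(m[, 1]))^2 + diff(range(m[, 2]))^2)
    vext >= params$ch && hext <= params$maxHorizontalExtent
  }, logical(1))
  ids[keep]
}

#' Extract the upper corner of a plate cluster
#'
#' The representative corner of a detected plate: z is the largest z of the
#' cluster, y the smallest y, and x the mean of all x values (the plate
#' plane faces the robot, so x is nearly constant across the cluster).
#'
#' @param cluster a \linkS4class{PointCloud} or n x 3 matrix of the cluster
#'   points.
#' @return numeric length-3 corner point (x, y, z).
#' @export
extractCorner <- function(cluster) {
  m <- if (is(cluster, "PointCloud")) coords(cluster) else cluster
  if (!nrow(m)) stop("cannot extract a corner from an empty cluster")
  c(x = mean(m[, 1]), y = min(m[, 2]), z = max(m[, 3]))
}

#' Generate a virtual landmark plate cloud
#'
#' Interpolates a regular grid of points on the vertical plane through the
#' detected upper corner: the plate is assumed perpendicular to the terrain
#' and parallel to the robot travel direction, extending \code{plateW}
#' along +Y from the corner and \code{plateH} along -Z, at constant x.
#' Grid size is \code{(floor(plateW/hStep)+1) x (floor(plateH/vStep)+1)}.
#'
#' @param corner numeric length-3 upper corner (from [extractCorner()]).
#' @param params a [landmarkFilterParams()] providing plate dimensions.
#' @param hStep,vStep horizontal and vertical interpolation steps (m),
#'   default 0.01.
#' @param frameId frame label of the returned cloud.
#' @return a \linkS4class{PointCloud} of the interpolated plate.
#' @export
makeVirtualLandmark <- function(corner, params = landmarkFilterParams(),
                                hStep = 0.01, vStep = 0.01,
                                frameId = "sensor") {
  stopifnot(hStep > 0, vStep > 0)
  ys <- corner[2] + seq(0, by = hStep,
                        length.out = floor(params$plateW / hStep) + 1)
  zs <- corner[3] - seq(0, by = vStep,
                        length.out = floor(params$plateH / vStep) + 1)
  g <- expand.grid(y = ys, z = zs)
  pointCloud(cbind(x = corner[1], y = g$y, z = g$z), frameId = frameId)
}

#' Detect landmark plates in a scan
#'
#' The full single-scan landmark pipeline: cut points above the canopy,
#' cluster them with octree-backed DBSCAN, filter plate candidates by
#' vertical extent, and emit per-plate upper corners and virtual plate
#' clouds for registration.
#'
#' @param scan an ROI-abstracted \linkS4class{PointCloud}.
#' @param dbParams a [dbscanParams()].
#' @param lmParams a [landmarkFilterParams()]; its \code{canopyCutZ} is the
#'   canopy threshold.
#' @param hStep,vStep virtual landmark interpolation steps (m).
#' @return list of landmark detections, each with elements \code{ids}
#'   (point ids into the canopy-cut cloud), \code{corner}, and
#'   \code{virtualCloud}; the list carries the canopy-cut cloud in
#'   attribute \code{"aboveCanopy"}. Empty list when nothing is found.
#' @export
detectLandmarks <- function(scan, dbParams = dbscanParams(),
                            lmParams = landmarkFilterParams(),
                            hStep = 0.01, vStep = 0.01) {
  up <- cutAboveCanopy(scan, lmParams$canopyCutZ)
  if (nPoints(up) == 0)
    return(structure(list(), aboveCanopy = up))
  cl <- dbscan(up, dbParams)
  ids <- filterLandmarkCandidates(cl, up, lmParams)
  out <- lapply(ids, function(k) {
    sel <- which(cl$labels == k)
    corner <- extractCorner(up[sel])
    list(ids = sel, corner = corner,
         virtualCloud = makeVirtualLandmark(corner, lmParams, hStep, vStep,
                                            frameId = frameId(scan)))
  })
  # report plates left to right (ascending corner y) for stable output
  if (length(out))
    out <- out[order(vapply(out, function(d) d$corner[2], numeric(1)))]
  structure(out, aboveCanopy = up)
}

#' Landmark detection success rate
#'
#' DSR = 100 * DNL / NLV percent, where DNL is the number of detected and
#' NLV the number of in-view landmarks.
#'
#' @param DNL detected landmark count(s).
#' @param NLV landmarks in view (> 0); vectorized with \code{DNL}.
#' @return DSR in percent.
#' @examples
#' detectionSuccessRate(4, 6)  # 66.66667
#' @export
detectionSuccessRate <- function(DNL, NLV) {
  if (!all(NLV > 0)) stop("NLV must be positive")
  if (any(DNL < 0) || any(DNL > NLV)) stop("DNL must lie in [0, NLV]")
  100 * DNL / NLV
}
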