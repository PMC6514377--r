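#' @useDynLib phenolidar, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' PointCloud: a set of 3-D points in meters
#'
#' The universal currency of the pipeline. Coordinates are stored as an
#' n x 3 numeric matrix with columns \code{x}, \code{y}, \code{z}, in a named
#' frame. The convention throughout the package is: X pointing into the
#' field, Y along the robot travel direction (left positive), Z up; the
#' global frame coincides with the sensor frame at the last observation spot.
#'
#' @slot coords numeric matrix (n x 3) of finite coordinates in meters.
#' @slot frameId single non-empty character label of the coordinate frame,
#'   e.g. \code{"sensor"} or \code{"global"}.
#' @export
setClass("PointCloud",
  representation(coords = "matrix", frameId = "character"),
  prototype(coords = matrix(numeric(0), 0, 3,
                            dimnames = list(NULL, c("x", "y", "z"))),
            frameId = "sensor"))

setValidity("PointCloud", function(object) {
  msg <- NULL
  if (!is.numeric(object@coords) || ncol(object@coords) != 3L)
    msg <- c(msg, "coords must be a numeric matrix with 3 columns")
  else if (length(object@coords) && !all(is.finite(object@coords)))
    msg <- c(msg, "all coordinates must be finite")
  if (length(object@frameId) != 1L || is.na(object@frameId) ||
      !nzchar(object@frameId))
    msg <- c(msg, "frameId must be a single non-empty string")
  if (is.null(msg)) TRUE else msg
})

#' RigidTransform: rotation plus translation
#'
#' A proper rigid motion p -> R p + t mapping one frame into another, as
#' estimated by registration. The rotation is orthonormal with determinant
#' +1 (tolerance 1e-9 enforced by the validity method).
#'
#' @slot rotation 3 x 3 orthonormal rotation matrix.
#' @slot translation numeric length-3 translation in meters.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"),
  prototype(rotation = diag(3), translation = c(0, 0, 0)))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  msg <- NULL
  if (!is.numeric(R) || !all(dim(R) == c(3L, 3L)))
    msg <- c(msg, "rotation must be a 3x3 numeric matrix")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      msg <- c(msg, "rotation must be orthonormal (R'R = I within 1e-9)")
    if (abs(det(R) - 1) > 1e-9)
      msg <- c(msg, "rotation must be proper (det = 1 within 1e-9)")
  }
  if (length(object@translation) != 3L || !all(is.finite(object@translation)))
    msg <- c(msg, "translation must be a finite length-3 numeric")
  if (is.null(msg)) TRUE else msg
})

#' OctreeIndex: spatial index over a PointCloud
#'
#' Octree over the points of a cloud for fast fixed-radius neighbour search,
#' used by DBSCAN landmark clustering. The external pointer is rebuilt
#' transparently if the index is restored from a serialized session.
#'
#' @slot ptr external pointer to the C++ octree.
#' @slot coords the indexed coordinates (kept for oracle checks and rebuilds).
#' @slot leafSize leaf edge length in meters.
#' @export
setClass("OctreeIndex",
  representation(ptr = "externalptr", coords = "matrix", leafSize = "numeric"))
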