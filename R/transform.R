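#' Construct a RigidTransform
#'
#' @param rotation 3 x 3 orthonormal rotation matrix (determinant +1).
#' @param translation numeric length-3 translation in meters.
#' @return a \linkS4class{RigidTransform}.
#' @examples
#' tr <- rigidTransform(rotationZ(10), c(1, 0, 0))
#' translation(tr)
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' @rdname RigidTransform-class
#' @param x a \linkS4class{RigidTransform}.
#' @export
setMethod("rotation", "RigidTransform", function(x) x@rotation)

#' @rdname RigidTransform-class
#' @export
setMethod("translation", "RigidTransform", function(x) x@translation)

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngle(object@rotation)
  cat(sprintf("RigidTransform: rotation %.4f deg, translation (%.4f, %.4f, %.4f) m\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
  invisible(object)
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "matrix", function(x, transform, frameId = NULL) {
  stopifnot(ncol(x) == 3)
  out <- x %*% t(transform@rotation)
  out[, 1] <- out[, 1] + transform@translation[1]
  out[, 2] <- out[, 2] + transform@translation[2]
  out[, 3] <- out[, 3] + transform@translation[3]
  out
})

#' @rdname applyTransform
#' @export
setMethod("applyTransform", "PointCloud", function(x, transform,
                                                   frameId = NULL) {
  pointCloud(applyTransform(x@coords, transform),
             frameId = if (is.null(frameId)) x@frameId else frameId)
})

#' Compose and invert rigid transforms
#'
#' \code{composeTransforms(a, b)} returns the transform applying \code{b}
#' first, then \code{a} (i.e. \code{a \%then-after\% b}).
#'
#' @param a,b,x \linkS4class{RigidTransform}s.
#' @return a \linkS4class{RigidTransform}.
#' @export
composeTransforms <- function(a, b) {
  rigidTransform(a@rotation %*% b@rotation,
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' @rdname composeTransforms
#' @export
invertTransform <- function(x) {
  Rt <- t(x@rotation)
  rigidTransform(Rt, as.numeric(-Rt %*% x@translation))
}

#' Elementary rotation about the Z axis
#'
#' @param deg angle in degrees (counter-clockwise looking down +Z).
#' @return 3 x 3 rotation matrix.
#' @export
rotationZ <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), 0,
           sin(a),  cos(a), 0,
           0,       0,      1), 3, 3, byrow = TRUE)
}

#' Rotation angle of a rotation matrix
#'
#' Geodesic angle in degrees, from the matrix trace.
#'
#' @param R 3 x 3 rotation matrix.
#' @return angle in degrees in [0, 180].
#' @export
rotationAngle <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c_))) * 180 / pi
}
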