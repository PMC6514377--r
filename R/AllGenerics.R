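#' @rdname PointCloud-class
#' @param x,object a \linkS4class{PointCloud} (or other object).
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname PointCloud-class
#' @export
setGeneric("frameId", function(x) standardGeneric("frameId"))

#' @rdname PointCloud-class
#' @param value replacement value.
#' @export
setGeneric("frameId<-", function(x, value) standardGeneric("frameId<-"))

#' @rdname PointCloud-class
#' @export
setGeneric("nPoints", function(x) standardGeneric("nPoints"))

#' @rdname RigidTransform-class
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))

#' @rdname RigidTransform-class
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))

#' Apply a rigid transform to points
#'
#' Maps every point p to R p + t.
#'
#' @param x a \linkS4class{PointCloud} or n x 3 matrix.
#' @param transform a \linkS4class{RigidTransform}.
#' @param frameId optional new frame label for the transformed cloud.
#' @return an object of the same class as \code{x}.
#' @export
setGeneric("applyTransform",
           function(x, transform, frameId = NULL)
             standardGeneric("applyTransform"))

#' Fixed-radius neighbour query
#'
#' Returns the 1-based ids of all indexed points within Euclidean distance
#' \code{radius} of \code{center} (inclusive).
#'
#' @param index an \linkS4class{OctreeIndex}.
#' @param center numeric length-3 query point.
#' @param radius search radius in meters (> 0).
#' @return integer vector of point ids.
#' @export
setGeneric("radiusQuery",
           function(index, center, radius) standardGeneric("radiusQuery"))
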