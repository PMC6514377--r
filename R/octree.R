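#' Build an octree index over a point cloud
#'
#' @param cloud a \linkS4class{PointCloud} or n x 3 matrix.
#' @param leafSize leaf edge length (m); internal nodes are split down to
#'   this scale. Defaults to half the landmark clustering radius, 0.26 m.
#' @return an \linkS4class{OctreeIndex}.
#' @examples
#' pc <- pointCloud(matrix(runif(300), ncol = 3))
#' idx <- octreeIndex(pc, leafSize = 0.1)
#' radiusQuery(idx, c(0.5, 0.5, 0.5), 0.2)
#' @export
octreeIndex <- function(cloud, leafSize = 0.26) {
  stopifnot(leafSize > 0)
  m <- if (is(cloud, "PointCloud")) coords(cloud) else cloud
  stopifnot(is.matrix(m), ncol(m) == 3)
  new("OctreeIndex", ptr = octreeBuildCpp(m, leafSize), coords = m,
      leafSize = leafSize)
}

.octreePtr <- function(index) {
  # external pointers do not survive serialization; rebuild lazily
  if (octreeSizeCpp(index@ptr) != nrow(index@coords)) {
    octreeBuildCpp(index@coords, index@leafSize)
  } else index@ptr
}

#' @rdname radiusQuery
#' @export
setMethod("radiusQuery", "OctreeIndex", function(index, center, radius) {
  if (!isTRUE(radius > 0)) stop("radius must be > 0")
  stopifnot(length(center) == 3)
  sort(octreeRadiusQueryCpp(.octreePtr(index), as.numeric(center), radius))
})

setMethod("show", "OctreeIndex", function(object) {
  cat("OctreeIndex over", nrow(object@coords), "points, leaf size",
      object@leafSize, "m\n")
  invisible(object)
})
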