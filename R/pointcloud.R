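#' Construct a PointCloud
#'
#' @param coords numeric n x 3 matrix (or coercible data frame / vector of
#'   length 3) of x, y, z coordinates in meters.
#' @param frameId coordinate frame label.
#' @return a \linkS4class{PointCloud}.
#' @examples
#' pc <- pointCloud(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' nPoints(pc)
#' @export
pointCloud <- function(coords = matrix(numeric(0), 0, 3), frameId = "sensor") {
  if (is.data.frame(coords)) coords <- as.matrix(coords)
  if (is.null(dim(coords))) {
    if (length(coords) == 0) coords <- matrix(numeric(0), 0, 3)
    else coords <- matrix(as.numeric(coords), ncol = 3, byrow = TRUE)
  }
  storage.mode(coords) <- "double"
  colnames(coords) <- c("x", "y", "z")
  rownames(coords) <- NULL
  new("PointCloud", coords = coords, frameId = frameId)
}

#' @rdname PointCloud-class
#' @export
setMethod("coords", "PointCloud", function(x) x@coords)

#' @rdname PointCloud-class
#' @export
setMethod("frameId", "PointCloud", function(x) x@frameId)

#' @rdname PointCloud-class
#' @export
setReplaceMethod("frameId", "PointCloud", function(x, value) {
  x@frameId <- value
  validObject(x)
  x
})

#' @rdname PointCloud-class
#' @export
setMethod("nPoints", "PointCloud", function(x) nrow(x@coords))

#' @rdname PointCloud-class
#' @param i integer or logical index of points to keep.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PointCloud", function(x, i, j, ..., drop = FALSE) {
  pointCloud(x@coords[i, , drop = FALSE], frameId = x@frameId)
})

setMethod("show", "PointCloud", function(object) {
  n <- nrow(object@coords)
  cat(sprintf("PointCloud with %d points in frame '%s'\n", n,
              object@frameId))
  if (n > 0) {
    rng <- apply(object@coords, 2, range)
    cat(sprintf("  x: [%.3f, %.3f]  y: [%.3f, %.3f]  z: [%.3f, %.3f] m\n",
                rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2],
                rng[1, 3], rng[2, 3]))
  }
  invisible(object)
})

#' Concatenate point clouds
#'
#' All clouds must share a frame; the result preserves point order.
#'
#' @param clouds list of \linkS4class{PointCloud}s.
#' @return a single \linkS4class{PointCloud}.
#' @export
concatClouds <- function(clouds) {
  stopifnot(length(clouds) >= 1)
  fid <- unique(vapply(clouds, frameId, character(1)))
  if (length(fid) > 1)
    stop("cannot concatenate clouds from different frames: ",
         paste(fid, collapse = ", "))
  pointCloud(do.call(rbind, lapply(clouds, coords)), frameId = fid)
}
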