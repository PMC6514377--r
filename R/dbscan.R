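#' DBSCAN parameters for landmark clustering
#'
#' The adjacency radius \code{E} defaults to 0.52 m — the diagonal of the
#' 0.40 m x 0.30 m landmark plate — so that all returns from one plate are
#' density-connected. \code{minPts} defaults to 5, the smallest integer
#' exceeding dimension + 1 = 4.
#'
#' @param E adjacency radius (m), > 0.
#' @param minPts minimum neighbour count for a core point, >= 1.
#' @return a \code{dbscanParams} list.
#' @export
dbscanParams <- function(E = 0.52, minPts = 5L) {
  stopifnot(E > 0, minPts >= 1)
  structure(list(E = E, minPts = as.integer(minPts)),
            class = "dbscanParams")
}

#' Density-based clustering of a point cloud
#'
#' Standard DBSCAN over an octree neighbour index. Points are typed as
#' \code{CORE} (at least \code{minPts} neighbours within \code{E}, the point
#' itself included), \code{BORDER} (within \code{E} of a core point but not
#' core), or \code{NOISE}. Density-reachable core points — core points lying
#' in each other's adjacency region — always share a cluster, which merges
#' over-segmented fragments. Border points reachable from several clusters
#' are assigned to the first-discovered one.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param params a [dbscanParams()].
#' @return a \code{clusterResult} list with \code{labels} (integer, 0 =
#'   noise, clusters numbered contiguously from 1 in discovery order) and
#'   \code{pointType} (factor with levels \code{CORE}, \code{BORDER},
#'   \code{NOISE}).
#' @export
dbscan <- function(cloud, params = dbscanParams()) {
  m <- if (is(cloud, "PointCloud")) coords(cloud) else cloud
  res <- dbscanCpp(m, params$E, params$minPts)
  structure(list(
    labels = res$labels,
    pointType = factor(c("CORE", "BORDER", "NOISE")[res$types + 1L],
                       levels = c("CORE", "BORDER", "NOISE")),
    params = params), class = "clusterResult")
}

#' Number of clusters in a clustering result
#'
#' @param clusters a \code{clusterResult} from [dbscan()].
#' @return integer count of clusters (noise excluded).
#' @export
nClusters <- function(clusters) {
  if (!length(clusters$labels)) return(0L)
  max(0L, clusters$labels)
}
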