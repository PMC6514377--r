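#' Plant height extraction parameters
#'
#' @param BL grid border (cell edge) length on the horizontal plane (m),
#'   default 0.1.
#' @param ptsThre depth-dependent point-count thresholds: a data frame with
#'   columns \code{xMax} (upper depth bound, last = Inf) and
#'   \code{threshold}. Default: 80 for 0 <= x <= 5 m, 30 for 5 < x <= 8 m,
#'   10 for x > 8 m.
#' @param rowMargin half-width of the row neighbourhood (m), default 0.25.
#' @param heightMin ground reference (m): the global minimum elevation plus
#'   the ground slice thickness, i.e. \code{zMin + 0.005}; supply the value
#'   from [removeGroundSlice()].
#' @return a \code{heightParams} list.
#' @export
heightParams <- function(BL = 0.1,
                         ptsThre = data.frame(xMax = c(5, 8, Inf),
                                              threshold = c(80, 30, 10)),
                         rowMargin = 0.25, heightMin = 0.005) {
  stopifnot(BL > 0, all(ptsThre$threshold > 0),
            !is.unsorted(ptsThre$xMax),
            all(diff(ptsThre$threshold) <= 0), rowMargin > 0)
  structure(list(BL = BL, ptsThre = ptsThre, rowMargin = rowMargin,
                 heightMin = heightMin), class = "heightParams")
}

#' Depth-dependent density threshold
#'
#' Piecewise-constant point count threshold by depth x; cells deeper into
#' the field receive fewer returns, so the seeding threshold decreases.
#'
#' @param x depth coordinate (m), >= 0.
#' @param params a [heightParams()].
#' @return integer threshold (vectorized over \code{x}).
#' @examples
#' ptsThreForX(c(3, 6, 9))  # 80 30 10
#' @export
ptsThreForX <- function(x, params = heightParams()) {
  if (any(x < 0)) stop("depth x must be non-negative")
  idx <- vapply(x, function(v) which(v <= params$ptsThre$xMax)[1],
                integer(1))
  params$ptsThre$threshold[idx]
}

#' Select the neighbourhood of a crop row
#'
#' Keeps points whose perpendicular (horizontal) distance to the row line
#' is at most \code{margin}.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param row one-row data frame (or list) with \code{theta} and \code{rho}
#'   as produced by [houghRows()].
#' @param margin neighbourhood half-width (m).
#' @return the selected \linkS4class{PointCloud}.
#' @export
selectRowNeighborhood <- function(cloud, row, margin) {
  stopifnot(margin > 0)
  xyz <- coords(cloud)
  nvec <- .lineNormal(row$theta)
  d <- abs(xyz[, 1] * nvec[1] + xyz[, 2] * nvec[2] - row$rho)
  cloud[d <= margin]
}

#' Horizontal grid point density
#'
#' Meshes the horizontal bounding box of the points with square cells of
#' edge \code{BL} (half-open cells \code{[lo, hi)}, anchored at the
#' bounding-box minimum corner; boundary points go to the higher-index
#' cell) and counts points per cell. Counts are conserved.
#'
#' @param points a \linkS4class{PointCloud} or n x 3 (or n x 2) matrix.
#' @param BL cell edge length (m).
#' @return a \code{gridMesh} list: \code{origin} (x0, y0), \code{BL},
#'   \code{counts} (ni x nj integer matrix, i over x, j over y),
#'   \code{cellIndex} (n x 2 matrix of per-point cells). Empty input gives
#'   an empty mesh (0 x 0 counts).
#' @export
meshDensity <- function(points, BL = 0.1) {
  stopifnot(BL > 0)
  m <- if (is(points, "PointCloud")) coords(points) else points
  if (!nrow(m)) {
    return(structure(list(origin = c(NA_real_, NA_real_), BL = BL,
                          counts = matrix(0L, 0, 0),
                          cellIndex = matrix(integer(0), 0, 2)),
                     class = "gridMesh"))
  }
  x0 <- min(m[, 1]); y0 <- min(m[, 2])
  ci <- floor((m[, 1] - x0) / BL) + 1L
  cj <- floor((m[, 2] - y0) / BL) + 1L
  ni <- max(ci); nj <- max(cj)
  counts <- matrix(0L, ni, nj)
  tab <- table(factor(ci, levels = seq_len(ni)),
               factor(cj, levels = seq_len(nj)))
  counts[] <- as.integer(tab)
  structure(list(origin = c(x0, y0), BL = BL, counts = counts,
                 cellIndex = cbind(i = as.integer(ci), j = as.integer(cj))),
            class = "gridMesh")
}

#' Detect single plants from grid density
#'
#' Cells whose count exceeds the depth-dependent threshold seed plant
#' detections; adjacent (8-connected) super-threshold cells are merged into
#' one detection whose seed is the densest cell, so one plant spanning two
#' cells is not counted twice. Each detection carries its 3 x 3 cell
#' neighbourhood footprint.
#'
#' @param mesh a [meshDensity()] result.
#' @param params a [heightParams()].
#' @return list of detections, each with \code{seed} (i, j), \code{pts}
#'   (seed cell count), \code{cells} (component cells), and
#'   \code{footprint} (x/y bounds of the 3 x 3 neighbourhood). Ordered by
#'   seed x then y.
#' @export
detectPlants <- function(mesh, params = heightParams()) {
  counts <- mesh$counts
  if (!length(counts)) return(list())
  ni <- nrow(counts); nj <- ncol(counts)
  xc <- mesh$origin[1] + (seq_len(ni) - 0.5) * mesh$BL
  thr <- ptsThreForX(pmax(xc, 0), params)
  seedMask <- counts > matrix(thr, ni, nj)
  if (!any(seedMask)) return(list())
  # 8-connected component labelling over super-threshold cells
  comp <- matrix(0L, ni, nj)
  lab <- 0L
  for (s in which(seedMask)) {
    if (comp[s] != 0L) next
    lab <- lab + 1L
    queue <- s
    comp[s] <- lab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1L) %% ni + 1L; j <- (cur - 1L) %/% ni + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > ni || jj < 1 || jj > nj) next
        nidx <- (jj - 1L) * ni + ii
        if (seedMask[nidx] && comp[nidx] == 0L) {
          comp[nidx] <- lab
          queue <- c(queue, nidx)
        }
      }
    }
  }
  dets <- lapply(seq_len(lab), function(k) {
    cells <- which(comp == k)
    i <- (cells - 1L) %% ni + 1L; j <- (cells - 1L) %/% ni + 1L
    seedIdx <- which.max(counts[cells])
    si <- i[seedIdx]; sj <- j[seedIdx]
    list(seed = c(i = si, j = sj), pts = counts[cells[seedIdx]],
         cells = cbind(i = i, j = j),
         footprint = list(
           x = mesh$origin[1] + c(si - 2, si + 1) * mesh$BL,
           y = mesh$origin[2] + c(sj - 2, sj + 1) * mesh$BL))
  })
  ord <- order(vapply(dets, function(d) d$seed[1], numeric(1)),
               vapply(dets, function(d) d$seed[2], numeric(1)))
  dets[ord]
}

#' Height of one detected plant
#'
#' PH = (maximum z over the points inside the 3 x 3 neighbourhood
#' footprint) minus the ground reference \code{heightMin}.
#'
#' @param cloud the \linkS4class{PointCloud} the mesh was built from.
#' @param det one detection from [detectPlants()].
#' @param heightMin ground reference (m), \code{zMin + 0.005}.
#' @return plant height PH in meters.
#' @export
plantHeight <- function(cloud, det, heightMin) {
  xyz <- coords(cloud)
  fp <- det$footprint
  inside <- xyz[, 1] >= fp$x[1] & xyz[, 1] < fp$x[2] &
            xyz[, 2] >= fp$y[1] & xyz[, 2] < fp$y[2]
  if (!any(inside)) stop("no points inside the detection footprint")
  max(xyz[inside, 3]) - heightMin
}

#' Per-plant height errors and per-group RMSE
#'
#' Compares computed plant heights with manual reference measurements:
#' error = |computed - manual| (m), error ratio = 100 * error / manual
#' (percent), and root mean squared error per depth group.
#'
#' @param manual,computed equal-length numeric vectors of heights (m);
#'   manual values must be positive.
#' @param xGroup character or factor assigning each plant to a depth group
#'   (e.g. \code{"0<=x<5"}).
#' @return list with \code{perPlant} (data frame: manual, computed, error,
#'   errorRatio, xGroup) and \code{groupRmse} (data frame: xGroup, rmse, n).
#' @export
heightErrorTable <- function(manual, computed, xGroup) {
  if (length(manual) != length(computed) || length(manual) != length(xGroup))
    stop("manual, computed and xGroup must have equal length")
  if (any(manual <= 0)) stop("manual heights must be positive")
  err <- abs(computed - manual)
  per <- data.frame(manual = manual, computed = computed, error = err,
                    errorRatio = 100 * err / manual,
                    xGroup = as.character(xGroup),
                    stringsAsFactors = FALSE)
  grp <- unique(per$xGroup)
  groupRmse <- data.frame(
    xGroup = grp,
    rmse = vapply(grp, function(g) sqrt(mean(err[per$xGroup == g]^2)),
                  numeric(1)),
    n = vapply(grp, function(g) sum(per$xGroup == g), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(perPlant = per, groupRmse = groupRmse)
}
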