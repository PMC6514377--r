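#' Closed-form least-squares rigid alignment (Kabsch)
#'
#' Given matched point pairs, finds the rotation R and translation t
#' minimizing sum ||R src_i + t - dst_i||^2 via SVD of the cross-covariance,
#' with the determinant correction that guarantees a proper rotation.
#'
#' @param src,dst n x 3 matrices of matched points (n >= 3, not collinear).
#' @return a \linkS4class{RigidTransform} mapping src onto dst.
#' @examples
#' src <- matrix(rnorm(30), ncol = 3)
#' dst <- applyTransform(src, rigidTransform(rotationZ(10), c(1, 2, 3)))
#' kabsch(src, dst)
#' @export
kabsch <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 3 || nrow(dst) != nrow(src))
    stop("kabsch needs >= 3 matched point pairs")
  cs <- colMeans(src); cd <- colMeans(dst)
  A <- sweep(src, 2, cs); B <- sweep(dst, 2, cd)
  if (svd(A, nu = 0, nv = 0)$d[2] < 1e-12 * max(1, max(abs(A))))
    stop("kabsch: source points are collinear")
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigidTransform(R, as.numeric(cd - R %*% cs))
}

# run expr with a fixed RNG state, restoring the caller's state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Voxel-grid downsampling
#'
#' Replaces all points falling in each cubic voxel by their centroid;
#' deterministic and order-independent.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param voxel voxel edge length (m).
#' @return the downsampled \linkS4class{PointCloud}.
#' @export
voxelDownsample <- function(cloud, voxel) {
  stopifnot(voxel > 0)
  m <- coords(cloud)
  if (!nrow(m)) return(cloud)
  key <- paste(floor(m[, 1] / voxel), floor(m[, 2] / voxel),
               floor(m[, 3] / voxel))
  idx <- split(seq_len(nrow(m)), key)
  cen <- t(vapply(idx, function(i) colMeans(m[i, , drop = FALSE]),
                  numeric(3)))
  pointCloud(cen[order(names(idx)), , drop = FALSE], frameId = frameId(cloud))
}

#' Estimate per-point surface normals
#'
#' PCA of the fixed-radius neighbourhood of each point; the normal is the
#' eigenvector of the smallest eigenvalue, oriented towards the sensor
#' origin. Points with fewer than 3 neighbours get the mean normal.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param radius neighbourhood radius (m); default 3x the virtual landmark
#'   interpolation step.
#' @return n x 3 matrix of unit normals.
#' @export
estimateNormals <- function(cloud, radius = 0.03) {
  m <- coords(cloud)
  n <- nrow(m)
  idx <- octreeIndex(m, leafSize = radius)
  nrm <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    nb <- octreeRadiusQueryCpp(idx@ptr, m[i, ], radius)
    if (length(nb) >= 3) {
      e <- eigen(stats::cov(m[nb, , drop = FALSE]), symmetric = TRUE)
      v <- e$vectors[, 3]
      if (sum(v * (-m[i, ])) < 0) v <- -v   # face the origin
      nrm[i, ] <- v
    }
  }
  bad <- which(is.na(nrm[, 1]))
  if (length(bad)) {
    fallback <- if (length(bad) < n) colMeans(nrm[-bad, , drop = FALSE])
                else c(-1, 0, 0)
    fallback <- fallback / sqrt(sum(fallback^2))
    nrm[bad, ] <- matrix(fallback, length(bad), 3, byrow = TRUE)
  }
  nrm
}

#' Fast point feature histograms
#'
#' 33-bin FPFH-style descriptors: for every point, the three Darboux-frame
#' angles between its normal, each neighbour's normal and the connecting
#' segment are histogrammed into 11 bins each (simplified point feature
#' histogram), then neighbour histograms are blended in with inverse
#' distance weights.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param radius feature neighbourhood radius (m).
#' @param normals optional precomputed normals; estimated at
#'   \code{radius / 2} otherwise.
#' @return a \code{featureSet} list with \code{histograms} (n x 33,
#'   rows summing to 1 for non-isolated points), \code{support} (the
#'   neighbour count each histogram was built from — on geometrically
#'   degenerate targets such as perfect planes, where all Darboux angles
#'   vanish, the support profile is what still distinguishes borders and
#'   corners from the interior) and \code{normals}.
#' @export
fpfhFeatures <- function(cloud, radius = 0.1, normals = NULL) {
  m <- coords(cloud)
  n <- nrow(m)
  if (is.null(normals)) normals <- estimateNormals(cloud, radius / 2)
  idx <- octreeIndex(m, leafSize = radius)
  nbins <- 11L
  spfh <- matrix(0, n, 3L * nbins)
  nblist <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- setdiff(octreeRadiusQueryCpp(idx@ptr, m[i, ], radius), i)
    nblist[[i]] <- nb
    if (!length(nb)) next
    d <- m[nb, , drop = FALSE] - matrix(m[i, ], length(nb), 3, byrow = TRUE)
    dn <- sqrt(rowSums(d^2))
    d <- d / dn
    u <- normals[i, ]
    # Darboux frame per neighbour
    v <- cbind(u[2] * d[, 3] - u[3] * d[, 2],
               u[3] * d[, 1] - u[1] * d[, 3],
               u[1] * d[, 2] - u[2] * d[, 1])
    vn <- sqrt(rowSums(v^2)); vn[vn < 1e-12] <- 1
    v <- v / vn
    w <- cbind(u[2] * v[, 3] - u[3] * v[, 2],
               u[3] * v[, 1] - u[1] * v[, 3],
               u[1] * v[, 2] - u[2] * v[, 1])
    nq <- normals[nb, , drop = FALSE]
    alpha <- rowSums(v * nq)                            # in [-1, 1]
    phi <- d %*% u                                      # in [-1, 1]
    theta <- atan2(rowSums(w * nq), nq %*% u)           # in [-pi, pi]
    b1 <- pmin(pmax(floor((alpha + 1) / 2 * nbins), 0), nbins - 1)
    b2 <- pmin(pmax(floor((phi + 1) / 2 * nbins), 0), nbins - 1)
    b3 <- pmin(pmax(floor((theta + pi) / (2 * pi) * nbins), 0), nbins - 1)
    h <- tabulate(b1 + 1, nbins)
    h <- c(h, tabulate(b2 + 1, nbins), tabulate(b3 + 1, nbins))
    spfh[i, ] <- h / length(nb)
  }
  fp <- spfh
  for (i in seq_len(n)) {
    nb <- nblist[[i]]
    if (!length(nb)) next
    dn <- sqrt(rowSums((m[nb, , drop = FALSE] -
                          matrix(m[i, ], length(nb), 3, byrow = TRUE))^2))
    wgt <- 1 / pmax(dn, 1e-6)
    fp[i, ] <- spfh[i, ] +
      colSums(spfh[nb, , drop = FALSE] * wgt) / sum(wgt)
  }
  rs <- rowSums(fp)
  fp[rs > 0, ] <- fp[rs > 0, ] / rs[rs > 0]
  structure(list(histograms = fp,
                 support = lengths(nblist),
                 normals = normals), class = "featureSet")
}

.rmsNN <- function(srcm, dstm, trim = 1) {
  d <- nearestNeighborCpp(srcm, dstm)$distance
  if (trim < 1) d <- sort(d)[seq_len(max(3, floor(trim * length(d))))]
  sqrt(mean(d^2))
}

# consensus score: inlier count first, inlier rms as tie-break (lower is
# better). Penalising missing inliers avoids the shifted local optima of
# repetitive landmark layouts.
.consensusScore <- function(srcm, dstm, inlierDist) {
  d <- nearestNeighborCpp(srcm, dstm)$distance
  inl <- d <= inlierDist
  list(nInlier = sum(inl),
       rms = if (any(inl)) sqrt(mean(d[inl]^2)) else Inf)
}

.scoreBetter <- function(a, b) {
  a$nInlier > b$nInlier || (a$nInlier == b$nInlier && a$rms < b$rms)
}

#' Coarse alignment by sampled feature consensus (SAC-IA)
#'
#' Randomized initial alignment of two virtual-landmark clouds: both clouds
#' are voxel-downsampled, FPFH descriptors computed, and for a number of
#' iterations three well-separated source points are drawn, matched to
#' feature-similar target points, and scored by the trimmed RMS
#' nearest-neighbour residual of the implied rigid transform. The best
#' transform is returned. Deterministic for a fixed seed.
#'
#' @param srcVl,dstVl non-empty \linkS4class{PointCloud}s (virtual
#'   landmarks of the moving and fixed scan).
#' @param nSamples consensus iterations, default 1000.
#' @param seed RNG seed, default 0.
#' @param voxel downsampling voxel (m), default 0.04.
#' @param featureRadius FPFH radius (m), default 0.1.
#' @param kCandidates feature-space candidates per sampled point.
#' @param inlierDist correspondence distance (m) below which a downsampled
#'   source point counts as an inlier when scoring a candidate transform;
#'   default 3x the voxel size.
#' @param maxRotDeg candidate transforms rotating by more than this are
#'   rejected, default 30. Between nearby observation spots the pose
#'   deviation is a large translation with a small rotation, and the
#'   planar plate grids are nearly symmetric under half-turns, so
#'   unconstrained rotations admit spurious flip solutions.
#' @return a \linkS4class{RigidTransform} with attributes
#'   \code{"score"} (inlier RMS residual, m), \code{"nInlier"} and
#'   \code{"converged"} (TRUE when the alignment beats the identity
#'   transform's consensus).
#' @export
coarseAlign <- function(srcVl, dstVl, nSamples = 4000, seed = 0,
                        voxel = 0.04, featureRadius = 0.1,
                        kCandidates = 20, inlierDist = 3 * voxel,
                        maxRotDeg = 30) {
  if (nPoints(srcVl) == 0 || nPoints(dstVl) == 0)
    stop("coarseAlign needs non-empty clouds")
  src <- coords(voxelDownsample(srcVl, voxel))
  dst <- coords(voxelDownsample(dstVl, voxel))
  fsAll <- fpfhFeatures(pointCloud(src), featureRadius)
  fdAll <- fpfhFeatures(pointCloud(dst), featureRadius)
  # matching descriptor = angle histogram plus normalized local support;
  # the support term keeps borders/corners distinguishable on planar
  # targets whose angle histograms are degenerate
  withSupport <- function(f)
    cbind(f$histograms, f$support / max(f$support, 1))
  fs <- withSupport(fsAll)
  fd <- withSupport(fdAll)
  # feature-space candidate lists (k nearest target descriptors per source)
  fdist <- as.matrix(stats::dist(rbind(fs, fd)))[seq_len(nrow(src)),
                                                 nrow(src) + seq_len(nrow(dst)),
                                                 drop = FALSE]
  kC <- min(kCandidates, ncol(fdist))
  cand <- t(apply(fdist, 1, function(r) order(r)[seq_len(kC)]))
  # persistent-feature sampling: triples are drawn from the points whose
  # descriptors deviate most from the cloud mean (plate borders and
  # corners). Interior points of a planar target all share one histogram,
  # so their feature matches are uninformative; border features are where
  # correspondence carries signal.
  distinct <- sqrt(rowSums(sweep(fs, 2, colMeans(fs))^2))
  pool <- which(distinct >= stats::quantile(distinct, 0.7))
  if (length(pool) < 10) pool <- seq_len(nrow(src))
  spread <- sqrt(max(rowSums(sweep(src, 2, colMeans(src))^2)))
  minSep <- 0.25 * spread
  idScore <- .consensusScore(src, dst, inlierDist)
  best <- rigidTransform(); bestScore <- idScore
  .withSeed(seed, {
    for (it in seq_len(nSamples)) {
      si <- pool[sample.int(length(pool), 1)]
      ok <- pool[sqrt(rowSums(sweep(src[pool, , drop = FALSE], 2,
                                    src[si, ])^2)) > minSep]
      if (length(ok) < 2) next
      sj <- ok[sample.int(length(ok), 1)]
      ok2 <- ok[sqrt(rowSums(sweep(src[ok, , drop = FALSE], 2,
                                   src[sj, ])^2)) > minSep]
      if (!length(ok2)) next
      sk <- ok2[sample.int(length(ok2), 1)]
      tri <- c(si, sj, sk)
      dtri <- cand[cbind(tri, sample.int(kC, 3, replace = TRUE))]
      # rigidity pre-check: pairwise distances of the sampled triple must
      # match those of the candidate triple, or no rigid motion fits
      ds_ <- stats::dist(src[tri, , drop = FALSE])
      dd_ <- stats::dist(dst[dtri, , drop = FALSE])
      if (any(abs(ds_ - dd_) > inlierDist)) next
      tr <- tryCatch(kabsch(src[tri, , drop = FALSE],
                            dst[dtri, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(tr)) next
      if (rotationAngle(rotation(tr)) > maxRotDeg) next
      sc <- .consensusScore(applyTransform(src, tr), dst, inlierDist)
      if (.scoreBetter(sc, bestScore)) { bestScore <- sc; best <- tr }
    }
  })
  # polish: closed-form re-fit on the inlier correspondences of the best
  # candidate (up to three rounds), keeping improvements only
  for (round in 1:3) {
    nn <- nearestNeighborCpp(applyTransform(src, best), dst)
    inl <- which(nn$distance <= inlierDist)
    if (length(inl) < 3) break
    ref <- tryCatch(kabsch(src[inl, , drop = FALSE],
                           dst[nn$index[inl], , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(ref) || rotationAngle(rotation(ref)) > maxRotDeg) break
    sc <- .consensusScore(applyTransform(src, ref), dst, inlierDist)
    if (!.scoreBetter(sc, bestScore)) break
    best <- ref
    bestScore <- sc
  }
  attr(best, "score") <- bestScore$rms
  attr(best, "nInlier") <- bestScore$nInlier
  # converged: the consensus beat the identity, or the clouds were already
  # aligned (most points are inliers without moving)
  attr(best, "converged") <- .scoreBetter(bestScore, idScore) ||
    bestScore$nInlier >= 0.5 * nrow(src)
  best
}

#' Corner-correspondence coarse alignment
#'
#' Deterministic alternative to [coarseAlign()] when at least three landmark
#' corners are available on each side: corners are matched by mutual
#' nearest neighbour after shifting both sets to their centroids, then
#' aligned in closed form by [kabsch()]. Plate corners typically lie close
#' to a single line along the path, which leaves the rotation about that
#' line unconstrained; when the corner geometry is that degenerate (second
#' singular value below \code{minSpread}) or the fitted rotation exceeds
#' \code{maxRotDeg}, the rotation is dropped and the translation of the
#' matched corners is returned instead (the subsequent ICP recovers the
#' small real rotation).
#'
#' @param cornersA,cornersB n x 3 matrices of landmark corners (moving and
#'   fixed scan).
#' @param minSpread conditioning threshold (m) on the second singular value
#'   of the centered corner set, default 0.05.
#' @param maxRotDeg rotation cap (degrees), default 30.
#' @return a \linkS4class{RigidTransform}.
#' @export
cornerAlign <- function(cornersA, cornersB, minSpread = 0.05,
                        maxRotDeg = 30) {
  cornersA <- as.matrix(cornersA); cornersB <- as.matrix(cornersB)
  if (nrow(cornersA) < 3 || nrow(cornersB) < 3)
    stop("cornerAlign needs >= 3 corners on each side")
  A <- sweep(cornersA, 2, colMeans(cornersA))
  B <- sweep(cornersB, 2, colMeans(cornersB))
  ab <- nearestNeighborCpp(A, B)$index
  ba <- nearestNeighborCpp(B, A)$index
  mutual <- which(ba[ab] == seq_len(nrow(A)))
  if (length(mutual) < 3)
    stop("cornerAlign: fewer than 3 mutual corner matches")
  srcM <- cornersA[mutual, , drop = FALSE]
  dstM <- cornersB[ab[mutual], , drop = FALSE]
  translationOnly <- function()
    rigidTransform(diag(3), colMeans(dstM) - colMeans(srcM))
  spread <- svd(sweep(srcM, 2, colMeans(srcM)), nu = 0, nv = 0)$d
  if (spread[2] < minSpread) return(translationOnly())
  tr <- tryCatch(kabsch(srcM, dstM), error = function(e) NULL)
  if (is.null(tr) || rotationAngle(rotation(tr)) > maxRotDeg)
    return(translationOnly())
  tr
}

#' Iterative closest point refinement
#'
#' Point-to-point ICP: alternate nearest-neighbour correspondence with the
#' closed-form Kabsch update. Correspondences farther than
#' \code{maxCorrDist} are dropped from the update (guarding against
#' partially overlapping landmark sets). Iteration stops when the RMS
#' residual improves by less than \code{tol}, would increase, or
#' \code{maxIter} is reached; the reported residual sequence is
#' non-increasing.
#'
#' @param src,dst non-empty \linkS4class{PointCloud}s.
#' @param init initial \linkS4class{RigidTransform}, default identity.
#' @param maxIter maximum iterations, default 50.
#' @param tol convergence tolerance on the residual change (m), default
#'   1e-4.
#' @param maxCorrDist correspondence rejection distance (m), default 0.5.
#' @param maxSrcPoints source points are uniformly subsampled to at most
#'   this many for speed (deterministic).
#' @return a \code{registrationResult} list: \code{transform},
#'   \code{rmsResidual}, \code{nIterations}, \code{converged},
#'   \code{residuals} (per-iteration trace).
#' @export
icpRefine <- function(src, dst, init = rigidTransform(), maxIter = 50,
                      tol = 1e-4, maxCorrDist = 0.5, maxSrcPoints = 2000) {
  if (nPoints(src) == 0 || nPoints(dst) == 0)
    stop("icpRefine needs non-empty clouds")
  sm <- coords(src)
  if (nrow(sm) > maxSrcPoints)
    sm <- sm[round(seq(1, nrow(sm), length.out = maxSrcPoints)), ,
             drop = FALSE]
  dm <- coords(dst)
  tr <- init
  resid <- function(trf) {
    nn <- nearestNeighborCpp(applyTransform(sm, trf), dm)
    use <- nn$distance <= maxCorrDist
    if (sum(use) < 3) use <- rep(TRUE, length(use))
    list(rms = sqrt(mean(nn$distance[use]^2)), idx = nn$index, use = use)
  }
  st <- resid(tr)
  trace <- st$rms
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    upd <- tryCatch(
      kabsch(sm[st$use, , drop = FALSE],
             dm[st$idx[st$use], , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(upd)) break
    stNew <- resid(upd)
    if (stNew$rms > utils::tail(trace, 1)) { iter <- iter - 1L; break }
    improvement <- utils::tail(trace, 1) - stNew$rms
    tr <- upd; st <- stNew
    trace <- c(trace, stNew$rms)
    if (improvement < tol) { converged <- TRUE; break }
  }
  structure(list(transform = tr, rmsResidual = utils::tail(trace, 1),
                 nIterations = iter, converged = converged,
                 residuals = trace),
            class = "registrationResult")
}

#' Register two scans through their virtual landmarks
#'
#' Detects landmark plates in each ROI-abstracted scan, pools the virtual
#' plate clouds, coarse-aligns them (sampled feature consensus, with a
#' corner-correspondence fallback when consensus fails and at least three
#' corners are present on each side), and refines with ICP. The resulting
#' transform maps the frame of \code{scanA} into the frame of \code{scanB}
#' and can be applied to the full scans for merging.
#'
#' @param scanA,scanB ROI-abstracted \linkS4class{PointCloud}s.
#' @param dbParams,lmParams clustering and plate-filter parameters.
#' @param coarse \code{"sacia"} (default) or \code{"corner"}.
#' @param seed consensus seed, default 0.
#' @param hStep,vStep virtual landmark interpolation steps (m).
#' @param ... passed to [icpRefine()].
#' @return a \code{registrationResult} (see [icpRefine()]) with extra
#'   elements \code{nLandmarksA}, \code{nLandmarksB}, \code{coarseMethod}.
#' @export
registerViaLandmarks <- function(scanA, scanB, dbParams = dbscanParams(),
                                 lmParams = landmarkFilterParams(),
                                 coarse = c("sacia", "corner"), seed = 0,
                                 hStep = 0.01, vStep = 0.01, ...) {
  coarse <- match.arg(coarse)
  lmA <- detectLandmarks(scanA, dbParams, lmParams, hStep, vStep)
  lmB <- detectLandmarks(scanB, dbParams, lmParams, hStep, vStep)
  .registerVirtual(lmA, lmB, coarse = coarse, seed = seed, ...)
}

# register two landmark detection sets through their pooled virtual clouds.
# The sampled-consensus coarse transform competes with the deterministic
# corner-correspondence transform under the same consensus score; the
# better initialization goes into ICP.
.registerVirtual <- function(lmA, lmB, coarse = "sacia", seed = 0, ...) {
  if (length(lmA) < 1 || length(lmB) < 1)
    stop("registration failed: ", length(lmA), " landmark(s) in scan A, ",
         length(lmB), " in scan B")
  vlA <- concatClouds(lapply(lmA, `[[`, "virtualCloud"))
  vlB <- concatClouds(lapply(lmB, `[[`, "virtualCloud"))
  cA <- do.call(rbind, lapply(lmA, `[[`, "corner"))
  cB <- do.call(rbind, lapply(lmB, `[[`, "corner"))
  usedCoarse <- coarse
  if (coarse == "corner") {
    init <- cornerAlign(cA, cB)
  } else {
    init <- coarseAlign(vlA, vlB, seed = seed)
    if (nrow(cA) >= 3 && nrow(cB) >= 3) {
      cini <- tryCatch(cornerAlign(cA, cB), error = function(e) NULL)
      if (!is.null(cini)) {
        srcD <- coords(voxelDownsample(vlA, 0.04))
        dstD <- coords(voxelDownsample(vlB, 0.04))
        scS <- .consensusScore(applyTransform(srcD, init), dstD, 0.12)
        scC <- .consensusScore(applyTransform(srcD, cini), dstD, 0.12)
        if (.scoreBetter(scC, scS)) {
          init <- cini
          usedCoarse <- "corner-fallback"
        }
      }
    }
  }
  res <- icpRefine(vlA, vlB, init = init, ...)
  res$nLandmarksA <- length(lmA)
  res$nLandmarksB <- length(lmB)
  res$coarseMethod <- usedCoarse
  res
}

#' Merge clouds into a common frame
#'
#' Applies one rigid transform per cloud and concatenates; the output point
#' count equals the sum of input counts.
#'
#' @param clouds list of \linkS4class{PointCloud}s.
#' @param transforms list of \linkS4class{RigidTransform}s, one per cloud.
#' @param frameId frame label of the merged cloud, default \code{"global"}.
#' @return the merged \linkS4class{PointCloud}.
#' @export
mergeClouds <- function(clouds, transforms, frameId = "global") {
  if (length(clouds) != length(transforms))
    stop("need exactly one transform per cloud")
  moved <- mapply(function(cl, tr) applyTransform(cl, tr, frameId = frameId),
                  clouds, transforms, SIMPLIFY = FALSE)
  concatClouds(moved)
}

#' Select observation plots with an incremental step
#'
#' Every \code{step}-th plot starting from plot \code{step}; e.g. 30 plots
#' with step 3 gives plots 3, 6, ..., 30 (10 frames). A step exceeding the
#' plot count falls back to the single last plot.
#'
#' @param nPlots total number of observation plots (>= 1).
#' @param step incremental step (>= 1).
#' @return integer vector of selected plot indices.
#' @export
selectPlots <- function(nPlots, step) {
  stopifnot(nPlots >= 1, step >= 1)
  if (step > nPlots) return(as.integer(nPlots))
  as.integer(seq(step, nPlots, by = step))
}
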