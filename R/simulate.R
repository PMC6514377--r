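#' Synthetic maize parcel specification
#'
#' Describes the emulated parcel: rows of plants running perpendicular to
#' the robot path (along X, into the field), spaced along Y by the row
#' spacing. Each plant is a dense vertical stem plus a few arched leaf
#' polylines; the ground is a sparse horizontal point carpet. Defaults
#' emulate a juvenile maize stand of ~0.6 m plants in 0.6 m rows starting
#' 3 m from the robot path.
#'
#' @param parcelDepth extent of the parcel along X (m), default 8.
#' @param fieldStartX distance from the path to the first plants (m),
#'   default 3 (beyond the sensor blind zone).
#' @param nRows number of crop rows, default 20.
#' @param rowSpacingMean,rowSpacingSd row spacing mean and jitter (m),
#'   defaults 0.6 and 0.02.
#' @param plantSpacing in-row plant spacing (m), default 0.25.
#' @param plantHeightMean,plantHeightSd plant height mean and s.d. (m),
#'   defaults 0.6 and 0.04 (heights truncated at +/- 2.5 s.d.).
#' @param stemPointsPerM stem surface sampling density (points per meter of
#'   stem height), default 700.
#' @param stemRadius stem radius (m), default 0.015.
#' @param leavesPerPlant leaves per plant, default 3.
#' @param leafLength leaf arc length scale (m), default 0.25.
#' @param leafPoints sampled points per leaf, default 15 (leaves return far
#'   fewer points per unit area than stems, which is what row detection
#'   exploits).
#' @param yJitterSd lateral jitter of plant positions off the row line (m),
#'   default 0.01.
#' @param groundPointsPerM2 ground sampling density (points per square
#'   meter), default 25.
#' @return a \code{fieldSpec} list.
#' @export
fieldSpec <- function(parcelDepth = 8, fieldStartX = 3, nRows = 20,
                      rowSpacingMean = 0.6, rowSpacingSd = 0.02,
                      plantSpacing = 0.25,
                      plantHeightMean = 0.6, plantHeightSd = 0.04,
                      stemPointsPerM = 700, stemRadius = 0.015,
                      leavesPerPlant = 3, leafLength = 0.25,
                      leafPoints = 15, yJitterSd = 0.01,
                      groundPointsPerM2 = 25) {
  stopifnot(parcelDepth > 0, fieldStartX > 0, nRows >= 1,
            rowSpacingMean > 0, rowSpacingSd >= 0, plantSpacing > 0,
            plantHeightMean > 0, plantHeightSd >= 0, stemPointsPerM > 0,
            leafLength > 0, groundPointsPerM2 >= 0)
  if (plantHeightSd * 2.5 >= plantHeightMean)
    stop("plant height s.d. too large relative to the mean")
  structure(as.list(environment()), class = "fieldSpec")
}

#' Landmark plate specification
#'
#' Rectangular 0.40 m x 0.30 m plates on tripods along the path side of the
#' parcel, raised so the lower border clears the canopy by at least 0.1 m.
#'
#' @param nPlates number of plates, default 5.
#' @param plateW,plateH plate width and height (m), defaults 0.40, 0.30.
#' @param clearance gap between the canopy top and the plate lower border
#'   (m), default 0.12 (must be >= 0.1).
#' @param plateX depth at which plates stand (m), default 2.7 (just beyond
#'   the blind zone, before the first row).
#' @param plateYs optional explicit plate corner y positions (m); when NULL
#'   the plates are spread along the parcel with jitter.
#' @param surfaceStep horizontal plate surface sampling step (m), default
#'   0.02.
#' @param surfaceStepV vertical plate surface sampling step (m), default
#'   0.004 — fine enough that every scanner beam crossing the plate face
#'   produces returns, as it would on a continuous surface.
#' @return a \code{landmarkSpec} list.
#' @export
landmarkSpec <- function(nPlates = 5, plateW = 0.40, plateH = 0.30,
                         clearance = 0.12, plateX = 2.7, plateYs = NULL,
                         surfaceStep = 0.02, surfaceStepV = 0.004) {
  stopifnot(nPlates >= 0, plateW > 0, plateH > 0, surfaceStep > 0,
            surfaceStepV > 0)
  if (clearance < 0.1)
    stop("plate clearance above the canopy must be at least 0.1 m")
  structure(as.list(environment()), class = "landmarkSpec")
}

#' Scan acquisition specification
#'
#' The simulated scanner applies, in the sensor frame: vertical
#' field-of-view and blind-radius culling, discrete-beam elevation gating
#' (points survive only within a beam half-width of one of the scanner's
#' elevation lines — this reproduces the growing vertical gaps between
#' scan lines with range), mild 1/range azimuthal thinning, optional
#' line-of-sight stem occlusion, random dropout, and Gaussian range noise
#' along the ray.
#'
#' @param sensor a [sensorConfig()].
#' @param mount a [mountGeometry()]; the sensor origin sits \code{H + h}
#'   above ground and the blind radius follows [blindZoneDiameter()].
#' @param rangeNoiseSd range noise sigma (m), default the sensor's 0.02.
#' @param dropout fraction of returns lost at random, in [0, 1), default
#'   0.1.
#' @param beamHalfWidthDeg elevation half-width of a beam (degrees),
#'   default 0.06.
#' @param thinningRefRange range (m) beyond which azimuthal thinning
#'   reduces density as ref/range, default 4.
#' @param spotSpacing spacing of adjacent observation spots along the path
#'   (m), default 1.
#' @param yawSdDeg s.d. of the per-spot heading jitter (degrees), default
#'   0.3 (stop-and-go pose repeatability: large translations, small
#'   rotations between spots).
#' @param occlusion apply geometric line-of-sight occlusion by nearer
#'   plants (default TRUE): returns whose ray grazes a nearer plant below
#'   its top are lost, which is what starves deep rows of points in real
#'   side-view acquisitions.
#' @param occluderRadiusScale effective occluder radius as a multiple of
#'   the stem radius, default 3 — a maize plant blocks a corridor much
#'   wider than its bare stem because of the leaf sheath and leaves.
#' @return a \code{scanSpec} list.
#' @export
scanSpec <- function(sensor = sensorConfig(), mount = mountGeometry(),
                     rangeNoiseSd = sensor$rangeAccuracyM, dropout = 0.1,
                     beamHalfWidthDeg = 0.06, thinningRefRange = 4,
                     spotSpacing = 1, yawSdDeg = 0.3, occlusion = TRUE,
                     occluderRadiusScale = 3) {
  stopifnot(rangeNoiseSd >= 0, dropout >= 0, dropout < 1,
            beamHalfWidthDeg > 0, spotSpacing > 0, yawSdDeg >= 0,
            occluderRadiusScale > 0)
  structure(list(sensor = sensor, mount = mount,
                 rangeNoiseSd = rangeNoiseSd, dropout = dropout,
                 beamHalfWidthDeg = beamHalfWidthDeg,
                 thinningRefRange = thinningRefRange,
                 spotSpacing = spotSpacing, yawSdDeg = yawSdDeg,
                 occlusion = occlusion,
                 occluderRadiusScale = occluderRadiusScale),
            class = "scanSpec")
}

#' Build a synthetic parcel world cloud with ground truth
#'
#' Generates the world-frame point cloud (ground at z = 0, robot path along
#' Y at x = 0) and the matching ground truth: per-plant positions and
#' heights, row lines, landmark plate corners and stem segments. The same
#' seed reproduces the world bit for bit.
#'
#' @param field a [fieldSpec()].
#' @param lm a [landmarkSpec()].
#' @param seed RNG seed.
#' @return list with \code{world} (\linkS4class{PointCloud}, frame
#'   \code{"world"}) and \code{truth} (list: \code{plants} data frame
#'   (rowNum, cropNum, x, y, height), \code{rows} data frame (theta, rho),
#'   \code{spacings}, \code{corners} matrix, \code{stems} matrix,
#'   \code{canopyTop}).
#' @export
buildField <- function(field = fieldSpec(), lm = landmarkSpec(), seed = 0) {
  .withSeed(seed, {
    nPlants <- floor(field$parcelDepth / field$plantSpacing) + 1L
    rowY <- cumsum(c(0, stats::rnorm(field$nRows - 1, field$rowSpacingMean,
                                     field$rowSpacingSd)))
    if (any(diff(rowY) <= 2 * field$stemRadius))
      stop("row spacing jitter implies overlapping rows")
    width <- max(rowY)
    plants <- expand.grid(rowNum = seq_len(field$nRows),
                          cropNum = seq_len(nPlants))
    plants <- plants[order(plants$rowNum, plants$cropNum), ]
    plants$x <- field$fieldStartX + (plants$cropNum - 1) * field$plantSpacing
    plants$y <- rowY[plants$rowNum] +
      stats::rnorm(nrow(plants), 0, field$yJitterSd)
    h <- stats::rnorm(nrow(plants), field$plantHeightMean,
                      field$plantHeightSd)
    lim <- 2.5 * field$plantHeightSd
    plants$height <- pmin(pmax(h, field$plantHeightMean - lim),
                          field$plantHeightMean + lim)
    rownames(plants) <- NULL

    pts <- vector("list", nrow(plants) + 3L)
    for (p in seq_len(nrow(plants))) {
      hgt <- plants$height[p]
      ns <- max(2L, round(field$stemPointsPerM * hgt))
      az <- stats::runif(ns, 0, 2 * pi)
      rr <- field$stemRadius * sqrt(stats::runif(ns))
      stem <- cbind(plants$x[p] + rr * cos(az), plants$y[p] + rr * sin(az),
                    stats::runif(ns, 0, hgt))
      stem[which.max(stem[, 3]), 3] <- hgt   # the tip is part of the plant
      leaves <- NULL
      if (field$leavesPerPlant > 0) {
        lv <- lapply(seq_len(field$leavesPerPlant), function(l) {
          phi <- stats::runif(1, 0, 2 * pi)
          attach_z <- stats::runif(1, 0.35, 0.8) * hgt
          t <- stats::runif(field$leafPoints)
          rad <- field$leafLength * t
          z <- pmin(attach_z + 0.5 * field$leafLength * sin(pi * t) -
                      0.35 * field$leafLength * t, hgt)
          cbind(plants$x[p] + rad * cos(phi), plants$y[p] + rad * sin(phi),
                pmax(z, 0.02))
        })
        leaves <- do.call(rbind, lv)
      }
      pts[[p]] <- rbind(stem, leaves)
    }
    canopyTop <- max(plants$height)

    # ground carpet under and just around the parcel
    gx <- c(field$fieldStartX - 0.5, field$fieldStartX + field$parcelDepth +
              0.5)
    gy <- c(-0.5, width + 0.5)
    ng <- round(field$groundPointsPerM2 * diff(gx) * diff(gy))
    if (ng > 0)
      pts[[nrow(plants) + 1L]] <- cbind(stats::runif(ng, gx[1], gx[2]),
                                        stats::runif(ng, gy[1], gy[2]), 0)

    # landmark plates
    corners <- NULL
    if (lm$nPlates > 0) {
      plateYs <- lm$plateYs
      if (is.null(plateYs)) {
        # plates go at random positions along the path, kept at least 1 m
        # apart so DBSCAN never merges two plates
        yHi <- max(width - lm$plateW, 1)
        plateYs <- numeric(0)
        for (tries in seq_len(2000)) {
          cand <- stats::runif(1, 0, yHi)
          if (all(abs(cand - plateYs) >= 1)) plateYs <- c(plateYs, cand)
          if (length(plateYs) == lm$nPlates) break
        }
        if (length(plateYs) < lm$nPlates)
          stop("could not place ", lm$nPlates, " plates at least 1 m apart")
        plateYs <- sort(plateYs)
      }
      zLo <- canopyTop + lm$clearance
      gy_ <- seq(0, lm$plateW, by = lm$surfaceStep)
      gz <- seq(0, lm$plateH, by = lm$surfaceStepV)
      g <- expand.grid(dy = gy_, dz = gz)
      plate <- do.call(rbind, lapply(plateYs, function(py)
        cbind(lm$plateX, py + g$dy, zLo + g$dz)))
      pts[[nrow(plants) + 2L]] <- plate
      corners <- cbind(x = rep(lm$plateX, length(plateYs)), y = plateYs,
                       z = zLo + lm$plateH)
    }

    world <- pointCloud(do.call(rbind, pts), frameId = "world")
    truth <- list(
      plants = plants,
      rows = data.frame(theta = 90, rho = rowY),
      spacings = diff(rowY),
      corners = corners,
      stems = cbind(x = plants$x, y = plants$y, zBase = 0,
                    zTop = plants$height,
                    radius = field$stemRadius),
      canopyTop = canopyTop,
      width = width)
    list(world = world, truth = truth)
  })
}

#' Simulate one scan of the world from a sensor pose
#'
#' Transforms the world into the sensor frame and applies the acquisition
#' model of [scanSpec()]. Deterministic for a fixed seed. With zero noise
#' and dropout, the returned points are exactly rigidly transformed world
#' points.
#'
#' @param world the world \linkS4class{PointCloud} from [buildField()].
#' @param pose \linkS4class{RigidTransform} mapping the sensor frame into
#'   the world frame.
#' @param spec a [scanSpec()].
#' @param seed RNG seed.
#' @param stems optional stem matrix (from the ground truth) enabling
#'   occlusion when \code{spec$occlusion} is TRUE.
#' @return a \linkS4class{PointCloud} in the \code{"sensor"} frame.
#' @export
simulateScan <- function(world, pose, spec = scanSpec(), seed = 0,
                         stems = NULL) {
  m <- applyTransform(coords(world), invertTransform(pose))
  rHoriz <- sqrt(m[, 1]^2 + m[, 2]^2)
  elev <- atan2(m[, 3], rHoriz) * 180 / pi
  vfov <- spec$sensor$vfovDeg
  blind <- blindZoneDiameter(spec$mount)
  keep <- elev >= vfov[1] & elev <= vfov[2] & rHoriz >= blind & rHoriz <= 120
  # discrete beam elevations: survive only near one of the nLines angles
  beams <- seq(vfov[1], vfov[2], length.out = spec$sensor$nLines)
  beamStep <- beams[2] - beams[1]
  offset <- abs((elev - vfov[1]) %% beamStep)
  offset <- pmin(offset, beamStep - offset)
  keep <- keep & offset <= spec$beamHalfWidthDeg
  m <- m[keep, , drop = FALSE]
  rHoriz <- rHoriz[keep]
  .withSeed(seed, {
    pKeep <- pmin(1, spec$thinningRefRange / pmax(rHoriz, 1e-9)) *
      (1 - spec$dropout)
    keep2 <- stats::runif(nrow(m)) < pKeep
    m <- m[keep2, , drop = FALSE]
    if (isTRUE(spec$occlusion) && !is.null(stems) && nrow(m)) {
      sm <- applyTransform(unname(cbind(stems[, 1], stems[, 2],
                                        stems[, 3])),
                           invertTransform(pose))
      smTop <- applyTransform(unname(cbind(stems[, 1], stems[, 2],
                                           stems[, 4])),
                              invertTransform(pose))
      stemSensor <- cbind(sm[, 1], sm[, 2], sm[, 3], smTop[, 3],
                          stems[, 5] * (spec$occluderRadiusScale %||% 1))
      m <- m[occludeCpp(m, stemSensor), , drop = FALSE]
    }
    if (spec$rangeNoiseSd > 0 && nrow(m)) {
      rng <- sqrt(rowSums(m^2))
      eps <- stats::rnorm(nrow(m), 0, spec$rangeNoiseSd)
      m <- m * (1 + eps / pmax(rng, 1e-9))
    }
    pointCloud(m, frameId = "sensor")
  })
}

#' Observation spot poses along the path
#'
#' Spot k stands at (0, (k-1) * spotSpacing, H + h) in the world frame with
#' a small random heading jitter; the global frame is the sensor frame at
#' the last spot.
#'
#' @param nSpots number of observation spots.
#' @param spec a [scanSpec()].
#' @param seed RNG seed (drives the heading jitter).
#' @return list of \linkS4class{RigidTransform}s (sensor -> world).
#' @export
spotPoses <- function(nSpots, spec = scanSpec(), seed = 0) {
  .withSeed(seed, {
    yaw <- stats::rnorm(nSpots, 0, spec$yawSdDeg)
    lapply(seq_len(nSpots), function(k)
      rigidTransform(rotationZ(yaw[k]),
                     c(0, (k - 1) * spec$spotSpacing,
                       spec$mount$H + spec$mount$h)))
  })
}

#' Simulate a complete multi-spot dataset in memory
#'
#' @param field,lm,spec specifications (see [fieldSpec()],
#'   [landmarkSpec()], [scanSpec()]).
#' @param nSpots number of observation spots, default 10.
#' @param seed master seed; the world, poses and every scan derive their
#'   own sub-seed from it.
#' @return list with \code{scans} (list of sensor-frame
#'   \linkS4class{PointCloud}s), \code{world}, \code{truth}, \code{poses}.
#' @export
simulateDataset <- function(field = fieldSpec(), lm = landmarkSpec(),
                            spec = scanSpec(), nSpots = 10, seed = 0) {
  fw <- buildField(field, lm, seed = seed)
  poses <- spotPoses(nSpots, spec, seed = seed + 1L)
  scans <- lapply(seq_len(nSpots), function(k)
    simulateScan(fw$world, poses[[k]], spec, seed = seed + 1L + k,
                 stems = fw$truth$stems))
  list(scans = scans, world = fw$world, truth = fw$truth, poses = poses)
}

#' Write a simulated dataset to disk
#'
#' Writes \code{spot_NN.pcd} per viewpoint, \code{world.pcd},
#' \code{truth.json} (poses as row-major rotation plus translation, plants,
#' rows, plate corners) and \code{config.json}; fully reproducible from the
#' seed.
#'
#' @inheritParams simulateDataset
#' @param outDir output directory (created if needed).
#' @return the dataset list of [simulateDataset()], invisibly, with file
#'   paths in \code{files}.
#' @export
makeDataset <- function(field = fieldSpec(), lm = landmarkSpec(),
                        spec = scanSpec(), nSpots = 10, outDir, seed = 0) {
  ds <- simulateDataset(field, lm, spec, nSpots, seed)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  spotFiles <- file.path(outDir, sprintf("spot_%02d.pcd", seq_len(nSpots)))
  for (k in seq_len(nSpots)) writeCloud(ds$scans[[k]], spotFiles[k])
  writeCloud(ds$world, file.path(outDir, "world.pcd"))
  truth <- ds$truth
  tj <- list(
    poses = lapply(ds$poses, function(p)
      list(R = as.numeric(t(rotation(p))), T = translation(p))),
    plants = truth$plants,
    rows = truth$rows,
    spacings = truth$spacings,
    corners = truth$corners,
    canopyTop = truth$canopyTop)
  jsonlite::write_json(tj, file.path(outDir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  cfg <- list(field = unclass(field), landmarks = unclass(lm),
              scan = list(rangeNoiseSd = spec$rangeNoiseSd,
                          dropout = spec$dropout,
                          spotSpacing = spec$spotSpacing,
                          yawSdDeg = spec$yawSdDeg,
                          occlusion = spec$occlusion),
              nSpots = nSpots, seed = seed)
  jsonlite::write_json(cfg, file.path(outDir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  ds$files <- list(spots = spotFiles,
                   world = file.path(outDir, "world.pcd"),
                   truth = file.path(outDir, "truth.json"),
                   config = file.path(outDir, "config.json"))
  invisible(ds)
}
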