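#' End-to-end pipeline configuration
#'
#' Bundles all stage parameters with their defaults. Unknown parameters
#' are rejected because the constructor has a fixed signature.
#'
#' @param sensor a [sensorConfig()].
#' @param mount a [mountGeometry()].
#' @param roi a [roiSpec()] (built with the mount by default).
#' @param dbscan a [dbscanParams()].
#' @param ch minimum landmark cluster height (m).
#' @param canopyCutHeight canopy cut height above the lowest scan point
#'   (m): plate returns live above it, plants below. Default 0.72 (plant
#'   height plus a small margin).
#' @param step merging plot incremental step, default 3.
#' @param seed registration consensus seed, default 0.
#' @param coarse coarse alignment method, \code{"sacia"} or
#'   \code{"corner"}.
#' @param icpTol,icpMaxIter ICP stopping parameters.
#' @param bandWidth,binWidth depth band and Y histogram widths (m).
#' @param peakMinCount,peakWindow histogram peak parameters
#'   (absolute floor and comparison half-window).
#' @param peakMinFrac per-band adaptive peak threshold: a bin must also
#'   reach this fraction of the band's maximum count, default 0.2. Stems
#'   concentrate an order of magnitude more projected points per bin than
#'   leaves, so a relative threshold separates them at any point density.
#' @param thetaRange,thetaRes,rhoRes,minSupport Hough parameters.
#' @param heights a [heightParams()].
#' @param verbose print per-stage progress, default FALSE.
#' @return a \code{pipelineConfig} list.
#' @export
pipelineConfig <- function(sensor = sensorConfig(), mount = mountGeometry(),
                           roi = roiSpec(geom = mount),
                           dbscan = dbscanParams(), ch = 0.1,
                           canopyCutHeight = 0.72,
                           step = 3, seed = 0,
                           coarse = c("sacia", "corner"),
                           icpTol = 1e-4, icpMaxIter = 50,
                           bandWidth = 1.0, binWidth = 0.02,
                           peakMinCount = 5, peakWindow = 2L,
                           peakMinFrac = 0.2,
                           thetaRange = c(75, 105), thetaRes = 1,
                           rhoRes = 0.02, minSupport = 3,
                           heights = heightParams(), verbose = FALSE) {
  coarse <- match.arg(coarse)
  stopifnot(step >= 1, canopyCutHeight > 0)
  structure(as.list(environment()), class = "pipelineConfig")
}

.log <- function(config, ...) if (isTRUE(config$verbose)) message(...)

# read a dataset directory written by makeDataset()
.readDataset <- function(dir) {
  spots <- sort(list.files(dir, pattern = "^spot_\\d+\\.pcd$",
                           full.names = TRUE))
  if (!length(spots)) stop("no spot_NN.pcd files in ", dir)
  scans <- lapply(spots, readCloud)
  truth <- NULL
  poses <- NULL
  tf <- file.path(dir, "truth.json")
  if (file.exists(tf)) {
    tj <- jsonlite::read_json(tf, simplifyVector = FALSE)
    poses <- lapply(tj$poses, function(p)
      rigidTransform(matrix(unlist(p$R), 3, 3, byrow = TRUE),
                     unlist(p$T)))
    asdf <- function(x) as.data.frame(lapply(x, unlist))
    truth <- list(plants = asdf(tj$plants),
                  rows = asdf(tj$rows),
                  spacings = unlist(tj$spacings),
                  corners = if (!is.null(tj$corners) && length(tj$corners))
                    do.call(rbind, lapply(tj$corners, function(r)
                      c(x = r[[1]], y = r[[2]], z = r[[3]])))
                  else NULL,
                  canopyTop = tj$canopyTop)
  }
  list(scans = scans, truth = truth, poses = poses)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full phenotyping pipeline
#'
#' Executes the four framework stages on a set of observation scans:
#' landmark detection, registration and cloud fusion, row spacing
#' computation, and plant height computation; when ground truth is
#' available (simulated datasets) an evaluation report is attached.
#'
#' @param data a directory written by [makeDataset()], a list returned by
#'   [simulateDataset()], or a plain list of sensor-frame
#'   \linkS4class{PointCloud}s.
#' @param config a [pipelineConfig()].
#' @return list with \code{merged} (global-frame cloud),
#'   \code{heightMin}, \code{lines} (detected rows), \code{spacings},
#'   \code{heights} (per-plant data frame), \code{registrations},
#'   \code{landmarks} (per selected scan), \code{selected} (plot indices),
#'   and \code{report} (see [evaluateAgainstTruth()]; NULL without truth).
#' @export
runPipeline <- function(data, config = pipelineConfig()) {
  if (is.character(data)) data <- .readDataset(data)
  if (!is.null(data$scans)) {
    scans <- data$scans; truth <- data$truth; poses <- data$poses
  } else {
    scans <- data; truth <- NULL; poses <- NULL
  }
  if (length(scans) < 2) stop("pipeline needs at least 2 scans")
  sel <- selectPlots(length(scans), config$step)
  .log(config, "selected plots: ", paste(sel, collapse = ", "))

  # stage 1: ROI + landmark detection per selected scan
  lmParamsFor <- function(zMin)
    landmarkFilterParams(ch = config$ch,
                         canopyCutZ = zMin + config$canopyCutHeight)
  rois <- lapply(scans[sel], abstractRoi, roi = config$roi)
  zMins <- vapply(rois, function(cl) min(coords(cl)[, 3]), numeric(1))
  landmarks <- lapply(seq_along(rois), function(i)
    detectLandmarks(rois[[i]], config$dbscan, lmParamsFor(zMins[i])))
  .log(config, "landmarks per scan: ",
       paste(lengths(landmarks), collapse = ", "))

  # stage 2: consecutive registration, composed into the last plot's frame
  n <- length(rois)
  pairwise <- vector("list", max(n - 1, 0))
  for (i in seq_len(n - 1)) {
    pairwise[[i]] <- .registerVirtual(landmarks[[i]], landmarks[[i + 1]],
                                      coarse = config$coarse,
                                      seed = config$seed + i,
                                      tol = config$icpTol,
                                      maxIter = config$icpMaxIter)
  }
  toGlobal <- vector("list", n)
  toGlobal[[n]] <- rigidTransform()
  for (i in rev(seq_len(n - 1)))
    toGlobal[[i]] <- composeTransforms(toGlobal[[i + 1]],
                                       pairwise[[i]]$transform)
  merged <- mergeClouds(rois, toGlobal)
  .log(config, "merged cloud: ", nPoints(merged), " points")

  # ground reference and bottom slice; the landmark plates sit above the
  # canopy cut and are fiducials, not plants, so the crop stages work on
  # the sub-canopy cloud only
  gs <- removeGroundSlice(merged, config$roi$groundSliceM)
  heightMin <- gs$zMin + config$roi$groundSliceM
  work <- gs$cloud
  work <- work[coords(work)[, 3] <= gs$zMin + config$canopyCutHeight]

  # stage 3: row spacing
  pts2d <- projectToPlane(work)
  hists <- bandHistograms(pts2d, config$bandWidth, config$binWidth)
  peaks <- do.call(rbind, lapply(hists, function(h)
    findPeaks(h, minCount = max(config$peakMinCount,
                                config$peakMinFrac * max(h$counts)),
              window = config$peakWindow)))
  lines <- houghRows(peaks, config$thetaRange, config$thetaRes,
                     config$rhoRes, config$minSupport)
  xMid <- if (nrow(pts2d)) mean(range(pts2d[, 1])) else 0
  spacings <- rowSpacings(lines, xMid = xMid)
  .log(config, nrow(lines), " rows detected")

  # stage 4: plant heights along each detected row
  hp <- config$heights
  hp$heightMin <- heightMin
  heights <- list()
  for (r in seq_len(nrow(lines))) {
    nbh <- selectRowNeighborhood(work, lines[r, ], hp$rowMargin)
    if (nPoints(nbh) == 0) next
    mesh <- meshDensity(nbh, hp$BL)
    dets <- detectPlants(mesh, hp)
    if (!length(dets)) next
    ph <- vapply(dets, function(d)
      plantHeight(nbh, d, heightMin), numeric(1))
    sx <- vapply(dets, function(d)
      mesh$origin[1] + (d$seed[1] - 0.5) * mesh$BL, numeric(1))
    sy <- vapply(dets, function(d)
      mesh$origin[2] + (d$seed[2] - 0.5) * mesh$BL, numeric(1))
    ord <- order(sx)
    heights[[r]] <- data.frame(rowIndex = r, cropNum = seq_along(ord),
                               x = sx[ord], y = sy[ord], PH = ph[ord])
  }
  heights <- if (length(heights)) do.call(rbind, heights)
             else data.frame(rowIndex = integer(0), cropNum = integer(0),
                             x = numeric(0), y = numeric(0),
                             PH = numeric(0))
  rownames(heights) <- NULL
  .log(config, nrow(heights), " plants detected")

  out <- list(merged = merged, heightMin = heightMin, lines = lines,
              spacings = spacings, heights = heights,
              registrations = pairwise, landmarks = landmarks,
              selected = sel, config = config, report = NULL)
  if (!is.null(truth))
    out$report <- evaluateAgainstTruth(out, truth, poses, scans, config)
  out
}

#' Evaluate pipeline output against simulator ground truth
#'
#' Produces the three evaluation tables: landmark detection success rate
#' per selected scan (NLV, DNL, DSR), row spacing estimates against true
#' spacings with R squared and RMSE, and per-plant height errors with
#' per-depth-group RMSE.
#'
#' @param result a [runPipeline()] result.
#' @param truth the simulator ground truth.
#' @param poses list of true sensor poses (sensor -> world), or NULL.
#' @param scans the original scan list.
#' @param config the [pipelineConfig()] used.
#' @param matchDist maximum detection-to-truth matching distance (m).
#' @return an \code{evaluationReport} list with \code{dsr},
#'   \code{rowSpacing} (\code{perRow}, \code{rSquared}, \code{rmse},
#'   \code{nRowsDetected}, \code{nRowsTrue}) and \code{heights}
#'   (\code{perPlant}, \code{groupRmse}).
#' @export
evaluateAgainstTruth <- function(result, truth, poses = NULL, scans = NULL,
                                 config = pipelineConfig(),
                                 matchDist = 0.15) {
  sel <- result$selected
  report <- list()

  # landmark DSR per selected scan
  if (!is.null(truth$corners) && !is.null(poses)) {
    blind <- blindZoneDiameter(config$mount)
    dsr <- lapply(seq_along(sel), function(i) {
      k <- sel[i]
      inv <- invertTransform(poses[[k]])
      cs <- applyTransform(truth$corners, inv)    # sensor frame
      ctr <- cs
      ctr[, 3] <- ctr[, 3] - 0.15                 # plate center
      r <- sqrt(ctr[, 1]^2 + ctr[, 2]^2)
      elev <- atan2(ctr[, 3], r) * 180 / pi
      vis <- ctr[, 1] > 0 & r >= blind & r <= 120 &
        elev >= config$sensor$vfovDeg[1] & elev <= config$sensor$vfovDeg[2]
      det <- result$landmarks[[i]]
      dnl <- 0L
      if (length(det)) {
        dc <- do.call(rbind, lapply(det, `[[`, "corner"))
        nn <- nearestNeighborCpp(cs[vis, , drop = FALSE], dc)
        dnl <- sum(nn$distance <= 0.2)
      }
      nlv <- sum(vis)
      data.frame(spot = k, NLV = nlv, DNL = dnl,
                 DSR = if (nlv > 0) detectionSuccessRate(dnl, nlv)
                       else NA_real_)
    })
    report$dsr <- do.call(rbind, dsr)
  }

  # row spacing against truth (spacings are invariant to the rigid frame)
  trueRs <- truth$spacings
  estRs <- result$spacings
  nTrue <- length(trueRs) + 1L
  perRow <- NULL
  reg <- list(rSquared = NA_real_, rmse = NA_real_)
  if (length(estRs) == length(trueRs) && length(trueRs) >= 2) {
    perRow <- data.frame(index = seq_along(trueRs), truth = trueRs,
                         estimate = estRs, error = abs(estRs - trueRs))
    reg <- evalRegression(estRs, trueRs)
  }
  report$rowSpacing <- list(perRow = perRow, rSquared = reg$rSquared,
                            rmse = reg$rmse,
                            nRowsDetected = nrow(result$lines),
                            nRowsTrue = nTrue)

  # plant heights against truth: truth positions mapped into the global
  # frame (the sensor frame at the last selected spot)
  if (!is.null(truth$plants) && nrow(result$heights)) {
    plantsXY <- cbind(truth$plants$x, truth$plants$y, 0)
    if (!is.null(poses)) {
      inv <- invertTransform(poses[[sel[length(sel)]]])
      plantsXY <- applyTransform(plantsXY, inv)
    }
    detXY <- cbind(result$heights$x, result$heights$y, 0)
    nn <- nearestNeighborCpp(cbind(plantsXY[, 1], plantsXY[, 2], 0), detXY)
    ok <- nn$distance <= matchDist
    if (any(ok)) {
      xg <- cut(plantsXY[ok, 1], c(-Inf, 5, 8, Inf),
                labels = c("0<=x<5", "5<=x<8", "x>=8"), right = FALSE)
      tab <- heightErrorTable(truth$plants$height[ok],
                              result$heights$PH[nn$index[ok]],
                              as.character(xg))
      tab$perPlant <- cbind(
        data.frame(rowNum = truth$plants$rowNum[ok],
                   cropNum = truth$plants$cropNum[ok]),
        tab$perPlant)
      report$heights <- tab
      report$heights$nMatched <- sum(ok)
      report$heights$nTruePlants <- nrow(truth$plants)
    }
  }
  structure(report, class = "evaluationReport")
}

#' Write an evaluation report to disk
#'
#' One CSV per table (landmark DSR, row spacings, per-plant heights, group
#' RMSE) plus a plain-text summary whose aggregates are recomputed from
#' the CSV rows.
#'
#' @param report an \code{evaluationReport} from [runPipeline()].
#' @param outDir output directory (created if needed).
#' @return character vector of written file paths, invisibly.
#' @export
writeReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wcsv <- function(df, name, empty) {
    p <- file.path(outDir, name)
    if (is.null(df) || !nrow(df)) {
      writeLines(paste(empty, collapse = ","), p)
    } else utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }
  wcsv(report$dsr, "landmark_dsr.csv", c("spot", "NLV", "DNL", "DSR"))
  wcsv(report$rowSpacing$perRow, "row_spacings.csv",
       c("index", "truth", "estimate", "error"))
  wcsv(report$heights$perPlant, "plant_heights.csv",
       c("rowNum", "cropNum", "manual", "computed", "error", "errorRatio",
         "xGroup"))
  wcsv(report$heights$groupRmse, "height_group_rmse.csv",
       c("xGroup", "rmse", "n"))
  summary_ <- c(
    "phenolidar evaluation summary",
    sprintf("rows detected: %s of %s",
            report$rowSpacing$nRowsDetected %||% NA,
            report$rowSpacing$nRowsTrue %||% NA),
    sprintf("row spacing R^2: %.4f  RMSE: %.4f m",
            report$rowSpacing$rSquared, report$rowSpacing$rmse),
    if (!is.null(report$dsr))
      sprintf("mean DSR: %.1f %%", mean(report$dsr$DSR, na.rm = TRUE)),
    if (!is.null(report$heights))
      sprintf("height RMSE [%s]: %.3f m (n=%d)",
              report$heights$groupRmse$xGroup,
              report$heights$groupRmse$rmse,
              report$heights$groupRmse$n))
  sp <- file.path(outDir, "summary.txt")
  writeLines(summary_, sp)
  invisible(c(files, sp))
}

#' @export
print.evaluationReport <- function(x, ...) {
  cat("Evaluation report\n")
  if (!is.null(x$dsr)) {
    cat(sprintf("  landmark DSR: mean %.1f%% over %d scans\n",
                mean(x$dsr$DSR, na.rm = TRUE), nrow(x$dsr)))
  }
  cat(sprintf("  rows: %s detected / %s true; spacing RMSE %.4f m, R^2 %.4f\n",
              x$rowSpacing$nRowsDetected, x$rowSpacing$nRowsTrue,
              x$rowSpacing$rmse, x$rowSpacing$rSquared))
  if (!is.null(x$heights)) {
    g <- x$heights$groupRmse
    cat("  height RMSE by depth group:\n")
    for (i in seq_len(nrow(g)))
      cat(sprintf("    %-8s %.3f m (n=%d)\n", g$xGroup[i], g$rmse[i],
                  g$n[i]))
  }
  invisible(x)
}
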