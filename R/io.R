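#' Read a point cloud file
#'
#' Supported dialects: PCD (ASCII and binary little-endian, fields
#' \code{x y z} possibly among others), PLY (ASCII), and XYZ/CSV
#' (whitespace- or comma-separated \code{x y z} per line; lines starting
#' with \code{#} are skipped). The format is guessed from the file extension
#' when not given.
#'
#' @param path file path.
#' @param format one of \code{"pcd"}, \code{"ply"}, \code{"xyz"}, or
#'   \code{"auto"} (default: by extension; unknown extensions fall back to
#'   XYZ).
#' @param frameId frame label attached to the cloud.
#' @return a \linkS4class{PointCloud}.
#' @seealso [writeCloud()]
#' @export
readCloud <- function(path, format = c("auto", "pcd", "ply", "xyz"),
                      frameId = "sensor") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pcd = "pcd", ply = "ply", "xyz")
  }
  coords <- switch(format,
                   pcd = .readPcd(path),
                   ply = .readPly(path),
                   xyz = .readXyz(path))
  pointCloud(coords, frameId = frameId)
}

#' Write a point cloud file
#'
#' Writes PCD (ASCII), PLY (ASCII) or XYZ. Coordinates are written with
#' enough digits that a read/write round trip preserves them to well below
#' 1e-6 m.
#'
#' @param cloud a \linkS4class{PointCloud}.
#' @param path output file path.
#' @param format one of \code{"pcd"}, \code{"ply"}, \code{"xyz"},
#'   \code{"auto"} (by extension).
#' @return \code{path}, invisibly.
#' @export
writeCloud <- function(cloud, path, format = c("auto", "pcd", "ply", "xyz")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, pcd = "pcd", ply = "ply", xyz = , csv = , txt = "xyz",
                     stop("cannot infer point cloud format from '", ext, "'"))
  }
  xyz <- coords(cloud)
  n <- nrow(xyz)
  body <- if (n)
    paste(formatC(xyz[, 1], format = "g", digits = 10),
          formatC(xyz[, 2], format = "g", digits = 10),
          formatC(xyz[, 3], format = "g", digits = 10))
  else character(0)
  lines <- switch(format,
    pcd = c("# .PCD v0.7 - Point Cloud Data file format",
            "VERSION 0.7", "FIELDS x y z", "SIZE 8 8 8", "TYPE F F F",
            "COUNT 1 1 1", paste("WIDTH", n), "HEIGHT 1",
            "VIEWPOINT 0 0 0 1 0 0 0", paste("POINTS", n), "DATA ascii",
            body),
    ply = c("ply", "format ascii 1.0", paste("element vertex", n),
            "property double x", "property double y", "property double z",
            "end_header", body),
    xyz = body)
  writeLines(lines, path)
  invisible(path)
}

.readXyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(matrix(numeric(0), 0, 3))
  toks <- strsplit(trimws(lines), "[,[:space:]]+")
  bad <- which(vapply(toks, length, integer(1)) < 3L)
  if (length(bad))
    stop("line ", lineno[bad[1]], ": expected at least 3 coordinates")
  m <- matrix(suppressWarnings(
    as.numeric(unlist(lapply(toks, `[`, 1:3)))), ncol = 3, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1, any))[1]
    stop("line ", lineno[bad], ": non-numeric coordinate")
  }
  m
}

.readPcd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  nheader <- 0L
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) stop("malformed PCD header: no DATA line")
    nheader <- nheader + 1L
    if (nheader > 100L) stop("malformed PCD header: DATA line not found")
    line <- trimws(line)
    if (!nzchar(line) || startsWith(line, "#")) next
    toks <- strsplit(line, "[[:space:]]+")[[1]]
    key <- toupper(toks[1])
    hdr[[key]] <- toks[-1]
    if (key == "DATA") break
  }
  for (need in c("FIELDS", "SIZE", "TYPE", "POINTS", "DATA"))
    if (is.null(hdr[[need]]))
      stop("malformed PCD header: missing ", need)
  fields <- hdr$FIELDS
  sizes <- as.integer(hdr$SIZE)
  types <- toupper(hdr$TYPE)
  cnts <- if (is.null(hdr$COUNT)) rep(1L, length(fields))
          else as.integer(hdr$COUNT)
  npts <- suppressWarnings(as.integer(hdr$POINTS[1]))
  if (is.na(npts)) stop("malformed PCD header: non-numeric POINTS")
  ixyz <- match(c("x", "y", "z"), fields)
  if (anyNA(ixyz)) stop("PCD file lacks x/y/z fields")
  mode <- tolower(hdr$DATA[1])
  if (mode == "ascii") {
    lines <- readLines(con, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < npts)
      stop("PCD DATA section has ", length(lines), " rows, header declares ",
           npts)
    toks <- strsplit(trimws(lines[seq_len(npts)]), "[[:space:]]+")
    colstart <- cumsum(c(0L, cnts))[seq_along(fields)] + 1L
    m <- matrix(NA_real_, npts, 3)
    for (k in 1:3) {
      vals <- suppressWarnings(
        as.numeric(vapply(toks, `[`, character(1), colstart[ixyz[k]])))
      if (anyNA(vals))
        stop("line ", nheader + which(is.na(vals))[1],
             ": non-numeric coordinate in PCD DATA")
      m[, k] <- vals
    }
    m
  } else if (mode %in% c("binary", "binary_compressed")) {
    if (mode == "binary_compressed")
      stop("compressed binary PCD is not supported")
    stride <- sum(sizes * cnts)
    raw <- readBin(con, "raw", n = npts * stride)
    if (length(raw) < npts * stride)
      stop("binary PCD truncated: expected ", npts * stride, " bytes")
    offs <- cumsum(c(0L, sizes * cnts))
    m <- matrix(NA_real_, npts, 3)
    base <- (seq_len(npts) - 1L) * stride
    for (k in 1:3) {
      f <- ixyz[k]
      sz <- sizes[f]
      what <- if (types[f] == "F") "double" else "integer"
      idx <- as.vector(outer(seq_len(sz), base + offs[f], `+`))
      m[, k] <- readBin(raw[idx], what, n = npts, size = sz,
                        endian = "little", signed = TRUE)
    }
    m
  } else stop("unsupported PCD DATA mode: ", mode)
}

.readPly <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply")
    stop("line 1: not a PLY file")
  endh <- which(trimws(lines) == "end_header")[1]
  if (is.na(endh)) stop("malformed PLY header: no end_header")
  hdr <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format[[:space:]]+ascii", hdr)))
    stop("only ASCII PLY is supported")
  vline <- grep("^element[[:space:]]+vertex", hdr, value = TRUE)
  if (!length(vline)) stop("malformed PLY header: no vertex element")
  n <- as.integer(strsplit(vline[1], "[[:space:]]+")[[1]][3])
  # property order within the vertex element
  vidx <- grep("^element[[:space:]]+vertex", hdr)[1]
  nexte <- grep("^element[[:space:]]", hdr)
  stopidx <- c(nexte[nexte > vidx], endh)[1]
  props <- hdr[(vidx + 1):(stopidx - 1)]
  props <- props[startsWith(props, "property")]
  pnames <- vapply(strsplit(props, "[[:space:]]+"), function(t) t[length(t)],
                   character(1))
  ixyz <- match(c("x", "y", "z"), pnames)
  if (anyNA(ixyz)) stop("PLY vertex element lacks x/y/z properties")
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n)
    stop("PLY vertex data has ", length(body), " rows, header declares ", n)
  toks <- strsplit(trimws(body[seq_len(n)]), "[[:space:]]+")
  m <- matrix(NA_real_, max(n, 0L), 3)
  for (k in 1:3) {
    vals <- suppressWarnings(
      as.numeric(vapply(toks, `[`, character(1), ixyz[k])))
    if (length(vals) && anyNA(vals))
      stop("line ", endh + which(is.na(vals))[1], ": non-numeric coordinate")
    m[, k] <- vals
  }
  m
}
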