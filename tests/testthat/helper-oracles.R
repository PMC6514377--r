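# Independent brute-force oracles used against the package implementations.

# all-pairs fixed-radius neighbourhood (ids, inclusive, self included)
bruteRadiusQuery <- function(m, center, radius) {
  d <- sqrt(colSums((t(m) - center)^2))
  which(d <= radius)
}

# reference DBSCAN from the textbook definition, all-pairs distances.
# Same conventions as the package: neighbourhood includes the point itself,
# clusters numbered in discovery order, border points keep the first
# cluster that reaches them.
bruteDbscan <- function(m, eps, minPts) {
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= minPts
  labels <- integer(n)
  types <- rep("NOISE", n)
  cl <- 0L
  visited <- logical(n)
  for (i in seq_len(n)) {
    if (visited[i]) next
    visited[i] <- TRUE
    if (!core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    types[i] <- "CORE"
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (types[j] == "NOISE") types[j] <- "BORDER"
      }
      if (visited[j]) next
      visited[j] <- TRUE
      if (core[j]) {
        types[j] <- "CORE"
        for (k in nb[[j]]) {
          if (labels[k] == 0L) {
            labels[k] <- cl
            if (types[k] == "NOISE") types[k] <- "BORDER"
          }
          if (!visited[k]) queue <- c(queue, k)
        }
      }
    }
  }
  list(labels = labels, types = types)
}

# canonical relabelling by first appearance, for label comparison
canonicalLabels <- function(labels) {
  seen <- unique(labels[labels != 0L])
  out <- labels
  for (i in seq_along(seen)) out[labels == seen[i]] <- i
  out
}

# two-pass reference R^2 / RMSE, independent of lm()
refRegression <- function(est, tru) {
  fitRes <- est - (cov(est, tru) / var(tru)) * (tru - mean(tru)) - mean(est)
  list(rSquared = 1 - sum(fitRes^2) / sum((est - mean(est))^2),
       rmse = sqrt(mean((est - tru)^2)))
}

# a small axis-aligned plate grid used by landmark tests
makePlateCloud <- function(x, y0, z0, w = 0.40, h = 0.30, step = 0.02) {
  g <- expand.grid(y = seq(0, w, by = step), z = seq(0, h, by = step))
  cbind(x = rep(x, nrow(g)), y = y0 + g$y, z = z0 + g$z)
}

# tiny simulated dataset used by several end-to-end tests (kept small so
# the default suite stays fast)
smallDataset <- function(seed = 0, nSpots = 4, occlusion = TRUE) {
  simulateDataset(
    field = fieldSpec(parcelDepth = 3, nRows = 8, stemPointsPerM = 500),
    lm = landmarkSpec(plateYs = c(0.3, 1.6, 3.4)),
    spec = scanSpec(occlusion = occlusion),
    nSpots = nSpots, seed = seed)
}
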