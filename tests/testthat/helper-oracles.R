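# Independent brute-force oracles used to validate the fast implementations.

# Connected components by queue-based flood fill, scanning pixels in
# row-major order (independent of the package's column-major Rcpp BFS; only
# the partition into components is compared, not label numbering).
floodFillOracle <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nbrs <- if (connectivity == 4L)
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  else
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  k <- 0L
  stackI <- integer(nr * nc); stackJ <- integer(nr * nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    k <- k + 1L
    top <- 1L
    stackI[1L] <- i; stackJ[1L] <- j
    lab[i, j] <- k
    while (top > 0L) {
      pi <- stackI[top]; pj <- stackJ[top]; top <- top - 1L
      for (m in seq_len(nrow(nbrs))) {
        qi <- pi + nbrs[m, 1]; qj <- pj + nbrs[m, 2]
        if (qi >= 1 && qi <= nr && qj >= 1 && qj <= nc &&
            mask[qi, qj] && lab[qi, qj] == 0L) {
          lab[qi, qj] <- k
          top <- top + 1L
          stackI[top] <- qi; stackJ[top] <- qj
        }
      }
    }
  }
  lab
}

# TRUE when two label rasters induce the same partition of the foreground.
samePartition <- function(a, b) {
  if (!identical(a > 0L, b > 0L)) return(FALSE)
  fg <- which(a > 0L)
  if (!length(fg)) return(TRUE)
  # components are equal iff the label pairs are in bijection
  pairs <- unique(cbind(a[fg], b[fg]))
  !anyDuplicated(pairs[, 1]) && !anyDuplicated(pairs[, 2])
}

# Convex-hull area by gift wrapping (Jarvis march) plus the triangle-fan
# area; independent of grDevices::chull and the shoelace helper.
giftWrapHullArea <- function(points) {
  pts <- unique(points[, 2:1, drop = FALSE])  # work in (x, y)
  n <- nrow(pts)
  if (n < 3L) return(0)
  start <- which.min(pts[, 1] + 1e-9 * pts[, 2])
  hull <- start
  repeat {
    p <- hull[length(hull)]
    cand <- if (length(hull) == 1L) setdiff(seq_len(n), p) else seq_len(n)[-p]
    best <- cand[1]
    for (q in cand[-1]) {
      cr <- (pts[best, 1] - pts[p, 1]) * (pts[q, 2] - pts[p, 2]) -
            (pts[best, 2] - pts[p, 2]) * (pts[q, 1] - pts[p, 1])
      if (cr < 0 ||
          (cr == 0 && sum((pts[q, ] - pts[p, ])^2) >
                      sum((pts[best, ] - pts[p, ])^2)))
        best <- q
    }
    if (best == start) break
    hull <- c(hull, best)
    if (length(hull) > n) stop("gift wrapping failed to terminate")
  }
  h <- pts[hull, , drop = FALSE]
  area <- 0
  for (i in 2:(nrow(h) - 1L))
    area <- area + ((h[i, 1] - h[1, 1]) * (h[i + 1, 2] - h[1, 2]) -
                    (h[i, 2] - h[1, 2]) * (h[i + 1, 1] - h[1, 1])) / 2
  abs(area)
}

# Scene builder: a LarvaImage whose tumor channel is an arbitrary matrix
# (pixel size 1 um by default), for tests that construct masks by hand.
imageFromMatrix <- function(m, pixelSize = 1) {
  new("LarvaImage", channels = list(tumor = m), pixelSize = pixelSize,
      dialect = "custom")
}

# CellObjects built directly from a binary mask (threshold at 0.5 on a 0/1
# matrix), bypassing thresholding choices.
objectsFromMask <- function(mask, pixelSize = 1, connectivity = 8L) {
  img <- imageFromMatrix(mask * 1000, pixelSize)
  segmentTumorChannel(img, threshold = 500, connectivity = connectivity)
}

# Small parameter set used across tests: quick to render, debris well below
# cell size, clean separation of intensities.
testParams <- function(...) {
  defaults <- list(imageShape = c(160L, 200L), pixelSize = 2.5, nCells = 30L,
                   cellRadius = c(8, 0.5), cellIntensity = c(30000, 0),
                   dispersionSigma = 50, trunkFraction = 0.1, nDebris = 6L,
                   debrisRadius = 3, yolkAutofluor = 0, noiseSd = 0,
                   seed = 1L, dialect = "custom")
  args <- utils::modifyList(defaults, list(...))
  do.call(simulationParams, args)
}
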