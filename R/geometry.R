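# Polygon geometry on the raster grid.
#
# Coordinate convention used throughout the package: 0-based (row, col)
# continuous coordinates with the origin at the top-left image corner.
# Pixel (i, j) of an R matrix (1-based indices) occupies the unit square
# [i-1, i] x [j-1, j]; its centre is (i - 0.5, j - 0.5). Polygons are vertex
# lists in these pixel-corner coordinates.

#' Even-odd point-in-polygon test
#'
#' Vectorised crossing-number (even-odd) test. The boundary is resolved by
#' the standard half-open rule: an edge counts a crossing when one endpoint
#' is strictly below the query row and the other is not, so points exactly on
#' a horizontal edge, or on the "upper" side of a vertex, fall consistently
#' on one side. Pixel centres sit at half-integer coordinates, so polygons
#' with integer or otherwise non-pathological vertices never hit the
#' ambiguous cases.
#'
#' @param points n x 2 numeric matrix of (row, col) query points.
#' @param vertices m x 2 numeric matrix of polygon vertices (closed
#'   implicitly; do not repeat the first vertex).
#' @return logical vector of length n.
#' @export
pointInPolygon <- function(points, vertices) {
  points <- rbind(points)
  stopifnot(ncol(points) == 2L, ncol(vertices) == 2L, nrow(vertices) >= 3L)
  py <- points[, 1]; px <- points[, 2]
  vy <- vertices[, 1]; vx <- vertices[, 2]
  n <- length(vy)
  inside <- logical(length(py))
  j <- n
  for (i in seq_len(n)) {
    yi <- vy[i]; yj <- vy[j]; xi <- vx[i]; xj <- vx[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# TRUE when segments p1-p2 and p3-p4 properly intersect (shared endpoints of
# adjacent polygon edges are excluded by the caller).
segmentsCross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Check that a polygon is simple (non-self-intersecting)
#'
#' @param vertices m x 2 matrix of (row, col) vertices.
#' @return TRUE invisibly, or an error describing the offending edge pair.
#' @export
assertSimplePolygon <- function(vertices) {
  if (is.null(dim(vertices)) || nrow(vertices) < 3L)
    stop("polygon must have at least 3 vertices", call. = FALSE)
  n <- nrow(vertices)
  edges <- cbind(seq_len(n), c(seq_len(n)[-1], 1L))
  for (a in seq_len(n - 1L)) {
    for (b in seq((a + 1L), n)) {
      # skip adjacent edges (they share a vertex)
      if (abs(a - b) == 1L || (a == 1L && b == n)) next
      if (segmentsCross(vertices[edges[a, 1], ], vertices[edges[a, 2], ],
                        vertices[edges[b, 1], ], vertices[edges[b, 2], ]))
        stop("polygon is self-intersecting (edges ", a, " and ", b, ")",
             call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Rasterize a polygon region of interest
#'
#' Produces the boolean mask of pixels whose centres lie inside the polygon,
#' under the pixel-centre / even-odd convention of [pointInPolygon()]. An
#' axis-aligned rectangle with corners (0,0)-(10,20) in pixel-corner
#' coordinates therefore covers exactly 200 pixels.
#'
#' @param vertices m x 2 numeric matrix of (row, col) polygon vertices in
#'   0-based pixel-corner coordinates; the polygon must be simple and have at
#'   least 3 vertices.
#' @param imageShape integer(2), (rows, cols) of the target raster.
#' @return logical matrix of dim imageShape.
#' @examples
#' m <- rasterizeRoi(cbind(c(0, 0, 10, 10), c(0, 20, 20, 0)), c(16, 32))
#' sum(m)  # 200
#' @export
rasterizeRoi <- function(vertices, imageShape) {
  imageShape <- as.integer(imageShape)
  if (length(imageShape) != 2L || any(imageShape <= 0L))
    stop("imageShape must be two positive integers", call. = FALSE)
  vertices <- as.matrix(vertices)
  assertSimplePolygon(vertices)
  mask <- matrix(FALSE, imageShape[1], imageShape[2])
  # restrict the test to the polygon bounding box
  r0 <- max(1L, floor(min(vertices[, 1])) + 1L)
  r1 <- min(imageShape[1], ceiling(max(vertices[, 1])))
  c0 <- max(1L, floor(min(vertices[, 2])) + 1L)
  c1 <- min(imageShape[2], ceiling(max(vertices[, 2])))
  if (r0 > r1 || c0 > c1) return(mask)
  rows <- r0:r1; cols <- c0:c1
  centres <- cbind(rep(rows, times = length(cols)) - 0.5,
                   rep(cols, each = length(rows)) - 0.5)
  mask[rows, cols] <- pointInPolygon(centres, vertices)
  mask
}

#' Polygon area by the shoelace formula
#'
#' @param vertices m x 2 matrix of (row, col) vertices of a simple polygon.
#' @return non-negative area in squared coordinate units.
#' @export
polygonArea <- function(vertices) {
  y <- vertices[, 1]; x <- vertices[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Convex hull (as a closed vertex matrix, counter-clockwise in (row, col))
# of a point set, via grDevices::chull.
convexHullPolygon <- function(points) {
  points <- unique(rbind(points))
  if (nrow(points) < 3L) return(points)
  idx <- grDevices::chull(points[, 2], points[, 1])
  points[idx, , drop = FALSE]
}

#' Construct a RoiSet from named polygons
#'
#' Rasterizes each polygon at the given shape and validates the result
#' (simple polygons, disjoint yolk/trunk masks).
#'
#' @param polygons named list of m x 2 (row, col) vertex matrices; names must
#'   include "yolk" and "trunk".
#' @param imageShape integer(2) raster shape.
#' @return a [RoiSet-class].
#' @export
roiSet <- function(polygons, imageShape) {
  imageShape <- as.integer(imageShape)
  polygons <- lapply(polygons, as.matrix)
  masks <- lapply(polygons, rasterizeRoi, imageShape = imageShape)
  new("RoiSet", polygons = polygons, masks = masks, shape = imageShape)
}
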