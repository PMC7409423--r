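# Tumor-channel segmentation and size-based debris exclusion.
#
# Micrographs of dye-labelled xenografts contain bright spots that are not
# cells (apoptotic bodies, dye aggregates, nonspecific yolk signal). These
# spots are much smaller than cells, so after connected-component labeling a
# size threshold separates them: objects below the minimum cell area are
# flagged as debris and excluded from every downstream area and hull
# computation, while staying in the object table for audit.

# Otsu threshold of an intensity sample on the 16-bit scale, computed with
# EBImage's histogram optimiser by packing the sample into a 1 x n image.
otsuThreshold <- function(values) {
  v <- as.numeric(values)
  EBImage::otsu(EBImage::Image(matrix(v / 65535, 1L)),
                range = c(0, 1), levels = 65536L) * 65535
}

#' Segment the tumor channel into labeled objects
#'
#' Thresholds the tumor channel (fixed intensity, or Otsu restricted to the
#' union of the ROI masks) and labels the connected foreground under the
#' requested connectivity. A pixel is foreground when its value is greater
#' than or equal to the threshold. No debris flags are set at this stage;
#' see [filterDebris()].
#'
#' Automatic thresholding on a degenerate field (all-background or
#' all-foreground result, e.g. an uninjected control larva) falls back to
#' `fixedFallback` with a warning when one is supplied, and errors otherwise.
#'
#' @param image a [LarvaImage-class].
#' @param threshold numeric fixed threshold, or "otsu" (default) for
#'   automatic selection.
#' @param rois optional [RoiSet-class]; under Otsu, restricts the intensity
#'   sample to the union of the region masks so background outside the larva
#'   does not drive the threshold.
#' @param connectivity 8 (default) or 4. Anti-aliased cell rims fragment
#'   under 4-connectivity, hence the 8-connected default.
#' @param fixedFallback numeric fixed threshold used when Otsu degenerates.
#' @return a [CellObjects-class] with `is_debris` all FALSE.
#' @examples
#' sim <- simulateLarva(simulationParams(imageShape = c(160, 200),
#'                                       nCells = 25, nDebris = 4, seed = 5))
#' segmentTumorChannel(sim$image, rois = sim$rois)
#' @export
segmentTumorChannel <- function(image, threshold = "otsu", rois = NULL,
                                connectivity = 8L, fixedFallback = NULL) {
  stopifnot(is(image, "LarvaImage"))
  connectivity <- as.integer(connectivity)
  tumor <- getChannel(image, "tumor")

  if (identical(threshold, "otsu")) {
    sample <- if (!is.null(rois)) {
      un <- Reduce(`|`, rois@masks)
      tumor[un]
    } else as.numeric(tumor)
    thr <- otsuThreshold(sample)
    fg <- tumor >= thr
    if (!any(fg) || all(fg)) {
      if (is.null(fixedFallback))
        stop("automatic threshold degenerated (all background or all ",
             "foreground) and no fixedFallback was given", call. = FALSE)
      warning("automatic threshold degenerated; falling back to fixed ",
              "threshold ", fixedFallback, call. = FALSE)
      thr <- fixedFallback
      fg <- tumor >= thr
    }
  } else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    thr <- threshold
    fg <- tumor >= thr
  }

  labels <- .labelComponents(fg, connectivity)
  tab <- objectFeatures(labels, tumor, image@pixelSize)
  obj <- new("CellObjects", labels = labels, table = tab,
             pixelSize = image@pixelSize, connectivity = connectivity)
  attr(obj, "threshold") <- thr
  obj
}

# Per-object features from a label raster: area, centroid (0-based
# pixel-corner coordinates of the pixel-centre mean), bounding box (1-based
# matrix indices), mean intensity.
objectFeatures <- function(labels, intensity, pixelSize) {
  k <- max(labels)
  empty <- data.frame(label = integer(0), area_px = integer(0),
                      area_um2 = numeric(0), centroid_row = numeric(0),
                      centroid_col = numeric(0), bbox_rmin = integer(0),
                      bbox_rmax = integer(0), bbox_cmin = integer(0),
                      bbox_cmax = integer(0), mean_intensity = numeric(0),
                      is_debris = logical(0))
  if (k == 0L) return(empty)
  idx <- which(labels > 0L)
  area <- tabulate(labels[idx], k)
  # factor with explicit numeric levels: split() otherwise orders "10" < "2"
  lab <- factor(labels[idx], levels = seq_len(k))
  nr <- nrow(labels)
  i <- (idx - 1L) %% nr + 1L
  j <- (idx - 1L) %/% nr + 1L
  data.frame(
    label = seq_len(k),
    area_px = area,
    area_um2 = area * pixelSize^2,
    centroid_row = vapply(split(i - 0.5, lab), mean, numeric(1)),
    centroid_col = vapply(split(j - 0.5, lab), mean, numeric(1)),
    bbox_rmin = vapply(split(i, lab), min, integer(1)),
    bbox_rmax = vapply(split(i, lab), max, integer(1)),
    bbox_cmin = vapply(split(j, lab), min, integer(1)),
    bbox_cmax = vapply(split(j, lab), max, integer(1)),
    mean_intensity = vapply(split(intensity[idx], lab), mean, numeric(1)),
    is_debris = FALSE,
    row.names = NULL
  )
}

#' Flag sub-cellular objects as debris by size
#'
#' Objects whose area falls strictly below the threshold are flagged
#' `is_debris = TRUE`. Flagged objects are excluded from region areas and
#' the coverage hull but kept in the table for audit. The default threshold
#' (when `minCellArea = NULL`) is 25% of the area implied by
#' `expectedCellDiameter`, so behaviour does not depend on the acquisition
#' dialect.
#'
#' @param objects a [CellObjects-class].
#' @param minCellArea minimum area of a genuine cell, in um^2; objects below
#'   it are debris. `0` flags nothing.
#' @param expectedCellDiameter um; used only when `minCellArea` is NULL.
#' @return the [CellObjects-class] with updated flags.
#' @examples
#' sim <- simulateLarva(simulationParams(imageShape = c(160, 200),
#'                                       nCells = 25, nDebris = 6, seed = 5))
#' obj <- segmentTumorChannel(sim$image, rois = sim$rois)
#' filterDebris(obj, expectedCellDiameter = 16)
#' @export
filterDebris <- function(objects, minCellArea = NULL,
                         expectedCellDiameter = 16) {
  stopifnot(is(objects, "CellObjects"))
  if (is.null(minCellArea))
    minCellArea <- 0.25 * pi * (expectedCellDiameter / 2)^2
  if (minCellArea < 0) stop("minCellArea must be >= 0", call. = FALSE)
  objects@table$is_debris <- objects@table$area_um2 < minCellArea
  objects
}

# Logical mask of non-debris foreground pixels.
foregroundMask <- function(objects) {
  tab <- objects@table
  if (!nrow(tab)) return(objects@labels > 0L)
  keep <- tab$label[!tab$is_debris]
  matrix(objects@labels %in% keep & objects@labels > 0L,
         nrow(objects@labels), ncol(objects@labels))
}
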