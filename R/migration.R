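# Coverage polygon and migration index.
#
# Migration of xenografted cells within a single timepoint image is scored
# by the area of the polygon spanned by the peripheral cells (the "coverage
# area") divided by the dye-positive tumor area. Dividing out the tumor area
# removes the dependence on cell number, leaving a dimensionless dispersion
# score. The coverage polygon is realised as the convex hull of the corner
# points of every non-debris foreground pixel, so the hull always contains
# the tumor pixel set and the index is >= 1, with equality exactly when the
# tumor pixel union is convex.

#' Convex coverage hull of the tumor pixels
#'
#' Collects all four corners of every non-debris foreground pixel (optionally
#' restricted to a region mask) and returns their convex hull polygon and its
#' area. A single foreground pixel yields its own unit square.
#'
#' @param objects a [CellObjects-class] with debris flagged.
#' @param regionMask optional logical matrix restricting the pixels
#'   considered (e.g. the yolk mask).
#' @param pixelSize um per pixel; defaults to the value in `objects`.
#' @return list with `polygon` (closed vertex matrix in 0-based pixel-corner
#'   (row, col) coordinates), `area_px2` and `area_um2`. When no non-debris
#'   foreground pixel intersects the mask, all three are NA and the element
#'   `status = "empty_tumor"` is set (a warning is raised).
#' @examples
#' sim <- simulateLarva(simulationParams(imageShape = c(160, 200),
#'                                       nCells = 25, seed = 5))
#' obj <- filterDebris(segmentTumorChannel(sim$image, rois = sim$rois),
#'                     expectedCellDiameter = 16)
#' coverageHull(obj, roiMask(sim$rois, "yolk"))$area_um2
#' @export
coverageHull <- function(objects, regionMask = NULL, pixelSize = NULL) {
  stopifnot(is(objects, "CellObjects"))
  if (is.null(pixelSize)) pixelSize <- objects@pixelSize
  fg <- foregroundMask(objects)
  if (!is.null(regionMask)) {
    stopifnot(identical(dim(regionMask), dim(fg)))
    fg <- fg & regionMask
  }
  idx <- which(fg)
  if (!length(idx)) {
    warning("no non-debris tumor pixels in the analysis region ",
            "(empty-tumor condition)", call. = FALSE)
    return(list(polygon = NULL, area_px2 = NA_real_, area_um2 = NA_real_,
                status = "empty_tumor"))
  }
  corners <- pixelCorners(idx, nrow(fg))
  hull <- convexHullPolygon(corners)
  # a single pixel (or collinear pixel row/column) still has positive hull
  # area because the pixel squares themselves span it; with >= 1 pixel the
  # corner set always holds >= 4 non-collinear points
  area <- polygonArea(hull)
  list(polygon = hull, area_px2 = area, area_um2 = area * pixelSize^2,
       status = "ok")
}

#' Migration index: coverage area over tumor area
#'
#' @param coverageArea coverage-hull area (um^2 or px^2).
#' @param tumorArea non-debris dye-positive area in the same units; must be
#'   positive.
#' @return dimensionless ratio, >= 1 under the pixel-corner hull convention;
#'   NA (with a warning) when `tumorArea` is zero or missing.
#' @export
migrationIndex <- function(coverageArea, tumorArea) {
  if (is.na(tumorArea) || is.na(coverageArea) || tumorArea == 0) {
    warning("tumor area is zero or missing; migration index undefined",
            call. = FALSE)
    return(NA_real_)
  }
  coverageArea / tumorArea
}

#' Assemble per-larva xenograft metrics
#'
#' Combines the region areas (proliferation = yolk, invasion = trunk), the
#' coverage hull over the analysis region (default: yolk, matching the
#' high-resolution migration analysis; "all" widens to the whole field) and
#' the migration index into one record.
#'
#' @param objects a [CellObjects-class] with debris flagged.
#' @param rois a [RoiSet-class] with "yolk" and "trunk".
#' @param pixelSize um per pixel; defaults to the value in `objects`.
#' @param analysisRegion "yolk" (default) or "all": where the coverage hull
#'   and tumor area for the migration index are measured.
#' @param larvaId,groupLabel identifiers copied into the record.
#' @return one-row data.frame: larva_id, group_label, yolk_area_um2,
#'   trunk_area_um2, outside_area_um2, tumor_area_um2,
#'   coverage_hull_area_um2, migration_index, status ("ok" or
#'   "empty_tumor"; empty scenes carry NA metrics, not zeros).
#' @examples
#' sim <- simulateLarva(simulationParams(imageShape = c(160, 200),
#'                                       nCells = 25, seed = 5))
#' obj <- filterDebris(segmentTumorChannel(sim$image, rois = sim$rois),
#'                     expectedCellDiameter = 16)
#' computeMetrics(obj, sim$rois, larvaId = "demo")
#' @export
computeMetrics <- function(objects, rois, pixelSize = NULL,
                           analysisRegion = c("yolk", "all"),
                           larvaId = NA_character_,
                           groupLabel = NA_character_) {
  analysisRegion <- match.arg(analysisRegion)
  if (is.null(pixelSize)) pixelSize <- objects@pixelSize
  areas <- measureRegionAreas(objects, rois, pixelSize)

  mask <- if (analysisRegion == "yolk") rois@masks[["yolk"]] else NULL
  fg <- foregroundMask(objects)
  tumorPx <- if (is.null(mask)) sum(fg) else sum(fg & mask)
  tumorArea <- tumorPx * pixelSize^2

  if (tumorPx == 0L) {
    return(data.frame(
      larva_id = larvaId, group_label = groupLabel,
      yolk_area_um2 = areas@yolkArea, trunk_area_um2 = areas@trunkArea,
      outside_area_um2 = areas@outsideArea,
      tumor_area_um2 = NA_real_, coverage_hull_area_um2 = NA_real_,
      migration_index = NA_real_, status = "empty_tumor",
      stringsAsFactors = FALSE))
  }
  hull <- coverageHull(objects, regionMask = mask, pixelSize = pixelSize)
  data.frame(
    larva_id = larvaId, group_label = groupLabel,
    yolk_area_um2 = areas@yolkArea, trunk_area_um2 = areas@trunkArea,
    outside_area_um2 = areas@outsideArea,
    tumor_area_um2 = tumorArea,
    coverage_hull_area_um2 = hull$area_um2,
    migration_index = migrationIndex(hull$area_um2, tumorArea),
    status = "ok", stringsAsFactors = FALSE)
}
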