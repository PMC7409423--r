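# Per-region dye-positive area measurement.
#
# The proliferation readout is the dye-positive area inside the yolk region;
# the invasion readout is the dye-positive area inside the trunk region.
# Accounting is pixel-based (foreground pixels intersected with each region
# mask), so yolk + trunk + outside always partitions the non-debris
# foreground exactly; the per-object assignment table is a convenience
# output only.

#' Measure dye-positive area per region
#'
#' Counts non-debris foreground pixels inside the yolk mask, the trunk mask
#' and outside both, and converts counts to um^2 via the pixel size. Each
#' object is additionally assigned to the region holding the majority of its
#' pixels; ties go to "outside".
#'
#' @param objects a [CellObjects-class] with debris already flagged (or not;
#'   unflagged tables are used as-is).
#' @param rois a [RoiSet-class] containing "yolk" and "trunk".
#' @param pixelSize um per pixel; defaults to the pixel size recorded in
#'   `objects`.
#' @return a [RegionAreas-class].
#' @examples
#' sim <- simulateLarva(simulationParams(imageShape = c(160, 200),
#'                                       nCells = 25, seed = 5))
#' obj <- filterDebris(segmentTumorChannel(sim$image, rois = sim$rois),
#'                     expectedCellDiameter = 16)
#' measureRegionAreas(obj, sim$rois)
#' @export
measureRegionAreas <- function(objects, rois, pixelSize = NULL) {
  stopifnot(is(objects, "CellObjects"), is(rois, "RoiSet"))
  if (is.null(pixelSize)) pixelSize <- objects@pixelSize
  if (!all(c("yolk", "trunk") %in% roiNames(rois)))
    stop("RoiSet must provide 'yolk' and 'trunk' regions", call. = FALSE)
  if (!identical(dim(objects@labels), as.integer(rois@shape)))
    stop("label raster and ROI masks have different shapes", call. = FALSE)

  fg <- foregroundMask(objects)
  yolk <- rois@masks[["yolk"]]
  trunk <- rois@masks[["trunk"]]
  nYolk <- sum(fg & yolk)
  nTrunk <- sum(fg & trunk)
  nTotal <- sum(fg)
  nOutside <- nTotal - nYolk - nTrunk

  tab <- objects@table
  keep <- tab[!tab$is_debris, , drop = FALSE]
  assignments <- if (nrow(keep)) {
    regionOf <- function(lab) {
      inObj <- objects@labels == lab
      counts <- c(yolk = sum(inObj & yolk), trunk = sum(inObj & trunk))
      counts["outside"] <- sum(inObj) - sum(counts)
      best <- which(counts == max(counts))
      # unique majority region, ties resolved to "outside"
      if (length(best) > 1L) "outside" else names(counts)[best]
    }
    data.frame(label = keep$label,
               region = vapply(keep$label, regionOf, character(1)),
               area_px = keep$area_px, row.names = NULL)
  } else data.frame(label = integer(0), region = character(0),
                    area_px = integer(0))

  new("RegionAreas",
      yolkArea = nYolk * pixelSize^2,
      trunkArea = nTrunk * pixelSize^2,
      outsideArea = nOutside * pixelSize^2,
      pixelCounts = c(yolk = as.integer(nYolk), trunk = as.integer(nTrunk),
                      outside = as.integer(nOutside),
                      total = as.integer(nTotal)),
      assignments = assignments)
}
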