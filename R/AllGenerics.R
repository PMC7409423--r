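#' @describeIn LarvaImage-class names of the channels present.
#' @param x,object an object of the documented class.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @describeIn LarvaImage-class extract one channel raster by name.
#' @param name channel or region name.
#' @export
setGeneric("getChannel", function(x, name = "tumor") standardGeneric("getChannel"))

#' Physical pixel size in micrometres
#' @param x a LarvaImage, CellObjects or SimulationParams object.
#' @return numeric scalar, micrometres per pixel.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @describeIn RoiSet-class region names.
#' @export
setGeneric("roiNames", function(x) standardGeneric("roiNames"))

#' @describeIn RoiSet-class logical mask of one region.
#' @export
setGeneric("roiMask", function(x, name) standardGeneric("roiMask"))

#' @describeIn RoiSet-class vertex matrix (row, col) of one region polygon.
#' @export
setGeneric("roiPolygon", function(x, name) standardGeneric("roiPolygon"))

#' @describeIn CellObjects-class the per-object feature table.
#' @export
setGeneric("objectTable", function(x) standardGeneric("objectTable"))

#' @describeIn CellObjects-class the integer label raster.
#' @export
setGeneric("labelRaster", function(x) standardGeneric("labelRaster"))

#' @describeIn CellObjects-class number of objects (including debris).
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))

#' @describeIn GroundTruth-class data.frame of true cell positions/radii.
#' @export
setGeneric("trueCells", function(x) standardGeneric("trueCells"))

#' @describeIn GroundTruth-class data.frame of true debris positions/radii.
#' @export
setGeneric("trueDebris", function(x) standardGeneric("trueDebris"))

setMethod("channelNames", "LarvaImage", function(x) names(x@channels))

setMethod("getChannel", "LarvaImage", function(x, name = "tumor") {
  if (!name %in% names(x@channels))
    stop("no channel named '", name, "'", call. = FALSE)
  x@channels[[name]]
})

setMethod("pixelSize", "LarvaImage", function(x) x@pixelSize)
setMethod("pixelSize", "CellObjects", function(x) x@pixelSize)
setMethod("pixelSize", "SimulationParams", function(x) x@pixelSize)

setMethod("roiNames", "RoiSet", function(x) names(x@polygons))

setMethod("roiMask", "RoiSet", function(x, name) {
  if (!name %in% names(x@masks))
    stop("no region named '", name, "'", call. = FALSE)
  x@masks[[name]]
})

setMethod("roiPolygon", "RoiSet", function(x, name) {
  if (!name %in% names(x@polygons))
    stop("no region named '", name, "'", call. = FALSE)
  x@polygons[[name]]
})

setMethod("objectTable", "CellObjects", function(x) x@table)
setMethod("labelRaster", "CellObjects", function(x) x@labels)
setMethod("nObjects", "CellObjects", function(x) nrow(x@table))

setMethod("trueCells", "GroundTruth", function(x) x@cells)
setMethod("trueDebris", "GroundTruth", function(x) x@debris)

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams (", object@dialect, " dialect)\n", sep = "")
  cat("  image: ", object@imageShape[1], " x ", object@imageShape[2],
      " px at ", object@pixelSize, " um/px\n", sep = "")
  cat("  cells: n=", object@nCells, ", radius ", object@cellRadius[1], " +/- ",
      object@cellRadius[2], " um, trunk fraction ", object@trunkFraction,
      "\n", sep = "")
  cat("  dispersion sigma: ", object@dispersionSigma, " um\n", sep = "")
  cat("  debris: n=", object@nDebris, ", radius ~", object@debrisRadius,
      " um\n", sep = "")
  cat("  yolk autofluorescence ", object@yolkAutofluor, ", noise sd ",
      object@noiseSd, ", seed ", object@seed, "\n", sep = "")
})

setMethod("show", "LarvaImage", function(object) {
  d <- dim(object@channels[[1]])
  cat("LarvaImage: ", d[1], " x ", d[2], " px (", object@dialect,
      "), ", object@pixelSize, " um/px\n", sep = "")
  cat("  channels:", paste(names(object@channels), collapse = ", "), "\n")
})

setMethod("show", "RoiSet", function(object) {
  cat("RoiSet on ", object@shape[1], " x ", object@shape[2], " px\n", sep = "")
  for (nm in names(object@polygons))
    cat("  ", nm, ": ", nrow(object@polygons[[nm]]), " vertices, ",
        sum(object@masks[[nm]]), " px\n", sep = "")
})

setMethod("show", "CellObjects", function(object) {
  tab <- object@table
  cat("CellObjects: ", nrow(tab), " objects (", sum(tab$is_debris),
      " flagged as debris), ", object@connectivity, "-connectivity\n",
      sep = "")
  if (nrow(tab))
    cat("  areas [px]: ", paste(range(tab$area_px), collapse = " - "),
        ", foreground ", sum(tab$area_px), " px\n", sep = "")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth: ", nrow(object@cells), " cells, ", nrow(object@debris),
      " debris\n", sep = "")
  cat("  true areas [px]: yolk ", object@trueYolkAreaPx, ", trunk ",
      object@trueTrunkAreaPx, ", yolk hull ",
      format(object@trueHullAreaPx), "\n", sep = "")
})

setMethod("show", "CohortDesign", function(object) {
  cat("CohortDesign: ", nrow(object@groups), " groups, ",
      sum(object@groups$n_larvae), " larvae, seed ", object@seed, "\n",
      sep = "")
  print(object@groups, row.names = FALSE)
})

setMethod("show", "RegionAreas", function(object) {
  cat("RegionAreas [um^2]: yolk ", format(object@yolkArea), ", trunk ",
      format(object@trunkArea), ", outside ", format(object@outsideArea),
      "\n", sep = "")
})
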