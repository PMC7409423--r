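#' @useDynLib xenoquant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' Simulation parameters for a synthetic larva micrograph
#'
#' Bundles everything that defines one simulated two-channel larval field:
#' raster geometry, cell population, debris population, yolk
#' autofluorescence, read noise and the random seed. Lengths are micrometres;
#' intensities are on the 16-bit scale (0--65535).
#'
#' Defaults emulate a stereomicroscope acquisition of a whole larva at 4 days
#' post-injection: a 1200 x 1600 field at 2.5 um/pixel holding ~400 injected
#' cells clustered around the yolk, a small fraction disseminated to the
#' trunk, and a few dozen sub-cellular bright spots (cell debris /
#' nonspecific dye signal) confined to the yolk.
#'
#' @slot imageShape integer(2), raster size as (rows, cols).
#' @slot pixelSize numeric, micrometres per pixel (> 0).
#' @slot nCells integer, number of labelled tumor cells placed.
#' @slot cellRadius numeric(2), mean and sd of the cell radius in um.
#' @slot cellIntensity numeric(2), mean and sd of per-object peak intensity.
#' @slot dispersionSigma numeric, sd (um) of the isotropic Gaussian placement
#'   of yolk cells around the yolk centroid; larger values emulate stronger
#'   migration.
#' @slot trunkFraction numeric in [0,1], expected fraction of cells placed in
#'   the trunk (invasion).
#' @slot nDebris integer, number of debris spots.
#' @slot debrisRadius numeric, mean debris radius in um; must be smaller than
#'   the mean cell radius (debris is by construction much smaller than cells).
#' @slot yolkAutofluor numeric, mean diffuse background added inside the yolk.
#' @slot noiseSd numeric, sd of additive Gaussian read noise.
#' @slot seed integer, RNG seed; identical parameters and seed reproduce the
#'   scene bit-for-bit.
#' @slot dialect character, acquisition tag: "stereo", "confocal" or "custom".
#' @seealso [SimulationParams()], [simulateLarva()]
#' @export
setClass("SimulationParams",
  slots = c(
    imageShape      = "integer",
    pixelSize       = "numeric",
    nCells          = "integer",
    cellRadius      = "numeric",
    cellIntensity   = "numeric",
    dispersionSigma = "numeric",
    trunkFraction   = "numeric",
    nDebris         = "integer",
    debrisRadius    = "numeric",
    yolkAutofluor   = "numeric",
    noiseSd         = "numeric",
    seed            = "integer",
    dialect         = "character"
  )
)

setValidity("SimulationParams", function(object) {
  msg <- character()
  if (length(object@imageShape) != 2L || any(object@imageShape <= 0L))
    msg <- c(msg, "imageShape must be two positive integers (rows, cols)")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@nCells < 0L) msg <- c(msg, "nCells must be >= 0")
  if (object@nDebris < 0L) msg <- c(msg, "nDebris must be >= 0")
  if (length(object@cellRadius) != 2L || object@cellRadius[1] <= 0 ||
      object@cellRadius[2] < 0)
    msg <- c(msg, "cellRadius must be (mean > 0, sd >= 0)")
  if (length(object@cellIntensity) != 2L || object@cellIntensity[1] <= 0 ||
      object@cellIntensity[2] < 0)
    msg <- c(msg, "cellIntensity must be (mean > 0, sd >= 0)")
  if (object@trunkFraction < 0 || object@trunkFraction > 1)
    msg <- c(msg, "trunkFraction must lie in [0, 1]")
  if (object@debrisRadius <= 0 || object@debrisRadius >= object@cellRadius[1])
    msg <- c(msg, "debrisRadius must be positive and below the mean cellRadius")
  if (object@dispersionSigma <= 0) msg <- c(msg, "dispersionSigma must be > 0")
  if (object@yolkAutofluor < 0) msg <- c(msg, "yolkAutofluor must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (!object@dialect %in% c("stereo", "confocal", "custom"))
    msg <- c(msg, "dialect must be 'stereo', 'confocal' or 'custom'")
  if (length(msg)) msg else TRUE
})

#' One acquired or simulated larval field
#'
#' Named 2-D channel rasters (the tumor channel is mandatory; a vasculature
#' channel is optional and purely decorative in simulations), the physical
#' pixel size and the acquisition dialect. Rasters are numeric matrices on
#' the 16-bit intensity scale, row/col indexed like R matrices.
#'
#' @slot channels named list of numeric matrices sharing one shape; must
#'   contain "tumor".
#' @slot pixelSize numeric, micrometres per pixel.
#' @slot dialect character, "stereo", "confocal" or "custom".
#' @seealso [simulateLarva()], [readLarvaImage()]
#' @export
setClass("LarvaImage",
  slots = c(channels = "list", pixelSize = "numeric", dialect = "character")
)

setValidity("LarvaImage", function(object) {
  msg <- character()
  if (!length(object@channels) || is.null(names(object@channels)) ||
      !"tumor" %in% names(object@channels))
    msg <- c(msg, "channels must be a named list containing 'tumor'")
  if (!all(vapply(object@channels, is.matrix, logical(1))))
    msg <- c(msg, "all channels must be matrices")
  dims <- vapply(object@channels, function(ch) paste(dim(ch), collapse = "x"),
                 character(1))
  if (length(unique(dims)) > 1L)
    msg <- c(msg, "all channels must share the same shape")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Named regions of interest with rasterized masks
#'
#' Closed simple polygons named by anatomical region, together with their
#' boolean masks at the image shape. Polygons live in continuous 0-based
#' pixel-corner coordinates (see [rasterizeRoi()] for the containment
#' convention). Quantification requires "yolk" and "trunk" regions, whose
#' masks must be disjoint.
#'
#' @slot polygons named list of n x 2 numeric matrices (row, col vertices).
#' @slot masks named list of logical matrices, same names as polygons.
#' @slot shape integer(2), raster shape the masks were made for.
#' @seealso [roiSet()], [readRoiSet()], [defaultRoiSet()]
#' @export
setClass("RoiSet",
  slots = c(polygons = "list", masks = "list", shape = "integer")
)

setValidity("RoiSet", function(object) {
  msg <- character()
  nms <- names(object@polygons)
  if (is.null(nms) || any(!nzchar(nms)) ||
      !identical(nms, names(object@masks)))
    msg <- c(msg, "polygons and masks must share non-empty names")
  if (!all(c("yolk", "trunk") %in% nms))
    msg <- c(msg, "RoiSet must contain 'yolk' and 'trunk' regions")
  shapeOk <- all(vapply(object@masks,
                        function(m) identical(dim(m), as.integer(object@shape)),
                        logical(1)))
  if (!shapeOk) msg <- c(msg, "all masks must have dim == shape")
  if (all(c("yolk", "trunk") %in% nms) && shapeOk &&
      any(object@masks[["yolk"]] & object@masks[["trunk"]]))
    msg <- c(msg, "'yolk' and 'trunk' masks must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Labeled connected tumor-channel objects
#'
#' The result of segmenting the tumor channel: an integer label raster
#' (0 = background, objects labeled 1..K) and a per-object feature table
#' with area, centroid, bounding box, mean intensity and the debris flag
#' assigned later by [filterDebris()]. Debris-flagged objects are retained
#' for audit but excluded from all area and hull computations downstream.
#'
#' @slot labels integer matrix, the label raster.
#' @slot table data.frame with one row per object: label, area_px, area_um2,
#'   centroid_row, centroid_col, bbox_rmin, bbox_rmax, bbox_cmin, bbox_cmax,
#'   mean_intensity, is_debris.
#' @slot pixelSize numeric, micrometres per pixel (for unit conversion).
#' @slot connectivity integer, 4 or 8, the connectivity used.
#' @seealso [segmentTumorChannel()], [filterDebris()]
#' @export
setClass("CellObjects",
  slots = c(labels = "matrix", table = "data.frame", pixelSize = "numeric",
            connectivity = "integer")
)

setValidity("CellObjects", function(object) {
  msg <- character()
  k <- nrow(object@table)
  labs <- object@labels
  if (k > 0L && !identical(sort(unique(object@table$label)), seq_len(k)))
    msg <- c(msg, "object labels must be contiguous 1..K")
  nz <- sum(labs > 0L)
  if (k == 0L && nz > 0L)
    msg <- c(msg, "label raster has foreground but table is empty")
  if (k > 0L) {
    if (max(labs) != k)
      msg <- c(msg, "label raster and table disagree on object count")
    if (sum(object@table$area_px) != nz)
      msg <- c(msg, "sum of object areas must equal foreground pixel count")
  }
  if (!object@connectivity %in% c(4L, 8L))
    msg <- c(msg, "connectivity must be 4 or 8")
  if (length(msg)) msg else TRUE
})

#' Simulator ground truth for one synthetic larva
#'
#' Sidecar record of everything the simulator knows: true cell and debris
#' positions and radii (in pixels, continuous 0-based pixel-corner
#' coordinates), the parameters used, and reference areas recomputed from
#' the cell list by rasterization -- the yolk-region and trunk-region true
#' tumor pixel counts and the convex-hull area over the yolk-region tumor
#' pixels.
#'
#' @slot cells data.frame: row, col, radius_px, region ("yolk"/"trunk").
#' @slot debris data.frame: row, col, radius_px.
#' @slot params the [SimulationParams-class] used.
#' @slot trueYolkAreaPx numeric, pixels of the true cell mask inside yolk.
#' @slot trueTrunkAreaPx numeric, pixels of the true cell mask inside trunk.
#' @slot trueHullAreaPx numeric, convex-hull area (pixel^2) over yolk-region
#'   true tumor pixels (NA when the yolk holds no cell pixel).
#' @seealso [simulateLarva()]
#' @export
setClass("GroundTruth",
  slots = c(cells = "data.frame", debris = "data.frame",
            params = "SimulationParams",
            trueYolkAreaPx = "numeric", trueTrunkAreaPx = "numeric",
            trueHullAreaPx = "numeric")
)

#' Design of a simulated multi-group cohort
#'
#' Group-level multiplicative effects applied to the base simulation
#' parameters: the proliferation multiplier scales the number of cells, the
#' invasion multiplier scales the trunk fraction, and the dispersion
#' multiplier scales the placement sigma. Per-larva seeds are derived
#' deterministically from the design seed, so a cohort is reproducible
#' independent of generation order.
#'
#' @slot groups data.frame: name, n_larvae, proliferation, invasion,
#'   dispersion (all multipliers > 0, n_larvae >= 1).
#' @slot baseParams the [SimulationParams-class] shared baseline.
#' @slot seed integer root seed.
#' @seealso [cohortDesign()], [simulateCohort()]
#' @export
setClass("CohortDesign",
  slots = c(groups = "data.frame", baseParams = "SimulationParams",
            seed = "integer")
)

setValidity("CohortDesign", function(object) {
  msg <- character()
  g <- object@groups
  need <- c("name", "n_larvae", "proliferation", "invasion", "dispersion")
  if (!all(need %in% names(g)))
    msg <- c(msg, paste("groups must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(g) < 1L) msg <- c(msg, "at least one group is required")
    if (any(g$n_larvae < 1L)) msg <- c(msg, "n_larvae must be >= 1")
    if (any(g$proliferation <= 0 | g$invasion <= 0 | g$dispersion <= 0))
      msg <- c(msg, "all multipliers must be > 0")
    if (anyDuplicated(g$name)) msg <- c(msg, "group names must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Per-region dye-positive areas
#'
#' Pixel-based accounting of non-debris foreground over the yolk and trunk
#' masks. Pixel counts always satisfy yolk + trunk + outside == total
#' non-debris foreground, exactly. The per-object assignment table (majority
#' region, ties assigned "outside") is a convenience output only; areas are
#' computed from pixels, not objects.
#'
#' @slot yolkArea numeric, um^2 inside the yolk mask.
#' @slot trunkArea numeric, um^2 inside the trunk mask.
#' @slot outsideArea numeric, um^2 outside both masks.
#' @slot pixelCounts named integer: yolk, trunk, outside, total.
#' @slot assignments data.frame: label, region, n_pixels_in_region.
#' @seealso [measureRegionAreas()]
#' @export
setClass("RegionAreas",
  slots = c(yolkArea = "numeric", trunkArea = "numeric",
            outsideArea = "numeric", pixelCounts = "integer",
            assignments = "data.frame")
)
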