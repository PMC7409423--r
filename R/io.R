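# File I/O: 16-bit TIFF channels, RoiSet / GroundTruth JSON, assay CSVs.
#
# All outputs are plain interoperable formats (TIFF, JSON, CSV); intensity
# rasters are written as 16-bit TIFF with values rounded to the integer
# grid.

#' Write a LarvaImage as per-channel 16-bit TIFF
#'
#' @param image a [LarvaImage-class].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix; channels are written as
#'   `<prefix>_<channel>.tif`.
#' @return invisibly, the named vector of paths written.
#' @export
writeLarvaImage <- function(image, dir, prefix = "larva") {
  stopifnot(is(image, "LarvaImage"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(image@channels), function(nm) {
    path <- file.path(dir, paste0(prefix, "_", nm, ".tif"))
    raster <- round(pmin(pmax(image@channels[[nm]], 0), 65535)) / 65535
    tiff::writeTIFF(raster, path, bits.per.sample = 16L, compression = "none")
    path
  }, character(1))
  invisible(paths)
}

#' Read a LarvaImage from per-channel TIFF files
#'
#' @param paths named character vector of TIFF paths; names become channel
#'   names and must include "tumor".
#' @param pixelSize um per pixel.
#' @param dialect acquisition tag.
#' @return a [LarvaImage-class] on the 16-bit intensity scale.
#' @export
readLarvaImage <- function(paths, pixelSize, dialect = "custom") {
  stopifnot(!is.null(names(paths)), "tumor" %in% names(paths))
  channels <- lapply(paths, function(p) {
    raster <- tiff::readTIFF(p, as.is = FALSE)
    if (length(dim(raster)) == 3L) raster <- raster[, , 1]  # first plane
    raster * 65535
  })
  new("LarvaImage", channels = channels, pixelSize = pixelSize,
      dialect = dialect)
}

#' Write a RoiSet (or any polygon list) as JSON
#'
#' Schema: `{"rois": [{"name": "yolk", "vertices": [[r, c], ...]}, ...]}`
#' with vertices in 0-based (row, col) pixel-corner coordinates.
#'
#' @param rois a [RoiSet-class] or a named list of vertex matrices.
#' @param path output path.
#' @export
writeRoiSet <- function(rois, path) {
  polys <- if (is(rois, "RoiSet")) rois@polygons else rois
  obj <- list(rois = lapply(names(polys), function(nm)
    list(name = nm, vertices = unname(as.matrix(polys[[nm]])))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a RoiSet from JSON
#'
#' @param path JSON file in the schema of [writeRoiSet()].
#' @param imageShape integer(2) raster shape to rasterize at.
#' @return a [RoiSet-class].
#' @export
readRoiSet <- function(path, imageShape) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  polys <- lapply(seq_len(nrow(obj$rois)), function(i)
    as.matrix(obj$rois$vertices[[i]]))
  names(polys) <- obj$rois$name
  roiSet(polys, imageShape)
}

#' Write simulator ground truth as JSON
#'
#' @param truth a [GroundTruth-class].
#' @param path output path.
#' @export
writeGroundTruth <- function(truth, path) {
  p <- truth@params
  obj <- list(
    cells = truth@cells, debris = truth@debris,
    true_yolk_area_px = truth@trueYolkAreaPx,
    true_trunk_area_px = truth@trueTrunkAreaPx,
    true_hull_area_px = truth@trueHullAreaPx,
    params = list(
      image_shape = p@imageShape, pixel_size_um = p@pixelSize,
      n_cells = p@nCells, cell_radius_um = p@cellRadius,
      cell_intensity = p@cellIntensity,
      dispersion_sigma_um = p@dispersionSigma,
      trunk_fraction = p@trunkFraction, n_debris = p@nDebris,
      debris_radius_um = p@debrisRadius,
      yolk_autofluor_level = p@yolkAutofluor, noise_sd = p@noiseSd,
      seed = p@seed, dialect = p@dialect))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns")
  invisible(path)
}

#' Read a qRT-PCR Ct table from CSV
#'
#' Required columns: sample_id, group, ct_target, ct_reference; typical
#' extras (target_gene, reference_gene, replicate) are kept.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
readCtTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "ct_target", "ct_reference")
  if (!all(need %in% names(tab)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab
}

#' Read a CCK-8 OD450 plate table from CSV
#'
#' Required columns: sample_id, group, time_h, od450, is_blank.
#'
#' @param path CSV path.
#' @return validated data.frame with logical is_blank.
#' @export
readViabilityTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "time_h", "od450", "is_blank")
  if (!all(need %in% names(tab)))
    stop("viability table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab$is_blank <- as.logical(tab$is_blank)
  tab
}

#' Write a metrics table as CSV
#'
#' Deterministic writer (fixed column order, no row names) so identical
#' runs produce byte-identical files.
#'
#' @param metrics data.frame of per-larva metrics.
#' @param path output path.
#' @export
writeMetricsCsv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
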