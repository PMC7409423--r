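# Packaged larva region template.
#
# The yolk/trunk geometry of a real larva is drawn by hand on each image; the
# package ships one canonical polygon pair (ellipse-like yolk plus an
# elongated, tapering trunk) in unit coordinates, scaled to any raster shape.
# A user-supplied RoiSet always overrides the template.

# memoise rasterized template masks per shape: rasterization of a 1200x1600
# mask is cheap but not free, and cohort simulation reuses one shape
.templateCache <- new.env(parent = emptyenv())

templatePolygons <- function(imageShape) {
  path <- system.file("extdata", "larva_template_rois.json",
                      package = "xenoquant", mustWork = TRUE)
  tpl <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  polys <- lapply(seq_len(nrow(tpl$rois)), function(i) {
    uv <- tpl$rois$unit_vertices[[i]]
    cbind(uv[, 1] * imageShape[1], uv[, 2] * imageShape[2])
  })
  names(polys) <- tpl$rois$name
  polys
}

#' Canonical larva yolk/trunk regions for a raster shape
#'
#' Scales the packaged larva template (an ellipse-like yolk and an elongated
#' trunk, disjoint by construction) to the requested shape and rasterizes it.
#' Masks are cached per shape within a session.
#'
#' @param imageShape integer(2), (rows, cols).
#' @return a [RoiSet-class] with regions "yolk" and "trunk".
#' @examples
#' rois <- defaultRoiSet(c(120, 160))
#' roiNames(rois)
#' @export
defaultRoiSet <- function(imageShape) {
  imageShape <- as.integer(imageShape)
  key <- paste(imageShape, collapse = "x")
  if (!is.null(.templateCache[[key]])) return(.templateCache[[key]])
  rs <- roiSet(templatePolygons(imageShape), imageShape)
  .templateCache[[key]] <- rs
  rs
}
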