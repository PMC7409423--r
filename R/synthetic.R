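# Synthetic larva micrograph simulator.
#
# Emulates the two acquisition dialects used for larval xenografts: a
# stereomicroscope overview of the whole larva (1600 x 1200) and a confocal
# field (1024 x 1024). The tumor channel holds anti-aliased disk-shaped
# cells clustered around the yolk centroid, a trunk-disseminated fraction,
# sub-cellular bright debris confined to the yolk, diffuse yolk
# autofluorescence and additive Gaussian read noise. Every scene carries a
# full ground-truth sidecar so downstream stages can be tested exactly.

#' Construct simulation parameters
#'
#' All lengths in micrometres, intensities on the 16-bit scale. The defaults
#' describe the stereomicroscope dialect: a whole larva at 2.5 um/px with
#' ~400 injected cells around the yolk, a few percent disseminated into the
#' trunk and a few dozen sub-cellular debris spots.
#'
#' @param imageShape integer(2) (rows, cols); the two acquisition dialects
#'   are c(1200, 1600) (stereo) and c(1024, 1024) (confocal).
#' @param pixelSize um per pixel.
#' @param nCells number of tumor cells.
#' @param cellRadius c(mean, sd) cell radius in um.
#' @param cellIntensity c(mean, sd) per-object peak intensity.
#' @param dispersionSigma sd (um) of Gaussian placement about the yolk
#'   centroid.
#' @param trunkFraction expected fraction of cells placed in the trunk.
#' @param nDebris number of debris spots.
#' @param debrisRadius mean debris radius in um (must be < mean cell radius).
#' @param yolkAutofluor mean diffuse background inside the yolk.
#' @param noiseSd additive Gaussian noise sd.
#' @param seed integer RNG seed.
#' @param dialect "stereo", "confocal" or "custom".
#' @return a validated [SimulationParams-class].
#' @examples
#' p <- simulationParams(imageShape = c(160, 200), nCells = 40, seed = 7)
#' p
#' @export
simulationParams <- function(imageShape = c(1200L, 1600L),
                             pixelSize = 2.5,
                             nCells = 400L,
                             cellRadius = c(8, 1),
                             cellIntensity = c(30000, 3000),
                             dispersionSigma = 150,
                             trunkFraction = 0.05,
                             nDebris = 30L,
                             debrisRadius = 3,
                             yolkAutofluor = 2000,
                             noiseSd = 500,
                             seed = 1L,
                             dialect = c("stereo", "confocal", "custom")) {
  dialect <- match.arg(dialect)
  new("SimulationParams",
      imageShape = as.integer(imageShape), pixelSize = as.numeric(pixelSize),
      nCells = as.integer(nCells), cellRadius = as.numeric(cellRadius),
      cellIntensity = as.numeric(cellIntensity),
      dispersionSigma = as.numeric(dispersionSigma),
      trunkFraction = as.numeric(trunkFraction),
      nDebris = as.integer(nDebris), debrisRadius = as.numeric(debrisRadius),
      yolkAutofluor = as.numeric(yolkAutofluor), noiseSd = as.numeric(noiseSd),
      seed = as.integer(seed), dialect = dialect)
}

#' Construct a cohort design
#'
#' @param groups data.frame with columns name, n_larvae, proliferation,
#'   invasion, dispersion (multipliers > 0). Convenience: a list of vectors
#'   `list(name, n, prolif, inv, disp)` is also accepted.
#' @param baseParams shared [SimulationParams-class] baseline.
#' @param seed integer root seed; per-larva seeds are derived from it.
#' @return a validated [CohortDesign-class].
#' @examples
#' d <- cohortDesign(
#'   data.frame(name = c("NC", "si"), n_larvae = c(5, 5),
#'              proliferation = c(1, 0.6), invasion = c(1, 0.6),
#'              dispersion = c(1, 0.5)),
#'   simulationParams(imageShape = c(160, 200), nCells = 40), seed = 3)
#' @export
cohortDesign <- function(groups, baseParams = simulationParams(), seed = 1L) {
  if (is.list(groups) && !is.data.frame(groups))
    groups <- do.call(rbind, lapply(groups, function(g)
      data.frame(name = g[[1]], n_larvae = as.integer(g[[2]]),
                 proliferation = as.numeric(g[[3]]),
                 invasion = as.numeric(g[[4]]),
                 dispersion = as.numeric(g[[5]]))))
  groups$n_larvae <- as.integer(groups$n_larvae)
  new("CohortDesign", groups = groups, baseParams = baseParams,
      seed = as.integer(seed))
}

# Deterministic per-larva seed from the root seed: a fixed affine step
# modulo the Mersenne prime 2^31 - 1 keeps child seeds valid R integers and
# independent of generation order.
childSeed <- function(rootSeed, index) {
  as.integer((as.double(rootSeed) + 92821 * as.double(index)) %% 2147483647)
}

# Additively render anti-aliased disks onto a canvas. Centres are continuous
# 0-based (row, col) pixel-corner coordinates; pixel (i, j) centre is
# (i - 0.5, j - 0.5). Per-pixel coverage ramps linearly across the rim:
# clamp(r + 0.5 - d, 0, 1), so coverage >= 0.5 exactly when d <= r -- the
# same test that defines the ground-truth mask.
renderDisks <- function(canvas, centres, radii, intensities) {
  nr <- nrow(canvas); nc <- ncol(canvas)
  for (k in seq_len(nrow(centres))) {
    r <- radii[k]
    i0 <- max(1L, floor(centres[k, 1] - r)); i1 <- min(nr, ceiling(centres[k, 1] + r + 1))
    j0 <- max(1L, floor(centres[k, 2] - r)); j1 <- min(nc, ceiling(centres[k, 2] + r + 1))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    d <- sqrt(outer((ii - 0.5 - centres[k, 1])^2, (jj - 0.5 - centres[k, 2])^2, "+"))
    cov <- pmin(1, pmax(0, r + 0.5 - d))
    canvas[ii, jj] <- canvas[ii, jj] + cov * intensities[k]
  }
  canvas
}

# Boolean mask of pixels whose centre lies within radius of any disk centre
# (the ground-truth rasterization; independent of the anti-aliased render).
diskUnionMask <- function(imageShape, centres, radii) {
  mask <- matrix(FALSE, imageShape[1], imageShape[2])
  if (!nrow(centres)) return(mask)
  for (k in seq_len(nrow(centres))) {
    r <- radii[k]
    i0 <- max(1L, floor(centres[k, 1] - r)); i1 <- min(imageShape[1], ceiling(centres[k, 1] + r + 1))
    j0 <- max(1L, floor(centres[k, 2] - r)); j1 <- min(imageShape[2], ceiling(centres[k, 2] + r + 1))
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    d2 <- outer((ii - 0.5 - centres[k, 1])^2, (jj - 0.5 - centres[k, 2])^2, "+")
    mask[ii, jj] <- mask[ii, jj] | (d2 <= r * r)
  }
  mask
}

# Uniform point inside a mask: draw a pixel, jitter uniformly within it.
samplePointInMask <- function(maskIdx, nr, n = 1L) {
  pix <- maskIdx[sample.int(length(maskIdx), n, replace = TRUE)]
  i <- (pix - 1L) %% nr + 1L
  j <- (pix - 1L) %/% nr + 1L
  cbind(i - 1 + stats::runif(n), j - 1 + stats::runif(n))
}

# Gaussian placement about the yolk centroid, rejected into the yolk
# polygon; falls back to uniform-in-yolk for points that fail repeatedly
# (only relevant when sigma vastly exceeds the yolk size).
placeYolkCells <- function(n, yolkPoly, yolkIdx, nr, sigmaPx) {
  if (n == 0L) return(matrix(numeric(0), 0, 2))
  centroid <- colMeans(yolkPoly)
  out <- matrix(NA_real_, n, 2)
  need <- seq_len(n)
  for (tries in 1:200) {
    m <- length(need)
    if (!m) break
    cand <- cbind(stats::rnorm(m, centroid[1], sigmaPx),
                  stats::rnorm(m, centroid[2], sigmaPx))
    ok <- pointInPolygon(cand, yolkPoly)
    out[need[ok], ] <- cand[ok, , drop = FALSE]
    need <- need[!ok]
  }
  if (length(need))
    out[need, ] <- samplePointInMask(yolkIdx, nr, length(need))
  out
}

# Debris placement: uniform in the yolk, but rejected against contact with
# any cell or previously placed debris (centre distance must exceed the sum
# of radii plus a 2 px guard). Keeping debris as isolated components is what
# makes size-based debris recovery exact on synthetic scenes.
placeDebris <- function(nDebris, debrisRadii, yolkIdx, nr,
                        cellCentres, cellRadii) {
  placed <- matrix(numeric(0), 0, 2)
  kept <- integer(0)
  for (k in seq_len(nDebris)) {
    ok <- FALSE
    for (tries in 1:200) {
      cand <- samplePointInMask(yolkIdx, nr, 1L)
      minGap <- debrisRadii[k] + 2
      clearCells <- !nrow(cellCentres) ||
        all((cellCentres[, 1] - cand[1])^2 + (cellCentres[, 2] - cand[2])^2 >
              (cellRadii + minGap)^2)
      clearDebris <- !nrow(placed) ||
        all((placed[, 1] - cand[1])^2 + (placed[, 2] - cand[2])^2 >
              (debrisRadii[kept] + minGap)^2)
      if (clearCells && clearDebris) {
        placed <- rbind(placed, cand)
        kept <- c(kept, k)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      warning("dropped a debris spot: no contact-free position found",
              call. = FALSE)
  }
  list(centres = placed, idx = kept)
}

# Decorative vasculature channel: a few smooth EGFP-like vessel bands along
# the trunk axis. Static; carries no information used by quantification.
renderVasculature <- function(imageShape, trunkMask) {
  nr <- imageShape[1]; nc <- imageShape[2]
  ch <- matrix(0, nr, nc)
  rowsMid <- 0.5 * nr
  jj <- seq_len(nc)
  for (off in c(-0.06, 0, 0.06) * nr) {
    centreRow <- rowsMid + off + 0.02 * nr * sin(jj / nc * 6 * pi)
    for (j in jj) {
      band <- exp(-((seq_len(nr) - centreRow[j])^2) / (2 * (0.004 * nr)^2))
      ch[, j] <- ch[, j] + 12000 * band
    }
  }
  ch * (trunkMask + 0.15)
}

#' Simulate one larva micrograph with ground truth
#'
#' Builds the tumor channel (anti-aliased cells and debris, yolk
#' autofluorescence, additive noise, clipped to the 16-bit range), a static
#' decorative vasculature channel, and the ground-truth sidecar whose
#' reference areas are obtained by an independent rasterization of the cell
#' list (pixel centre within radius). Identical parameters and seed
#' reproduce the output bit-for-bit.
#'
#' @param params a [SimulationParams-class].
#' @param rois optional [RoiSet-class]; defaults to the packaged larva
#'   template scaled to `params@imageShape`.
#' @return list with elements `image` ([LarvaImage-class]), `truth`
#'   ([GroundTruth-class]) and `rois` ([RoiSet-class]).
#' @examples
#' sim <- simulateLarva(simulationParams(imageShape = c(160, 200),
#'                                       nCells = 30, nDebris = 5, seed = 2))
#' sim$truth
#' @export
simulateLarva <- function(params, rois = NULL) {
  validObject(params)
  shape <- params@imageShape
  if (is.null(rois)) rois <- defaultRoiSet(shape)
  if (!identical(rois@shape, shape))
    stop("RoiSet shape does not match params@imageShape", call. = FALSE)

  if (exists(".Random.seed", envir = globalenv())) {
    oldSeed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", oldSeed, envir = globalenv()), add = TRUE)
  }
  set.seed(params@seed)

  nr <- shape[1]
  pxUm <- params@pixelSize
  yolkPoly <- rois@polygons[["yolk"]]
  yolkIdx <- which(rois@masks[["yolk"]])
  trunkIdx <- which(rois@masks[["trunk"]])

  n <- params@nCells
  nTrunk <- if (n > 0L) stats::rbinom(1L, n, params@trunkFraction) else 0L
  nYolk <- n - nTrunk
  yolkC <- placeYolkCells(nYolk, yolkPoly, yolkIdx, nr,
                          params@dispersionSigma / pxUm)
  trunkC <- if (nTrunk > 0L) samplePointInMask(trunkIdx, nr, nTrunk)
            else matrix(numeric(0), 0, 2)
  centres <- rbind(yolkC, trunkC)
  region <- c(rep("yolk", nYolk), rep("trunk", nTrunk))
  radiiUm <- pmax(0.2 * params@cellRadius[1],
                  stats::rnorm(n, params@cellRadius[1], params@cellRadius[2]))
  radiiPx <- radiiUm / pxUm
  intens <- pmax(1, stats::rnorm(n, params@cellIntensity[1],
                                 params@cellIntensity[2]))

  deb <- placeDebris(params@nDebris,
                     rep(params@debrisRadius / pxUm, params@nDebris),
                     yolkIdx, nr, centres, radiiPx)
  debRadiiPx <- rep(params@debrisRadius / pxUm, params@nDebris)[deb$idx]
  debIntens <- pmax(1, stats::rnorm(length(deb$idx),
                                    params@cellIntensity[1],
                                    params@cellIntensity[2]))

  tumor <- matrix(0, shape[1], shape[2])
  tumor <- renderDisks(tumor, centres, radiiPx, intens)
  tumor <- renderDisks(tumor, deb$centres, debRadiiPx, debIntens)
  if (params@yolkAutofluor > 0)
    tumor[yolkIdx] <- tumor[yolkIdx] + params@yolkAutofluor
  if (params@noiseSd > 0)
    tumor <- tumor + matrix(stats::rnorm(length(tumor), 0, params@noiseSd),
                            shape[1], shape[2])
  tumor <- pmin(pmax(tumor, 0), 65535)  # matrix first: pmax keeps its dim

  vasc <- renderVasculature(shape, rois@masks[["trunk"]])

  cellMask <- diskUnionMask(shape, centres, radiiPx)
  yolkTumor <- cellMask & rois@masks[["yolk"]]
  trueYolk <- as.numeric(sum(yolkTumor))
  trueTrunk <- as.numeric(sum(cellMask & rois@masks[["trunk"]]))
  trueHull <- if (trueYolk > 0) {
    hull <- convexHullPolygon(pixelCorners(which(yolkTumor), nr))
    if (nrow(hull) >= 3L) polygonArea(hull) else 0
  } else NA_real_

  image <- new("LarvaImage",
               channels = list(tumor = tumor, vasculature = vasc),
               pixelSize = pxUm, dialect = params@dialect)
  truth <- new("GroundTruth",
               cells = data.frame(row = centres[, 1], col = centres[, 2],
                                  radius_px = radiiPx,
                                  region = region,
                                  stringsAsFactors = FALSE)[seq_len(n), ,
                                                            drop = FALSE],
               debris = data.frame(row = deb$centres[, 1],
                                   col = deb$centres[, 2],
                                   radius_px = debRadiiPx),
               params = params,
               trueYolkAreaPx = trueYolk, trueTrunkAreaPx = trueTrunk,
               trueHullAreaPx = trueHull)
  list(image = image, truth = truth, rois = rois)
}

#' Simulate a multi-group cohort
#'
#' Applies each group's multipliers to the base parameters (cell count x
#' proliferation, trunk fraction x invasion clamped to 1, dispersion sigma x
#' dispersion) and simulates `n_larvae` fields per group. Per-larva seeds
#' derive deterministically from `design@seed`, so any larva can be
#' regenerated in isolation.
#'
#' @param design a [CohortDesign-class].
#' @param rois optional shared [RoiSet-class] override.
#' @return list with one element per larva: `image`, `truth`, `rois`,
#'   `group`, `larva_id`.
#' @export
simulateCohort <- function(design, rois = NULL) {
  validObject(design)
  g <- design@groups
  if (!nrow(g)) stop("cohort design has no groups", call. = FALSE)
  base <- design@baseParams
  out <- vector("list", sum(g$n_larvae))
  idx <- 0L
  for (gi in seq_len(nrow(g))) {
    for (li in seq_len(g$n_larvae[gi])) {
      idx <- idx + 1L
      p <- base
      p@nCells <- as.integer(round(base@nCells * g$proliferation[gi]))
      p@trunkFraction <- min(1, base@trunkFraction * g$invasion[gi])
      p@dispersionSigma <- base@dispersionSigma * g$dispersion[gi]
      p@seed <- childSeed(design@seed, idx)
      sim <- simulateLarva(p, rois = rois)
      sim$group <- g$name[gi]
      sim$larva_id <- sprintf("%s_%02d", g$name[gi], li)
      out[[idx]] <- sim
    }
  }
  out
}

# Convert linear pixel indices of an nr-row raster to the 4 corner points of
# each pixel in 0-based (row, col) pixel-corner coordinates.
pixelCorners <- function(pixIdx, nr) {
  i <- (pixIdx - 1L) %% nr + 1L
  j <- (pixIdx - 1L) %/% nr + 1L
  cbind(rep(c(0, 0, 1, 1), each = length(i)) + rep(i - 1, 4),
        rep(c(0, 1, 0, 1), each = length(j)) + rep(j - 1, 4))
}
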