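# Orchestration: configuration, cohort quantification, QC overlays,
# structured run logs and the end-to-end demonstration run.

# Polynomial rolling hash of a string modulo the Mersenne prime 2^31 - 1,
# hex-encoded; used to fingerprint run configs in the run log. Exact in
# double arithmetic (intermediate values stay far below 2^53).
configHash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 0
  for (b in bytes) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Build a run configuration
#'
#' A config either points at acquired data (an input manifest of image and
#' ROI paths plus a metadata CSV) or embeds a simulation design. It
#' round-trips losslessly through JSON via [writeRunConfig()] /
#' [readRunConfig()].
#'
#' @param design optional [CohortDesign-class] (simulation mode).
#' @param manifest optional data.frame with columns larva_id, group_label,
#'   tumor_tiff, roi_json (acquired-data mode); paths are checked at
#'   validation time.
#' @param pixelSize um per pixel for acquired images.
#' @param threshold "otsu" or a fixed intensity.
#' @param fixedFallback fixed threshold used when Otsu degenerates.
#' @param minCellArea debris threshold in um^2 (NULL: 25% of the area of a
#'   disk of `expectedCellDiameter`).
#' @param expectedCellDiameter um, used when `minCellArea` is NULL.
#' @param analysisRegion "yolk" or "all" for the migration analysis.
#' @param outDir output directory.
#' @param seed integer seed.
#' @param writeOverlays write per-larva QC overlay PNGs.
#' @return a validated list with class "xq_run_config".
#' @export
runConfig <- function(design = NULL, manifest = NULL, pixelSize = NULL,
                      threshold = "otsu", fixedFallback = 8000,
                      minCellArea = NULL, expectedCellDiameter = 16,
                      analysisRegion = "yolk", outDir = tempfile("xq_run_"),
                      seed = 1L, writeOverlays = FALSE) {
  if (is.null(design) && is.null(manifest))
    stop("config needs a simulation design or an input manifest", call. = FALSE)
  if (!is.null(manifest)) {
    need <- c("larva_id", "group_label", "tumor_tiff", "roi_json")
    if (!all(need %in% names(manifest)))
      stop("manifest must have columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    if (is.null(pixelSize))
      stop("pixelSize is required with an input manifest", call. = FALSE)
    missing <- !file.exists(manifest$tumor_tiff)
    if (any(missing))
      warning("manifest references missing image file(s): ",
              paste(manifest$tumor_tiff[missing], collapse = ", "),
              call. = FALSE)
  }
  structure(list(design = design, manifest = manifest, pixelSize = pixelSize,
                 threshold = threshold, fixedFallback = fixedFallback,
                 minCellArea = minCellArea,
                 expectedCellDiameter = expectedCellDiameter,
                 analysisRegion = analysisRegion, outDir = outDir,
                 seed = as.integer(seed), writeOverlays = writeOverlays),
            class = "xq_run_config")
}

configToList <- function(config) {
  out <- unclass(config)
  if (!is.null(out$design)) {
    d <- out$design
    p <- d@baseParams
    out$design <- list(
      groups = d@groups, seed = d@seed,
      base_params = list(
        image_shape = p@imageShape, pixel_size_um = p@pixelSize,
        n_cells = p@nCells, cell_radius_um = p@cellRadius,
        cell_intensity = p@cellIntensity,
        dispersion_sigma_um = p@dispersionSigma,
        trunk_fraction = p@trunkFraction, n_debris = p@nDebris,
        debris_radius_um = p@debrisRadius,
        yolk_autofluor_level = p@yolkAutofluor, noise_sd = p@noiseSd,
        seed = p@seed, dialect = p@dialect))
  }
  out
}

#' Serialize / restore a run configuration
#'
#' @param config an object from [runConfig()].
#' @param path JSON path.
#' @return `readRunConfig` returns the restored config.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(configToList(config), path, auto_unbox = TRUE,
                       digits = I(17), dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  design <- NULL
  if (!is.null(obj$design)) {
    bp <- obj$design$base_params
    design <- cohortDesign(
      as.data.frame(obj$design$groups),
      simulationParams(
        imageShape = bp$image_shape, pixelSize = bp$pixel_size_um,
        nCells = bp$n_cells, cellRadius = bp$cell_radius_um,
        cellIntensity = bp$cell_intensity,
        dispersionSigma = bp$dispersion_sigma_um,
        trunkFraction = bp$trunk_fraction, nDebris = bp$n_debris,
        debrisRadius = bp$debris_radius_um,
        yolkAutofluor = bp$yolk_autofluor_level, noiseSd = bp$noise_sd,
        seed = bp$seed, dialect = bp$dialect),
      seed = obj$design$seed)
  }
  manifest <- if (!is.null(obj$manifest)) as.data.frame(obj$manifest) else NULL
  runConfig(design = design, manifest = manifest, pixelSize = obj$pixelSize,
            threshold = obj$threshold, fixedFallback = obj$fixedFallback,
            minCellArea = obj$minCellArea,
            expectedCellDiameter = obj$expectedCellDiameter,
            analysisRegion = obj$analysisRegion, outDir = obj$outDir,
            seed = obj$seed, writeOverlays = isTRUE(obj$writeOverlays))
}

# RGB QC overlay: tumor channel in grey, ROI boundaries in blue, non-debris
# object pixels tinted red, debris tinted yellow, coverage hull drawn green.
writeOverlayPng <- function(image, objects, rois, hullPolygon, path) {
  tumor <- getChannel(image, "tumor")
  base <- tumor / max(tumor, 1)
  rgb <- array(rep(base, 3L), dim = c(dim(tumor), 3L))
  tab <- objects@table
  fg <- foregroundMask(objects)
  rgb[, , 1][fg] <- pmin(1, rgb[, , 1][fg] + 0.35)
  if (any(tab$is_debris)) {
    dl <- tab$label[tab$is_debris]
    dm <- matrix(objects@labels %in% dl & objects@labels > 0L,
                 nrow(tumor), ncol(tumor))
    rgb[, , 1][dm] <- 1
    rgb[, , 2][dm] <- pmin(1, rgb[, , 2][dm] + 0.8)
  }
  for (nm in roiNames(rois)) {
    m <- rois@masks[[nm]]
    inner <- m
    inner[-1, ] <- inner[-1, ] & m[-nrow(m), ]
    inner[, -1] <- inner[, -1] & m[, -ncol(m)]
    inner[-nrow(m), ] <- inner[-nrow(m), ] & m[-1, ]
    inner[, -ncol(m)] <- inner[, -ncol(m)] & m[, -1]
    edge <- m & !inner
    rgb[, , 3][edge] <- 1
  }
  if (!is.null(hullPolygon) && nrow(hullPolygon) >= 2L) {
    # sample points densely along hull edges and mark their pixels
    closed <- rbind(hullPolygon, hullPolygon[1, ])
    for (e in seq_len(nrow(closed) - 1L)) {
      t <- seq(0, 1, length.out = 200)
      rr <- pmin(nrow(tumor), pmax(1, ceiling(
        closed[e, 1] * (1 - t) + closed[e + 1, 1] * t)))
      cc <- pmin(ncol(tumor), pmax(1, ceiling(
        closed[e, 2] * (1 - t) + closed[e + 1, 2] * t)))
      rgb[cbind(rr, cc, 2L)] <- 1
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}

quantifyOne <- function(image, rois, config, larvaId, groupLabel) {
  obj <- segmentTumorChannel(image, threshold = config$threshold, rois = rois,
                             fixedFallback = config$fixedFallback)
  obj <- filterDebris(obj, minCellArea = config$minCellArea,
                      expectedCellDiameter = config$expectedCellDiameter)
  metrics <- computeMetrics(obj, rois,
                            analysisRegion = config$analysisRegion,
                            larvaId = larvaId, groupLabel = groupLabel)
  list(metrics = metrics, objects = obj)
}

errorRow <- function(larvaId, groupLabel, msg) {
  data.frame(larva_id = larvaId, group_label = groupLabel,
             yolk_area_um2 = NA_real_, trunk_area_um2 = NA_real_,
             outside_area_um2 = NA_real_, tumor_area_um2 = NA_real_,
             coverage_hull_area_um2 = NA_real_, migration_index = NA_real_,
             status = paste0("error: ", msg), stringsAsFactors = FALSE)
}

#' Quantify a cohort (simulated or from an input manifest)
#'
#' Runs segmentation, debris filtering, region areas and migration metrics
#' for every larva in the config, writing `metrics.csv`, a machine-readable
#' `run_log.json` (config echo, config hash, seed, per-larva status) and
#' optional QC overlay PNGs into `config$outDir`. Per-larva failures are
#' recorded as error rows and never abort the cohort.
#'
#' @param config from [runConfig()].
#' @return the metrics data.frame, invisibly; written files are the main
#'   product.
#' @export
runQuantify <- function(config) {
  stopifnot(inherits(config, "xq_run_config"))
  if (!dir.exists(config$outDir)) dir.create(config$outDir, recursive = TRUE)

  entries <- if (!is.null(config$design)) {
    simulateCohort(config$design)
  } else {
    lapply(seq_len(nrow(config$manifest)), function(i) {
      row <- config$manifest[i, ]
      entry <- try({
        image <- readLarvaImage(c(tumor = row$tumor_tiff),
                                pixelSize = config$pixelSize)
        rois <- readRoiSet(row$roi_json, dim(getChannel(image)))
        list(image = image, rois = rois, group = row$group_label,
             larva_id = row$larva_id)
      }, silent = TRUE)
      if (inherits(entry, "try-error"))
        list(image = NULL, rois = NULL, group = row$group_label,
             larva_id = row$larva_id,
             error = attr(entry, "condition")$message)
      else entry
    })
  }

  rows <- vector("list", length(entries))
  status <- character(length(entries))
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    if (!is.null(e$error)) {
      rows[[i]] <- errorRow(e$larva_id, e$group, e$error)
      status[i] <- "error"
      next
    }
    res <- try(quantifyOne(e$image, e$rois, config, e$larva_id, e$group),
               silent = TRUE)
    if (inherits(res, "try-error")) {
      rows[[i]] <- errorRow(e$larva_id, e$group,
                            attr(res, "condition")$message)
      status[i] <- "error"
    } else {
      rows[[i]] <- res$metrics
      status[i] <- res$metrics$status
      if (isTRUE(config$writeOverlays)) {
        hull <- if (!is.na(res$metrics$coverage_hull_area_um2))
          coverageHull(res$objects,
                       if (config$analysisRegion == "yolk")
                         roiMask(e$rois, "yolk") else NULL)$polygon
        else NULL
        writeOverlayPng(e$image, res$objects, e$rois, hull,
                        file.path(config$outDir,
                                  paste0("overlay_", e$larva_id, ".png")))
      }
    }
  }
  metrics <- do.call(rbind, rows)
  writeMetricsCsv(metrics, file.path(config$outDir, "metrics.csv"))

  cfgList <- configToList(config)
  cfgJson <- jsonlite::toJSON(cfgList, auto_unbox = TRUE, digits = I(17),
                              dataframe = "columns", null = "null")
  log <- list(config = cfgList, config_hash = configHash(cfgJson),
              seed = config$seed,
              larvae = data.frame(
                larva_id = metrics$larva_id,
                group_label = metrics$group_label, status = status))
  jsonlite::write_json(log, file.path(config$outDir, "run_log.json"),
                       auto_unbox = TRUE, digits = I(17),
                       dataframe = "columns", null = "null")
  invisible(metrics)
}

#' End-to-end demonstration run on synthetic data
#'
#' Simulates a negative-control versus knockdown cohort with programmed
#' effects (knockdown: 0.6x cell number, 0.6x trunk fraction, 0.5x
#' dispersion sigma -- reduced proliferation, invasion and migration),
#' quantifies every larva, compares the groups with unpaired Student's t
#' and reports whether the programmed direction of effect was recovered.
#'
#' @param seed integer root seed for the cohort.
#' @param nPerGroup larvae per group (default 20).
#' @param outDir output directory for metrics/log files.
#' @param baseParams base [SimulationParams-class]; the default is a
#'   down-scaled stereo field (320 x 400 px) holding 120 cells, which keeps
#'   a 2 x 20 larvae demo run in the tens of seconds.
#' @return list with `metrics`, `summaries`, `comparisons` and
#'   `effect_recovered` (named logical: proliferation, migration).
#' @export
runDemo <- function(seed = 20L, nPerGroup = 20L,
                    outDir = tempfile("xq_demo_"),
                    baseParams = simulationParams(
                      imageShape = c(320L, 400L), pixelSize = 2.5,
                      nCells = 120L, cellRadius = c(8, 1),
                      dispersionSigma = 80, trunkFraction = 0.05,
                      nDebris = 12L, debrisRadius = 3,
                      yolkAutofluor = 2000, noiseSd = 500)) {
  design <- cohortDesign(
    data.frame(name = c("NC", "si"), n_larvae = c(nPerGroup, nPerGroup),
               proliferation = c(1, 0.6), invasion = c(1, 0.6),
               dispersion = c(1, 0.5)),
    baseParams, seed = seed)
  config <- runConfig(design = design, outDir = outDir, seed = seed)
  metrics <- runQuantify(config)

  ok <- metrics$status == "ok"
  summaries <- list(
    yolk_area = summarizeGroups(metrics[ok, ], "yolk_area_um2"),
    trunk_area = summarizeGroups(metrics[ok, ], "trunk_area_um2"),
    migration = summarizeGroups(metrics[ok, ], "migration_index"))
  comparisons <- rbind(
    compareGroups(metrics[ok, ], "yolk_area_um2", "NC"),
    compareGroups(metrics[ok, ], "trunk_area_um2", "NC"),
    compareGroups(metrics[ok, ], "migration_index", "NC"))

  meanOf <- function(s, g) s$mean[s$group == g]
  recovered <- c(
    proliferation = meanOf(summaries$yolk_area, "si") <
      meanOf(summaries$yolk_area, "NC"),
    migration = meanOf(summaries$migration, "si") <
      meanOf(summaries$migration, "NC"))
  list(metrics = metrics, summaries = summaries, comparisons = comparisons,
       effect_recovered = recovered, outDir = outDir)
}
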