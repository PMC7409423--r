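# Tumor-channel segmentation: thresholding, labeling, debris size filter.

test_that("an all-zero channel under a fixed threshold yields no objects", {
  img <- imageFromMatrix(matrix(0, 40, 40))
  obj <- segmentTumorChannel(img, threshold = 100)
  expect_identical(nObjects(obj), 0L)
  expect_identical(sum(labelRaster(obj)), 0L)
})

test_that("disjoint synthetic disks are recovered with truth-exact areas", {
  # noise-free scene, constant intensity: threshold at half the peak
  # reproduces the ground-truth rasterization (pixel centre within radius).
  # 12 disks on a jittered grid, guaranteed disjoint by construction.
  set.seed(42)
  centres <- as.matrix(expand.grid(row = c(30, 70, 110), col = seq(25, 175, 50)))
  centres <- centres + matrix(runif(24, -5, 5), 12, 2)
  radii <- runif(12, 3, 6)
  img <- imageFromMatrix(
    xenoquant:::renderDisks(matrix(0, 160, 200), centres, radii,
                            rep(30000, 12)),
    pixelSize = 2.5)
  cells <- data.frame(row = centres[, 1], col = centres[, 2],
                      radius_px = radii)
  obj <- segmentTumorChannel(img, threshold = 15000)
  expect_identical(nObjects(obj), 12L)
  # per-object area matches a brute-force count of the truth disk whose
  # centre is nearest the object centroid
  diskPixels <- function(i) {
    rpx <- cells$radius_px[i]
    rows <- floor(cells$row[i] - rpx):ceiling(cells$row[i] + rpx + 1)
    cols <- floor(cells$col[i] - rpx):ceiling(cells$col[i] + rpx + 1)
    cnt <- 0L
    for (r in rows) for (cc in cols)
      if ((r - 0.5 - cells$row[i])^2 + (cc - 0.5 - cells$col[i])^2 <= rpx^2)
        cnt <- cnt + 1L
    cnt
  }
  tab <- objectTable(obj)
  for (k in seq_len(nrow(tab))) {
    d <- sqrt((cells$row - tab$centroid_row[k])^2 +
                (cells$col - tab$centroid_col[k])^2)
    expect_identical(tab$area_px[k], diskPixels(which.min(d)))
  }
  expect_identical(sum(tab$area_px),
                   sum(vapply(seq_len(nrow(cells)), diskPixels, integer(1))))
})

test_that("overlapping disks merge into one object covering the union", {
  m <- matrix(0, 30, 30)
  m[5:10, 5:10] <- 1000
  m[10:15, 10:15] <- 1000  # overlaps the first block in exactly one pixel
  obj <- segmentTumorChannel(imageFromMatrix(m), threshold = 500)
  expect_identical(nObjects(obj), 1L)
  expect_identical(objectTable(obj)$area_px, sum(m > 0))
})

test_that("labeling matches a brute-force flood fill on random rasters", {
  set.seed(101)
  for (rep in 1:25) {
    nr <- sample(3:64, 1); nc <- sample(3:64, 1)
    mask <- matrix(runif(nr * nc) < runif(1, 0.2, 0.7), nr, nc)
    for (conn in c(4L, 8L)) {
      got <- xenoquant:::.labelComponents(mask, conn)
      want <- floodFillOracle(mask, conn)
      expect_true(samePartition(got, want),
                  info = sprintf("rep %d conn %d", rep, conn))
    }
  }
})

test_that("labeling agrees with EBImage bwlabel at 4-connectivity", {
  set.seed(7)
  mask <- matrix(runif(60 * 50) < 0.4, 60, 50)
  got <- xenoquant:::.labelComponents(mask, 4L)
  ref <- EBImage::bwlabel(mask * 1)
  expect_true(samePartition(got, matrix(as.integer(ref), 60, 50)))
})

test_that("raising a fixed threshold never grows the foreground", {
  p <- testParams(noiseSd = 600, yolkAutofluor = 2000, seed = 3L)
  sim <- simulateLarva(p)
  counts <- vapply(c(5000, 10000, 15000, 20000, 30000), function(thr) {
    obj <- segmentTumorChannel(sim$image, threshold = thr)
    sum(objectTable(obj)$area_px)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("object areas always sum to the foreground pixel count", {
  p <- testParams(noiseSd = 500, yolkAutofluor = 1800, seed = 8L)
  sim <- simulateLarva(p)
  obj <- segmentTumorChannel(sim$image, rois = sim$rois)
  expect_identical(sum(objectTable(obj)$area_px),
                   sum(labelRaster(obj) > 0L))
})

test_that("degenerate automatic thresholding warns and falls back", {
  img <- imageFromMatrix(matrix(100, 50, 50))  # unimodal, featureless
  expect_warning(obj <- segmentTumorChannel(img, fixedFallback = 5000),
                 "degenerated")
  expect_identical(nObjects(obj), 0L)
  expect_error(segmentTumorChannel(img), "degenerated")
})

test_that("Otsu restricted to ROI masks matches EBImage on the same sample", {
  p <- testParams(noiseSd = 400, yolkAutofluor = 1500, seed = 21L)
  sim <- simulateLarva(p)
  obj <- segmentTumorChannel(sim$image, rois = sim$rois)
  un <- roiMask(sim$rois, "yolk") | roiMask(sim$rois, "trunk")
  vals <- getChannel(sim$image)[un]
  ref <- EBImage::otsu(EBImage::Image(matrix(vals / 65535, 1)),
                       range = c(0, 1), levels = 65536L) * 65535
  expect_equal(attr(obj, "threshold"), ref, tolerance = 1e-12)
})

test_that("debris flagging is an exact size rule", {
  p <- testParams(nCells = 20L, nDebris = 8L, seed = 13L)
  sim <- simulateLarva(p)
  obj <- segmentTumorChannel(sim$image, threshold = 15000)
  # threshold 0 um^2 flags nothing
  expect_false(any(objectTable(filterDebris(obj, minCellArea = 0))$is_debris))
  # a huge threshold flags everything and empties downstream areas
  all_flagged <- filterDebris(obj, minCellArea = 1e9)
  expect_true(all(objectTable(all_flagged)$is_debris))
  areas <- measureRegionAreas(all_flagged, sim$rois)
  expect_identical(areas@pixelCounts[["total"]], 0L)
  # flagged count is monotone in the threshold
  thresholds <- c(0, 20, 60, 200, 1e5)
  flagged <- vapply(thresholds, function(a)
    sum(objectTable(filterDebris(obj, minCellArea = a))$is_debris), numeric(1))
  expect_true(all(diff(flagged) >= 0))
})

test_that("flagged objects match simulated debris exactly on clean scenes", {
  # cells ~ 4.8 px radius (area >= 40 px), debris ~ 1 px radius (<= 8 px);
  # a 20 px cut separates them perfectly
  p <- testParams(nCells = 25L, nDebris = 8L, cellRadius = c(12, 0.5),
                  debrisRadius = 2.5, seed = 31L)
  sim <- simulateLarva(p)
  obj <- filterDebris(segmentTumorChannel(sim$image, threshold = 15000),
                      minCellArea = 20 * p@pixelSize^2)
  tab <- objectTable(obj)
  deb <- trueDebris(sim$truth)
  expect_identical(sum(tab$is_debris), nrow(deb))
  # every flagged object centroid sits on a true debris spot
  for (k in which(tab$is_debris)) {
    d <- sqrt((deb$row - tab$centroid_row[k])^2 +
                (deb$col - tab$centroid_col[k])^2)
    expect_lt(min(d), 1.5)
  }
})
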