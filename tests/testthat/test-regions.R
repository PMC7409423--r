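# Polygon rasterization and per-region area accounting.

test_that("an axis-aligned rectangle rasterizes to its exact pixel area", {
  m <- rasterizeRoi(cbind(c(0, 0, 10, 10), c(0, 20, 20, 0)), c(16, 32))
  expect_identical(sum(m), 200L)
  expect_true(all(which(m, arr.ind = TRUE)[, 1] <= 10))
  expect_true(all(which(m, arr.ind = TRUE)[, 2] <= 20))
})

test_that("degenerate and self-intersecting polygons are rejected", {
  expect_error(rasterizeRoi(matrix(numeric(0), 0, 2), c(10, 10)),
               "at least 3 vertices")
  expect_error(rasterizeRoi(cbind(c(0, 10), c(0, 10)), c(10, 10)),
               "at least 3 vertices")
  bowtie <- cbind(c(0, 10, 0, 10), c(0, 10, 10, 0))
  expect_error(rasterizeRoi(bowtie, c(12, 12)), "self-intersecting")
})

test_that("rasterization matches an independent point-in-polygon oracle", {
  skip_if_not_installed("mgcv")
  set.seed(55)
  for (rep in 1:20) {
    # random star-shaped (hence simple) polygon on a 32x32 grid
    k <- sample(5:12, 1)
    ang <- sort(runif(k, 0, 2 * pi))
    rad <- runif(k, 4, 15)
    ctr <- runif(2, 12, 20)
    poly <- cbind(ctr[1] + rad * sin(ang), ctr[2] + rad * cos(ang))
    mask <- rasterizeRoi(poly, c(32, 32))
    centres <- cbind(rep(1:32, 32) - 0.5, rep(1:32, each = 32) - 0.5)
    want <- mgcv::in.out(rbind(poly, poly[1, ]),
                         cbind(centres[, 1], centres[, 2]))
    expect_identical(as.vector(mask), want, info = paste("rep", rep))
  }
})

test_that("region areas follow the pixel x pixel-size^2 arithmetic", {
  # one 100-px object fully inside the yolk at 2 um/px -> 400 um^2
  shape <- c(40L, 40L)
  rois <- roiSet(list(yolk = cbind(c(2, 2, 30, 30), c(2, 30, 30, 2)),
                      trunk = cbind(c(32, 32, 38, 38), c(2, 38, 38, 2))),
                 shape)
  m <- matrix(0, 40, 40)
  m[10:19, 10:19] <- 1  # 100 px
  obj <- objectsFromMask(m, pixelSize = 2)
  areas <- measureRegionAreas(obj, rois, pixelSize = 2)
  expect_identical(areas@yolkArea, 400)
  expect_identical(areas@trunkArea, 0)
  expect_identical(areas@outsideArea, 0)
  expect_identical(areas@assignments$region, "yolk")
})

test_that("no objects means zero areas everywhere", {
  rois <- roiSet(list(yolk = cbind(c(2, 2, 10, 10), c(2, 10, 10, 2)),
                      trunk = cbind(c(12, 12, 18, 18), c(2, 18, 18, 2))),
                 c(20L, 20L))
  obj <- objectsFromMask(matrix(0, 20, 20))
  areas <- measureRegionAreas(obj, rois)
  expect_identical(areas@yolkArea + areas@trunkArea + areas@outsideArea, 0)
  expect_identical(nrow(areas@assignments), 0L)
})

test_that("trunk_fraction 0 gives zero trunk area and truth-exact yolk area", {
  # exactness requires no two rendered disks to touch (summed rim coverage
  # would otherwise add pixels the truth rasterization does not contain),
  # so draw scenes until the cells are pairwise separated
  # low density so that a pairwise-separated draw occurs within a few seeds
  p <- testParams(nCells = 5L, cellRadius = c(6, 0.5), trunkFraction = 0,
                  nDebris = 0L, cellIntensity = c(30000, 0),
                  dispersionSigma = 120, seed = 6L)
  sim <- simulateLarva(p)
  separated <- function(cells) {
    d <- as.matrix(dist(cells[, c("row", "col")])); diag(d) <- Inf
    all(d > outer(cells$radius_px, cells$radius_px, "+") + 3)
  }
  while (!separated(trueCells(sim$truth))) {
    p@seed <- p@seed + 1L
    sim <- simulateLarva(p)
  }
  obj <- filterDebris(segmentTumorChannel(sim$image, threshold = 15000),
                      minCellArea = 0)
  areas <- measureRegionAreas(obj, sim$rois)
  expect_identical(areas@trunkArea, 0)
  expect_identical(areas@pixelCounts[["yolk"]],
                   as.integer(sim$truth@trueYolkAreaPx))
  expect_identical(areas@yolkArea,
                   sim$truth@trueYolkAreaPx * p@pixelSize^2)
})

test_that("yolk + trunk + outside pixels partition the foreground exactly", {
  for (seed in c(2L, 14L, 27L)) {
    p <- testParams(noiseSd = 500, yolkAutofluor = 1500, trunkFraction = 0.3,
                    seed = seed)
    sim <- simulateLarva(p)
    obj <- filterDebris(segmentTumorChannel(sim$image, rois = sim$rois),
                        expectedCellDiameter = 16)
    areas <- measureRegionAreas(obj, sim$rois)
    pc <- areas@pixelCounts
    expect_identical(pc[["yolk"]] + pc[["trunk"]] + pc[["outside"]],
                     pc[["total"]])
    expect_identical(pc[["total"]], sum(foregroundMask(obj)))
  }
})

test_that("integer translation of scene and ROIs leaves areas unchanged", {
  shape <- c(60L, 60L)
  yolk <- cbind(c(5, 5, 25, 25), c(5, 25, 25, 5))
  trunk <- cbind(c(30, 30, 40, 40), c(5, 40, 40, 5))
  m <- matrix(0, 60, 60)
  m[8:20, 8:20] <- 1
  m[32:35, 10:30] <- 1
  dr <- 7L; dc <- 11L
  m2 <- matrix(0, 60, 60)
  m2[(8:20) + dr, (8:20) + dc] <- 1
  m2[(32:35) + dr, (10:30) + dc] <- 1
  roisA <- roiSet(list(yolk = yolk, trunk = trunk), shape)
  roisB <- roiSet(list(yolk = yolk + cbind(dr, dc)[rep(1, 4), ],
                       trunk = trunk + cbind(dr, dc)[rep(1, 4), ]), shape)
  a <- measureRegionAreas(objectsFromMask(m), roisA)
  b <- measureRegionAreas(objectsFromMask(m2), roisB)
  expect_identical(a@pixelCounts, b@pixelCounts)
})

test_that("overlapping yolk/trunk masks are rejected at construction", {
  expect_error(
    roiSet(list(yolk = cbind(c(0, 0, 10, 10), c(0, 10, 10, 0)),
                trunk = cbind(c(5, 5, 15, 15), c(5, 15, 15, 5))),
           c(20L, 20L)),
    "disjoint")
})

test_that("missing yolk or trunk region is a configuration error", {
  expect_error(
    roiSet(list(yolk = cbind(c(0, 0, 5, 5), c(0, 5, 5, 0))), c(10L, 10L)),
    "yolk")
  obj <- objectsFromMask(matrix(0, 10, 10))
  rois <- roiSet(list(yolk = cbind(c(0, 0, 4, 4), c(0, 4, 4, 0)),
                      trunk = cbind(c(6, 6, 9, 9), c(0, 9, 9, 0))),
                 c(10L, 10L))
  expect_error(measureRegionAreas(obj, rois, pixelSize = 1), NA)
})
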