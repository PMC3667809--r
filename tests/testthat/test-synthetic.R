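# Phantom generator: reproducibility, geometry, noise honesty, seeding.

test_that("identical seeds give bit-identical phantoms and annotations", {
  a <- defaultPhantom(seed = 71, frames = 4, dim = c(96, 96), nCells = 2)
  b <- defaultPhantom(seed = 71, frames = 4, dim = c(96, 96), nCells = 2)
  expect_identical(gridValues(phantomGrid(a)), gridValues(phantomGrid(b)))
  expect_identical(segLabels(a), segLabels(b))
  expect_identical(analyticAreas(a), analyticAreas(b))
  sa <- defaultSeedAnnotation(a, seed = 72)
  sb <- defaultSeedAnnotation(b, seed = 72)
  expect_identical(seedCoords(sa), seedCoords(sb))

  c2 <- defaultPhantom(seed = 73, frames = 4, dim = c(96, 96), nCells = 2)
  expect_false(identical(gridValues(phantomGrid(a)), gridValues(phantomGrid(c2))))
})

test_that("noiseless phantom is piecewise constant and exactly thresholdable", {
  ph <- simulateSpreadingStack(
    list(cellParams(c(24, 24), maxArea = 60, rate = 0.02, midpoint = 30,
                    intensity = 500, irregularity = 0)),
    frames = 4, dim = c(48, 48), gaussianSigma = 0, poisson = FALSE,
    background = 100, seed = 74)
  v <- gridValues(phantomGrid(ph))
  expect_identical(sort(unique(as.vector(v))), c(100, 500))
  truth <- segLabels(ph)
  expect_identical(array(as.integer(v > 300), dim(v)), truth)

  # measured and true areas agree exactly without noise (noise honesty)
  seeds <- defaultSeedAnnotation(ph, seed = 75)
  seg <- segmentVolume(phantomGrid(ph), seeds)
  m <- computeAreas(seg, pixelArea(phantomGrid(ph)),
                    frameInterval(phantomGrid(ph)))
  expect_identical(areaData(m), areaData(groundTruthAreas(ph)))
})

test_that("pixel-count areas track the analytic logistic within the discretization bound", {
  ph <- simulateSpreadingStack(
    list(cellParams(c(48, 48), maxArea = 300, rate = 0.02, midpoint = 50,
                    intensity = 500, irregularity = 0.1)),
    frames = 20, dim = c(96, 96), gaussianSigma = 0, poisson = FALSE,
    pixelSize = 0.5, seed = 76)
  truth <- segLabels(ph)
  an <- analyticAreas(ph)
  for (t in seq_len(20)) {
    mask <- truth[, , t] == 1L
    px <- sum(mask)
    analyticPx <- an$area_um2[an$frame == t - 1L] / 0.25
    # boundary pixels: mask pixels with a 4-neighbour outside
    er <- EBImage::erode(mask + 0, EBImage::makeBrush(3, "diamond")) > 0
    perim <- sum(mask & !er)
    expect_lte(abs(px - analyticPx), max(perim, 4))
  }
})

test_that("a very steep growth rate approximates step growth at the midpoint", {
  ph <- simulateSpreadingStack(
    list(cellParams(c(32, 32), maxArea = 200, rate = 50, midpoint = 27.5,
                    intensity = 500, irregularity = 0)),
    frames = 12, dim = c(64, 64), frameInterval = 5, gaussianSigma = 0,
    poisson = FALSE, seed = 77)
  px <- areaData(groundTruthAreas(ph))$area_px
  expect_true(all(px[1:6] <= 1))                # ~0 before t0
  expect_gte(min(px[7:12]), 0.95 * 200 / 0.25)  # ~Amax after t0
})

test_that("overlapping cells at plateau are rejected naming the pair", {
  cells <- list(cellParams(c(30, 30), maxArea = 400),
                cellParams(c(30, 50), maxArea = 400))
  expect_error(simulateSpreadingStack(cells, frames = 2, dim = c(64, 64),
                                      seed = 78),
               "cells 1 and 2 overlap")
})

test_that("intensity draws must clear the background", {
  expect_error(simulateSpreadingStack(list(cellParams(c(16, 16))), frames = 2,
                                      dim = c(32, 32), background = 100,
                                      intensityRange = c(50, 80), seed = 79),
               "above the background")
})

test_that("ground-truth areas equal the measurement path on truth labels", {
  ph <- defaultPhantom(seed = 80, frames = 3, dim = c(96, 96), nCells = 2)
  direct <- computeAreas(truthLabels(ph), pixelArea(phantomGrid(ph)),
                         frameInterval(phantomGrid(ph)))
  expect_identical(areaData(groundTruthAreas(ph)), areaData(direct))

  # no cells: the background row is reported instead of an empty table
  empty <- simulateSpreadingStack(list(), frames = 2, dim = c(16, 16),
                                  gaussianSigma = 0, poisson = FALSE,
                                  seed = 81)
  d <- areaData(groundTruthAreas(empty))
  expect_identical(unique(d$cell_label), 0L)
  expect_identical(d$area_px, rep(256L, 2L))
})

test_that("sampled seeds lie inside their true regions, one label per cell", {
  ph <- defaultPhantom(seed = 82, frames = 4, dim = c(128, 128), nCells = 3)
  s <- defaultSeedAnnotation(ph, perCellSeedCount = 4, seed = 83)
  truth <- segLabels(ph)
  co <- seedCoords(s); lab <- seedLabels(s)
  for (i in seq_len(length(s)))
    expect_identical(truth[co[i, "row"], co[i, "col"], co[i, "t"]], lab[i])
  expect_setequal(unique(lab), c(0L, 1L, 2L, 3L))
  # one seed per cell when asked for one
  s1 <- defaultSeedAnnotation(ph, perCellSeedCount = 1, seed = 84)
  counts <- table(seedLabels(s1))
  expect_true(all(counts[c("1", "2", "3")] == 1L))
})

test_that("lower cell-background contrast degrades segmentation quality", {
  dice <- vapply(list(c(140, 150), c(200, 220), c(500, 600)), function(rng) {
    ph <- defaultPhantom(seed = 85, frames = 4, dim = c(96, 96), nCells = 1,
                         intensityRange = rng)
    seeds <- defaultSeedAnnotation(ph, seed = 86)
    seg <- segmentVolume(phantomGrid(ph), seeds)
    mean(vapply(1:4, function(t)
      diceCoefficient(segLabels(truthLabels(ph))[, , t] == 1L,
                      segLabels(seg)[, , t] == 1L), numeric(1)))
  }, numeric(1))
  expect_true(dice[1] <= dice[2] && dice[2] <= dice[3])
  expect_lt(dice[1], 0.999)   # the low-contrast setting is genuinely hard
})
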