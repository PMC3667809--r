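# Area quantification, CSV dialect, cohort curves and auxiliary numerics.

test_that("areas count pixels and respect the calibration", {
  seg <- SegmentationVolume(matrix(1L, 10, 10))
  at <- computeAreas(seg, pixelArea = 1, frameInterval = 5)
  d <- areaData(at)
  expect_identical(d$area_px, 100L)
  expect_identical(d$area_um2, 100)
  expect_identical(d$frame, 0L)
  expect_identical(d$time_s, 0)

  # calibration linearity
  at2 <- computeAreas(seg, pixelArea = 0.25, frameInterval = 5)
  expect_identical(areaData(at2)$area_um2, 25)
})

test_that("a label absent from a frame gets an explicit zero row", {
  labels <- array(0L, dim = c(4, 4, 2))
  labels[1:2, 1:2, 1L] <- 1L           # cell 1 only in frame 1
  labels[3:4, 3:4, ] <- 2L             # cell 2 in both
  at <- computeAreas(SegmentationVolume(labels), pixelArea = 1,
                     frameInterval = 5)
  d <- areaData(at)
  expect_identical(nrow(d), 4L)        # 2 cells x 2 frames
  expect_identical(d$area_px[d$cell_label == 1L & d$frame == 1L], 0L)
})

test_that("background plus cell areas conserve the pixel count per frame", {
  set.seed(61)
  labels <- array(sample(0:3, 6 * 7 * 3, replace = TRUE), dim = c(6, 7, 3))
  at <- computeAreas(SegmentationVolume(labels), pixelArea = 1,
                     frameInterval = 1, includeBackground = TRUE)
  d <- areaData(at)
  sums <- tapply(d$area_px, d$frame, sum)
  expect_true(all(sums == 6L * 7L))
})

test_that("area CSV round trip is exact and byte-identical", {
  set.seed(62)
  labels <- array(sample(0:2, 5 * 5 * 4, replace = TRUE), dim = c(5, 5, 4))
  at <- computeAreas(SegmentationVolume(labels), pixelArea = 0.3,
                     frameInterval = 5)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  exportAreasCSV(at, f1)
  back <- readAreasCSV(f1)
  expect_equal(areaData(back), areaData(at))
  expect_equal(pixelArea(back), pixelArea(at))
  exportAreasCSV(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # fixed dialect
  expect_identical(readLines(f1, n = 1L),
                   "cell_label,frame,time_s,area_px,area_um2")

  # empty table writes a header-only file
  empty <- computeAreas(SegmentationVolume(matrix(0L, 3, 3)), 1, 5)
  f3 <- tempfile(fileext = ".csv")
  exportAreasCSV(empty, f3)
  expect_identical(length(readLines(f3)), 1L)
})

test_that("cohort curves report mean and s.e.m. per frame", {
  mk <- function(area) {
    labels <- array(0L, dim = c(20, 20, 3))
    labels[seq_len(area %/% 20), 1:20, ] <- 1L
    computeAreas(SegmentationVolume(labels), pixelArea = 1, frameInterval = 5)
  }
  cv <- aggregateCurves(list(a = mk(100), b = mk(200)))
  d <- curveData(cv)
  expect_identical(d$n, rep(2L, 3L))
  expect_equal(d$mean_um2, rep(150, 3L))
  expect_equal(d$sem_um2, rep(50, 3L), tolerance = 1e-12)
  expect_equal(d$sem_um2 * sqrt(2), rep(sd(c(100, 200)), 3L))
  expect_equal(d$time_s, c(0, 5, 10))

  # single cell: mean is its trace, s.e.m. undefined
  cv1 <- aggregateCurves(mk(100))
  expect_true(all(is.na(curveData(cv1)$sem_um2)))
  expect_equal(curveData(cv1)$mean_um2, rep(100, 3L))

  # independent re-computation of mean/sd on a random fixture
  set.seed(63)
  vals <- matrix(rpois(5 * 3, 50), 5, 3)   # 5 cells x 3 frames
  tabs <- lapply(1:5, function(i) {
    labels <- array(0L, dim = c(100, 1, 3))
    for (t in 1:3) labels[seq_len(vals[i, t]), 1, t] <- 1L
    computeAreas(SegmentationVolume(labels), pixelArea = 1, frameInterval = 5)
  })
  d <- curveData(aggregateCurves(tabs))
  for (t in 1:3) {
    expect_equal(d$mean_um2[t], mean(vals[, t]))
    expect_equal(d$sem_um2[t], sd(vals[, t]) / sqrt(5))
  }
})

test_that("custom per-cell frame offsets shift traces before pooling", {
  labels <- array(1L, dim = c(2, 2, 3))
  at <- computeAreas(SegmentationVolume(labels), 1, 5)
  cv <- aggregateCurves(list(x = at, y = at), alignment = "custom",
                        offsets = c(x.1 = 0, y.1 = 1))
  d <- curveData(cv)
  expect_identical(d$frame, c(-1, 0, 1, 2))
  expect_identical(d$n, c(1L, 2L, 2L, 1L))
})

test_that("pooled t statistic matches the closed form", {
  r <- compareGroups(c(10, 12, 14), c(20, 22, 24))
  expect_equal(r$statistic, -6.123724356957945, tolerance = 1e-10)
  expect_identical(r$df, 4L)
  expect_identical(compareGroups(c(5, 5, 5), c(5, 5))$df, 3L)
  # independent closed form
  sp2 <- (var(c(10, 12, 14)) * 2 + var(c(20, 22, 24)) * 2) / 4
  tman <- (12 - 22) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(r$statistic, tman, tolerance = 1e-12)
  expect_equal(r$p.value, 2 * pt(tman, 4), tolerance = 1e-12)

  ident <- compareGroups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$statistic, 0)
  expect_equal(ident$p.value, 1)

  const <- compareGroups(c(5, 5, 5), c(5, 5))
  expect_equal(const$statistic, 0)
  expect_equal(const$p.value, 1)
  expect_false(const$degenerate)

  deg <- compareGroups(c(5, 5, 5), c(7, 7))
  expect_true(deg$degenerate)
  expect_equal(deg$p.value, 0)
  expect_error(compareGroups(1, c(2, 3)), "at least two")
})

test_that("group comparison extracts per-cell areas from tables", {
  mk <- function(areas) {   # one cell per table entry, constant over 2 frames
    lapply(areas, function(a) {
      labels <- array(0L, dim = c(30, 30, 2))
      labels[seq_len(a), 1, 1:2] <- 1L
      computeAreas(SegmentationVolume(labels), 1, 5)
    })
  }
  r <- compareGroups(mk(c(10, 12, 14)), mk(c(20, 22, 24)), frame = 1)
  expect_equal(r$statistic, -6.123724356957945, tolerance = 1e-10)
  rw <- compareGroups(mk(c(10, 12, 14)), mk(c(20, 22, 24)), window = 0:1)
  expect_equal(rw$statistic, r$statistic, tolerance = 1e-12)
})

test_that("blot loading normalization follows the reference-lane rule", {
  tab <- data.frame(lane = c("stim", "inh"),
                    antibody_signal = c(40, 30),
                    actin_signal = c(100, 50),
                    is_reference = c(TRUE, FALSE))
  out <- normalizeBlot(tab)
  expect_equal(out$norm_actin, c(1, 0.5))
  expect_equal(out$adjusted_signal, c(40, 60))

  # equal loading leaves antibody signals untouched
  eq <- normalizeBlot(data.frame(lane = 1:3, antibody_signal = c(3, 5, 7),
                                 actin_signal = 80,
                                 is_reference = c(TRUE, FALSE, FALSE)))
  expect_equal(eq$adjusted_signal, c(3, 5, 7))

  # invariant under global rescaling of the actin channel
  sc <- tab; sc$actin_signal <- sc$actin_signal * 37.5
  expect_equal(normalizeBlot(sc)$adjusted_signal, out$adjusted_signal)

  expect_error(normalizeBlot(transform(tab, actin_signal = c(100, 0))),
               "positive")
  expect_error(normalizeBlot(transform(tab, is_reference = c(TRUE, TRUE))),
               "exactly one")
})

test_that("ratio traces are normalized to a unit baseline", {
  out <- normalizeRatioTrace(c(2, 2, 2, 4, 4), c(1, 1, 1, 1, 1),
                             baselineWindow = 1:3)
  expect_equal(as.vector(out), c(1, 1, 1, 2, 2))
  expect_equal(attr(out, "R0"), 2)

  # constant traces give identically 1
  expect_equal(as.vector(normalizeRatioTrace(rep(3, 6), rep(7, 6))),
               rep(1, 6))

  # invariant under independent rescaling of either channel
  set.seed(64)
  num <- runif(20, 1, 2); den <- runif(20, 1, 2)
  a <- normalizeRatioTrace(num, den, 1:5)
  b <- normalizeRatioTrace(num * 13, den * 0.2, 1:5)
  expect_equal(as.vector(a), as.vector(b), tolerance = 1e-12)

  # baseline mean is 1 exactly, detrended or not
  dt <- normalizeRatioTrace(num, den, 1:5, detrend = TRUE)
  expect_equal(mean(dt[1:5]), 1, tolerance = 1e-12)

  expect_error(normalizeRatioTrace(c(1, 2), c(1, 0)), "index 2")
  expect_error(normalizeRatioTrace(1:3, 1:4), "same length")
})

test_that("logistic fits recover generative parameters from clean curves", {
  t <- seq(0, 295, by = 5)
  y <- 400 / (1 + exp(-0.015 * (t - 60)))
  fit <- fitSpreadingCurve(data.frame(time_s = t, mean_um2 = y))
  expect_equal(unname(fit["Amax"]), 400, tolerance = 1e-6)
  expect_equal(unname(fit["k"]), 0.015, tolerance = 1e-6)
  expect_equal(unname(fit["t0"]), 60, tolerance = 1e-4)
})
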