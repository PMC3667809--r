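## Synthetic TIRF spreading phantoms with exact ground truth.

.logisticArea <- function(t, Amax, k, t0) Amax / (1 + exp(-k * (t - t0)))

## Radial shape modulation: low-order Fourier perturbation of the disc
## boundary, normalized so max|g| = 1, then rescaled so the mean of s^2 over
## the boundary is 1 (the perturbed footprint keeps the disc's area).
.makeShape <- function(irregularity, nHarmonics = 5L) {
  if (irregularity <= 0)
    return(list(a = numeric(0), b = numeric(0), scale = 1,
                irregularity = 0))
  a <- stats::runif(nHarmonics, -1, 1)
  b <- stats::runif(nHarmonics, -1, 1)
  th <- seq(0, 2 * pi, length.out = 720L)
  g <- .evalHarmonics(th, a, b)
  m <- max(abs(g))
  if (m > 0) { a <- a / m; b <- b / m }
  s <- 1 + irregularity * .evalHarmonics(th, a, b)
  list(a = a, b = b, scale = 1 / sqrt(mean(s^2)),
       irregularity = irregularity)
}

.evalHarmonics <- function(theta, a, b) {
  g <- numeric(length(theta))
  for (m in seq_along(a))
    g <- g + a[m] * cos(m * theta) + b[m] * sin(m * theta)
  g
}

.shapeRadiusFactor <- function(theta, shape) {
  if (shape$irregularity <= 0) return(rep(1, length(theta)))
  (1 + shape$irregularity * .evalHarmonics(theta, shape$a, shape$b)) *
    shape$scale
}

.maxShapeFactor <- function(shape) {
  if (shape$irregularity <= 0) return(1)
  (1 + shape$irregularity) * shape$scale
}

## Footprint mask of one cell at pixel radius rpx, clipped to the image.
.cellMask <- function(d, center, rpx, shape) {
  mask <- NULL
  rmax <- rpx * .maxShapeFactor(shape)
  r1 <- max(1L, floor(center[1L] - rmax - 1)); r2 <- min(d[1L], ceiling(center[1L] + rmax + 1))
  c1 <- max(1L, floor(center[2L] - rmax - 1)); c2 <- min(d[2L], ceiling(center[2L] + rmax + 1))
  if (r1 > r2 || c1 > c2) return(NULL)
  rows <- r1:r2; cols <- c1:c2
  dy <- outer(rows - center[1L], rep(1, length(cols)))
  dx <- outer(rep(1, length(rows)), cols - center[2L])
  dist2 <- dy^2 + dx^2
  theta <- atan2(dx, dy)
  rb <- rpx * .shapeRadiusFactor(as.vector(theta), shape)
  inside <- matrix(as.vector(dist2) <= rb^2, length(rows), length(cols))
  if (!any(inside)) return(NULL)
  list(rows = rows, cols = cols, inside = inside)
}

#' Simulate a TIRF cell-spreading stack with ground truth
#'
#' Generates a time-lapse of cells whose substrate-contact footprints grow
#' by the logistic law `A(t) = Amax / (1 + exp(-k (t - t0)))`, rendered as
#' discs with low-order Fourier boundary perturbation over a constant
#' background. Each cell's plateau intensity is fixed or drawn from
#' `intensityRange` — emulating the cell-to-cell brightness variability of
#' dye-labeled cells that makes real TIRF segmentation non-trivial. The
#' noise model is Poisson resampling of the clean image (shot noise,
#' optional) followed by additive Gaussian noise; ground-truth labels and
#' analytic areas are recorded before noise.
#'
#' @param cells list of [CellSimParams-class]; footprints at `Amax` must be
#'   pairwise disjoint (validated).
#' @param frames number of frames (>= 1).
#' @param frameInterval frame interval in seconds.
#' @param dim image size `c(rows, cols)` in pixels.
#' @param background background mean intensity.
#' @param gaussianSigma additive Gaussian noise sigma (0 disables).
#' @param poisson apply Poisson resampling?
#' @param pixelSize pixel size in micrometres.
#' @param intensityRange uniform range cells with `NA` intensity draw from;
#'   must lie strictly above `background`.
#' @param seed RNG seed for reproducibility; the same seed gives a
#'   bit-identical phantom. `NULL` uses (and advances) the current RNG.
#' @return A [PhantomStack-class].
#' @examples
#' ph <- simulateSpreadingStack(list(cellParams(c(16, 16), maxArea = 30,
#'                                              intensity = 400)),
#'                              frames = 3, dim = c(32, 32),
#'                              gaussianSigma = 0, poisson = FALSE, seed = 1)
#' groundTruthAreas(ph)
#' @export
simulateSpreadingStack <- function(cells, frames = 60, frameInterval = 5,
                                   dim = c(256, 256), background = 100,
                                   gaussianSigma = 30, poisson = TRUE,
                                   pixelSize = 0.5, intensityRange = c(300, 800),
                                   seed = NULL) {
  stopifnot(frames >= 1, frameInterval > 0, length(dim) == 2L,
            background >= 0, gaussianSigma >= 0, pixelSize > 0)
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  cells <- lapply(cells, function(cl) {
    stopifnot(is(cl, "CellSimParams")); cl
  })
  nC <- length(cells)
  if (any(intensityRange <= background))
    stop("intensityRange must lie strictly above the background mean")

  ## draw missing intensities, then the boundary shapes (in cell order)
  for (i in seq_len(nC)) {
    if (is.na(cells[[i]]@intensity))
      cells[[i]]@intensity <- stats::runif(1L, intensityRange[1L],
                                           intensityRange[2L])
    if (cells[[i]]@intensity <= background)
      stop("cell ", i, " intensity must exceed the background mean")
  }
  shapes <- lapply(cells, function(cl) .makeShape(cl@irregularity))

  ## pairwise disjointness at Amax
  if (nC >= 2L) {
    rmax <- vapply(seq_len(nC), function(i)
      sqrt(cells[[i]]@maxArea / pi) / pixelSize * .maxShapeFactor(shapes[[i]]),
      numeric(1L))
    for (i in seq_len(nC - 1L)) for (j in (i + 1L):nC) {
      dd <- sqrt(sum((cells[[i]]@center - cells[[j]]@center)^2))
      if (dd <= rmax[i] + rmax[j] + 2)
        stop(sprintf("cells %d and %d overlap at Amax (centres %.1f px apart, radii %.1f + %.1f px)",
                     i, j, dd, rmax[i], rmax[j]))
    }
  }

  d3 <- c(as.integer(dim), as.integer(frames))
  img <- array(background, dim = d3)
  labels <- array(0L, dim = d3)
  for (t in seq_len(frames)) {
    tSec <- (t - 1) * frameInterval
    for (i in seq_len(nC)) {
      cl <- cells[[i]]
      A <- .logisticArea(tSec, cl@maxArea, cl@rate, cl@midpoint)
      rpx <- sqrt(A / pi) / pixelSize
      m <- .cellMask(d3, cl@center, rpx, shapes[[i]])
      if (is.null(m)) next
      sub <- img[m$rows, m$cols, t]
      sub[m$inside] <- cl@intensity
      img[m$rows, m$cols, t] <- sub
      lsub <- labels[m$rows, m$cols, t]
      lsub[m$inside] <- i
      labels[m$rows, m$cols, t] <- lsub
    }
  }

  if (poisson)
    img <- array(as.numeric(stats::rpois(length(img), lambda = img)),
                 dim = d3)
  if (gaussianSigma > 0)
    img <- img + array(stats::rnorm(length(img), 0, gaussianSigma), dim = d3)
  img <- pmax(img, 0)

  tSec <- (seq_len(frames) - 1) * frameInterval
  analytic <- do.call(rbind, lapply(seq_len(nC), function(i) {
    data.frame(cell_label = i, frame = seq_len(frames) - 1L, time_s = tSec,
               area_um2 = .logisticArea(tSec, cells[[i]]@maxArea,
                                        cells[[i]]@rate, cells[[i]]@midpoint))
  }))
  if (is.null(analytic))
    analytic <- data.frame(cell_label = integer(), frame = integer(),
                           time_s = numeric(), area_um2 = numeric())

  new("PhantomStack",
      grid = ImageGrid(img, frameInterval = frameInterval,
                       pixelSize = pixelSize),
      truthLabels = SegmentationVolume(labels,
                                       provenance = list(source = "synthetic phantom",
                                                         seed = seed)),
      analyticAreas = analytic,
      cells = cells,
      noise = list(background = background, gaussianSigma = gaussianSigma,
                   poisson = poisson, shapes = shapes),
      seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
}

#' Draw default phantom cell parameters
#'
#' Places `nCells` cells on a regular grid over the image and draws their
#' logistic growth parameters from the package's default ranges: plateau
#' area uniform in 250–450 um^2, rate uniform in 0.010–0.020 /s, midpoint
#' uniform in 30–80 s — a cell landing with a few tens of um^2 of contact and
#' plateauing within a 5-minute recording. Intensities stay `NA` so the
#' simulator draws them per cell.
#'
#' @param nCells number of cells.
#' @param dim image size in pixels.
#' @param maxAreaRange,rateRange,midpointRange uniform draw ranges (set both
#'   ends equal for fixed parameters).
#' @param irregularity boundary perturbation amplitude for all cells.
#' @return A list of [CellSimParams-class].
#' @export
defaultPhantomCells <- function(nCells = 5, dim = c(256, 256),
                                maxAreaRange = c(250, 450),
                                rateRange = c(0.010, 0.020),
                                midpointRange = c(30, 80),
                                irregularity = 0.1) {
  nCells <- as.integer(nCells)
  stopifnot(nCells >= 1L)
  k <- ceiling(sqrt(nCells))
  rows <- ceiling(nCells / k)
  centers <- list()
  for (i in seq_len(nCells)) {
    ri <- (i - 1L) %/% k; ci <- (i - 1L) %% k
    centers[[i]] <- c((ri + 0.5) / rows * dim[1L], (ci + 0.5) / k * dim[2L])
  }
  lapply(seq_len(nCells), function(i)
    cellParams(center = centers[[i]],
               maxArea = stats::runif(1L, maxAreaRange[1L], maxAreaRange[2L]),
               rate = stats::runif(1L, rateRange[1L], rateRange[2L]),
               midpoint = stats::runif(1L, midpointRange[1L], midpointRange[2L]),
               intensity = NA_real_, irregularity = irregularity))
}

#' The package's default test phantom
#'
#' A 256 x 256 px stack of 60 frames at 5 s interval with 5 spreading cells:
#' background mean 100, per-cell plateau intensities drawn uniformly from
#' 300–800, Poisson shot noise on and additive Gaussian noise of sigma 30 —
#' conditions under which default segmentation succeeds but is not trivial.
#'
#' @param seed RNG seed; all draws (kinetic parameters, intensities, shapes,
#'   noise) derive from it, so equal seeds give bit-identical phantoms.
#' @param nCells,frames,dim,frameInterval,pixelSize,background,gaussianSigma,poisson,intensityRange
#'   overrides of the default phantom conditions.
#' @return A [PhantomStack-class].
#' @examples
#' ph <- defaultPhantom(seed = 7, frames = 3, dim = c(96, 96), nCells = 2)
#' ph
#' @export
defaultPhantom <- function(seed = NULL, nCells = 5, frames = 60,
                           dim = c(256, 256), frameInterval = 5,
                           pixelSize = 0.5, background = 100,
                           gaussianSigma = 30, poisson = TRUE,
                           intensityRange = c(300, 800)) {
  ## keep the cell layout disjoint on smaller fields of view by scaling the
  ## plateau-area range with the imaged area (unchanged at the 256 px, 0.5 um
  ## default)
  areaScale <- min(1, (min(dim) * pixelSize)^2 / (256 * 0.5)^2)
  build <- function() {
    cells <- defaultPhantomCells(nCells = nCells, dim = dim,
                                 maxAreaRange = c(250, 450) * areaScale)
    simulateSpreadingStack(cells, frames = frames,
                           frameInterval = frameInterval, dim = dim,
                           background = background,
                           gaussianSigma = gaussianSigma, poisson = poisson,
                           pixelSize = pixelSize,
                           intensityRange = intensityRange, seed = NULL)
  }
  ph <- if (is.null(seed)) build() else withr::with_seed(as.integer(seed), build())
  ph@seed <- if (is.null(seed)) NA_real_ else as.numeric(seed)
  ph
}

#' Pixel-count ground-truth areas of a phantom
#'
#' Counts the ground-truth label pixels with the same counting path as the
#' measurement side ([computeAreas()]), using the phantom's calibration.
#' For a phantom with no cells, the background row is reported instead of an
#' empty table.
#'
#' @param phantom a [PhantomStack-class].
#' @return An [AreaTable-class].
#' @export
groundTruthAreas <- function(phantom) {
  stopifnot(is(phantom, "PhantomStack"))
  anyCells <- length(phantom@cells) > 0L
  computeAreas(truthLabels(phantom),
               pixelArea = pixelArea(phantomGrid(phantom)),
               frameInterval = frameInterval(phantomGrid(phantom)),
               includeBackground = !anyCells)
}

#' Sample a seed annotation from a phantom's ground truth
#'
#' Stands in for the user's manual seed clicks: samples interior points of
#' each true cell region in its first visible frame (interior = the region
#' eroded by one pixel, falling back to the deepest pixel when erosion
#' empties it) plus background points farther than `margin` pixels from
#' every cell at any frame. Cell seeds are listed before background seeds.
#'
#' @param phantom a [PhantomStack-class] with at least one cell.
#' @param perCellSeedCount seeds sampled per cell.
#' @param nBackground background seeds sampled.
#' @param margin minimal distance (px) between a background seed and any
#'   cell pixel.
#' @param seed RNG seed for the sampling.
#' @return A [SeedSet-class].
#' @export
defaultSeedAnnotation <- function(phantom, perCellSeedCount = 5,
                                  nBackground = 20, margin = 5, seed = NULL) {
  stopifnot(is(phantom, "PhantomStack"), perCellSeedCount >= 1,
            nBackground >= 1)
  if (length(phantom@cells) == 0L)
    stop("phantom has no cells to seed")
  if (!is.null(seed)) withr::local_seed(as.integer(seed))
  labels <- segLabels(phantom)
  d <- dim(labels)
  t <- integer(); row <- integer(); col <- integer(); lab <- integer()
  for (i in seq_along(phantom@cells)) {
    perFrame <- colSums(matrix(labels == i, d[1L] * d[2L], d[3L]))
    tf <- which(perFrame > 0L)[1L]
    if (is.na(tf))
      stop("cell ", i, " has an empty region in every frame")
    mask <- labels[, , tf] == i
    core <- EBImage::erode(mask + 0, EBImage::makeBrush(3L, "box")) > 0
    if (!any(core)) {
      dm <- EBImage::distmap(mask + 0)
      core <- array(FALSE, dim(mask))
      core[which.max(dm)] <- TRUE
    }
    w <- which(core, arr.ind = TRUE)
    pick <- w[sample.int(nrow(w), min(perCellSeedCount, nrow(w))), ,
              drop = FALSE]
    t <- c(t, rep(tf, nrow(pick)))
    row <- c(row, pick[, 1L]); col <- c(col, pick[, 2L])
    lab <- c(lab, rep(i, nrow(pick)))
  }
  cellAny <- matrix(rowSums(matrix(labels > 0L, d[1L] * d[2L], d[3L])) > 0L,
                    d[1L], d[2L])
  far <- if (any(cellAny))
    EBImage::distmap((!cellAny) + 0) > margin
  else
    !cellAny
  wbg <- which(far)
  if (length(wbg) == 0L)
    stop("no background pixels farther than ", margin, " px from the cells")
  pick <- wbg[sample.int(length(wbg), min(nBackground, length(wbg)))]
  pr <- ((pick - 1L) %% d[1L]) + 1L
  pc <- ((pick - 1L) %/% d[1L]) + 1L
  SeedSet(t = c(t, rep(1L, length(pick))), row = c(row, pr),
          col = c(col, pc), label = c(lab, rep(0L, length(pick))))
}
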