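#' @import methods
NULL

## ---------------------------------------------------------------------------
## ImageGrid
## ---------------------------------------------------------------------------

#' ImageGrid: an intensity volume interpreted as a pixel graph
#'
#' Holds a (rows x cols x frames) array of non-negative fluorescence
#' intensities together with its physical calibration: the frame interval in
#' seconds and the pixel size in micrometres. Every pixel of the volume is a
#' node of the adjacency graph that [runIFT()] operates on.
#'
#' @slot values numeric array with `dim = c(rows, cols, frames)`; a single
#'   image is stored with `frames = 1`. Intensities are held in double
#'   precision regardless of the bit depth of the source file.
#' @slot frameInterval acquisition interval between frames, in seconds.
#' @slot pixelSize numeric of length 2, pixel height and width in micrometres.
#'
#' @seealso [ImageGrid()], [runIFT()], [readStack()]
#' @exportClass ImageGrid
setClass("ImageGrid",
  representation(values = "array", frameInterval = "numeric",
                 pixelSize = "numeric"))

setValidity("ImageGrid", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L)
    return("values must be a 3-d array (rows, cols, frames)")
  if (any(dim(v) < 1L))
    return("all dimensions must be >= 1")
  if (!all(is.finite(v)))
    return("all intensities must be finite")
  if (any(v < 0))
    return("intensities must be non-negative")
  if (length(object@frameInterval) != 1L || !is.finite(object@frameInterval) ||
      object@frameInterval <= 0)
    return("frameInterval must be a single positive number")
  if (length(object@pixelSize) != 2L || any(!is.finite(object@pixelSize)) ||
      any(object@pixelSize <= 0))
    return("pixelSize must be two positive numbers (height, width) in um")
  TRUE
})

#' Construct an ImageGrid
#'
#' @param values numeric matrix (a single frame) or 3-d array
#'   (rows, cols, frames).
#' @param frameInterval frame interval in seconds (default 5 s, the standard
#'   TIRF spreading acquisition rate).
#' @param pixelSize pixel size in micrometres; a single number is used for
#'   both pixel height and width.
#'
#' @return An [ImageGrid-class] object.
#' @examples
#' g <- ImageGrid(matrix(runif(64), 8, 8), frameInterval = 5, pixelSize = 0.5)
#' dim(g)
#' @export
ImageGrid <- function(values, frameInterval = 5, pixelSize = 1) {
  if (is.matrix(values))
    values <- array(values, dim = c(dim(values), 1L))
  storage.mode(values) <- "double"
  if (length(pixelSize) == 1L) pixelSize <- rep(pixelSize, 2L)
  new("ImageGrid", values = values, frameInterval = as.numeric(frameInterval),
      pixelSize = as.numeric(pixelSize))
}

## ---------------------------------------------------------------------------
## SeedSet
## ---------------------------------------------------------------------------

#' SeedSet: labeled seed pixels for the forest computation
#'
#' Seeds are the user-designated pixels from which label propagation starts:
#' each cell carries a unique positive integer label, the background carries
#' label 0. In-memory coordinates are 1-based `(t, row, col)`; the on-disk
#' CSV/JSON dialect (see [readSeedFile()]) is 0-based.
#'
#' The order of entries matters: when two seeds offer a pixel identical path
#' costs, the seed listed earlier in the set wins (the package's documented
#' deterministic tie rule).
#'
#' @slot coords integer matrix with columns `t`, `row`, `col` (1-based).
#' @slot label integer vector of per-entry labels (0 = background).
#'
#' @seealso [SeedSet()], [validateSeeds()], [defaultSeedAnnotation()]
#' @exportClass SeedSet
setClass("SeedSet", representation(coords = "matrix", label = "integer"))

setValidity("SeedSet", function(object) {
  co <- object@coords
  if (!is.integer(co) || ncol(co) != 3L ||
      !identical(colnames(co), c("t", "row", "col")))
    return("coords must be an integer matrix with columns t, row, col")
  if (nrow(co) != length(object@label))
    return("one label per coordinate required")
  if (nrow(co) == 0L)
    return("seed set must not be empty")
  if (any(!is.finite(co)) || any(co < 1L))
    return("coordinates must be positive integers (1-based)")
  if (any(object@label < 0L) || any(is.na(object@label)))
    return("labels must be non-negative integers")
  key <- paste(co[, 1L], co[, 2L], co[, 3L])
  conflict <- tapply(object@label, key, function(l) length(unique(l)) > 1L)
  if (any(conflict))
    return(sprintf("coordinate %s carries conflicting labels",
                   names(conflict)[which(conflict)[1L]]))
  if (!any(object@label == 0L))
    return("at least one background seed (label 0) is required")
  if (!any(object@label >= 1L))
    return("at least one cell seed (label >= 1) is required")
  TRUE
})

#' Construct a SeedSet
#'
#' @param t,row,col 1-based frame, row and column indices (integer vectors of
#'   equal length).
#' @param label non-negative integer labels; 0 marks background, each cell
#'   uses its own positive label.
#'
#' @return A [SeedSet-class] object. Exact duplicate entries (same coordinate,
#'   same label) are collapsed, keeping the earliest.
#' @examples
#' SeedSet(t = c(1, 1), row = c(4, 1), col = c(4, 1), label = c(1, 0))
#' @export
SeedSet <- function(t, row, col, label) {
  co <- cbind(t = as.integer(t), row = as.integer(row), col = as.integer(col))
  label <- as.integer(label)
  key <- paste(co[, 1L], co[, 2L], co[, 3L], label)
  keep <- !duplicated(key)
  new("SeedSet", coords = co[keep, , drop = FALSE], label = label[keep])
}

## ---------------------------------------------------------------------------
## Adjacency and cost configuration
## ---------------------------------------------------------------------------

#' AdjacencySpec: which pixels are graph neighbours
#'
#' @slot inPlane 4 or 8 (in-plane connectivity).
#' @slot temporal logical; if `TRUE`, each pixel is also linked to the same
#'   pixel in the previous and next frame.
#' @slot temporalScale non-negative multiplier applied to the weight of arcs
#'   that cross frames.
#'
#' @exportClass AdjacencySpec
setClass("AdjacencySpec",
  representation(inPlane = "integer", temporal = "logical",
                 temporalScale = "numeric"))

setValidity("AdjacencySpec", function(object) {
  if (!object@inPlane %in% c(4L, 8L))
    return("inPlane connectivity must be 4 or 8")
  if (length(object@temporal) != 1L || is.na(object@temporal))
    return("temporal must be TRUE or FALSE")
  if (length(object@temporalScale) != 1L || !is.finite(object@temporalScale) ||
      object@temporalScale < 0)
    return("temporalScale must be a single non-negative number")
  TRUE
})

#' Construct an AdjacencySpec
#'
#' Defaults: 4-connected in-plane neighbours plus temporal arcs to the same
#' pixel one frame earlier/later, with unscaled weights.
#'
#' @param inPlane 4 or 8.
#' @param temporal link pixels across adjacent frames?
#' @param temporalScale weight multiplier for cross-frame arcs (>= 0).
#' @return An [AdjacencySpec-class] object.
#' @export
AdjacencySpec <- function(inPlane = 4, temporal = TRUE, temporalScale = 1) {
  new("AdjacencySpec", inPlane = as.integer(inPlane),
      temporal = as.logical(temporal), temporalScale = as.numeric(temporalScale))
}

#' CostModel: how path costs accumulate along seed-to-pixel paths
#'
#' The arc weight between adjacent pixels is the absolute intensity
#' difference `|I(p) - I(q)|` (after optional Gaussian pre-smoothing), scaled
#' for cross-frame arcs by the adjacency's `temporalScale`. Two path-cost
#' rules are supported: `"max"` takes the largest arc weight along the path
#' (the watershed-like rule, robust to gradual intensity ramps inside a TIRF
#' footprint and the package default) and `"additive"` sums the weights.
#' Both rules are monotone non-decreasing under path extension, which is what
#' makes the forest computation exact.
#'
#' @slot rule `"max"` or `"additive"`.
#' @slot smoothSigma Gaussian pre-smoothing sigma in pixels applied per frame
#'   before arc weights are computed; 0 disables smoothing.
#' @slot seedHandicap path cost assigned to the trivial path at every seed.
#'
#' @exportClass CostModel
setClass("CostModel",
  representation(rule = "character", smoothSigma = "numeric",
                 seedHandicap = "numeric"))

setValidity("CostModel", function(object) {
  if (!object@rule %in% c("max", "additive"))
    return("rule must be 'max' or 'additive'")
  if (length(object@smoothSigma) != 1L || !is.finite(object@smoothSigma) ||
      object@smoothSigma < 0)
    return("smoothSigma must be a single non-negative number")
  if (length(object@seedHandicap) != 1L || !is.finite(object@seedHandicap) ||
      object@seedHandicap < 0)
    return("seedHandicap must be a single non-negative number")
  TRUE
})

#' Construct a CostModel
#'
#' @param rule path-cost rule, `"max"` (default) or `"additive"`.
#' @param smoothSigma Gaussian pre-smoothing sigma in pixels (default 0).
#' @param seedHandicap initial cost at seeds (default 0).
#' @return A [CostModel-class] object.
#' @export
CostModel <- function(rule = c("max", "additive"), smoothSigma = 0,
                      seedHandicap = 0) {
  new("CostModel", rule = match.arg(rule),
      smoothSigma = as.numeric(smoothSigma),
      seedHandicap = as.numeric(seedHandicap))
}

## ---------------------------------------------------------------------------
## IFTResult
## ---------------------------------------------------------------------------

#' IFTResult: the minimum-cost path forest
#'
#' The output of [runIFT()] / [bruteForceIFT()]: for every pixel, the label of
#' the winning seed, the optimal path cost, the predecessor pixel on an
#' optimal path, and the seed pixel (root) at which that path starts. All
#' maps are arrays with the grid's dimensions; `predMap`/`rootMap` store
#' 1-based linear indices into that array (`predMap` is 0 at roots).
#'
#' @slot labelMap integer array of winning labels.
#' @slot costMap numeric array of optimal path costs.
#' @slot predMap integer array of predecessor linear indices (0 = none).
#' @slot rootMap integer array of root linear indices.
#' @slot seeds the [SeedSet-class] used.
#' @slot adjacency the [AdjacencySpec-class] used.
#' @slot cost the [CostModel-class] used.
#'
#' @exportClass IFTResult
setClass("IFTResult",
  representation(labelMap = "array", costMap = "array", predMap = "array",
                 rootMap = "array", seeds = "SeedSet",
                 adjacency = "AdjacencySpec", cost = "CostModel"))

setValidity("IFTResult", function(object) {
  d <- dim(object@labelMap)
  if (!identical(d, dim(object@costMap)) || !identical(d, dim(object@predMap)) ||
      !identical(d, dim(object@rootMap)))
    return("all maps must share one shape")
  if (anyNA(object@labelMap))
    return("every node must carry a label")
  TRUE
})

## ---------------------------------------------------------------------------
## Segmentation configuration and result
## ---------------------------------------------------------------------------

#' SegmentationConfig: how a time-lapse volume is segmented
#'
#' Two modes are supported. `"volume3d"` (default) runs a single forest
#' computation over the full 2D+t graph, so seeds placed in one or several
#' frames label the whole recording at once. `"per_frame_propagate"` segments
#' frame 1 from the user's seeds and then derives each next frame's seeds by
#' eroding the previous frame's labeled regions ([propagateSeeds()]), which
#' suits long drifting acquisitions.
#'
#' @slot mode `"volume3d"` or `"per_frame_propagate"`.
#' @slot adjacency an [AdjacencySpec-class].
#' @slot cost a [CostModel-class].
#' @slot erosionRadius erosion radius in pixels used by seed propagation
#'   (guards against leaking seeds across moving boundaries; default 2).
#'
#' @exportClass SegmentationConfig
setClass("SegmentationConfig",
  representation(mode = "character", adjacency = "AdjacencySpec",
                 cost = "CostModel", erosionRadius = "integer"))

setValidity("SegmentationConfig", function(object) {
  if (!object@mode %in% c("volume3d", "per_frame_propagate"))
    return("mode must be 'volume3d' or 'per_frame_propagate'")
  if (length(object@erosionRadius) != 1L || is.na(object@erosionRadius) ||
      object@erosionRadius < 0L)
    return("erosionRadius must be a single integer >= 0")
  TRUE
})

#' Construct a SegmentationConfig
#'
#' @param mode `"volume3d"` (default) or `"per_frame_propagate"`.
#' @param adjacency an [AdjacencySpec-class].
#' @param cost a [CostModel-class].
#' @param erosionRadius seed-propagation erosion radius in pixels.
#' @return A [SegmentationConfig-class] object.
#' @export
SegmentationConfig <- function(mode = c("volume3d", "per_frame_propagate"),
                               adjacency = AdjacencySpec(),
                               cost = CostModel(), erosionRadius = 2) {
  new("SegmentationConfig", mode = match.arg(mode), adjacency = adjacency,
      cost = cost, erosionRadius = as.integer(erosionRadius))
}

#' SegmentationVolume: a labeled 2D+t volume
#'
#' @slot labels integer array with the grid's dimensions; 0 = background,
#'   positive values are the seed labels verbatim.
#' @slot provenance list recording how the volume was produced (mode, cost and
#'   adjacency parameters, seed digest, package version).
#'
#' @exportClass SegmentationVolume
setClass("SegmentationVolume",
  representation(labels = "array", provenance = "list"))

setValidity("SegmentationVolume", function(object) {
  if (length(dim(object@labels)) != 3L)
    return("labels must be a 3-d array (rows, cols, frames)")
  if (anyNA(object@labels) || any(object@labels < 0L))
    return("labels must be non-negative integers with no missing values")
  TRUE
})

#' Construct a SegmentationVolume
#'
#' @param labels integer matrix (one frame) or 3-d array of labels.
#' @param provenance optional provenance list.
#' @return A [SegmentationVolume-class] object.
#' @export
SegmentationVolume <- function(labels, provenance = list()) {
  if (is.matrix(labels)) labels <- array(labels, dim = c(dim(labels), 1L))
  storage.mode(labels) <- "integer"
  new("SegmentationVolume", labels = labels, provenance = provenance)
}

## ---------------------------------------------------------------------------
## AreaTable and SpreadingCurve
## ---------------------------------------------------------------------------

#' AreaTable: per-cell, per-frame contact areas
#'
#' One row per (cell label, frame) pair; `frame` is the 0-based acquisition
#' index so `time_s = frame * frameInterval`. `area_um2` is exactly
#' `area_px * pixelArea`. A label absent from a frame gets an explicit
#' zero-area row rather than a missing one.
#'
#' @slot data data.frame with columns `cell_label`, `frame`, `time_s`,
#'   `area_px`, `area_um2`.
#' @slot pixelArea pixel area in square micrometres.
#' @slot frameInterval frame interval in seconds.
#'
#' @seealso [computeAreas()], [exportAreasCSV()], [aggregateCurves()]
#' @exportClass AreaTable
setClass("AreaTable",
  representation(data = "data.frame", pixelArea = "numeric",
                 frameInterval = "numeric"))

setValidity("AreaTable", function(object) {
  d <- object@data
  need <- c("cell_label", "frame", "time_s", "area_px", "area_um2")
  if (!identical(names(d), need))
    return(paste("data must have columns", paste(need, collapse = ", ")))
  if (nrow(d) > 0L) {
    if (any(d$area_px < 0) || any(d$area_px != round(d$area_px)))
      return("area_px must be non-negative integers")
    if (max(abs(d$area_um2 - d$area_px * object@pixelArea)) > 1e-8)
      return("area_um2 must equal area_px * pixelArea")
    if (anyDuplicated(d[, c("cell_label", "frame")]))
      return("one row per (cell_label, frame) pair required")
  }
  if (object@pixelArea <= 0 || object@frameInterval <= 0)
    return("calibration must be positive")
  TRUE
})

#' Construct an AreaTable
#'
#' @param data data.frame with columns `cell_label`, `frame`, `time_s`,
#'   `area_px`, `area_um2`.
#' @param pixelArea pixel area in square micrometres.
#' @param frameInterval frame interval in seconds.
#' @return An [AreaTable-class] object.
#' @export
AreaTable <- function(data, pixelArea, frameInterval) {
  new("AreaTable", data = data, pixelArea = as.numeric(pixelArea),
      frameInterval = as.numeric(frameInterval))
}

#' SpreadingCurve: cohort mean-area kinetics
#'
#' Per aligned frame: the number of cells contributing, the mean contact area
#' and its standard error (sample standard deviation / sqrt(n); flagged `NA`
#' when fewer than two cells contribute).
#'
#' @slot data data.frame with columns `frame`, `time_s`, `n`, `mean_um2`,
#'   `sem_um2`.
#' @slot frameInterval frame interval in seconds.
#' @slot group group name.
#' @slot alignment alignment rule used.
#'
#' @seealso [aggregateCurves()], [fitSpreadingCurve()]
#' @exportClass SpreadingCurve
setClass("SpreadingCurve",
  representation(data = "data.frame", frameInterval = "numeric",
                 group = "character", alignment = "character"))

## ---------------------------------------------------------------------------
## Synthetic phantoms
## ---------------------------------------------------------------------------

#' CellSimParams: parameters of one simulated spreading cell
#'
#' The footprint area follows a logistic law
#' `A(t) = Amax / (1 + exp(-k (t - t0)))`, the sigmoid-to-plateau shape
#' typical of cell-spreading recordings. The footprint is a disc whose radius
#' is modulated by a low-order Fourier perturbation so cells are not
#' perfectly circular, and the cell's plateau intensity is either fixed or
#' drawn per cell from the simulator's uniform range — emulating the varying
#' fluorescence brightness across labeled cells that makes real segmentation
#' non-trivial.
#'
#' @slot center numeric (row, col) centre in pixels.
#' @slot maxArea plateau area `Amax` in square micrometres.
#' @slot rate logistic growth rate `k` in 1/s.
#' @slot midpoint logistic midpoint `t0` in seconds.
#' @slot intensity mean plateau intensity (arbitrary units); `NA` means "draw
#'   from the simulator's intensity range".
#' @slot irregularity radial perturbation amplitude in `[0, 1)`.
#'
#' @exportClass CellSimParams
setClass("CellSimParams",
  representation(center = "numeric", maxArea = "numeric", rate = "numeric",
                 midpoint = "numeric", intensity = "numeric",
                 irregularity = "numeric"))

setValidity("CellSimParams", function(object) {
  if (length(object@center) != 2L || any(!is.finite(object@center)))
    return("center must be finite (row, col)")
  if (object@maxArea <= 0) return("maxArea must be > 0")
  if (object@rate <= 0) return("rate must be > 0")
  if (!is.finite(object@midpoint)) return("midpoint must be finite")
  if (!is.na(object@intensity) && object@intensity <= 0)
    return("intensity must be positive (or NA to draw)")
  if (object@irregularity < 0 || object@irregularity >= 1)
    return("irregularity must lie in [0, 1)")
  TRUE
})

#' Construct CellSimParams
#'
#' @param center numeric (row, col) centre in pixels.
#' @param maxArea plateau area in um^2.
#' @param rate logistic rate in 1/s.
#' @param midpoint logistic midpoint in seconds.
#' @param intensity plateau intensity; `NA` to draw from the simulator range.
#' @param irregularity radial perturbation amplitude in `[0, 1)`.
#' @return A [CellSimParams-class] object.
#' @export
cellParams <- function(center, maxArea = 350, rate = 0.015, midpoint = 50,
                       intensity = NA_real_, irregularity = 0.1) {
  new("CellSimParams", center = as.numeric(center),
      maxArea = as.numeric(maxArea), rate = as.numeric(rate),
      midpoint = as.numeric(midpoint), intensity = as.numeric(intensity),
      irregularity = as.numeric(irregularity))
}

#' PhantomStack: a simulated spreading stack with ground truth
#'
#' @slot grid the noisy [ImageGrid-class].
#' @slot truthLabels the pre-noise ground-truth [SegmentationVolume-class].
#' @slot analyticAreas data.frame of exact logistic areas per cell and frame
#'   (`cell_label`, `frame`, `time_s`, `area_um2`), before discretization.
#' @slot cells list of [CellSimParams-class] (with drawn intensities filled in).
#' @slot noise list recording the noise model (background mean, Gaussian
#'   sigma, Poisson on/off).
#' @slot seed RNG seed used (NA if none was supplied).
#'
#' @seealso [simulateSpreadingStack()], [groundTruthAreas()],
#'   [defaultSeedAnnotation()]
#' @exportClass PhantomStack
setClass("PhantomStack",
  representation(grid = "ImageGrid", truthLabels = "SegmentationVolume",
                 analyticAreas = "data.frame", cells = "list",
                 noise = "list", seed = "numeric"))
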