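## Generics and accessors: slot access stays behind these functions.

#' @describeIn ImageGrid the intensity array (rows x cols x frames)
#' @param x,object an object of the documented class
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @export
setMethod("gridValues", "ImageGrid", function(x) x@values)

#' @describeIn ImageGrid number of frames
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @export
setMethod("nFrames", "ImageGrid", function(x) dim(x@values)[3L])

#' @export
setMethod("nFrames", "SegmentationVolume", function(x) dim(x@labels)[3L])

#' @describeIn ImageGrid frame interval in seconds
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))

#' @export
setMethod("frameInterval", "ImageGrid", function(x) x@frameInterval)

#' @export
setMethod("frameInterval", "AreaTable", function(x) x@frameInterval)

#' @export
setMethod("frameInterval", "SpreadingCurve", function(x) x@frameInterval)

#' @describeIn ImageGrid pixel (height, width) in micrometres
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @export
setMethod("pixelSize", "ImageGrid", function(x) x@pixelSize)

#' @describeIn ImageGrid pixel area in square micrometres
#' @export
setGeneric("pixelArea", function(x) standardGeneric("pixelArea"))

#' @export
setMethod("pixelArea", "ImageGrid", function(x) prod(x@pixelSize))

#' @export
setMethod("pixelArea", "AreaTable", function(x) x@pixelArea)

#' @export
setMethod("dim", "ImageGrid", function(x) dim(x@values))

#' @export
setMethod("dim", "SegmentationVolume", function(x) dim(x@labels))

#' @describeIn SeedSet seed coordinates, 1-based (t, row, col) matrix
#' @export
setGeneric("seedCoords", function(x) standardGeneric("seedCoords"))

#' @export
setMethod("seedCoords", "SeedSet", function(x) x@coords)

#' @describeIn SeedSet per-entry labels (0 = background)
#' @export
setGeneric("seedLabels", function(x) standardGeneric("seedLabels"))

#' @export
setMethod("seedLabels", "SeedSet", function(x) x@label)

#' @export
setMethod("length", "SeedSet", function(x) nrow(x@coords))

#' @describeIn IFTResult winning label per pixel
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @export
setMethod("labelMap", "IFTResult", function(x) x@labelMap)

#' @describeIn IFTResult optimal path cost per pixel
#' @export
setGeneric("costMap", function(x) standardGeneric("costMap"))

#' @export
setMethod("costMap", "IFTResult", function(x) x@costMap)

#' @describeIn IFTResult predecessor linear index per pixel (0 at roots)
#' @export
setGeneric("predMap", function(x) standardGeneric("predMap"))

#' @export
setMethod("predMap", "IFTResult", function(x) x@predMap)

#' @describeIn IFTResult winning seed pixel (linear index) per pixel
#' @export
setGeneric("rootMap", function(x) standardGeneric("rootMap"))

#' @export
setMethod("rootMap", "IFTResult", function(x) x@rootMap)

#' @describeIn SegmentationVolume the integer label array
#' @export
setGeneric("segLabels", function(x) standardGeneric("segLabels"))

#' @export
setMethod("segLabels", "SegmentationVolume", function(x) x@labels)

#' @export
setMethod("segLabels", "PhantomStack", function(x) x@truthLabels@labels)

#' @describeIn SegmentationVolume provenance record of the run
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @export
setMethod("provenance", "SegmentationVolume", function(x) x@provenance)

#' @describeIn AreaTable the underlying data.frame
#' @export
setGeneric("areaData", function(x) standardGeneric("areaData"))

#' @export
setMethod("areaData", "AreaTable", function(x) x@data)

#' @describeIn SpreadingCurve the underlying data.frame
#' @export
setGeneric("curveData", function(x) standardGeneric("curveData"))

#' @export
setMethod("curveData", "SpreadingCurve", function(x) x@data)

#' @describeIn PhantomStack the noisy image grid
#' @export
setGeneric("phantomGrid", function(x) standardGeneric("phantomGrid"))

#' @export
setMethod("phantomGrid", "PhantomStack", function(x) x@grid)

#' @describeIn PhantomStack the ground-truth label volume
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))

#' @export
setMethod("truthLabels", "PhantomStack", function(x) x@truthLabels)

#' @describeIn PhantomStack exact logistic areas per cell and frame
#' @export
setGeneric("analyticAreas", function(x) standardGeneric("analyticAreas"))

#' @export
setMethod("analyticAreas", "PhantomStack", function(x) x@analyticAreas)

#' @describeIn PhantomStack the simulated cell parameter list
#' @export
setGeneric("phantomCells", function(x) standardGeneric("phantomCells"))

#' @export
setMethod("phantomCells", "PhantomStack", function(x) x@cells)

## show methods -------------------------------------------------------------

setMethod("show", "ImageGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("ImageGrid: %d x %d px, %d frame(s) @ %g s, pixel %g x %g um\n",
              d[1L], d[2L], d[3L], object@frameInterval,
              object@pixelSize[1L], object@pixelSize[2L]))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(object@values), max(object@values)))
})

setMethod("show", "SeedSet", function(object) {
  lab <- object@label
  cat(sprintf("SeedSet: %d entries; %d cell label(s) (%s), %d background seed(s)\n",
              length(lab), length(unique(lab[lab > 0L])),
              paste(sort(unique(lab[lab > 0L])), collapse = ", "),
              sum(lab == 0L)))
})

setMethod("show", "IFTResult", function(object) {
  d <- dim(object@labelMap)
  cat(sprintf("IFTResult: %d x %d x %d forest, %s path cost, labels {%s}\n",
              d[1L], d[2L], d[3L], object@cost@rule,
              paste(sort(unique(as.vector(object@labelMap))), collapse = ", ")))
})

setMethod("show", "SegmentationVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("SegmentationVolume: %d x %d x %d, labels {%s}\n",
              d[1L], d[2L], d[3L],
              paste(sort(unique(as.vector(object@labels))), collapse = ", ")))
})

setMethod("show", "AreaTable", function(object) {
  cat(sprintf("AreaTable: %d cell(s) x %d frame(s), pixel area %g um^2, interval %g s\n",
              length(unique(object@data$cell_label)),
              length(unique(object@data$frame)),
              object@pixelArea, object@frameInterval))
  if (nrow(object@data) > 0L) print(utils::head(object@data, 4L))
})

setMethod("show", "SpreadingCurve", function(object) {
  cat(sprintf("SpreadingCurve '%s': %d frame(s), n up to %d cells, alignment %s\n",
              object@group, nrow(object@data),
              if (nrow(object@data)) max(object@data$n) else 0L,
              object@alignment))
})

setMethod("show", "PhantomStack", function(object) {
  d <- dim(object@grid@values)
  cat(sprintf("PhantomStack: %d x %d x %d, %d cell(s), bg %g, sigma %g, Poisson %s\n",
              d[1L], d[2L], d[3L], length(object@cells),
              object@noise$background, object@noise$gaussianSigma,
              if (isTRUE(object@noise$poisson)) "on" else "off"))
})

setMethod("show", "CellSimParams", function(object) {
  cat(sprintf("CellSimParams: centre (%g, %g), Amax %g um^2, k %g /s, t0 %g s\n",
              object@center[1L], object@center[2L], object@maxArea,
              object@rate, object@midpoint))
})
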