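## Whole-volume segmentation front end on top of the forest core.

#' Validate seeds against a grid
#'
#' Reporting counterpart of the hard checks in [runIFT()]: lists
#' out-of-bounds entries, coordinates carrying conflicting labels, and
#' missing background/cell seeds. The report is empty exactly when the seeds
#' are usable for the given grid.
#'
#' @param grid an [ImageGrid-class].
#' @param seeds a [SeedSet-class], or a raw data.frame with columns
#'   `t`, `row`, `col`, `label` (1-based coordinates) so that files that do
#'   not even form a valid seed set can still be reported on.
#' @return A data.frame with columns `entry`, `type`, `message`;
#'   zero rows iff valid.
#' @examples
#' g <- ImageGrid(matrix(0, 4, 4))
#' validateSeeds(g, data.frame(t = 1, row = 9, col = 1, label = 1))
#' @export
validateSeeds <- function(grid, seeds) {
  stopifnot(is(grid, "ImageGrid"))
  if (is(seeds, "SeedSet")) {
    co <- seedCoords(seeds); lab <- seedLabels(seeds)
  } else {
    seeds <- as.data.frame(seeds)
    stopifnot(all(c("t", "row", "col", "label") %in% names(seeds)))
    co <- cbind(t = as.integer(seeds$t), row = as.integer(seeds$row),
                col = as.integer(seeds$col))
    lab <- as.integer(seeds$label)
  }
  rep <- .seedBoundsReport(co, lab, dim(grid))
  key <- paste(co[, 1L], co[, 2L], co[, 3L])
  for (k in unique(key[duplicated(key)])) {
    i <- which(key == k)
    if (length(unique(lab[i])) > 1L)
      rep <- rbind(rep, data.frame(
        entry = i[1L], type = "conflicting_labels",
        message = sprintf("entries %s share coordinate (%s) but carry labels %s",
                          paste(i, collapse = ","), k,
                          paste(lab[i], collapse = ",")),
        stringsAsFactors = FALSE))
  }
  if (!any(lab == 0L))
    rep <- rbind(rep, data.frame(entry = NA_integer_, type = "missing_background",
                                 message = "no background seed (label 0)",
                                 stringsAsFactors = FALSE))
  if (!any(lab >= 1L))
    rep <- rbind(rep, data.frame(entry = NA_integer_, type = "missing_cell",
                                 message = "no cell seed (label >= 1)",
                                 stringsAsFactors = FALSE))
  rep
}

#' Derive next-frame seeds from a segmented frame
#'
#' Seed-propagation step of the per-frame segmentation mode: each label's
#' region in the previous frame is eroded by `radius` pixels (a square
#' structuring element of side `2*radius + 1`) and the surviving pixels
#' become that label's seeds for the next frame. Erosion keeps seeds clear of
#' moving boundaries. If erosion empties a region, the region's maximal
#' interior point (the pixel deepest inside it, by distance transform) is
#' kept as a single fallback seed so the label is not lost.
#'
#' @param prevLabels integer label matrix of the previous frame (0 =
#'   background).
#' @param radius erosion radius in pixels (>= 0; 0 keeps every labeled pixel).
#' @param frame value to store in the seeds' `t` column (default 1, i.e. the
#'   seeds address a single-frame grid).
#' @return A [SeedSet-class] with cell labels first and background last.
#' @export
propagateSeeds <- function(prevLabels, radius = 2, frame = 1L) {
  stopifnot(is.matrix(prevLabels), radius >= 0)
  radius <- as.integer(radius)
  labs <- sort(unique(as.vector(prevLabels)))
  labs <- c(labs[labs > 0L], 0L)  # cells first, background last
  t <- integer(); row <- integer(); col <- integer(); lab <- integer()
  for (l in labs) {
    mask <- prevLabels == l
    if (!any(mask)) next
    core <- mask
    if (radius > 0L) {
      core <- EBImage::erode(mask + 0,
                             EBImage::makeBrush(2L * radius + 1L, "box")) > 0
    }
    if (!any(core)) {
      dm <- EBImage::distmap(mask + 0)
      core <- array(FALSE, dim(mask))
      core[which.max(dm)] <- TRUE
    }
    w <- which(core, arr.ind = TRUE)
    t <- c(t, rep(as.integer(frame), nrow(w)))
    row <- c(row, w[, 1L]); col <- c(col, w[, 2L])
    lab <- c(lab, rep(as.integer(l), nrow(w)))
  }
  SeedSet(t = t, row = row, col = col, label = lab)
}

.seedDigest <- function(seeds) {
  f <- tempfile(fileext = ".csv")
  on.exit(unlink(f))
  writeSeedCSV(seeds, f)
  unname(tools::md5sum(f))
}

.configProvenance <- function(config, seeds) {
  list(mode = config@mode,
       adjacency = list(inPlane = config@adjacency@inPlane,
                        temporal = config@adjacency@temporal,
                        temporalScale = config@adjacency@temporalScale),
       cost = list(rule = config@cost@rule,
                   smoothSigma = config@cost@smoothSigma,
                   seedHandicap = config@cost@seedHandicap),
       erosionRadius = config@erosionRadius,
       seedDigest = .seedDigest(seeds),
       package = "iftseg",
       version = as.character(utils::packageVersion("iftseg")))
}

#' Segment a time-lapse volume from seeds
#'
#' Turns a stack plus a seed annotation into a full label volume. In
#' `"volume3d"` mode (default) a single forest computation runs over the
#' whole 2D+t graph, so seeds placed in one or several frames classify every
#' frame at once via the temporal arcs. In `"per_frame_propagate"` mode
#' frame 1 is segmented from the seeds placed in it, and each subsequent
#' frame is seeded from the eroded regions of the previous result
#' ([propagateSeeds()]), keeping one consistent label per cell across frames.
#'
#' @param grid an [ImageGrid-class].
#' @param seeds a [SeedSet-class].
#' @param config a [SegmentationConfig-class].
#' @return A [SegmentationVolume-class]; its provenance records the
#'   configuration, a digest of the seeds and the package version so a run
#'   can be reproduced exactly.
#' @examples
#' ph <- defaultPhantom(seed = 1, frames = 4, dim = c(64, 64), nCells = 1)
#' seeds <- defaultSeedAnnotation(ph, seed = 2)
#' seg <- segmentVolume(phantomGrid(ph), seeds)
#' table(segLabels(seg)[, , 1])
#' @export
segmentVolume <- function(grid, seeds, config = SegmentationConfig()) {
  stopifnot(is(grid, "ImageGrid"), is(seeds, "SeedSet"),
            is(config, "SegmentationConfig"))
  .checkSeedsInGrid(seeds, grid)
  prov <- .configProvenance(config, seeds)
  d <- dim(grid)

  if (config@mode == "volume3d") {
    res <- runIFT(grid, seeds, config@adjacency, config@cost)
    return(new("SegmentationVolume", labels = labelMap(res),
               provenance = prov))
  }

  ## per_frame_propagate
  sc <- seedCoords(seeds); slab <- seedLabels(seeds)
  first <- sc[, "t"] == 1L
  if (!any(first & slab >= 1L))
    stop("per_frame_propagate requires cell seeds in the first frame",
         call. = FALSE)
  if (any(!first))
    warning("per_frame_propagate uses only first-frame seeds; ",
            sum(!first), " seed(s) in later frames ignored")
  frameAdj <- AdjacencySpec(inPlane = config@adjacency@inPlane,
                            temporal = FALSE,
                            temporalScale = config@adjacency@temporalScale)
  labels <- array(0L, dim = d)
  cur <- SeedSet(t = rep(1L, sum(first)), row = sc[first, "row"],
                 col = sc[first, "col"], label = slab[first])
  expected <- sort(unique(slab[slab >= 1L]))
  for (t in seq_len(d[3L])) {
    fg <- ImageGrid(grid@values[, , t, drop = FALSE],
                    frameInterval = grid@frameInterval,
                    pixelSize = grid@pixelSize)
    res <- runIFT(fg, cur, frameAdj, config@cost)
    fl <- labelMap(res)[, , 1L]
    labels[, , t] <- fl
    present <- unique(as.vector(fl))
    lost <- setdiff(expected, present)
    if (length(lost) > 0L) {
      warning(sprintf("frame %d: label(s) %s vanished and are dropped from later frames",
                      t, paste(lost, collapse = ", ")))
      expected <- setdiff(expected, lost)
      if (length(expected) == 0L)
        stop("all cell labels vanished during propagation", call. = FALSE)
    }
    if (t < d[3L])
      cur <- propagateSeeds(fl, radius = config@erosionRadius, frame = 1L)
  }
  new("SegmentationVolume", labels = labels, provenance = prov)
}
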