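## File I/O: multi-page TIFF stacks, seed CSV/JSON, provenance JSON.

#' Read a multi-page TIFF stack
#'
#' Reads a single-channel multi-page TIFF (8/16-bit integer or 32-bit float)
#' into an [ImageGrid-class], pages in acquisition order. Calibration is
#' taken from the arguments, never guessed from TIFF tags (resolution tags
#' are unreliable across writers).
#'
#' @param path TIFF file path.
#' @param frameInterval frame interval in seconds.
#' @param pixelSize pixel size in micrometres.
#' @return An [ImageGrid-class].
#' @export
readStack <- function(path, frameInterval = 5, pixelSize = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("cannot read TIFF ", path, ": ",
                                             conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  for (i in seq_along(pages)) {
    if (length(dim(pages[[i]])) == 3L) {
      if (dim(pages[[i]])[3L] > 1L)
        stop("unsupported format: page ", i,
             " has multiple channels (RGB/multi-channel TIFF)", call. = FALSE)
      pages[[i]] <- pages[[i]][, , 1L]
    }
  }
  d <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) identical(dim(p), d), logical(1L))))
    stop("TIFF pages differ in size")
  v <- array(0, dim = c(d, length(pages)))
  for (i in seq_along(pages)) v[, , i] <- pages[[i]]
  ImageGrid(v, frameInterval = frameInterval, pixelSize = pixelSize)
}

#' Write a stack as multi-page integer TIFF
#'
#' Values must be non-negative integers not exceeding the chosen bit depth;
#' 16-bit data round-trip exactly through [readStack()].
#'
#' @param x an [ImageGrid-class], [SegmentationVolume-class] or numeric
#'   array/matrix.
#' @param path destination file path.
#' @param bitsPerSample 8 or 16.
#' @return The path, invisibly.
#' @export
writeStack <- function(x, path, bitsPerSample = 16) {
  v <- if (is(x, "ImageGrid")) gridValues(x)
       else if (is(x, "SegmentationVolume")) segLabels(x)
       else x
  if (is.matrix(v)) v <- array(v, dim = c(dim(v), 1L))
  stopifnot(bitsPerSample %in% c(8, 16))
  scale <- 2^bitsPerSample - 1
  if (any(v < 0) || any(v > scale))
    stop("values must lie in [0, ", scale, "] for ", bitsPerSample,
         "-bit output")
  if (any(v != round(v)))
    stop("values must be integers for integer TIFF output")
  pages <- lapply(seq_len(dim(v)[3L]), function(t) v[, , t] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bitsPerSample))
  invisible(path)
}

#' Write a label volume as 16-bit multi-page TIFF
#'
#' Label values are written verbatim (0 = background), so they survive a
#' round trip through [readLabelTIFF()] exactly.
#'
#' @param seg a [SegmentationVolume-class].
#' @param path destination file path.
#' @return The path, invisibly.
#' @export
writeLabelTIFF <- function(seg, path) {
  stopifnot(is(seg, "SegmentationVolume"))
  if (max(segLabels(seg)) > 65535L)
    stop("labels exceed the 16-bit range")
  writeStack(segLabels(seg), path, bitsPerSample = 16)
}

#' Read a label volume from TIFF
#'
#' @param path a label TIFF written by [writeLabelTIFF()].
#' @return A [SegmentationVolume-class].
#' @export
readLabelTIFF <- function(path) {
  g <- readStack(path, frameInterval = 1, pixelSize = 1)
  SegmentationVolume(array(as.integer(round(gridValues(g))),
                           dim = dim(g)),
                     provenance = list(source = path))
}

## Parse a raw seed table (already data.frame) with 0-based file coordinates
## into a 1-based data.frame, with per-row error reporting.
.seedRawFromDF <- function(df, where) {
  need <- c("t", "row", "col", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("seed file ", where, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0L)
    stop("seed file ", where, " contains no seeds", call. = FALSE)
  for (cn in need) {
    x <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(!is.finite(x) | x != round(x))
    if (length(bad) > 0L)
      stop(sprintf("seed file %s: non-integer '%s' at data line %d",
                   where, cn, bad[1L]), call. = FALSE)
    df[[cn]] <- as.integer(x)
  }
  data.frame(t = df$t + 1L, row = df$row + 1L, col = df$col + 1L,
             label = df$label)
}

.readSeedRaw <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  isJSON <- grepl("\\.json$", path, ignore.case = TRUE) ||
    grepl("^\\s*[\\[{]", readChar(path, 1L, useBytes = TRUE))
  df <- if (isJSON) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, colClasses = "character")
  }
  .seedRawFromDF(df, path)
}

#' Read a seed annotation file
#'
#' Accepts the CSV dialect (header `t,row,col,label`) or a JSON array of
#' records with the same fields; both use 0-based `t`, `row`, `col`. The two
#' encodings of the same seeds parse to identical seed sets. Parse errors
#' name the offending line; validation errors (conflicting labels, missing
#' background or cell seeds, and — when `grid` is given — out-of-bounds
#' coordinates) are raised with the offending entry.
#'
#' @param path seed file path (.csv or .json).
#' @param grid optional [ImageGrid-class] for bounds checking.
#' @return A [SeedSet-class].
#' @export
readSeedFile <- function(path, grid = NULL) {
  raw <- .readSeedRaw(path)
  seeds <- SeedSet(t = raw$t, row = raw$row, col = raw$col,
                   label = raw$label)
  if (!is.null(grid)) .checkSeedsInGrid(seeds, grid)
  seeds
}

#' Write seeds as CSV (0-based dialect)
#'
#' @param seeds a [SeedSet-class].
#' @param path destination file path.
#' @return The path, invisibly.
#' @export
writeSeedCSV <- function(seeds, path) {
  stopifnot(is(seeds, "SeedSet"))
  co <- seedCoords(seeds)
  lines <- c("t,row,col,label",
             sprintf("%d,%d,%d,%d", co[, "t"] - 1L, co[, "row"] - 1L,
                     co[, "col"] - 1L, seedLabels(seeds)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write seeds as JSON (0-based dialect)
#'
#' @inheritParams writeSeedCSV
#' @return The path, invisibly.
#' @export
writeSeedJSON <- function(seeds, path) {
  stopifnot(is(seeds, "SeedSet"))
  co <- seedCoords(seeds)
  df <- data.frame(t = co[, "t"] - 1L, row = co[, "row"] - 1L,
                   col = co[, "col"] - 1L, label = seedLabels(seeds))
  jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

.writeProvenance <- function(path, prov) {
  jsonlite::write_json(prov, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
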