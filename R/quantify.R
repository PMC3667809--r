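## Per-cell area quantification, CSV export, cohort curves and the small
## auxiliary numerics (pooled t, blot loading normalization, R/R0 traces).

#' Quantify per-cell contact areas per frame
#'
#' Counts, for every frame, the pixels carrying each cell label and converts
#' them to square micrometres via the pixel-area calibration. Every cell
#' label present anywhere in the volume gets a row in every frame — an
#' explicit zero when absent — so traces have no holes. Background (label 0)
#' is excluded unless requested; with it included, the per-frame areas sum
#' exactly to the frame's pixel count.
#'
#' @param seg a [SegmentationVolume-class] (or plain integer array/matrix of
#'   labels).
#' @param pixelArea pixel area in square micrometres (> 0).
#' @param frameInterval frame interval in seconds (> 0).
#' @param includeBackground also report label 0?
#' @return An [AreaTable-class] with rows sorted by (cell_label, frame);
#'   `frame` is 0-based so `time_s = frame * frameInterval`.
#' @examples
#' seg <- SegmentationVolume(matrix(1L, 10, 10))
#' areaData(computeAreas(seg, pixelArea = 1, frameInterval = 5))
#' @export
computeAreas <- function(seg, pixelArea = 1, frameInterval = 5,
                         includeBackground = FALSE) {
  stopifnot(pixelArea > 0, frameInterval > 0)
  labels <- if (is(seg, "SegmentationVolume")) segLabels(seg) else seg
  if (is.matrix(labels)) labels <- array(labels, dim = c(dim(labels), 1L))
  storage.mode(labels) <- "integer"
  d <- dim(labels)
  labs <- sort(unique(as.vector(labels)))
  if (!includeBackground) labs <- labs[labs > 0L]
  if (length(labs) == 0L) {
    empty <- data.frame(cell_label = integer(), frame = integer(),
                        time_s = numeric(), area_px = integer(),
                        area_um2 = numeric())
    return(AreaTable(empty, pixelArea = pixelArea,
                     frameInterval = frameInterval))
  }
  rows <- vector("list", d[3L])
  for (t in seq_len(d[3L])) {
    fl <- labels[, , t]
    cnt <- vapply(labs, function(l) sum(fl == l), integer(1L))
    rows[[t]] <- data.frame(cell_label = labs, frame = t - 1L,
                            time_s = (t - 1L) * frameInterval,
                            area_px = cnt,
                            area_um2 = cnt * pixelArea)
  }
  d <- do.call(rbind, rows)
  d <- d[order(d$cell_label, d$frame), , drop = FALSE]
  rownames(d) <- NULL
  AreaTable(d, pixelArea = pixelArea, frameInterval = frameInterval)
}

## Fixed CSV number format: %.17g round-trips doubles exactly and prints
## clean short forms for clean values.
.fmtNum <- function(x) sprintf("%.17g", x)

#' Export an area table as CSV
#'
#' Fixed dialect: header `cell_label,frame,time_s,area_px,area_um2`, comma
#' separated, '.' decimal point, UTF-8, LF line endings, rows sorted by
#' (cell_label, frame). Doubles are written with full precision so
#' write-read-write is byte-identical and a read-back reproduces the table
#' exactly.
#'
#' @param table an [AreaTable-class].
#' @param path destination file path.
#' @return The path, invisibly.
#' @export
exportAreasCSV <- function(table, path) {
  stopifnot(is(table, "AreaTable"))
  d <- table@data
  d <- d[order(d$cell_label, d$frame), , drop = FALSE]
  lines <- c("cell_label,frame,time_s,area_px,area_um2",
             if (nrow(d) > 0L)
               sprintf("%d,%d,%s,%d,%s", as.integer(d$cell_label),
                       as.integer(d$frame), .fmtNum(d$time_s),
                       as.integer(d$area_px), .fmtNum(d$area_um2)))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read an area table from CSV
#'
#' Inverse of [exportAreasCSV()]. Calibration is inferred from the data
#' (pixel area from the first non-zero area row, frame interval from the
#' first non-zero frame) unless supplied.
#'
#' @param path CSV file in the [exportAreasCSV()] dialect.
#' @param pixelArea,frameInterval calibration overrides; `NULL` to infer.
#' @return An [AreaTable-class].
#' @export
readAreasCSV <- function(path, pixelArea = NULL, frameInterval = NULL) {
  d <- utils::read.csv(path, colClasses = c("integer", "integer", "numeric",
                                            "integer", "numeric"))
  if (!identical(names(d), c("cell_label", "frame", "time_s", "area_px",
                             "area_um2")))
    stop("not an area CSV: unexpected header in ", path)
  if (is.null(pixelArea)) {
    i <- which(d$area_px > 0L)[1L]
    pixelArea <- if (is.na(i)) 1 else d$area_um2[i] / d$area_px[i]
  }
  if (is.null(frameInterval)) {
    i <- which(d$frame > 0L)[1L]
    frameInterval <- if (is.na(i)) 5 else d$time_s[i] / d$frame[i]
  }
  AreaTable(d, pixelArea = pixelArea, frameInterval = frameInterval)
}

#' Aggregate per-cell traces into a cohort spreading curve
#'
#' Pools the per-cell area traces of one experimental group and reports, per
#' aligned frame, the number of contributing cells, the mean area and the
#' standard error of the mean (sample standard deviation / sqrt(n), `NA`
#' when n < 2). By default traces are aligned on the first acquisition frame
#' (recordings start as cells land); per-cell frame offsets can be given for
#' cells that landed mid-recording.
#'
#' @param tables an [AreaTable-class] or a list of them (one cohort); all
#'   must share the frame interval.
#' @param alignment `"first_frame"` (default) or `"custom"` with `offsets`.
#' @param offsets named numeric vector of per-cell frame shifts (names are
#'   cell keys `"<table>.<cell_label>"`, see Details) subtracted from each
#'   cell's frame index; required when `alignment = "custom"`.
#' @param group group name stored in the curve.
#' @details Cells from different tables are kept distinct with keys
#'   `"<table index or name>.<cell_label>"`.
#' @return A [SpreadingCurve-class].
#' @examples
#' seg <- SegmentationVolume(array(1L, c(4, 4, 3)))
#' at <- computeAreas(seg, pixelArea = 1, frameInterval = 5)
#' curveData(aggregateCurves(list(a = at, b = at)))
#' @export
aggregateCurves <- function(tables, alignment = c("first_frame", "custom"),
                            offsets = NULL, group = "group") {
  alignment <- match.arg(alignment)
  if (is(tables, "AreaTable")) tables <- list(tables)
  stopifnot(length(tables) > 0L,
            all(vapply(tables, function(x) is(x, "AreaTable"), logical(1L))))
  fi <- vapply(tables, frameInterval, numeric(1L))
  if (max(fi) - min(fi) > 1e-9)
    stop("all area tables must share one frame interval")
  nm <- names(tables)
  if (is.null(nm)) nm <- as.character(seq_along(tables))
  rows <- lapply(seq_along(tables), function(i) {
    d <- areaData(tables[[i]])
    d$cell <- paste(nm[i], d$cell_label, sep = ".")
    d
  })
  d <- do.call(rbind, rows)
  if (alignment == "custom") {
    if (is.null(offsets) || is.null(names(offsets)))
      stop("custom alignment requires a named offsets vector")
    miss <- setdiff(unique(d$cell), names(offsets))
    if (length(miss) > 0L)
      stop("offsets missing for cell(s): ", paste(miss, collapse = ", "))
    d$frame <- d$frame - offsets[d$cell]
  }
  frames <- sort(unique(d$frame))
  agg <- do.call(rbind, lapply(frames, function(f) {
    x <- d$area_um2[d$frame == f]
    n <- length(x)
    data.frame(frame = f, time_s = f * fi[1L], n = n, mean_um2 = mean(x),
               sem_um2 = if (n >= 2L) stats::sd(x) / sqrt(n) else NA_real_)
  }))
  rownames(agg) <- NULL
  new("SpreadingCurve", data = agg, frameInterval = fi[1L], group = group,
      alignment = alignment)
}

#' Export a spreading curve as CSV
#'
#' Header `frame,time_s,n,mean_um2,sem_um2`; same dialect conventions as
#' [exportAreasCSV()]; an undefined s.e.m. (n < 2) is written as `NA`.
#'
#' @param curve a [SpreadingCurve-class].
#' @param path destination file path.
#' @return The path, invisibly.
#' @export
exportCurveCSV <- function(curve, path) {
  stopifnot(is(curve, "SpreadingCurve"))
  d <- curve@data
  lines <- c("frame,time_s,n,mean_um2,sem_um2",
             if (nrow(d) > 0L)
               sprintf("%s,%s,%d,%s,%s", .fmtNum(d$frame), .fmtNum(d$time_s),
                       as.integer(d$n), .fmtNum(d$mean_um2),
                       ifelse(is.na(d$sem_um2), "NA", .fmtNum(d$sem_um2))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

.groupValues <- function(x, frame = NULL, window = NULL) {
  if (is.numeric(x)) return(as.numeric(x))
  if (is(x, "AreaTable")) x <- list(x)
  stopifnot(all(vapply(x, function(t) is(t, "AreaTable"), logical(1L))))
  nm <- names(x)
  if (is.null(nm)) nm <- as.character(seq_along(x))
  d <- do.call(rbind, lapply(seq_along(x), function(i) {
    dd <- areaData(x[[i]])
    dd$cell <- paste(nm[i], dd$cell_label, sep = ".")
    dd
  }))
  if (is.null(frame) && is.null(window))
    stop("give a frame or a window of frames to compare at")
  keep <- if (!is.null(frame)) d$frame == frame else d$frame %in% window
  d <- d[keep, , drop = FALSE]
  if (nrow(d) == 0L) stop("no observations at the requested frame(s)")
  vapply(split(d$area_um2, d$cell), mean, numeric(1L))
}

#' Pooled two-sample Student's t comparison between groups
#'
#' Two-tailed pooled-variance Student's t-test on per-cell areas at a chosen
#' frame (or per-cell means over a window of frames), with
#' `df = n_a + n_b - 2`. Degenerate zero-variance inputs are handled
#' explicitly: identical constant groups give t = 0, p = 1; constant groups
#' with different means give p = 0 and are flagged.
#'
#' @param a,b the two groups: numeric vectors of per-cell values, or
#'   [AreaTable-class] objects (or lists of them).
#' @param frame 0-based frame index at which to compare.
#' @param window alternative to `frame`: vector of 0-based frame indices;
#'   each cell contributes its mean over the window.
#' @return A list with `statistic` (t), `df`, `p.value`, `means` (group
#'   means) and `degenerate` (TRUE when variance was zero with unequal
#'   means).
#' @examples
#' compareGroups(c(10, 12, 14), c(20, 22, 24))
#' @export
compareGroups <- function(a, b, frame = NULL, window = NULL) {
  xa <- .groupValues(a, frame, if (is.null(frame)) window else NULL)
  xb <- .groupValues(b, frame, if (is.null(frame)) window else NULL)
  if (length(xa) < 2L || length(xb) < 2L)
    stop("each group needs at least two cells")
  df <- length(xa) + length(xb) - 2L
  pooledVar <- (sum((xa - mean(xa))^2) + sum((xb - mean(xb))^2)) / df
  if (pooledVar == 0) {
    if (mean(xa) == mean(xb))
      return(list(statistic = 0, df = df, p.value = 1,
                  means = c(mean(xa), mean(xb)), degenerate = FALSE))
    return(list(statistic = sign(mean(xa) - mean(xb)) * Inf, df = df,
                p.value = 0, means = c(mean(xa), mean(xb)),
                degenerate = TRUE))
  }
  ht <- stats::t.test(xa, xb, var.equal = TRUE)
  list(statistic = unname(ht$statistic), df = df,
       p.value = ht$p.value, means = unname(ht$estimate), degenerate = FALSE)
}

#' Fit a logistic spreading law to a cohort curve
#'
#' Least-squares fit of `A(t) = Amax / (1 + exp(-k (t - t0)))` to the mean
#' area trace, via Levenberg–Marquardt. Start values are derived from the
#' curve (plateau from the maximum, midpoint from the half-maximum crossing,
#' rate from the 10–90% rise time).
#'
#' @param curve a [SpreadingCurve-class] (or data.frame with `time_s` and
#'   `mean_um2`).
#' @return Named numeric `c(Amax, k, t0)` with the fit object attached as
#'   attribute `"fit"`.
#' @export
fitSpreadingCurve <- function(curve) {
  d <- if (is(curve, "SpreadingCurve")) curve@data else as.data.frame(curve)
  stopifnot(all(c("time_s", "mean_um2") %in% names(d)))
  y <- d$mean_um2; t <- d$time_s
  Amax0 <- max(y)
  t00 <- t[which.min(abs(y - Amax0 / 2))]
  t10 <- t[which(y >= 0.1 * Amax0)[1L]]
  t90 <- t[which(y >= 0.9 * Amax0)[1L]]
  k0 <- if (is.finite(t90 - t10) && t90 > t10) 4.4 / (t90 - t10) else 0.02
  fit <- minpack.lm::nlsLM(y ~ Amax / (1 + exp(-k * (t - t0))),
                           data = data.frame(t = t, y = y),
                           start = list(Amax = Amax0, k = k0, t0 = t00),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  out <- stats::coef(fit)[c("Amax", "k", "t0")]
  attr(out, "fit") <- fit
  out
}

#' Loading normalization of western-blot signals
#'
#' Corrects densitometric antibody signals for unequal protein loading using
#' each lane's actin signal: the reference lane's actin is set to 1, every
#' lane's actin is expressed relative to it, and the lane's antibody signal
#' is divided by that relative loading. Invariant under rescaling the whole
#' actin channel by a constant.
#'
#' @param table data.frame with columns `lane`, `antibody_signal`,
#'   `actin_signal`, `is_reference` (logical or 0/1; exactly one TRUE).
#' @return The table with added columns `norm_actin` (1 at the reference
#'   lane) and `adjusted_signal`.
#' @examples
#' normalizeBlot(data.frame(lane = c("stim", "inh"),
#'                          antibody_signal = c(40, 30),
#'                          actin_signal = c(100, 50),
#'                          is_reference = c(TRUE, FALSE)))
#' @export
normalizeBlot <- function(table) {
  table <- as.data.frame(table)
  need <- c("lane", "antibody_signal", "actin_signal", "is_reference")
  if (!all(need %in% names(table)))
    stop("blot table needs columns ", paste(need, collapse = ", "))
  ref <- which(as.logical(table$is_reference))
  if (length(ref) != 1L) stop("exactly one reference lane is required")
  if (any(!is.finite(table$actin_signal)) || any(table$actin_signal <= 0))
    stop("actin signals must all be positive")
  if (any(!is.finite(table$antibody_signal)) || any(table$antibody_signal <= 0))
    stop("antibody signals must all be positive")
  table$norm_actin <- table$actin_signal / table$actin_signal[ref]
  table$adjusted_signal <- table$antibody_signal / table$norm_actin
  table
}

#' Read a blot table from CSV
#'
#' Header `lane,antibody_signal,actin_signal,is_reference`.
#'
#' @param path CSV file path.
#' @return A data.frame suitable for [normalizeBlot()].
#' @export
readBlotCSV <- function(path) {
  d <- utils::read.csv(path)
  need <- c("lane", "antibody_signal", "actin_signal", "is_reference")
  if (!all(need %in% names(d)))
    stop("not a blot CSV: unexpected header in ", path)
  d$is_reference <- as.logical(d$is_reference)
  d
}

#' Baseline-normalized ratio trace (R/R0)
#'
#' For paired fluorescence traces (for instance an ATP reporter over a
#' cytosolic expression standard), forms the pointwise ratio
#' `R = numerator / denominator` and divides by its baseline mean `R0` so
#' traces from cells with different expression levels start at unity. An
#' optional linear detrend fits a line to the baseline window, subtracts it
#' over the whole trace and restores the baseline mean of 1; it is off by
#' default.
#'
#' @param numerator,denominator numeric traces of equal length; the
#'   denominator must be positive everywhere.
#' @param baselineWindow indices (1-based) of the baseline samples at the
#'   start of the trace; default the first 5 samples.
#' @param detrend apply the linear baseline detrend?
#' @return The normalized trace, with `R0` attached as attribute `"R0"`. Its
#'   baseline mean is 1 exactly.
#' @examples
#' normalizeRatioTrace(c(2, 2, 2, 4, 4), c(1, 1, 1, 1, 1),
#'                     baselineWindow = 1:3)
#' @export
normalizeRatioTrace <- function(numerator, denominator,
                                baselineWindow = seq_len(min(5L, length(numerator))),
                                detrend = FALSE) {
  if (length(numerator) != length(denominator))
    stop("numerator and denominator traces must have the same length")
  bad <- which(!is.finite(denominator) | denominator <= 0)
  if (length(bad) > 0L)
    stop("denominator must be positive everywhere; offending index ", bad[1L])
  if (length(baselineWindow) == 0L ||
      any(baselineWindow < 1L | baselineWindow > length(numerator)))
    stop("baselineWindow must be non-empty and inside the trace")
  R <- numerator / denominator
  R0 <- mean(R[baselineWindow])
  if (R0 <= 0) stop("baseline ratio R0 must be positive")
  out <- R / R0
  if (detrend) {
    i <- seq_along(out)
    fit <- stats::lm(y ~ i, data = data.frame(y = out[baselineWindow],
                                              i = baselineWindow))
    out <- out - (stats::coef(fit)[1L] + stats::coef(fit)[2L] * i) + 1
    out <- unname(out)
  }
  attr(out, "R0") <- R0
  out
}
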