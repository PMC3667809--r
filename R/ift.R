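## Image foresting transform: minimum-cost path forests on the pixel graph.

## Shared seed validation against a grid; returns a report data.frame
## (entry index, type, message), empty iff the seeds fit the grid.
.seedBoundsReport <- function(coords, label, d) {
  rep <- data.frame(entry = integer(), type = character(),
                    message = character(), stringsAsFactors = FALSE)
  oob <- coords[, "t"] < 1L | coords[, "t"] > d[3L] |
    coords[, "row"] < 1L | coords[, "row"] > d[1L] |
    coords[, "col"] < 1L | coords[, "col"] > d[2L]
  for (i in which(oob)) {
    rep <- rbind(rep, data.frame(
      entry = i, type = "out_of_bounds",
      message = sprintf("seed %d at (t=%d, row=%d, col=%d) lies outside the %d x %d x %d grid",
                        i, coords[i, "t"], coords[i, "row"], coords[i, "col"],
                        d[1L], d[2L], d[3L]),
      stringsAsFactors = FALSE))
  }
  rep
}

.checkSeedsInGrid <- function(seeds, grid) {
  rep <- .seedBoundsReport(seedCoords(seeds), seedLabels(seeds), dim(grid))
  if (nrow(rep) > 0L) stop(rep$message[1L], call. = FALSE)
  invisible(TRUE)
}

## Per-frame Gaussian pre-smoothing of the intensity volume.
.smoothFrames <- function(v, sigma) {
  if (sigma <= 0) return(v)
  d <- dim(v)
  # clamp the kernel so it fits small frames (must be odd and <= min side)
  radius <- min(2L * as.integer(ceiling(3 * sigma)) + 1L,
                2L * ((min(d[1L], d[2L]) - 1L) %/% 2L) + 1L)
  if (radius < 3L) return(v)
  out <- v
  for (t in seq_len(d[3L]))
    out[, , t] <- EBImage::gblur(v[, , t], sigma = sigma, radius = radius)
  out
}

## Neighbour offsets (dt, dr, dc) and their weight scales for an adjacency.
.adjOffsets <- function(adjacency, T) {
  off <- rbind(c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  if (adjacency@inPlane == 8L)
    off <- rbind(off, c(0, -1, -1), c(0, -1, 1), c(0, 1, -1), c(0, 1, 1))
  scale <- rep(1, nrow(off))
  if (adjacency@temporal && T > 1L) {
    off <- rbind(off, c(-1, 0, 0), c(1, 0, 0))
    scale <- c(scale, adjacency@temporalScale, adjacency@temporalScale)
  }
  list(off = off, scale = scale)
}

#' Arc weight between two adjacent pixels
#'
#' The dissimilarity assigned to the graph arc between pixels `p` and `q`:
#' the absolute intensity difference (after the cost model's optional
#' Gaussian pre-smoothing), multiplied by the adjacency's `temporalScale`
#' when the arc crosses frames. Symmetric in its two pixels and zero exactly
#' when the (smoothed) intensities are equal.
#'
#' @param grid an [ImageGrid-class].
#' @param p,q 1-based `(t, row, col)` coordinates of two adjacent pixels.
#' @param cost a [CostModel-class] (supplies `smoothSigma`).
#' @param adjacency an [AdjacencySpec-class]; `p` and `q` must be adjacent
#'   under it, otherwise an error is raised.
#' @return A single non-negative number.
#' @examples
#' g <- ImageGrid(matrix(c(2, 7.5, 1, 1), 2, 2))
#' arcWeight(g, c(1, 1, 1), c(1, 2, 1))
#' @export
arcWeight <- function(grid, p, q, cost = CostModel(),
                      adjacency = AdjacencySpec()) {
  stopifnot(is(grid, "ImageGrid"), length(p) == 3L, length(q) == 3L)
  d <- dim(grid)
  p <- as.integer(p); q <- as.integer(q)
  if (any(p < 1L) || any(q < 1L) || any(p > d[c(3L, 1L, 2L)]) ||
      any(q > d[c(3L, 1L, 2L)]))
    stop("p and q must lie inside the grid")
  dt <- abs(p[1L] - q[1L]); dr <- abs(p[2L] - q[2L]); dc <- abs(p[3L] - q[3L])
  inPlaneOK <- dt == 0L &&
    ((adjacency@inPlane == 4L && dr + dc == 1L) ||
     (adjacency@inPlane == 8L && max(dr, dc) == 1L && dr + dc > 0L))
  temporalOK <- adjacency@temporal && dt == 1L && dr == 0L && dc == 0L
  if (!inPlaneOK && !temporalOK)
    stop("p and q are not adjacent under the given adjacency")
  v <- .smoothFrames(gridValues(grid), cost@smoothSigma)
  w <- abs(v[p[2L], p[3L], p[1L]] - v[q[2L], q[3L], q[1L]])
  if (temporalOK) w <- w * adjacency@temporalScale
  w
}

.buildIFTResult <- function(raw, d, seeds, adjacency, cost) {
  new("IFTResult",
      labelMap = array(raw$label, dim = d),
      costMap = array(raw$cost, dim = d),
      predMap = array(raw$pred + 1L, dim = d),
      rootMap = array(raw$root + 1L, dim = d),
      seeds = seeds, adjacency = adjacency, cost = cost)
}

#' Compute the image foresting transform of a stack
#'
#' Labels every pixel of the volume with the label of the seed that reaches
#' it by the minimum-cost path, turning a handful of user-marked cell and
#' background points into a full segmentation. Implemented as a
#' Dijkstra-style propagation with a priority queue, exact for both
#' monotone path-cost rules. Seed pixels always keep their own label. Cost
#' ties are broken deterministically: a pixel takes the earliest-listed seed
#' among those that reach it along an optimal path all of whose prefixes are
#' themselves optimal; the queue is additionally FIFO on insertion order, so
#' results are bit-reproducible.
#'
#' @param grid an [ImageGrid-class].
#' @param seeds a [SeedSet-class]; all coordinates must lie inside the grid.
#' @param adjacency an [AdjacencySpec-class].
#' @param cost a [CostModel-class].
#' @return An [IFTResult-class] with label, cost, predecessor and root maps.
#' @examples
#' g <- ImageGrid(array(c(0, 0, 10, 0, 0), dim = c(1, 5, 1)))
#' s <- SeedSet(t = c(1, 1), row = c(1, 1), col = c(1, 5), label = c(1, 0))
#' r <- runIFT(g, s, cost = CostModel("additive"))
#' labelMap(r)[1, , 1]
#' costMap(r)[1, , 1]
#' @seealso [bruteForceIFT()] for the reference fixed-point implementation,
#'   [segmentVolume()] for the full segmentation front end.
#' @export
runIFT <- function(grid, seeds, adjacency = AdjacencySpec(),
                   cost = CostModel()) {
  stopifnot(is(grid, "ImageGrid"), is(seeds, "SeedSet"),
            is(adjacency, "AdjacencySpec"), is(cost, "CostModel"))
  .checkSeedsInGrid(seeds, grid)
  v <- .smoothFrames(gridValues(grid), cost@smoothSigma)
  d <- dim(v)
  sc <- seedCoords(seeds)
  node0 <- (sc[, "row"] - 1L) + d[1L] * ((sc[, "col"] - 1L) +
                                         d[2L] * (sc[, "t"] - 1L))
  raw <- .ift_forest_cpp(as.numeric(v), d[1L], d[2L], d[3L],
                         as.integer(node0), seedLabels(seeds),
                         adjacency@inPlane,
                         adjacency@temporal && d[3L] > 1L,
                         adjacency@temporalScale,
                         identical(cost@rule, "additive"),
                         cost@seedHandicap)
  .buildIFTResult(raw, d, seeds, adjacency, cost)
}

#' Reference forest computation by fixed-point relaxation
#'
#' An independent implementation of the same forest contract as [runIFT()],
#' in two order-independent fixed-point phases: first Bellman–Ford-style
#' cost relaxation over all arcs until the unique optimal cost map is
#' reached (seed nodes stay frozen at the seed handicap), then label
#' resolution by propagating the minimal seed entry order over the *tight*
#' arcs — arcs `p -> q` with `extend(cost(p), w) == cost(q)`, i.e. the arcs
#' lying on optimal paths. Both phases converge to unique fixed points for
#' both monotone path-cost rules, and the result provably coincides with the
#' priority-queue propagation, which makes the two routes mutually
#' checkable. Intended for small test instances; refuses grids beyond
#' 10,000 pixels.
#'
#' @inheritParams runIFT
#' @return An [IFTResult-class].
#' @export
bruteForceIFT <- function(grid, seeds, adjacency = AdjacencySpec(),
                          cost = CostModel()) {
  stopifnot(is(grid, "ImageGrid"), is(seeds, "SeedSet"))
  .checkSeedsInGrid(seeds, grid)
  v <- .smoothFrames(gridValues(grid), cost@smoothSigma)
  d <- dim(v)
  N <- prod(d)
  if (N > 10000L)
    stop("bruteForceIFT is a reference oracle limited to <= 10,000 pixels")
  additive <- identical(cost@rule, "additive")

  idx <- array(seq_len(N), dim = d)
  rI <- slice.index(idx, 1L); cI <- slice.index(idx, 2L)
  tI <- slice.index(idx, 3L)
  vv <- as.numeric(v)

  costv <- rep(Inf, N)
  ordv <- rep(.Machine$integer.max, N)
  labv <- rep(NA_integer_, N)
  predv <- rep(0L, N)
  rootv <- rep(0L, N)

  sc <- seedCoords(seeds)
  slab <- seedLabels(seeds)
  isSeed <- rep(FALSE, N)
  for (i in seq_len(nrow(sc))) {
    n <- idx[sc[i, "row"], sc[i, "col"], sc[i, "t"]]
    isSeed[n] <- TRUE
    if (cost@seedHandicap < costv[n] ||
        (cost@seedHandicap == costv[n] && i < ordv[n])) {
      costv[n] <- cost@seedHandicap
      ordv[n] <- i
      labv[n] <- slab[i]
      predv[n] <- 0L
      rootv[n] <- n
    }
  }

  ao <- .adjOffsets(adjacency, d[3L])
  arcs <- vector("list", nrow(ao$off))
  for (k in seq_len(nrow(ao$off))) {
    o <- ao$off[k, ]
    keep <- tI + o[1L] >= 1L & tI + o[1L] <= d[3L] &
      rI + o[2L] >= 1L & rI + o[2L] <= d[1L] &
      cI + o[3L] >= 1L & cI + o[3L] <= d[2L]
    p <- which(as.vector(keep))
    q <- p + o[2L] + d[1L] * o[3L] + d[1L] * d[2L] * o[1L]
    free <- !isSeed[q]          # seeds are never relaxation targets
    arcs[[k]] <- list(p = p[free], q = q[free],
                      w = abs(vv[p[free]] - vv[q[free]]) * ao$scale[k])
  }

  ## phase 1: optimal costs (unique fixed point, order-independent)
  repeat {
    changed <- FALSE
    for (a in arcs) {
      cand <- if (additive) costv[a$p] + a$w else pmax(costv[a$p], a$w)
      better <- cand < costv[a$q]
      if (any(better)) {
        costv[a$q[better]] <- cand[better]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  ## phase 2: labels = minimal seed order over tight arcs (arcs on optimal
  ## paths); again a unique least fixed point.
  repeat {
    changed <- FALSE
    for (a in arcs) {
      cand <- if (additive) costv[a$p] + a$w else pmax(costv[a$p], a$w)
      better <- cand == costv[a$q] & ordv[a$p] < ordv[a$q]
      if (any(better)) {
        p <- a$p[better]; q <- a$q[better]
        ordv[q] <- ordv[p]
        labv[q] <- labv[p]
        predv[q] <- p
        rootv[q] <- rootv[p]
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  .buildIFTResult(list(label = labv, cost = costv, pred = predv - 1L,
                       root = rootv - 1L),
                  d, seeds, adjacency, cost)
}

#' Dice overlap coefficient between two binary masks
#'
#' `2 |A ∩ B| / (|A| + |B|)`; returns 1 when both masks are empty.
#'
#' @param a,b logical arrays/vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
diceCoefficient <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  stopifnot(length(a) == length(b))
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(1)
  2 * sum(a & b) / denom
}
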