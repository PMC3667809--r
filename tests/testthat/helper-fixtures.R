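# Shared fixture builders and an independent forest-invariant checker.

randomGrid <- function(maxSide = 6L, maxIntensity = 9L) {
  H <- sample(2:maxSide, 1L)
  W <- sample(2:maxSide, 1L)
  ImageGrid(matrix(sample(0:maxIntensity, H * W, replace = TRUE), H, W))
}

randomSeeds <- function(grid, nSeeds = sample(2:4, 1L)) {
  d <- dim(grid)
  idx <- sample(d[1L] * d[2L], nSeeds)
  lab <- c(0L, seq_len(nSeeds - 1L))[sample(nSeeds)]
  if (!any(lab == 0L)) lab[1L] <- 0L
  SeedSet(t = rep(1L, nSeeds), row = ((idx - 1L) %% d[1L]) + 1L,
          col = ((idx - 1L) %/% d[1L]) + 1L, label = lab)
}

# Enumerate all directed arcs of a small grid, independently of the package's
# internal adjacency code.
enumArcs <- function(d, inPlane = 4L, temporal = FALSE, temporalScale = 1) {
  off <- rbind(c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  if (inPlane == 8L)
    off <- rbind(off, c(0, -1, -1), c(0, -1, 1), c(0, 1, -1), c(0, 1, 1))
  scale <- rep(1, nrow(off))
  if (temporal && d[3L] > 1L) {
    off <- rbind(off, c(-1, 0, 0), c(1, 0, 0))
    scale <- c(scale, temporalScale, temporalScale)
  }
  arcs <- list()
  for (t in seq_len(d[3L])) for (r in seq_len(d[1L])) for (c in seq_len(d[2L]))
    for (k in seq_len(nrow(off))) {
      t2 <- t + off[k, 1L]; r2 <- r + off[k, 2L]; c2 <- c + off[k, 3L]
      if (t2 >= 1L && t2 <= d[3L] && r2 >= 1L && r2 <= d[1L] &&
          c2 >= 1L && c2 <= d[2L])
        arcs[[length(arcs) + 1L]] <-
          c(t, r, c, t2, r2, c2, scale[k])
    }
  do.call(rbind, arcs)
}

# Assert the forest contract on a result: full labeling, seed fidelity,
# Bellman optimality at every arc, acyclic predecessor paths ending at the
# recorded root with a matching label.
checkForestInvariants <- function(res, grid, adjacency = AdjacencySpec(inPlane = 4, temporal = FALSE),
                                  cost = CostModel()) {
  lab <- labelMap(res); cv <- costMap(res)
  pred <- predMap(res); root <- rootMap(res)
  d <- dim(lab)
  seeds <- res@seeds
  expect_false(anyNA(lab))
  expect_true(all(lab %in% seedLabels(seeds)))

  sc <- seedCoords(seeds)
  for (i in seq_len(nrow(sc))) {
    expect_identical(lab[sc[i, "row"], sc[i, "col"], sc[i, "t"]],
                     seedLabels(seeds)[i])
    expect_equal(cv[sc[i, "row"], sc[i, "col"], sc[i, "t"]],
                 cost@seedHandicap)
  }

  v <- gridValues(grid)
  arcs <- enumArcs(d, adjacency@inPlane, adjacency@temporal,
                   adjacency@temporalScale)
  wp <- abs(v[cbind(arcs[, 2L], arcs[, 3L], arcs[, 1L])] -
            v[cbind(arcs[, 5L], arcs[, 6L], arcs[, 4L])]) * arcs[, 7L]
  cp <- cv[cbind(arcs[, 2L], arcs[, 3L], arcs[, 1L])]
  cq <- cv[cbind(arcs[, 5L], arcs[, 6L], arcs[, 4L])]
  ext <- if (cost@rule == "additive") cp + wp else pmax(cp, wp)
  seedIdx <- (sc[, "t"] - 1L) * d[1L] * d[2L] + (sc[, "col"] - 1L) * d[1L] +
    sc[, "row"]
  qIdx <- (arcs[, 4L] - 1L) * d[1L] * d[2L] + (arcs[, 6L] - 1L) * d[1L] +
    arcs[, 5L]
  free <- !(qIdx %in% seedIdx)   # seeds are frozen, exempt from relaxation
  expect_true(all(cq[free] <= ext[free] + 1e-12))

  N <- prod(d)
  for (n in seq_len(N)) {
    cur <- n; steps <- 0L
    while (pred[cur] != 0L) {
      cur <- pred[cur]
      steps <- steps + 1L
      expect_lte(steps, N)
    }
    expect_identical(cur, root[n])
    expect_identical(lab[cur], lab[n])
    expect_true(cur %in% seedIdx)
  }
  invisible(TRUE)
}

expectSameForest <- function(a, b) {
  expect_identical(labelMap(a), labelMap(b))
  expect_identical(costMap(a), costMap(b))
  expect_identical(rootMap(a), rootMap(b))
}

# Fast, vectorized version of the forest-invariant check: returns a character
# vector of violated properties (empty when the contract holds).
forestViolations <- function(res, grid, adjacency = AdjacencySpec(inPlane = 4, temporal = FALSE),
                             cost = CostModel()) {
  out <- character(0)
  lab <- labelMap(res); cv <- costMap(res)
  pred <- as.vector(predMap(res)); root <- as.vector(rootMap(res))
  d <- dim(lab)
  seeds <- res@seeds
  sc <- seedCoords(seeds)
  seedIdx <- (sc[, "t"] - 1L) * d[1L] * d[2L] + (sc[, "col"] - 1L) * d[1L] +
    sc[, "row"]

  if (anyNA(lab) || !all(lab %in% seedLabels(seeds)))
    out <- c(out, "labeling")
  if (!all(lab[cbind(sc[, "row"], sc[, "col"], sc[, "t"])] ==
           seedLabels(seeds)) ||
      !all(cv[cbind(sc[, "row"], sc[, "col"], sc[, "t"])] ==
           cost@seedHandicap))
    out <- c(out, "seed fidelity")

  v <- gridValues(grid)
  arcs <- enumArcs(d, adjacency@inPlane, adjacency@temporal,
                   adjacency@temporalScale)
  wp <- abs(v[cbind(arcs[, 2L], arcs[, 3L], arcs[, 1L])] -
            v[cbind(arcs[, 5L], arcs[, 6L], arcs[, 4L])]) * arcs[, 7L]
  cp <- cv[cbind(arcs[, 2L], arcs[, 3L], arcs[, 1L])]
  cq <- cv[cbind(arcs[, 5L], arcs[, 6L], arcs[, 4L])]
  ext <- if (cost@rule == "additive") cp + wp else pmax(cp, wp)
  qIdx <- (arcs[, 4L] - 1L) * d[1L] * d[2L] + (arcs[, 6L] - 1L) * d[1L] +
    arcs[, 5L]
  if (!all(cq[!(qIdx %in% seedIdx)] <= ext[!(qIdx %in% seedIdx)] + 1e-12))
    out <- c(out, "Bellman optimality")

  # pointer jumping: after <= N steps every predecessor chain must sit at a
  # root (pred 0); cycles would never settle
  N <- prod(d)
  cur <- seq_len(N)
  for (step in seq_len(N)) {
    nxt <- ifelse(pred[cur] == 0L, cur, pred[cur])
    if (all(nxt == cur)) break
    cur <- nxt
  }
  if (!all(pred[cur] == 0L) || !all(cur == root) ||
      !all(as.vector(lab)[cur] == as.vector(lab)) ||
      !all(cur %in% seedIdx))
    out <- c(out, "predecessor forest")
  out
}

# Minimum per-cell per-frame Dice between a segmentation and ground truth.
minDice <- function(seg, truth, labels, frames = seq_len(dim(truth)[3L])) {
  m <- 1
  for (i in labels) for (t in frames)
    m <- min(m, diceCoefficient(truth[, , t] == i, seg[, , t] == i))
  m
}
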