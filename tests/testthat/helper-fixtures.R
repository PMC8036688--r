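# Shared fixtures, independent oracles and a per-session result cache.

CLS <- landUseClasses()

# small deterministic landscape shared by several files
smallLandscape <- function(shape = c(32, 32), seed = 11L,
                           smoothingPasses = 0L) {
  drv <- genDrivers(shape, seed = seed)
  tr <- syntheticTruth(nLayers(drv), seed = seed)
  m0 <- genInitialMap(drv, tr, smoothingPasses = smoothingPasses)
  list(drivers = drv, truth = tr, map = m0)
}

# flat (uniform) suitability cube over a map's shape
flatCube <- function(map) {
  d <- dim(landUseGrid(map))
  new("SuitabilityCube",
      probs = array(1 / 6, dim = c(d[1], d[2], 6)))
}

# --- independent oracles -----------------------------------------------------

# brute-force 8-neighbour count (loop over cells and offsets)
bruteNeighborCount <- function(grid, k) {
  nr <- nrow(grid); nc <- ncol(grid)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    cnt <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; c2 <- cc + dc
      if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc && grid[rr, c2] == k)
        cnt <- cnt + 1
    }
    out[r, cc] <- cnt
  }
  out
}

# brute-force bivariate Moran double sum over the dense weight matrix
bruteBivariateMoran <- function(x, y, W) {
  n <- length(x)
  zx <- (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  zy <- (y - mean(y)) / sqrt(mean((y - mean(y))^2))
  Wd <- as.matrix(W@W)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + Wd[i, j] * zx[i] * zy[j]
  s / n
}

# Mann-Whitney rank AUC (midranks for ties)
rankAuc <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# exhaustive optimal k-partition of sorted values by within-class SSE
bruteJenksSse <- function(values, k) {
  x <- sort(values)
  n <- length(x)
  sse <- function(seg) sum((seg - mean(seg))^2)
  cuts <- utils::combn(seq_len(n - 1), k - 1)
  best <- Inf
  for (j in seq_len(ncol(cuts))) {
    b <- c(0, cuts[, j], n)
    tot <- sum(vapply(seq_len(k), function(i)
      sse(x[(b[i] + 1):b[i + 1]]), numeric(1)))
    if (tot < best) best <- tot
  }
  best
}

jenksSseOf <- function(values, levels) {
  sum(vapply(unique(levels), function(l) {
    seg <- values[levels == l]
    sum((seg - mean(seg))^2)
  }, numeric(1)))
}

makeBigPair <- function() {
  drv <- genDrivers(c(256, 256), seed = 31)
  tr <- syntheticTruth(nLayers(drv), seed = 31)
  m0 <- genInitialMap(drv, tr, smoothingPasses = 0)
  list(truth = tr, m0 = m0, m1 = evolveMap(m0, tr))
}

# cache for expensive computations reused across test files in one session
.fixtureCache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (is.null(.fixtureCache[[key]])) .fixtureCache[[key]] <- force(expr)
  .fixtureCache[[key]]
}
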