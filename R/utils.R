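# Internal numeric helpers shared across modules.

N_CLASSES <- 6L
NODATA <- 0L

#' Land-use class codes
#'
#' The package encodes land-use classes as integers `1..6` with `0` reserved
#' for nodata, in every map, matrix and coefficient table:
#' 1 = cultivated, 2 = woodland, 3 = grassland, 4 = water, 5 = built,
#' 6 = unused.
#'
#' @return Named integer vector of the six class codes.
#' @examples
#' landUseClasses()
#' @export
landUseClasses <- function() {
  c(cultivated = 1L, woodland = 2L, grassland = 3L,
    water = 4L, built = 5L, unused = 6L)
}

className <- function(code) names(landUseClasses())[code]

#' Ecosystem-service category of each service
#'
#' @return Named character vector mapping the eleven ecosystem services to
#'   their category (`provisioning`, `regulating`, `supporting`, `cultural`).
#' @examples
#' serviceCategories()
#' @export
serviceCategories <- function() {
  c(food_production = "provisioning",
    raw_materials = "provisioning",
    water_supply = "provisioning",
    gas_regulation = "regulating",
    climate_regulation = "regulating",
    environment_purification = "regulating",
    hydrology_regulation = "regulating",
    soil_maintenance = "supporting",
    nutrient_circulation = "supporting",
    biodiversity = "supporting",
    aesthetic_landscape = "cultural")
}

# row-wise softmax with max subtraction for stability
softmaxRows <- function(m) {
  m <- m - apply(m, 1L, max)
  e <- exp(m)
  e / rowSums(e)
}

# Round a non-negative vector to integers preserving sum(total) exactly
# (largest-remainder / Hamilton apportionment; ties broken by index).
largestRemainder <- function(x, total = round(sum(x))) {
  stopifnot(all(x >= 0), total >= 0)
  fl <- floor(x)
  need <- total - sum(fl)
  if (need > 0) {
    ord <- order(x - fl, decreasing = TRUE)
    fl[ord[seq_len(need)]] <- fl[ord[seq_len(need)]] + 1
  } else if (need < 0) {
    # total below the floors only when x itself sums below total; take from
    # the largest entries
    ord <- order(fl, decreasing = TRUE)
    i <- 1L
    while (need < 0) {
      if (fl[ord[i]] > 0) { fl[ord[i]] <- fl[ord[i]] - 1; need <- need + 1 }
      i <- if (i == length(fl)) 1L else i + 1L
    }
  }
  as.integer(fl)
}

# Shift a matrix by (dr, dc), zero-filling vacated cells.
shiftMatrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

MOORE_OFFSETS <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                       dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# Count, per cell, how many of its 8 Moore neighbours hold class k.
# Out-of-bounds and nodata neighbours count 0.
neighborClassCount <- function(grid, k) {
  ind <- (grid == k) * 1
  cnt <- matrix(0, nrow(grid), ncol(grid))
  for (i in seq_len(nrow(MOORE_OFFSETS))) {
    cnt <- cnt + shiftMatrix(ind, MOORE_OFFSETS[i, 1L], MOORE_OFFSETS[i, 2L])
  }
  cnt
}

# One majority-filter pass over a categorical grid (3x3 window including the
# centre cell; ties keep the current class). Nodata cells are untouched and
# never vote.
majorityPass <- function(grid) {
  counts <- vapply(seq_len(N_CLASSES), function(k) {
    neighborClassCount(grid, k) + (grid == k)
  }, matrix(0, nrow(grid), ncol(grid)))
  flat <- matrix(counts, nrow = length(grid), ncol = N_CLASSES)
  best <- max.col(flat, ties.method = "first")
  cur <- as.vector(grid)
  active <- cur != NODATA
  curcnt <- flat[cbind(seq_along(cur), pmax(cur, 1L))]
  bestcnt <- flat[cbind(seq_along(cur), best)]
  out <- cur
  take <- active & (bestcnt > curcnt)
  out[take] <- best[take]
  matrix(as.integer(out), nrow(grid), ncol(grid))
}

# Separable Gaussian smoothing with reflection padding.
gaussianSmooth <- function(m, sigma) {
  h <- max(1L, min(ceiling(3 * sigma), nrow(m) - 1L, ncol(m) - 1L))
  g <- dnorm(seq.int(-h, h), sd = sigma)
  g <- g / sum(g)
  smooth1 <- function(mat) {
    nr <- nrow(mat)
    padded <- rbind(mat[h:1, , drop = FALSE], mat,
                    mat[nr:(nr - h + 1L), , drop = FALSE])
    f <- stats::filter(padded, g, sides = 2)
    matrix(f[(h + 1L):(h + nr), ], nr, ncol(mat))
  }
  t(smooth1(t(smooth1(m))))
}

minMaxRescale <- function(m) {
  rng <- range(m, finite = TRUE)
  if (diff(rng) == 0) {
    list(values = matrix(0, nrow(m), ncol(m)), bounds = rng)
  } else {
    list(values = (m - rng[1L]) / diff(rng), bounds = rng)
  }
}

# deterministic child seeds below 2^31 from one master seed
childSeed <- function(seed, stream) {
  offsets <- c(demand = 101L, ann = 211L, ca = 307L, permutation = 401L,
               synth = 503L, mask = 601L, evolve = 701L)
  (as.integer(seed) * 1009L + offsets[[stream]]) %% 2147483629L
}
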