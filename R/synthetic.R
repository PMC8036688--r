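# Seeded synthetic landscapes: driver stacks, planted land-use maps, Markov
# evolution, constraint masks and crop statistics. These provide a known
# ground truth for every downstream stage (transition recovery, suitability
# recovery, demand bookkeeping), which the study's own rasters cannot.

#' Planted ground truth for synthetic landscapes
#'
#' Bundles the class-by-driver logit coefficients that plant the suitability
#' pattern, the row-stochastic transition matrix that evolves the map, and
#' the master seed. Defaults give a moderately separable landscape (logit
#' scale 3 over `[0,1]` drivers) evolving under a sticky diagonal-dominant
#' chain with a mild cultivated-to-built drift, i.e. the qualitative regime
#' of a rapidly urbanising region.
#'
#' @param nDrivers number of driver layers the weights must conform to.
#' @param seed integer master seed.
#' @param logitScale standard deviation of the planted logit coefficients.
#' @param stay diagonal persistence probability of the default transition.
#' @param logitWeights,trueTransition optional explicit overrides.
#' @return A [SyntheticTruth-class] object.
#' @examples
#' tr <- syntheticTruth(nDrivers = 8, seed = 1)
#' rowSums(tr@trueTransition)
#' @export
syntheticTruth <- function(nDrivers, seed = 1L, logitScale = 3,
                           stay = 0.85, logitWeights = NULL,
                           trueTransition = NULL) {
  set.seed(childSeed(seed, "synth"))
  if (is.null(logitWeights)) {
    logitWeights <- matrix(rnorm(N_CLASSES * nDrivers, sd = logitScale),
                           N_CLASSES, nDrivers)
    # centre each class's coefficients so no class dominates in expectation
    # (drivers live in [0,1]); class shares then reflect spatial pattern,
    # not random intercepts
    logitWeights <- logitWeights - rowMeans(logitWeights)
  }
  if (is.null(trueTransition)) {
    off <- matrix(runif(N_CLASSES * N_CLASSES, 0, 1), N_CLASSES, N_CLASSES)
    diag(off) <- 0
    # urbanisation drift: conversions into built land are favoured, land is
    # rarely returned to cultivation
    off[, landUseClasses()["built"]] <- off[, landUseClasses()["built"]] * 3
    off[, landUseClasses()["cultivated"]] <-
      off[, landUseClasses()["cultivated"]] * 0.2
    off <- off / rowSums(off) * (1 - stay)
    trueTransition <- off + diag(rep(stay, N_CLASSES))
    trueTransition <- trueTransition / rowSums(trueTransition)
  }
  new("SyntheticTruth", logitWeights = logitWeights,
      trueTransition = trueTransition, seed = as.integer(seed))
}

#' Generate a synthetic driver stack
#'
#' Produces the kind of driver set land-use CA models are trained on: a
#' smooth DEM-like field, slope and aspect derived from it by central finite
#' differences, two smooth socioeconomic surfaces (GDP, population), and
#' `nPointSources` Euclidean distance-to-point layers (town, highway,
#' railway, water analogues). Smooth fields are Gaussian-filtered white noise
#' with kernel width `corrLength`; all layers are min-max rescaled to
#' `[0, 1]` with the bounds retained.
#'
#' @param shape integer `(rows, cols)`, both at least 8.
#' @param nPointSources number of distance layers (at least 3).
#' @param corrLength spatial correlation length of the smooth fields, cells.
#' @param seed integer seed; the stack is bit-reproducible given it.
#' @return A [DriverStack-class].
#' @examples
#' drv <- genDrivers(c(16, 16), seed = 1)
#' driverNames(drv)
#' @export
genDrivers <- function(shape, nPointSources = 4L, corrLength = 4, seed = 1L) {
  if (length(shape) != 2L || any(shape < 8))
    stop("shape must be (rows, cols) with both >= 8")
  if (corrLength < 1) stop("corrLength must be >= 1")
  if (nPointSources < 3L) stop("at least 3 distance layers are required")
  nr <- as.integer(shape[1L]); nc <- as.integer(shape[2L])
  set.seed(childSeed(seed, "synth") + 7L)

  dem <- gaussianSmooth(matrix(rnorm(nr * nc), nr, nc), corrLength)
  # central differences; one-sided at the border
  dzdr <- (shiftMatrix(dem, -1, 0, NA) - shiftMatrix(dem, 1, 0, NA)) / 2
  dzdc <- (shiftMatrix(dem, 0, -1, NA) - shiftMatrix(dem, 0, 1, NA)) / 2
  dzdr[is.na(dzdr)] <- 0; dzdc[is.na(dzdc)] <- 0
  slope <- sqrt(dzdr^2 + dzdc^2)
  aspect <- atan2(dzdr, dzdc) %% (2 * pi)
  gdp <- gaussianSmooth(matrix(rnorm(nr * nc), nr, nc), corrLength)
  pop <- gaussianSmooth(matrix(rnorm(nr * nc), nr, nc), corrLength)

  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  distNames <- c("dist_town", "dist_highway", "dist_railway", "dist_water")
  if (nPointSources > 4L)
    distNames <- c(distNames, paste0("dist_", seq.int(5L, nPointSources)))
  distNames <- distNames[seq_len(nPointSources)]
  dists <- lapply(seq_len(nPointSources), function(i) {
    sr <- sample.int(nr, 1L); sc <- sample.int(nc, 1L)
    sqrt((rows - sr)^2 + (cols - sc)^2)
  })

  layers <- c(list(dem = dem, slope = slope, aspect = aspect,
                   gdp = gdp, population = pop),
              stats::setNames(dists, distNames))
  scaled <- lapply(layers, minMaxRescale)
  values <- array(unlist(lapply(scaled, `[[`, "values")),
                  dim = c(nr, nc, length(layers)),
                  dimnames = list(NULL, NULL, names(layers)))
  bounds <- do.call(rbind, lapply(scaled, `[[`, "bounds"))
  colnames(bounds) <- c("min", "max")
  new("DriverStack", values = values, bounds = bounds)
}

#' Generate the initial land-use map from planted logits
#'
#' Each cell's class is drawn from the multinomial whose logits are the
#' planted coefficients applied to the normalized driver vector, then the map
#' is passed `smoothingPasses` times through a 3x3 majority filter to add
#' neighbourhood contagion. With zero passes the map is a pure per-cell
#' multinomial draw, which is what the suitability-recovery tests exploit.
#'
#' @param drivers a [DriverStack-class].
#' @param truth a [SyntheticTruth-class] whose `logitWeights` columns match
#'   the driver count.
#' @param smoothingPasses number of majority-filter passes (default 2).
#' @return A [LandUseMap-class] (no nodata cells).
#' @export
genInitialMap <- function(drivers, truth, smoothingPasses = 2L) {
  stopifnot(is(drivers, "DriverStack"), is(truth, "SyntheticTruth"))
  if (ncol(truth@logitWeights) != nLayers(drivers))
    stop("logitWeights columns (", ncol(truth@logitWeights),
         ") do not match driver count (", nLayers(drivers), ")")
  d <- dim(drivers@values)
  X <- matrix(drivers@values, nrow = d[1L] * d[2L], ncol = d[3L])
  probs <- softmaxRows(X %*% t(truth@logitWeights))
  set.seed(childSeed(truth@seed, "synth") + 13L)
  u <- runif(nrow(probs))
  cum <- probs %*% upper.tri(diag(N_CLASSES), diag = TRUE)
  cls <- pmin(N_CLASSES + 1L - as.integer(rowSums(u <= cum)), N_CLASSES)
  grid <- matrix(as.integer(cls), d[1L], d[2L])
  for (i in seq_len(smoothingPasses)) grid <- majorityPass(grid)
  landUseMap(grid)
}

#' Evolve a land-use map one step under the planted transition matrix
#'
#' Each active cell's class at the second date is drawn independently from
#' the row of `truth@trueTransition` for its current class; nodata cells are
#' preserved. This is the ground-truth analogue of the Markov stage that the
#' transition-recovery tests invert.
#'
#' @param mapT0 a [LandUseMap-class].
#' @param truth a [SyntheticTruth-class].
#' @param seed integer seed.
#' @return A [LandUseMap-class] at the next date.
#' @export
evolveMap <- function(mapT0, truth, seed = truth@seed) {
  stopifnot(is(mapT0, "LandUseMap"), is(truth, "SyntheticTruth"))
  tt <- truth@trueTransition
  if (any(abs(rowSums(tt) - 1) > 1e-12)) stop("trueTransition not row-stochastic")
  g <- mapT0@grid
  present <- sort(unique(g[g != NODATA]))
  if (length(present) && any(present > nrow(tt)))
    stop("map contains a class absent from the transition matrix")
  out <- g
  set.seed(childSeed(seed, "evolve"))
  for (c0 in present) {
    idx <- which(g == c0)
    out[idx] <- sample.int(N_CLASSES, length(idx), replace = TRUE,
                           prob = tt[c0, ])
  }
  landUseMap(matrix(as.integer(out), nrow(g), ncol(g)), mapT0@cellSize)
}

#' Generate a scenario constraint mask
#'
#' Freezes a contiguous random subset of the cells a policy protects:
#' `"cultivated_protection"` freezes cultivated cells (a basic-farmland
#' analogue), `"ecological_protection"` freezes woodland and water cells
#' (an ecological-reserve analogue), `"natural_evolution"` freezes nothing.
#' Contiguous patches are grown by randomized breadth-first flood fill from
#' random seed cells until `fraction` of the eligible cells are frozen.
#'
#' @param map a [LandUseMap-class].
#' @param scenario one of `"natural_evolution"`, `"cultivated_protection"`,
#'   `"ecological_protection"`.
#' @param fraction fraction of eligible cells to freeze, in `[0, 1]`.
#' @param seed integer seed.
#' @return Binary matrix of the map's shape: 1 = convertible, 0 = frozen.
#' @export
genConstraintMask <- function(map, scenario, fraction = 0.5, seed = 1L) {
  stopifnot(is(map, "LandUseMap"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  cls <- landUseClasses()
  eligibleClasses <- switch(scenario,
    natural_evolution = integer(0),
    cultivated_protection = cls[["cultivated"]],
    ecological_protection = c(cls[["woodland"]], cls[["water"]]),
    stop("unknown scenario: ", scenario))
  g <- map@grid
  mask <- matrix(1L, nrow(g), ncol(g))
  eligible <- which(matrix(g %in% eligibleClasses, nrow(g)))
  target <- round(fraction * length(eligible))
  if (target == 0) return(mask)

  set.seed(childSeed(seed, "mask"))
  nr <- nrow(g)
  frozen <- logical(length(g))
  eligibleSet <- logical(length(g)); eligibleSet[eligible] <- TRUE
  nFrozen <- 0L
  while (nFrozen < target) {
    remaining <- which(eligibleSet & !frozen)
    if (!length(remaining)) break
    frontier <- remaining[sample.int(length(remaining), 1L)]
    while (length(frontier) && nFrozen < target) {
      pick <- sample.int(length(frontier), 1L)
      cell <- frontier[pick]; frontier <- frontier[-pick]
      if (frozen[cell]) next
      frozen[cell] <- TRUE; nFrozen <- nFrozen + 1L
      r <- (cell - 1L) %% nr + 1L; cc <- (cell - 1L) %/% nr + 1L
      for (i in seq_len(nrow(MOORE_OFFSETS))) {
        rr <- r + MOORE_OFFSETS[i, 1L]; c2 <- cc + MOORE_OFFSETS[i, 2L]
        if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= ncol(g)) {
          nb <- rr + (c2 - 1L) * nr
          if (eligibleSet[nb] && !frozen[nb]) frontier <- c(frontier, nb)
        }
      }
    }
  }
  mask[frozen] <- 0L
  mask
}

#' Generate a synthetic crop-statistics table
#'
#' Emulates the regional grain-statistics table that drives the
#' equivalent-factor unit value: per crop, a sown area (hm2), a yield
#' (t/hm2) and a national average price (yuan/t), drawn from ranges typical
#' of Chinese prefecture grain statistics (areas log-normal around 10^4 hm2,
#' yields 2-8 t/hm2, prices 1500-3600 yuan/t).
#'
#' @param nCrops number of crops (>= 1).
#' @param seed integer seed.
#' @return `data.frame` with columns `crop`, `sown_area_hm2`,
#'   `yield_t_per_hm2`, `price_yuan_per_t`; all values strictly positive.
#' @export
genCropTable <- function(nCrops = 6L, seed = 1L) {
  if (nCrops < 1L) stop("nCrops must be >= 1")
  set.seed(childSeed(seed, "synth") + 29L)
  data.frame(
    crop = paste0("crop_", seq_len(nCrops)),
    sown_area_hm2 = exp(rnorm(nCrops, mean = log(1e4), sd = 1)),
    yield_t_per_hm2 = runif(nCrops, 2, 8),
    price_yuan_per_t = runif(nCrops, 1500, 3600))
}
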