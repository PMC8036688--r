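# Cellular-automaton allocation: combined transition probability from
# suitability, Moore-neighbourhood effect, adaptive per-class inertia and
# conversion cost, resolved per cell by roulette-wheel selection under
# demand gating and constraint masks.

#' Moore-neighbourhood effect for one class
#'
#' For every cell, the share of its 8 Moore neighbours (3x3 window) holding
#' class `k`, scaled by that class's neighbourhood weight:
#' `count / (3*3 - 1) * omega_k`. Out-of-bounds and nodata neighbours count
#' as zero, so border cells see genuinely fewer neighbours.
#'
#' @param map a [LandUseMap-class] (the state after the last iteration).
#' @param k class code `1..6`.
#' @param omega named non-negative per-class neighbourhood weights
#'   (default all 1).
#' @return Numeric matrix of the map's shape.
#' @export
neighborhoodEffect <- function(map, k, omega = defaultOmega()) {
  stopifnot(is(map, "LandUseMap"), k %in% seq_len(N_CLASSES))
  if (any(omega < 0)) stop("omega must be non-negative")
  neighborClassCount(map@grid, k) / 8 * omega[[k]]
}

#' Default neighbourhood weights (all classes weight 1)
#' @return Named numeric vector of length 6.
#' @export
defaultOmega <- function() {
  stats::setNames(rep(1, N_CLASSES), names(landUseClasses()))
}

#' Conversion-cost matrix for a scenario
#'
#' Entry `(c, k)` is the cost of converting class `c` to class `k` in
#' `[0, 1]`; the diagonal is 0 (staying is free) and 1 forbids the
#' conversion outright (factor `1 - sc = 0`). The natural-evolution default
#' is 0.5 everywhere off-diagonal; the protection scenarios forbid
#' conversion out of the protected classes (cultivated; woodland and water).
#'
#' @param scenario scenario name (default `"natural_evolution"`).
#' @param base off-diagonal cost (default 0.5).
#' @return 6x6 numeric matrix with class dimnames.
#' @export
costMatrix <- function(scenario = "natural_evolution", base = 0.5) {
  sc <- matrix(base, N_CLASSES, N_CLASSES,
               dimnames = list(names(landUseClasses()),
                               names(landUseClasses())))
  diag(sc) <- 0
  protected <- switch(scenario,
    natural_evolution = character(0),
    cultivated_protection = "cultivated",
    ecological_protection = c("woodland", "water"),
    stop("unknown scenario: ", scenario))
  for (p in protected) { sc[p, ] <- 1; sc[p, p] <- 0 }
  sc
}

#' Adaptive inertia update
#'
#' Per class: the coefficient is unchanged when the absolute demand gap did
#' not worsen (`|D^{t-1}| <= |D^{t-2}|`). When both gaps are negative and
#' worsening (persistent overshoot) it is damped by `D^{t-2}/D^{t-1}`; when
#' both are positive and worsening (persistent undershoot) it is boosted by
#' `D^{t-1}/D^{t-2}`. A zero previous gap counts as ratio 1, and the result
#' is clamped to `[1e-3, 1e3]`.
#'
#' @param inertia positive per-class coefficients.
#' @param gapT1 demand minus current count at the last iteration.
#' @param gapT2 the same gap one iteration earlier.
#' @param epsilon,cap clamp bounds.
#' @return Updated per-class inertia vector.
#' @export
updateInertia <- function(inertia, gapT1, gapT2, epsilon = 1e-3, cap = 1e3) {
  ratio <- rep(1, length(inertia))
  worsening <- abs(gapT1) > abs(gapT2)
  over <- worsening & gapT1 < 0 & gapT2 < 0
  under <- worsening & gapT1 > 0 & gapT2 > 0
  ratio[over] <- ifelse(gapT1[over] == 0, 1, gapT2[over] / gapT1[over])
  ratio[under] <- ifelse(gapT2[under] == 0, 1, gapT1[under] / gapT2[under])
  pmin(pmax(inertia * ratio, epsilon), cap)
}

#' Combined per-cell transition probability
#'
#' The product `TProb(p, k) = sp(p, k) * Omega(p, k) * Inertia_k *
#' (1 - sc[current(p), k])`; staying in the current class always uses cost 0
#' (the diagonal of the cost matrix).
#'
#' @param cube a [SuitabilityCube-class].
#' @param omegaFields list of 6 neighbourhood-effect matrices (from
#'   [neighborhoodEffect()]).
#' @param inertia per-class inertia coefficients.
#' @param cost 6x6 cost matrix.
#' @param current the current [LandUseMap-class].
#' @return `cells x 6` score matrix (rows of nodata cells are `NA`).
#' @export
combinedProbability <- function(cube, omegaFields, inertia, cost, current) {
  stopifnot(is(cube, "SuitabilityCube"), is(current, "LandUseMap"))
  d <- dim(cube@probs)
  sp <- matrix(cube@probs, ncol = N_CLASSES)
  cur <- as.vector(current@grid)
  tp <- matrix(NA_real_, length(cur), N_CLASSES)
  for (k in seq_len(N_CLASSES)) {
    fac <- 1 - cost[pmax(cur, 1L), k]
    tp[, k] <- sp[, k] * as.vector(omegaFields[[k]]) * inertia[k] * fac
  }
  tp[cur == NODATA, ] <- NA_real_
  tp
}

#' Roulette-wheel class selection
#'
#' Draws class `k` with probability proportional to its score. All-zero
#' scores select nothing (`NA`), the caller's convention being to keep the
#' current class.
#'
#' @param scores non-negative per-class score vector.
#' @return Integer class code, or `NA` when no class has positive score.
#' @export
rouletteSelect <- function(scores) {
  if (any(scores < 0)) stop("internal error: negative roulette score")
  tot <- sum(scores)
  if (tot == 0) return(NA_integer_)
  cum <- cumsum(scores)
  which(runif(1L) * tot <= cum)[1L]
}

#' Run the cellular-automaton allocation
#'
#' Iterates: neighbourhood effect from the last map, inertia update from the
#' two previous demand gaps, combined probability, then a randomized sweep
#' over convertible cells in which each cell draws a candidate class by
#' roulette. A change is accepted only while the candidate class is still
#' under its demand and the source class is over its own, so class counts
#' march monotonically toward the demand vector. Frozen cells (mask 0) and
#' nodata cells never change. The run stops when every class count is within
#' `tol` cells of demand, or after `maxIter` sweeps.
#'
#' @param mapT0 starting [LandUseMap-class].
#' @param cube a conformal [SuitabilityCube-class].
#' @param demand named integer demand vector whose total equals the active
#'   cell count.
#' @param cost 6x6 conversion-cost matrix (default natural evolution).
#' @param mask binary constraint matrix, 1 = convertible (default all 1).
#' @param omega per-class neighbourhood weights.
#' @param maxIter maximum sweeps (default 200).
#' @param tol per-class tolerance in cells (default 0.1% of active cells).
#' @param seed integer seed; the run is exactly reproducible given it.
#' @return The simulated [LandUseMap-class]; the per-iteration gap/inertia
#'   log is available via [iterationLog()].
#' @export
runSimulation <- function(mapT0, cube, demand, cost = costMatrix(),
                          mask = NULL, omega = defaultOmega(),
                          maxIter = 200L, tol = NULL, seed = 1L) {
  stopifnot(is(mapT0, "LandUseMap"), is(cube, "SuitabilityCube"))
  g <- mapT0@grid
  active <- g != NODATA
  nActive <- sum(active)
  if (round(sum(demand)) != nActive)
    stop("demand total (", sum(demand), ") must equal active cells (",
         nActive, ")")
  if (is.null(mask)) mask <- matrix(1L, nrow(g), ncol(g))
  if (!identical(dim(mask), dim(g))) stop("mask shape differs from map")
  if (is.null(tol)) tol <- ceiling(0.001 * nActive)

  # feasibility: cells frozen at their class are guaranteed to that class
  frozenCounts <- tabulate(g[active & mask == 0L], nbins = N_CLASSES)
  infeasible <- which(demand < frozenCounts)
  if (length(infeasible))
    stop("infeasible demand for class ",
         paste(names(landUseClasses())[infeasible], collapse = ", "),
         ": fewer cells demanded than are frozen in place")

  counts <- tabulate(g[active], nbins = N_CLASSES)
  inertia <- rep(1, N_CLASSES)
  gapT1 <- demand - counts
  gapT2 <- gapT1
  convertible <- which(active & mask == 1L)
  log <- list()
  set.seed(childSeed(seed, "ca"))
  cur <- landUseMap(g, mapT0@cellSize)

  for (it in seq_len(maxIter)) {
    gaps <- demand - counts
    log[[it]] <- c(iter = it, stats::setNames(gaps, paste0("gap_", names(landUseClasses()))),
                   stats::setNames(inertia, paste0("inertia_", names(landUseClasses()))))
    if (all(abs(gaps) <= tol)) break
    if (it > 1L) {
      inertia <- updateInertia(inertia, gapT1 = gaps, gapT2 = gapT2)
    }
    gapT2 <- gaps
    omegaFields <- lapply(seq_len(N_CLASSES), function(k)
      neighborhoodEffect(cur, k, omega))
    tp <- combinedProbability(cube, omegaFields, inertia, cost, cur)
    gcur <- cur@grid
    # vectorized roulette draw for every convertible cell
    sc <- tp[convertible, , drop = FALSE]
    sc[sc < 0] <- 0
    tot <- rowSums(sc)
    u <- runif(length(convertible)) * tot
    cm <- sc %*% upper.tri(diag(N_CLASSES), diag = TRUE)
    pickAll <- pmin(N_CLASSES + 1L - rowSums(u <= cm), N_CLASSES)
    pickAll[tot == 0] <- NA_integer_
    # sequential acceptance in random visitation order
    ord <- sample.int(length(convertible))
    for (i in ord) {
      k <- pickAll[i]
      if (is.na(k)) next
      cell <- convertible[i]
      c0 <- gcur[cell]
      if (k == c0) next
      if (counts[k] < demand[k] && counts[c0] > demand[c0]) {
        gcur[cell] <- k
        counts[k] <- counts[k] + 1L
        counts[c0] <- counts[c0] - 1L
      }
    }
    cur <- landUseMap(gcur, mapT0@cellSize)
    gapT1 <- demand - counts
  }
  attr(cur, "iterationLog") <- do.call(rbind, log)
  cur
}

#' Per-iteration demand-gap and inertia log of a simulation
#'
#' @param map the [LandUseMap-class] returned by [runSimulation()].
#' @return Matrix with one row per iteration: per-class demand gaps and
#'   inertia coefficients at the start of the iteration.
#' @export
iterationLog <- function(map) attr(map, "iterationLog")
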