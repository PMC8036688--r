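# Markov stage: estimate the class-transition matrix from two snapshots and
# project per-class cell demand to the horizon date, then bend the projection
# to a policy scenario.

#' Estimate the land-class transition matrix from two snapshots
#'
#' Row-normalised cross-tabulation of (class at the first date, class at the
#' second date) over active cells. A class absent at the first date keeps an
#' identity row (it cannot be observed transitioning).
#'
#' @param mapT0,mapT1 conformal [LandUseMap-class] objects with matching
#'   nodata patterns.
#' @param period years between the snapshots (metadata only; default 10).
#' @return A [TransitionMatrix-class].
#' @examples
#' m0 <- landUseMap(matrix(c(1, 1, 2, 2), 2, 2))
#' m1 <- landUseMap(matrix(c(1, 5, 2, 2), 2, 2))
#' transitionProbs(estimateTransition(m0, m1))[1:2, c(1, 2, 5)]
#' @export
estimateTransition <- function(mapT0, mapT1, period = 10) {
  stopifnot(is(mapT0, "LandUseMap"), is(mapT1, "LandUseMap"))
  if (!identical(dim(mapT0@grid), dim(mapT1@grid)))
    stop("maps must share one shape")
  if (!identical(mapT0@grid == NODATA, mapT1@grid == NODATA))
    stop("maps must share one nodata pattern")
  act <- mapT0@grid != NODATA
  tab <- table(factor(mapT0@grid[act], levels = seq_len(N_CLASSES)),
               factor(mapT1@grid[act], levels = seq_len(N_CLASSES)))
  probs <- matrix(as.numeric(tab), N_CLASSES, N_CLASSES)
  rs <- rowSums(probs)
  for (c0 in seq_len(N_CLASSES)) {
    if (rs[c0] == 0) {
      probs[c0, ] <- 0; probs[c0, c0] <- 1
    } else {
      probs[c0, ] <- probs[c0, ] / rs[c0]
    }
  }
  dimnames(probs) <- list(names(landUseClasses()), names(landUseClasses()))
  new("TransitionMatrix", probs = probs, period = period)
}

#' Project per-class cell demand forward
#'
#' Applies the transition matrix `steps` times to the current per-class
#' counts, then rounds by largest remainder so the total cell count is
#' conserved exactly (the roulette allocation needs integer targets).
#'
#' @param tm a [TransitionMatrix-class].
#' @param countsT1 named non-negative per-class cell counts at the last
#'   observed date.
#' @param steps number of Markov steps (>= 1).
#' @return Named integer demand vector summing to `sum(countsT1)`.
#' @export
projectDemand <- function(tm, countsT1, steps = 1L) {
  stopifnot(is(tm, "TransitionMatrix"))
  if (steps < 1) stop("steps must be >= 1")
  if (any(countsT1 < 0)) stop("counts must be non-negative")
  if (length(countsT1) != N_CLASSES) stop("counts must have 6 entries")
  P <- diag(N_CLASSES)
  for (i in seq_len(steps)) P <- P %*% tm@probs
  raw <- as.vector(countsT1 %*% P)
  dem <- largestRemainder(raw, total = round(sum(countsT1)))
  names(dem) <- names(landUseClasses())
  dem
}

#' Bend projected demand to a policy scenario
#'
#' `natural_evolution` leaves the Markov projection untouched.
#' `cultivated_protection` floors cultivated demand at its last observed
#' count; `ecological_protection` floors woodland and water likewise. Any
#' deficit raised to meet a floor is taken from the donor classes'
#' demand (built land by default), proportionally to their demand, so the
#' total is conserved. Floors that exceed what the donors can supply are a
#' configuration error.
#'
#' @param dv named integer demand vector (from [projectDemand()]).
#' @param scenario scenario name.
#' @param countsT1 named per-class counts at the last observed date, the
#'   source of the floors.
#' @param donors classes whose demand absorbs the rebalancing
#'   (default `"built"`).
#' @return Named integer demand vector with the same total.
#' @export
applyScenarioDemand <- function(dv, scenario, countsT1,
                                donors = "built") {
  cls <- names(landUseClasses())
  dv <- stats::setNames(as.integer(dv), cls)
  floors <- switch(scenario,
    natural_evolution = return(dv),
    cultivated_protection = countsT1["cultivated"],
    ecological_protection = countsT1[c("woodland", "water")],
    stop("unknown scenario: ", scenario))
  deficit <- pmax(0L, as.integer(floors) - dv[names(floors)])
  need <- sum(deficit)
  if (need == 0L) return(dv)
  pool <- dv[donors]
  if (sum(pool) < need)
    stop("infeasible scenario floors: donors hold ", sum(pool),
         " cells, floors require ", need)
  take <- largestRemainder(need * pool / sum(pool), total = need)
  dv[names(floors)] <- dv[names(floors)] + deficit
  dv[donors] <- dv[donors] - take
  dv
}
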