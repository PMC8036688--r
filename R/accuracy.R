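# Map-comparison metrics for validating simulated maps: overall accuracy,
# Cohen's kappa, and the Pontius figure of merit for change prediction.

checkConformal <- function(a, b) {
  stopifnot(is(a, "LandUseMap"), is(b, "LandUseMap"))
  if (!identical(dim(a@grid), dim(b@grid))) stop("maps must share one shape")
}

activeBoth <- function(a, b) a@grid != NODATA & b@grid != NODATA

#' Overall accuracy of a map pair
#'
#' Share of active cells on which the two maps agree.
#'
#' @param a,b conformal [LandUseMap-class] objects.
#' @return Fraction in `[0, 1]`.
#' @export
overallAccuracy <- function(a, b) {
  checkConformal(a, b)
  act <- activeBoth(a, b)
  mean(a@grid[act] == b@grid[act])
}

#' Cohen's kappa of a map pair
#'
#' `(po - pe) / (1 - pe)` from the class confusion matrix over active cells,
#' `po` the observed agreement and `pe` the agreement expected from the
#' marginals. Two identical constant maps give `pe = 1`; kappa is defined as
#' 1 there by convention (perfect agreement).
#'
#' @param a,b conformal [LandUseMap-class] objects.
#' @return Kappa coefficient.
#' @export
kappaCoefficient <- function(a, b) {
  checkConformal(a, b)
  act <- activeBoth(a, b)
  tab <- table(factor(a@grid[act], levels = seq_len(N_CLASSES)),
               factor(b@grid[act], levels = seq_len(N_CLASSES)))
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < .Machine$double.eps * 4) return(1)
  (po - pe) / (1 - pe)
}

#' Figure of merit of a change simulation
#'
#' Pontius' four-component overlap of observed and simulated change,
#' `FoM = B / (A + B + C + D)` over active cells, where per cell:
#' A = observed change that the simulation missed (it predicts persistence),
#' B = observed change predicted as the correct class, C = observed change
#' predicted as change to a wrong class, D = false alarms (observed
#' persistence where the simulation predicts change). Persistence correctly
#' predicted enters no component.
#'
#' @param obsT0 observed map at the first date.
#' @param obsT1 observed map at the second date.
#' @param simT1 simulated map at the second date.
#' @return Fraction in `[0, 1]`; 0 with a warning when no cell changes in
#'   either the observation or the simulation.
#' @export
figureOfMerit <- function(obsT0, obsT1, simT1) {
  checkConformal(obsT0, obsT1)
  checkConformal(obsT0, simT1)
  act <- activeBoth(obsT0, obsT1) & simT1@grid != NODATA
  t0 <- obsT0@grid[act]; t1 <- obsT1@grid[act]; s1 <- simT1@grid[act]
  changed <- t0 != t1
  A <- sum(changed & s1 == t0)
  B <- sum(changed & s1 == t1)
  C <- sum(changed & s1 != t0 & s1 != t1)
  D <- sum(!changed & s1 != t0)
  denom <- A + B + C + D
  if (denom == 0) {
    warning("no observed or simulated change; figure of merit undefined, returning 0")
    return(0)
  }
  B / denom
}
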