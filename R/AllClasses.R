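# S4 containers for the pipeline's central objects.

#' LandUseMap: a categorical land-use raster
#'
#' Integer matrix of class codes (see [landUseClasses()]), `0` marking nodata,
#' with the cell edge length carried as metadata (metres; 30 m grids are the
#' package default, matching common Landsat-derived products).
#'
#' @slot grid integer matrix of codes in `0..6`.
#' @slot cellSize numeric, cell edge length in metres.
#' @export
setClass("LandUseMap",
  representation(grid = "matrix", cellSize = "numeric"),
  validity = function(object) {
    g <- object@grid
    if (!is.numeric(g)) return("grid must be numeric")
    if (any(!is.finite(g))) return("grid must not contain NA/NaN")
    if (any(g != round(g)) || any(g < 0) || any(g > N_CLASSES))
      return("grid values must be integer class codes in 0..6")
    if (length(object@cellSize) != 1L || object@cellSize <= 0)
      return("cellSize must be a single positive number")
    TRUE
  })

#' Construct a LandUseMap
#'
#' @param grid integer matrix of class codes `1..6`, `0` for nodata.
#' @param cellSize cell edge length in metres (default 30).
#' @return A [LandUseMap-class] object.
#' @examples
#' m <- landUseMap(matrix(c(1, 1, 2, 2), 2, 2))
#' classCounts(m)
#' @export
landUseMap <- function(grid, cellSize = 30) {
  storage.mode(grid) <- "integer"
  new("LandUseMap", grid = grid, cellSize = as.numeric(cellSize))
}

#' DriverStack: named continuous spatial driver layers
#'
#' @slot values numeric array `rows x cols x layers`; third dimnames hold the
#'   layer names. Values are min-max rescaled to `[0, 1]`.
#' @slot bounds numeric matrix `layers x 2` of the (min, max) used to rescale.
#' @export
setClass("DriverStack",
  representation(values = "array", bounds = "matrix"),
  validity = function(object) {
    v <- object@values
    if (length(dim(v)) != 3L) return("values must be a 3-d array")
    if (is.null(dimnames(v)[[3L]])) return("layers must be named")
    fin <- v[is.finite(v)]
    if (length(fin) && (min(fin) < -1e-9 || max(fin) > 1 + 1e-9))
      return("normalized driver values must lie in [0, 1]")
    if (nrow(object@bounds) != dim(v)[3L] || ncol(object@bounds) != 2L)
      return("bounds must be layers x 2")
    TRUE
  })

#' SuitabilityCube: per-cell, per-class suitability probabilities
#'
#' @slot probs numeric array `rows x cols x 6`; each active cell's six values
#'   are non-negative and sum to 1; nodata cells hold `NA`.
#' @export
setClass("SuitabilityCube",
  representation(probs = "array"),
  validity = function(object) {
    p <- object@probs
    if (length(dim(p)) != 3L || dim(p)[3L] != N_CLASSES)
      return("probs must be rows x cols x 6")
    flat <- matrix(p, ncol = N_CLASSES)
    act <- stats::complete.cases(flat)
    if (any(flat[act, ] < -1e-9)) return("probabilities must be >= 0")
    if (any(abs(rowSums(flat[act, , drop = FALSE]) - 1) > 1e-6))
      return("per-cell probabilities must sum to 1 (tol 1e-6)")
    TRUE
  })

#' TransitionMatrix: Markov land-class transition probabilities
#'
#' @slot probs 6x6 row-stochastic matrix, entry `(c, k)` the probability a
#'   cell of class `c` at the first date is class `k` at the second.
#' @slot period numeric, years between the two snapshots.
#' @export
setClass("TransitionMatrix",
  representation(probs = "matrix", period = "numeric"),
  validity = function(object) {
    p <- object@probs
    if (!all(dim(p) == N_CLASSES)) return("probs must be 6x6")
    if (any(p < -1e-12) || any(p > 1 + 1e-12)) return("entries must be in [0,1]")
    if (any(abs(rowSums(p) - 1) > 1e-9)) return("rows must sum to 1 (tol 1e-9)")
    TRUE
  })

#' SyntheticTruth: planted ground truth for recovery experiments
#'
#' @slot logitWeights 6 x n-driver coefficient matrix planting the
#'   driver-dependent multinomial class rule.
#' @slot trueTransition 6x6 row-stochastic matrix evolving the map in time.
#' @slot seed integer seed the generators derive their streams from.
#' @export
setClass("SyntheticTruth",
  representation(logitWeights = "matrix", trueTransition = "matrix",
                 seed = "integer"),
  validity = function(object) {
    if (nrow(object@logitWeights) != N_CLASSES)
      return("logitWeights must have 6 rows")
    if (any(!is.finite(object@logitWeights)))
      return("logitWeights must be finite")
    tt <- object@trueTransition
    if (!all(dim(tt) == N_CLASSES)) return("trueTransition must be 6x6")
    if (any(abs(rowSums(tt) - 1) > 1e-12))
      return("trueTransition rows must sum to 1 (tol 1e-12)")
    TRUE
  })

#' AnnModel: trained suitability network
#'
#' Single hidden layer of sigmoid units feeding a softmax output over the six
#' land classes.
#'
#' @slot w1 input-to-hidden weights (`drivers x hidden`); @slot b1 hidden bias.
#' @slot w2 hidden-to-output weights (`hidden x 6`); @slot b2 output bias.
#' @slot driverNames ordered driver layer names the model was trained on.
#' @slot meta list with sample size, epochs, learning rate and seed.
#' @export
setClass("AnnModel",
  representation(w1 = "matrix", b1 = "numeric", w2 = "matrix", b2 = "numeric",
                 driverNames = "character", meta = "list"),
  validity = function(object) {
    if (nrow(object@w1) != length(object@driverNames))
      return("w1 rows must match driverNames")
    if (ncol(object@w1) != nrow(object@w2) ||
        length(object@b1) != ncol(object@w1))
      return("hidden-layer shapes inconsistent")
    if (ncol(object@w2) != N_CLASSES || length(object@b2) != N_CLASSES)
      return("output layer must have 6 units")
    TRUE
  })

#' EsvTable: equivalent-factor coefficient table
#'
#' Unit values of eleven ecosystem services for each of the six land classes,
#' in hundred yuan per hectare per year (negative entries are permitted:
#' built land can be a net sink for a service).
#'
#' @slot values 11 x 6 numeric matrix, rows named by service, columns by
#'   land-class name in code order.
#' @slot categories named character vector mapping services to
#'   provisioning/regulating/supporting/cultural.
#' @export
setClass("EsvTable",
  representation(values = "matrix", categories = "character"),
  validity = function(object) {
    sv <- names(serviceCategories())
    if (!identical(sort(rownames(object@values)), sort(sv)))
      return("rows must be the eleven canonical services")
    if (!identical(colnames(object@values), names(landUseClasses())))
      return("columns must be the six land classes in code order")
    if (any(!is.finite(object@values))) return("all coefficients must be set")
    TRUE
  })

#' SpatialWeights: contiguity weights on an analysis grid
#'
#' @slot W sparse n x n row-standardised weight matrix (zero diagonal).
#' @slot scheme `"queen"` or `"rook"`.
#' @slot dims grid dimensions `(rows, cols)` the cells are unrolled from
#'   (column-major, matching R matrices).
#' @slot islands integer indices of cells without neighbours.
#' @export
setClass("SpatialWeights",
  representation(W = "Matrix", scheme = "character", dims = "integer",
                 islands = "integer"),
  validity = function(object) {
    if (!object@scheme %in% c("queen", "rook")) return("unknown scheme")
    if (any(Matrix::diag(object@W) != 0)) return("diagonal must be zero")
    rs <- Matrix::rowSums(object@W)
    ok <- setdiff(seq_along(rs), object@islands)
    if (any(abs(rs[ok] - 1) > 1e-9)) return("rows must be standardised to 1")
    TRUE
  })

# ---- accessors -------------------------------------------------------------

#' @describeIn LandUseMap-class the underlying integer grid.
#' @param x object.
#' @export
landUseGrid <- function(x) x@grid

#' @describeIn LandUseMap-class cell edge length in metres.
#' @export
cellSize <- function(x) x@cellSize

#' Per-class cell counts of a land-use map
#'
#' @param x a [LandUseMap-class].
#' @return Named integer vector of length 6 (nodata cells excluded).
#' @export
classCounts <- function(x) {
  stopifnot(is(x, "LandUseMap"))
  cnt <- tabulate(x@grid[x@grid != NODATA], nbins = N_CLASSES)
  names(cnt) <- names(landUseClasses())
  cnt
}

#' @describeIn DriverStack-class layer names, in order.
#' @param x object.
#' @export
driverNames <- function(x) dimnames(x@values)[[3L]]

#' @describeIn DriverStack-class number of layers.
#' @export
nLayers <- function(x) dim(x@values)[3L]

#' @describeIn SuitabilityCube-class the probability array.
#' @param x object.
#' @export
probsArray <- function(x) x@probs

#' @describeIn TransitionMatrix-class the 6x6 probability matrix.
#' @param x object.
#' @export
transitionProbs <- function(x) x@probs

#' @describeIn EsvTable-class the service x class coefficient matrix.
#' @param x object.
#' @export
esvValues <- function(x) x@values

# ---- show methods ----------------------------------------------------------

setMethod("show", "LandUseMap", function(object) {
  d <- dim(object@grid)
  cat(sprintf("LandUseMap: %d x %d cells (%.0f m), %d nodata\n",
              d[1L], d[2L], object@cellSize, sum(object@grid == NODATA)))
  print(classCounts(object))
})

setMethod("show", "DriverStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("DriverStack: %d x %d cells, %d layers\n", d[1L], d[2L], d[3L]))
  cat(" layers:", paste(driverNames(object), collapse = ", "), "\n")
})

setMethod("show", "SuitabilityCube", function(object) {
  d <- dim(object@probs)
  cat(sprintf("SuitabilityCube: %d x %d cells x %d classes\n",
              d[1L], d[2L], d[3L]))
})

setMethod("show", "TransitionMatrix", function(object) {
  cat(sprintf("TransitionMatrix (period %g yr):\n", object@period))
  print(round(object@probs, 4))
})

setMethod("show", "AnnModel", function(object) {
  cat(sprintf("AnnModel: %d drivers -> %d hidden -> 6 classes\n",
              nrow(object@w1), ncol(object@w1)))
  cat(" trained:", object@meta$n, "samples,", object@meta$epochs, "epochs\n")
})

setMethod("show", "EsvTable", function(object) {
  cat("EsvTable: 11 services x 6 classes (100 yuan/hm2/yr)\n")
  print(round(object@values, 2))
})

setMethod("show", "SpatialWeights", function(object) {
  cat(sprintf("SpatialWeights: %s contiguity on %d x %d grid (n = %d)\n",
              object@scheme, object@dims[1L], object@dims[2L],
              nrow(object@W)))
})
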