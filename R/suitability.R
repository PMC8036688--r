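# ANN suitability stage: sample training cells, fit a single-hidden-layer
# sigmoid/softmax network on the driver layers, and emit per-cell per-class
# suitability probabilities normalised to sum to 1.

#' Sample training cells for the suitability network
#'
#' Draws `n` (driver vector, class label) pairs from the active cells.
#' `"random"` samples cells uniformly without replacement; `"uniform"` aims
#' at equal counts per class, taking every cell of a class that is smaller
#' than its quota and redistributing the shortfall. A class entirely absent
#' triggers a warning and a proportional (random) fallback.
#'
#' @param map a [LandUseMap-class] supplying the labels.
#' @param drivers a conformal [DriverStack-class] supplying the features.
#' @param n sample size (at most the active cell count).
#' @param strategy `"uniform"` or `"random"`.
#' @param seed integer seed.
#' @return List with `x` (n x drivers feature matrix), `y` (factor of class
#'   codes with levels `1..6`) and `cells` (sampled cell indices).
#' @export
sampleTraining <- function(map, drivers, n, strategy = c("uniform", "random"),
                           seed = 1L) {
  stopifnot(is(map, "LandUseMap"), is(drivers, "DriverStack"))
  strategy <- match.arg(strategy)
  d <- dim(drivers@values)
  if (!identical(dim(map@grid), d[1:2])) stop("map and drivers shapes differ")
  active <- which(map@grid != NODATA)
  if (n > length(active)) stop("n exceeds the active cell count")
  labels <- map@grid[active]
  set.seed(childSeed(seed, "ann"))
  if (strategy == "uniform" && length(unique(labels)) < N_CLASSES) {
    warning("some classes have no cells; falling back to random sampling")
    strategy <- "random"
  }
  if (strategy == "random") {
    pick <- sample(seq_along(active), n)
  } else {
    quota <- largestRemainder(rep(n / N_CLASSES, N_CLASSES), total = n)
    byClass <- split(seq_along(active), labels)
    avail <- vapply(as.character(seq_len(N_CLASSES)),
                    function(k) length(byClass[[k]]), 0L)
    # classes smaller than their quota contribute everything they have;
    # the shortfall is spread over the classes with spare cells
    short <- sum(pmax(0L, quota - avail))
    while (short > 0L) {
      spare <- pmax(0L, avail - quota)
      quota <- pmin(quota, avail)
      add <- largestRemainder(short * spare / sum(spare), total = short)
      quota <- quota + pmin(add, spare)
      short <- n - sum(quota)
    }
    quota <- pmin(quota, avail)
    pick <- unlist(lapply(seq_len(N_CLASSES), function(k) {
      pool <- byClass[[as.character(k)]]
      pool[sample.int(length(pool), quota[k])]
    }), use.names = FALSE)
    pick <- pick[sample.int(length(pick))]
  }
  cells <- active[pick]
  X <- matrix(drivers@values, nrow = d[1L] * d[2L], ncol = d[3L],
              dimnames = list(NULL, driverNames(drivers)))[cells, , drop = FALSE]
  list(x = X, y = factor(map@grid[cells], levels = seq_len(N_CLASSES)),
       cells = cells)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

annForward <- function(X, w1, b1, w2, b2) {
  H <- sigmoid(sweep(X %*% w1, 2L, b1, "+"))
  P <- softmaxRows(sweep(H %*% w2, 2L, b2, "+"))
  list(H = H, P = P)
}

#' Train the suitability network
#'
#' Fits one hidden layer of sigmoid units and a softmax output over the six
#' classes by minimising the multinomial cross-entropy with full-batch
#' resilient backpropagation (iRprop-), whose sign-based per-weight steps are
#' insensitive to gradient scale; `lr` is the initial step. Training is
#' exactly reproducible for a given seed: rows are first put in a canonical
#' order and then shuffled by a seed-derived permutation, so the result is
#' invariant to the order the training set was assembled in.
#'
#' @param ts training set from [sampleTraining()].
#' @param hiddenSize hidden units (default 12).
#' @param epochs full-batch update steps (default 200, >= 1).
#' @param lr initial per-weight step size (default 0.01).
#' @param seed integer seed for initial weights and the internal shuffle.
#' @return An [AnnModel-class].
#' @export
trainAnn <- function(ts, hiddenSize = 12L, epochs = 200L, lr = 0.01,
                     seed = 1L) {
  if (epochs < 1) stop("epochs must be >= 1")
  X <- ts$x
  y <- as.integer(ts$y)
  canon <- do.call(order, c(list(y), lapply(seq_len(ncol(X)), function(j) X[, j])))
  set.seed(childSeed(seed, "ann") + 3L)
  sh <- sample.int(length(y))
  X <- X[canon, , drop = FALSE][sh, , drop = FALSE]
  y <- y[canon][sh]

  nIn <- ncol(X); nH <- as.integer(hiddenSize); n <- nrow(X)
  theta <- list(
    w1 = matrix(runif(nIn * nH, -1, 1) / sqrt(nIn), nIn, nH),
    b1 = numeric(nH),
    w2 = matrix(runif(nH * N_CLASSES, -1, 1) / sqrt(nH), nH, N_CLASSES),
    b2 = numeric(N_CLASSES))
  Y <- matrix(0, n, N_CLASSES); Y[cbind(seq_len(n), y)] <- 1
  delta <- lapply(theta, function(w) w * 0 + lr)
  gPrev <- lapply(theta, function(w) w * 0)
  for (e in seq_len(epochs)) {
    fw <- annForward(X, theta$w1, theta$b1, theta$w2, theta$b2)
    if (any(!is.finite(fw$P)))
      stop("training diverged: non-finite probabilities at epoch ", e)
    dS <- (fw$P - Y) / n                       # d loss / d output scores
    dH <- (dS %*% t(theta$w2)) * fw$H * (1 - fw$H)
    grad <- list(w1 = crossprod(X, dH), b1 = colSums(dH),
                 w2 = crossprod(fw$H, dS), b2 = colSums(dS))
    for (nm in names(theta)) {
      s <- grad[[nm]] * gPrev[[nm]]
      delta[[nm]] <- pmin(pmax(
        delta[[nm]] * ifelse(s > 0, 1.2, ifelse(s < 0, 0.5, 1)), 1e-6), 1)
      g <- grad[[nm]]; g[s < 0] <- 0           # iRprop-: drop reversed grads
      theta[[nm]] <- theta[[nm]] - sign(g) * delta[[nm]]
      gPrev[[nm]] <- g
    }
  }
  new("AnnModel", w1 = theta$w1, b1 = theta$b1, w2 = theta$w2, b2 = theta$b2,
      driverNames = colnames(ts$x),
      meta = list(n = n, epochs = as.integer(epochs), lr = lr,
                  seed = as.integer(seed)))
}

#' Predict the suitability cube
#'
#' Runs the trained network over every cell of the driver stack and
#' renormalises each cell's six output scores to sum to 1 (softmax output),
#' so the per-cell probability constraint holds by construction. The
#' prediction is a pure per-cell function of the drivers: it carries no
#' spatial term.
#'
#' @param model an [AnnModel-class].
#' @param drivers a [DriverStack-class] with the layers (by name) the model
#'   was trained on.
#' @param map optional [LandUseMap-class]; its nodata cells get `NA`
#'   probabilities.
#' @return A [SuitabilityCube-class].
#' @export
predictSuitability <- function(model, drivers, map = NULL) {
  stopifnot(is(model, "AnnModel"), is(drivers, "DriverStack"))
  missing <- setdiff(model@driverNames, driverNames(drivers))
  if (length(missing))
    stop("driver layers missing: ", paste(missing, collapse = ", "))
  d <- dim(drivers@values)
  X <- matrix(drivers@values, nrow = d[1L] * d[2L], ncol = d[3L],
              dimnames = list(NULL, driverNames(drivers)))
  X <- X[, model@driverNames, drop = FALSE]
  P <- annForward(X, model@w1, model@b1, model@w2, model@b2)$P
  P <- P / rowSums(P)
  if (!is.null(map)) {
    stopifnot(identical(dim(map@grid), d[1:2]))
    P[map@grid == NODATA, ] <- NA_real_
  }
  new("SuitabilityCube",
      probs = array(P, dim = c(d[1L], d[2L], N_CLASSES)))
}

#' One-vs-rest ROC AUC per land class
#'
#' For each class present in the observed map, the area under the ROC curve
#' of that class's suitability probabilities against the binary indicator of
#' observed membership, over active cells. Classes absent from the observed
#' map get `NA`.
#'
#' @param cube a [SuitabilityCube-class].
#' @param observed a conformal [LandUseMap-class].
#' @param cells optional cell indices to restrict to (e.g. held-out cells).
#' @return Named numeric vector of length 6.
#' @export
rocAucPerClass <- function(cube, observed, cells = NULL) {
  stopifnot(is(cube, "SuitabilityCube"), is(observed, "LandUseMap"))
  d <- dim(cube@probs)
  if (!identical(dim(observed@grid), d[1:2])) stop("shapes differ")
  flat <- matrix(cube@probs, ncol = N_CLASSES)
  idx <- if (is.null(cells)) which(observed@grid != NODATA) else cells
  lab <- observed@grid[idx]
  out <- rep(NA_real_, N_CLASSES)
  names(out) <- names(landUseClasses())
  for (k in seq_len(N_CLASSES)) {
    resp <- as.integer(lab == k)
    if (length(unique(resp)) < 2L) next
    out[k] <- as.numeric(pROC::auc(pROC::roc(
      response = resp, predictor = flat[idx, k],
      levels = c(0L, 1L), direction = "<", quiet = TRUE)))
  }
  out
}
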