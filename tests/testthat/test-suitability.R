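# Suitability stage: sampling, training determinism and order invariance,
# probability normalization, AUC.

test_that("training sampling honours size, strategy and seed", {
  ls <- smallLandscape(c(32, 32), seed = 11, smoothingPasses = 1)
  nAct <- sum(landUseGrid(ls$map) != 0)
  all <- sampleTraining(ls$map, ls$drivers, n = nAct, strategy = "random",
                        seed = 1)
  expect_setequal(all$cells, which(landUseGrid(ls$map) != 0))

  uni <- sampleTraining(ls$map, ls$drivers, n = 60, strategy = "uniform",
                        seed = 1)
  expect_true(all(table(uni$y) == 10))
  expect_identical(
    sampleTraining(ls$map, ls$drivers, 100, "uniform", seed = 5)$cells,
    sampleTraining(ls$map, ls$drivers, 100, "uniform", seed = 5)$cells)
  expect_error(sampleTraining(ls$map, ls$drivers, nAct + 1, "random"),
               "exceeds")
})

test_that("a class with no cells triggers a proportional fallback", {
  g <- matrix(rep(c(1L, 2L), each = 32), 8, 8)  # only two classes present
  m <- landUseMap(g)
  drv <- genDrivers(c(8, 8), seed = 2)
  expect_warning(
    ts <- sampleTraining(m, drv, 20, "uniform", seed = 1),
    "falling back")
  expect_identical(length(ts$cells), 20L)
})

test_that("training is deterministic and order-invariant given the seed", {
  ls <- smallLandscape(c(32, 32), seed = 12)
  ts <- sampleTraining(ls$map, ls$drivers, 300, "uniform", seed = 2)
  m1 <- trainAnn(ts, hiddenSize = 6, epochs = 50, seed = 3)
  m2 <- trainAnn(ts, hiddenSize = 6, epochs = 50, seed = 3)
  expect_identical(m1@w1, m2@w1)
  expect_identical(m1@w2, m2@w2)
  # permuting the assembled training set leaves the fit bit-identical
  perm <- sample(length(ts$y))
  tsP <- list(x = ts$x[perm, , drop = FALSE], y = ts$y[perm],
              cells = ts$cells[perm])
  m3 <- trainAnn(tsP, hiddenSize = 6, epochs = 50, seed = 3)
  expect_identical(m1@w1, m3@w1)
  expect_identical(m1@b2, m3@b2)
  expect_error(trainAnn(ts, epochs = 0), "epochs")
})

test_that("a separable two-class toy is fit to training accuracy 1", {
  set.seed(8)
  n <- 120
  y <- factor(rep(c(1, 5), each = n / 2), levels = 1:6)
  x <- cbind(ind = as.numeric(y == 1), noise = runif(n))
  mod <- trainAnn(list(x = x, y = y), hiddenSize = 4, epochs = 200, seed = 1)
  drv <- new("DriverStack",
             values = array(x, dim = c(n, 1, 2),
                            dimnames = list(NULL, NULL, colnames(x))),
             bounds = cbind(min = c(0, 0), max = c(1, 1)))
  cube <- predictSuitability(mod, drv)
  pred <- apply(matrix(probsArray(cube), ncol = 6), 1, which.max)
  expect_identical(pred, as.integer(as.character(y)))
})

test_that("suitability cubes are normalized, per-cell and driver-checked", {
  ls <- smallLandscape(c(24, 24), seed = 14)
  ts <- sampleTraining(ls$map, ls$drivers, 300, "uniform", seed = 2)
  mod <- trainAnn(ts, epochs = 60, seed = 2)
  cube <- predictSuitability(mod, ls$drivers)
  flat <- matrix(probsArray(cube), ncol = 6)
  expect_equal(rowSums(flat), rep(1, nrow(flat)), tolerance = 1e-6)
  expect_true(all(flat >= 0))

  # prediction is a pure per-cell function: shuffling cells commutes
  d <- dim(ls$drivers@values)
  perm <- sample(d[1] * d[2])
  shuf <- ls$drivers
  v <- matrix(shuf@values, ncol = d[3])[perm, ]
  shuf@values <- array(v, dim = d, dimnames = dimnames(ls$drivers@values))
  flatShuf <- matrix(probsArray(predictSuitability(mod, shuf)), ncol = 6)
  expect_equal(flatShuf, flat[perm, ], tolerance = 1e-12)

  bad <- ls$drivers
  dimnames(bad@values)[[3]][1] <- "renamed"
  expect_error(predictSuitability(mod, bad), "missing")
})

test_that("an output stage favouring one class makes it the argmax everywhere", {
  ls <- smallLandscape(c(16, 16), seed = 15)
  ts <- sampleTraining(ls$map, ls$drivers, 200, "random", seed = 2)
  mod <- trainAnn(ts, epochs = 30, seed = 2)
  mod@b2 <- c(0, 0, 50, 0, 0, 0)  # force class 3 at the output stage
  cube <- predictSuitability(mod, ls$drivers)
  pred <- apply(matrix(probsArray(cube), ncol = 6), 1, which.max)
  expect_true(all(pred == 3))
})

test_that("AUC matches the rank-count oracle and its degenerate limits", {
  # 4-cell toy: scores (.9,.8,.3,.1) against labels (1,1,0,0) -> AUC 1
  g <- matrix(c(1L, 1L, 2L, 2L), 2, 2)
  m <- landUseMap(g)
  p1 <- matrix(c(0.9, 0.8, 0.3, 0.1), 4, 1)
  probs <- cbind(p1, (1 - p1) / 5, (1 - p1) / 5, (1 - p1) / 5,
                 (1 - p1) / 5, (1 - p1) / 5)
  cube <- new("SuitabilityCube", probs = array(probs, dim = c(2, 2, 6)))
  auc <- rocAucPerClass(cube, m)
  expect_equal(unname(auc[1]), 1)
  expect_equal(unname(auc[1]),
               rankAuc(probs[, 1], as.integer(as.vector(g) == 1)))

  # one-hot predictions of the observed map give AUC 1 per present class
  oneHot <- matrix(0, 4, 6); oneHot[cbind(1:4, as.vector(g))] <- 1
  cube1 <- new("SuitabilityCube", probs = array(oneHot, dim = c(2, 2, 6)))
  expect_equal(unname(rocAucPerClass(cube1, m)[1:2]), c(1, 1))
  expect_true(all(is.na(rocAucPerClass(cube1, m)[3:6])))

  # constant probabilities carry no information: AUC 1/2
  flat <- flatCube(m)
  expect_equal(unname(rocAucPerClass(flat, m)[1]), 0.5)

  # random scores agree with the rank oracle
  set.seed(5)
  g2 <- matrix(sample(1:6, 64, replace = TRUE), 8, 8)
  m2 <- landUseMap(g2)
  sc <- matrix(runif(64 * 6), 64, 6); sc <- sc / rowSums(sc)
  cube2 <- new("SuitabilityCube", probs = array(sc, dim = c(8, 8, 6)))
  auc2 <- rocAucPerClass(cube2, m2)
  for (k in 1:6) {
    expect_equal(unname(auc2[k]),
                 rankAuc(sc[, k], as.integer(as.vector(g2) == k)),
                 tolerance = 1e-12)
  }
})

test_that("the planted suitability pattern is recovered (mean held-out AUC > 0.8)", {
  res <- cached("annRecovery", {
    drv <- genDrivers(c(64, 64), seed = 1)
    tr <- syntheticTruth(nLayers(drv), seed = 1)
    m0 <- genInitialMap(drv, tr, smoothingPasses = 0)
    ts <- sampleTraining(m0, drv, n = 20 * 6 * nLayers(drv),
                         strategy = "uniform", seed = 1)
    mod <- trainAnn(ts, seed = 1)
    cube <- predictSuitability(mod, drv)
    held <- setdiff(which(landUseGrid(m0) != 0), ts$cells)
    rocAucPerClass(cube, m0, cells = held)
  })
  expect_gt(mean(res, na.rm = TRUE), 0.8)
})

test_that("the trained network agrees with an independent fit on separable data", {
  skip_if_not_installed("nnet")
  set.seed(10)
  n <- 150
  y <- factor(rep(c(2, 4, 6), each = n / 3), levels = 1:6)
  x <- cbind(a = as.numeric(y == 2) + rnorm(n, 0, 0.05),
             b = as.numeric(y == 4) + rnorm(n, 0, 0.05))
  mine <- trainAnn(list(x = x, y = y), hiddenSize = 5, epochs = 300, seed = 2)
  drv <- new("DriverStack",
             values = array(pmin(pmax(x, 0), 1), dim = c(n, 1, 2),
                            dimnames = list(NULL, NULL, colnames(x))),
             bounds = cbind(min = c(0, 0), max = c(1, 1)))
  predMine <- apply(matrix(probsArray(predictSuitability(mine, drv)),
                           ncol = 6), 1, which.max)
  ref <- nnet::nnet(x, nnet::class.ind(y), size = 5, softmax = TRUE,
                    maxit = 300, trace = FALSE)
  predRef <- max.col(predict(ref, x))
  expect_gt(mean(predMine == as.integer(as.character(y))), 0.95)
  expect_gt(mean(predMine == predRef), 0.95)
})
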