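# Equivalent-factor valuation: unit value E, coefficient table, ESV
# linearity, UESV grids and Jenks levels.

test_that("the regional unit value follows the area-weighted crop formula", {
  # single crop: E collapses to p*q/7
  one <- data.frame(sown_area_hm2 = 123, yield_t_per_hm2 = 1,
                    price_yuan_per_t = 700)
  expect_equal(deriveUnitValue(one), 100)
  # linear in prices
  ct <- genCropTable(5, seed = 2)
  ct2 <- ct; ct2$price_yuan_per_t <- 2 * ct$price_yuan_per_t
  expect_equal(deriveUnitValue(ct2), 2 * deriveUnitValue(ct))
  # spreadsheet-style oracle over the packaged regional crop rows, treating
  # the printed yields as t/hm2 (the only dimensionally consistent reading)
  crops <- read.csv(system.file("extdata", "anyang_crops.csv",
                                package = "fluscape"), comment.char = "#")
  tidy <- data.frame(sown_area_hm2 = crops$sown_area_hm2,
                     yield_t_per_hm2 = crops$grain_yield_10kt,
                     price_yuan_per_t = crops$price_yuan_per_t)
  oracle <- with(tidy, sum(sown_area_hm2 * yield_t_per_hm2 *
                             price_yuan_per_t) / sum(sown_area_hm2) / 7)
  expect_equal(deriveUnitValue(tidy), oracle, tolerance = 1e-12)
  expect_equal(oracle, 1729.0027, tolerance = 1e-4)

  bad <- one; bad$sown_area_hm2 <- 0
  expect_error(deriveUnitValue(bad), "positive")
})

test_that("the packaged coefficient table carries the regional unit values", {
  tab <- esvCoefficients()
  v <- esvValues(tab)
  expect_identical(dim(v), c(11L, 6L))
  expect_equal(v["hydrology_regulation", "water"], 1766.01)
  expect_equal(v["water_supply", "built"], -268.66)
  expect_equal(v["food_production", "built"], 0)
  expect_equal(v["climate_regulation", "woodland"], 121.43)
  expect_equal(v["food_production", "cultivated"], 14.68)
  expect_setequal(unique(unname(tab@categories)),
                  c("provisioning", "regulating", "supporting", "cultural"))
  # a table with a missing cell is rejected
  tmp <- tempfile(fileext = ".csv")
  df <- read.csv(system.file("extdata", "anyang_esv_coefficients.csv",
                             package = "fluscape"), comment.char = "#")
  df$water[3] <- NA
  write.csv(df, tmp, row.names = FALSE)
  expect_error(esvCoefficients(tmp), "missing cells")
  df2 <- df[, setdiff(names(df), "unused")]
  write.csv(df2, tmp, row.names = FALSE)
  expect_error(esvCoefficients(tmp), "missing columns")
})

test_that("rescaling a table scales every coefficient by the unit-value ratio", {
  tab <- esvCoefficients()
  up <- rescaleCoefficients(tab, eNew = 300, eRef = 100)
  expect_equal(esvValues(up), 3 * esvValues(tab))
})

test_that("ESV of unit-area single-class maps reproduces the table cells", {
  tab <- esvCoefficients()
  oneCell <- function(classCode) landUseMap(matrix(classCode, 1, 1), cellSize = 100)
  water <- computeEsv(oneCell(4L), tab, services = "hydrology_regulation")
  expect_equal(water$value, 1766.01)
  built <- computeEsv(oneCell(5L), tab, services = "water_supply")
  expect_equal(built$value, -268.66)
  # two hectares, two classes: climate regulation adds 6.22 + 121.43
  two <- landUseMap(matrix(c(1L, 2L), 1, 2), cellSize = 100)
  clim <- computeEsv(two, tab, services = "climate_regulation")
  expect_equal(clim$value, 127.65)
  # all-nodata map values at zero for every service
  zero <- computeEsv(landUseMap(matrix(0L, 2, 2)), tab)
  expect_true(all(zero$value == 0))
  expect_error(computeEsv(two, tab, services = "pollination"), "unknown")
})

test_that("ESV is additive over disjoint supports and per-category totals close", {
  set.seed(3)
  tab <- esvCoefficients()
  gA <- matrix(sample(0:6, 64, replace = TRUE), 8, 8)
  gB <- matrix(sample(0:6, 64, replace = TRUE), 8, 8)
  gB[gA != 0] <- 0L  # disjoint active supports
  gU <- gA; gU[gB != 0] <- gB[gB != 0]
  esvA <- computeEsv(landUseMap(gA), tab)
  esvB <- computeEsv(landUseMap(gB), tab)
  esvU <- computeEsv(landUseMap(gU), tab)
  expect_equal(esvU$value, esvA$value + esvB$value, tolerance = 1e-9)
  # category sums equal the grand total
  expect_equal(sum(tapply(esvU$value, esvU$category, sum)),
               attr(esvU, "total"), tolerance = 1e-9)
})

test_that("UESV grids normalise by member area and conserve total ESV", {
  tab <- esvCoefficients()
  # uniform water map: every complete grid cell carries the same UESV
  uni <- landUseMap(matrix(4L, 8, 8), cellSize = 500)
  grid <- computeUesvGrid(uni, tab, gridSize = 2000)
  expect_equal(length(unique(round(grid$uesv, 9))), 1L)
  # an edge grid with half the area but the same composition has equal UESV
  half <- landUseMap(matrix(4L, 8, 10), cellSize = 500)  # 2 edge columns
  g2 <- computeUesvGrid(half, tab, gridSize = 2000)
  expect_equal(length(unique(round(g2$uesv, 9))), 1L)
  expect_gt(max(g2$area_hm2) / min(g2$area_hm2), 1.9)

  # hand-computed 2x2-grid toy
  g <- matrix(c(1L, 1L, 2L, 4L), 2, 2)  # cultivated col, woodland/water col
  m <- landUseMap(g, cellSize = 100)    # each cell 1 hm2
  gt <- computeUesvGrid(m, tab, gridSize = 100)
  expect_identical(nrow(gt), 4L)
  v <- esvValues(tab)
  expect_equal(gt$uesv[gt$grid_row == 1 & gt$grid_col == 1],
               sum(v[, "cultivated"]))
  expect_equal(gt$uesv[gt$grid_row == 1 & gt$grid_col == 2],
               sum(v[, "woodland"]))
  expect_equal(gt$uesv[gt$grid_row == 2 & gt$grid_col == 2],
               sum(v[, "water"]))

  # conservation: sum over grids of UESV * area = whole-map ESV
  set.seed(9)
  gr <- matrix(sample(0:6, 30 * 30, replace = TRUE), 30, 30)
  mr <- landUseMap(gr, cellSize = 30)
  grid3 <- computeUesvGrid(mr, tab, gridSize = 210)
  expect_equal(sum(grid3$uesv * grid3$area_hm2),
               attr(computeEsv(mr, tab), "total"),
               tolerance = 1e-6 * abs(attr(computeEsv(mr, tab), "total")))
  expect_error(computeUesvGrid(mr, tab, gridSize = 10), "cell size")
})

test_that("natural-breaks levels are optimal and ordered", {
  # one value per level, labels monotone in value
  lev <- classifyLevels(c(3, 1, 5, 2, 4), k = 5)
  expect_equal(lev, c(3L, 1L, 5L, 2L, 4L), ignore_attr = TRUE)
  # two well-separated clusters split at the gap
  x <- c(1.0, 1.2, 0.9, 10.1, 10.4, 9.8)
  lev2 <- classifyLevels(x, k = 2)
  expect_equal(lev2, c(1L, 1L, 1L, 2L, 2L, 2L), ignore_attr = TRUE)
  # optimality vs exhaustive search over all partitions, several draws
  set.seed(12)
  for (i in 1:5) {
    vals <- round(runif(sample(8:12, 1), 0, 100), 1)
    for (k in c(3, 5)) {
      lv <- classifyLevels(vals, k = k)
      expect_equal(jenksSseOf(vals, lv), bruteJenksSse(vals, k),
                   tolerance = 1e-9, label = paste("k =", k))
      # labels ordered by value
      expect_true(all(diff(lv[order(vals)]) >= 0))
    }
  }
  expect_warning(lev3 <- classifyLevels(c(1, 1, 2, 2), k = 5), "collapsing")
  expect_identical(sort(unique(lev3)), c(1L, 2L))
})
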