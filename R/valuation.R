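# Equivalent-factor valuation: regional unit value from crop statistics,
# service-by-class coefficient table, ESV of land mosaics, per-grid UESV and
# Jenks natural-breaks levels.

#' Regional unit value of food production
#'
#' The economic value of food production per unit cultivated area,
#' `E = (1/7) * sum(m_i * p_i * q_i) / M` over the crops of the regional
#' statistics table, where `m_i` is the sown area (hm2), `p_i` the national
#' average price (yuan/t), `q_i` the yield (t/hm2) and `M` the total sown
#' area. The 1/7 factor expresses the convention that an unmanaged natural
#' ecosystem delivers one seventh of the economic value of farmed food
#' production per unit area.
#'
#' @param cropTable `data.frame` with columns `sown_area_hm2`,
#'   `yield_t_per_hm2`, `price_yuan_per_t` (as produced by [genCropTable()]).
#' @return E in yuan per hectare per year.
#' @export
deriveUnitValue <- function(cropTable) {
  m <- cropTable$sown_area_hm2
  p <- cropTable$price_yuan_per_t
  q <- cropTable$yield_t_per_hm2
  if (any(c(m, p, q) <= 0)) stop("crop table entries must be positive")
  M <- sum(m)
  if (M <= 0) stop("total sown area must be positive")
  sum(m * p * q) / M / 7
}

#' Load an equivalent-factor coefficient table
#'
#' With no path, loads the coefficient table for Anyang shipped with the
#' package (eleven services by six land classes, 100 yuan/hm2/yr). A user
#' CSV must carry `service`, `category` and one column per land-class name.
#'
#' @param path optional CSV path.
#' @return An [EsvTable-class].
#' @examples
#' tab <- esvCoefficients()
#' esvValues(tab)["hydrology_regulation", "water"]
#' @export
esvCoefficients <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "anyang_esv_coefficients.csv",
                        package = "fluscape", mustWork = TRUE)
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  needed <- c("service", "category", names(landUseClasses()))
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stop("coefficient table is missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(df[, names(landUseClasses())]))))
    stop("coefficient table has missing cells")
  v <- as.matrix(df[, names(landUseClasses())])
  rownames(v) <- df$service
  new("EsvTable", values = v,
      categories = stats::setNames(df$category, df$service))
}

#' Rescale a coefficient table to a different regional unit value
#'
#' Coefficient tables are proportional to the regional unit value E they
#' were derived from; a table for one region is carried to another by the
#' ratio of unit values.
#'
#' @param table an [EsvTable-class].
#' @param eNew unit value of the target region (yuan/hm2).
#' @param eRef unit value the table was built with (yuan/hm2).
#' @return A rescaled [EsvTable-class].
#' @export
rescaleCoefficients <- function(table, eNew, eRef) {
  stopifnot(is(table, "EsvTable"), eNew > 0, eRef > 0)
  new("EsvTable", values = table@values * (eNew / eRef),
      categories = table@categories)
}

classAreas <- function(map) {
  # per-class area in hectares
  classCounts(map) * map@cellSize^2 / 1e4
}

#' Ecosystem-service value of a land-use map
#'
#' For each service `c`, `ESV_c = sum_k area_k * V[c, k]` over the six land
#' classes, with areas in hectares and coefficients in 100 yuan/hm2/yr;
#' negative contributions (built-land sinks) are retained.
#'
#' @param map a [LandUseMap-class] (cell size metadata supplies the areas).
#' @param table an [EsvTable-class].
#' @param services optional character vector restricting the services.
#' @return `data.frame` with columns `service`, `category`, `value` (100
#'   yuan/yr), plus the grand total as attribute `total`.
#' @export
computeEsv <- function(map, table = esvCoefficients(), services = NULL) {
  stopifnot(is(map, "LandUseMap"), is(table, "EsvTable"))
  v <- table@values
  if (!is.null(services)) {
    bad <- setdiff(services, rownames(v))
    if (length(bad)) stop("unknown services: ", paste(bad, collapse = ", "))
    v <- v[services, , drop = FALSE]
  }
  areas <- classAreas(map)
  vals <- as.vector(v %*% areas)
  out <- data.frame(service = rownames(v),
                    category = unname(table@categories[rownames(v)]),
                    value = vals)
  attr(out, "total") <- sum(vals)
  out
}

#' Per-grid UESV surface
#'
#' Partitions the raster into `gridSize`-metre squares (cells assigned by
#' their block, i.e. centroid membership), computes each grid unit's ESV
#' from its member cells and normalises by the member area actually present
#' (`UESV = ESV / S`), so irregular edge grids are comparable to interior
#' ones. Grids with no active cells are dropped.
#'
#' @param map a [LandUseMap-class].
#' @param table an [EsvTable-class].
#' @param gridSize analysis grid edge in metres (default 1000, i.e. the
#'   1 km x 1 km unit); must be at least the cell size.
#' @return `data.frame` with one row per grid unit: `grid_row`, `grid_col`,
#'   `area_hm2`, one column per service, one per category
#'   (`provisioning`, `regulating`, `supporting`, `cultural`), `total`
#'   (100 yuan/yr) and `uesv` (100 yuan/hm2/yr). Grid dimensions are kept in
#'   attributes `grid_dims`.
#' @export
computeUesvGrid <- function(map, table = esvCoefficients(), gridSize = 1000) {
  stopifnot(is(map, "LandUseMap"), is(table, "EsvTable"))
  if (gridSize < map@cellSize) stop("gridSize must be >= the cell size")
  g <- map@grid
  step <- gridSize / map@cellSize
  gr <- ceiling(row(g) / step)
  gc <- ceiling(col(g) / step)
  act <- g != NODATA
  cellArea <- map@cellSize^2 / 1e4
  key <- paste(gr[act], gc[act])
  byGrid <- split(g[act], key)
  ids <- do.call(rbind, strsplit(names(byGrid), " "))
  counts <- t(vapply(byGrid, function(cl) tabulate(cl, nbins = N_CLASSES),
                     integer(N_CLASSES)))
  areas <- counts * cellArea
  sv <- areas %*% t(table@values)          # grids x services
  catNames <- c("provisioning", "regulating", "supporting", "cultural")
  catTot <- vapply(catNames, function(ct)
    rowSums(sv[, names(table@categories)[table@categories == ct],
               drop = FALSE]), numeric(nrow(sv)))
  totalArea <- rowSums(areas)
  out <- data.frame(grid_row = as.integer(ids[, 1L]),
                    grid_col = as.integer(ids[, 2L]),
                    area_hm2 = totalArea)
  out <- cbind(out, as.data.frame(sv), as.data.frame(catTot))
  out$total <- rowSums(sv)
  out$uesv <- out$total / totalArea
  out <- out[order(out$grid_row, out$grid_col), ]
  rownames(out) <- NULL
  attr(out, "grid_dims") <- c(max(out$grid_row), max(out$grid_col))
  attr(out, "cell_size") <- map@cellSize
  out
}

#' Jenks natural-breaks classification
#'
#' Optimal 1-D classification into `k` classes minimising the within-class
#' sum of squared deviations (Fisher's dynamic program, which is exactly
#' optimal, not the heuristic reallocation variant). Labels `1..k` are
#' ordered by increasing value. With fewer distinct values than classes the
#' degenerate classes collapse, with a warning.
#'
#' @param values numeric vector to classify.
#' @param k number of classes (default 5, the conventional UESV levels).
#' @return Integer vector of levels `1..k` aligned with `values`; the break
#'   upper bounds are attached as attribute `breaks`.
#' @export
classifyLevels <- function(values, k = 5L) {
  n <- length(values)
  if (n == 0L) return(integer(0))
  distinct <- sort(unique(values))
  if (length(distinct) < k) {
    warning("fewer distinct values (", length(distinct), ") than classes (",
            k, "); collapsing")
    k <- length(distinct)
  }
  ord <- order(values)
  x <- values[ord]
  # Fisher DP over the sorted values: D[m, j] = min SSE of x[1..m] in j classes
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(i, j) {
    # SSE of x[i..j]
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  D <- matrix(Inf, n, k)
  B <- matrix(1L, n, k)
  for (m in seq_len(n)) D[m, 1L] <- sse(1L, m)
  if (k > 1L) for (j in 2L:k) {
    for (m in j:n) {
      best <- Inf; bi <- j
      for (i in j:m) {
        v <- D[i - 1L, j - 1L] + sse(i, m)
        if (v < best) { best <- v; bi <- i }
      }
      D[m, j] <- best; B[m, j] <- bi
    }
  }
  # recover class boundaries
  lev <- integer(n)
  m <- n
  for (j in k:1) {
    i <- if (j == 1L) 1L else B[m, j]
    lev[i:m] <- j
    m <- i - 1L
  }
  out <- integer(n)
  out[ord] <- lev
  attr(out, "breaks") <- vapply(seq_len(k), function(j) max(x[lev == j]),
                                numeric(1))
  out
}
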