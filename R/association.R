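# Trade-off/synergy analysis between service-category UESV surfaces:
# contiguity weights on the analysis grid, Pearson correlation, bivariate
# global and local Moran's I, conditional-permutation significance and LISA
# cluster labelling.

#' Build contiguity weights on a regular grid
#'
#' Queen (8-neighbour) or rook (4-neighbour) contiguity on an `r x c` grid,
#' row-standardised. Cells are unrolled column-major, matching R matrices.
#'
#' @param gridShape integer `(rows, cols)` with `rows*cols >= 2`.
#' @param scheme `"queen"` (default) or `"rook"`.
#' @return A [SpatialWeights-class].
#' @examples
#' w <- buildWeights(c(3, 3))
#' Matrix::rowSums(w@W)
#' @export
buildWeights <- function(gridShape, scheme = c("queen", "rook")) {
  scheme <- match.arg(scheme)
  r <- as.integer(gridShape[1L]); cc <- as.integer(gridShape[2L])
  if (r * cc < 2L) stop("grid must have at least 2 cells")
  offs <- if (scheme == "queen") MOORE_OFFSETS else
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  rows <- rep(seq_len(r), cc)
  cols <- rep(seq_len(cc), each = r)
  ii <- integer(0); jj <- integer(0)
  for (o in seq_len(nrow(offs))) {
    rr <- rows + offs[o, 1L]; c2 <- cols + offs[o, 2L]
    ok <- rr >= 1L & rr <= r & c2 >= 1L & c2 <= cc
    ii <- c(ii, which(ok))
    jj <- c(jj, (c2[ok] - 1L) * r + rr[ok])
  }
  W <- sparseMatrix(i = ii, j = jj, x = 1, dims = c(r * cc, r * cc))
  rs <- Matrix::rowSums(W)
  islands <- which(rs == 0)
  rs[rs == 0] <- 1
  W <- W / rs
  new("SpatialWeights", W = W, scheme = scheme, dims = c(r, cc),
      islands = as.integer(islands))
}

# population (1/n) z-scores; this standardisation makes mean(local) = global
# exact under row-standardised weights
zScore <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) stop("zero variance: spatial correlation undefined")
  (x - mean(x)) / s
}

#' Pearson correlation between two service surfaces
#'
#' @param x,y numeric vectors of equal length (>= 3) with positive variance.
#' @return Sample correlation coefficient.
#' @export
pearsonCorrelation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  cor(x, y)
}

#' Bivariate global Moran's I
#'
#' Spatial cross-correlation of `x` with the spatial lag of `y`: with
#' population z-scores and row-standardised weights,
#' `I = (1/n) * sum_i z_i^x * (W z^y)_i`. With `y = x` this is the classic
#' univariate Moran's I.
#'
#' @param x,y numeric vectors aligned to the weights.
#' @param W a [SpatialWeights-class].
#' @return The global index (typically in `[-1, 1]`; not clipped).
#' @export
bivariateMoran <- function(x, y, W) {
  stopifnot(is(W, "SpatialWeights"))
  n <- nrow(W@W)
  if (length(x) != n || length(y) != n) stop("x, y must match the weights")
  zx <- zScore(x); zy <- zScore(y)
  mean(zx * as.vector(W@W %*% zy))
}

#' Bivariate local Moran's I
#'
#' Per cell `i`, `I_i = z_i^x * (W z^y)_i`; the mean of the local statistics
#' equals the global index under row-standardised weights.
#'
#' @inheritParams bivariateMoran
#' @return Numeric vector of per-cell local statistics.
#' @export
bivariateLocalMoran <- function(x, y, W) {
  stopifnot(is(W, "SpatialWeights"))
  n <- nrow(W@W)
  if (length(x) != n || length(y) != n) stop("x, y must match the weights")
  zx <- zScore(x); zy <- zScore(y)
  zx * as.vector(W@W %*% zy)
}

# neighbour index/weight lists from the sparse weights
neighborList <- function(W) {
  Wt <- as(W@W, "TsparseMatrix")
  split(data.frame(j = Wt@j + 1L, w = Wt@x), Wt@i + 1L)
}

#' Conditional-permutation significance of the local statistics
#'
#' For each cell, the values of `y` at the other locations are permuted
#' `nPerm` times (the cell's own value is held out of its neighbourhood, the
#' standard conditional scheme), the local statistic recomputed, and the
#' two-sided pseudo p-value taken as
#' `(count(|I_perm| >= |I_obs|) + 1) / (nPerm + 1)`.
#'
#' @inheritParams bivariateMoran
#' @param nPerm number of permutations (>= 99; default 999).
#' @param seed integer seed; results are reproducible given it.
#' @return Numeric vector of per-cell pseudo p-values in
#'   `[1/(nPerm+1), 1]`.
#' @export
permutationSignificance <- function(x, y, W, nPerm = 999L, seed = 1L) {
  stopifnot(is(W, "SpatialWeights"))
  if (nPerm < 99L) stop("nPerm must be >= 99")
  n <- nrow(W@W)
  zy <- zScore(y)
  obsLag <- as.vector(W@W %*% zy)
  nbs <- neighborList(W)
  p <- rep(1, n)
  set.seed(childSeed(seed, "permutation"))
  for (i in seq_len(n)) {
    nb <- nbs[[as.character(i)]]
    if (is.null(nb)) next                    # island: no statistic
    k <- nrow(nb)
    pool <- zy[-i]
    lagPerm <- vapply(seq_len(nPerm), function(j)
      sum(nb$w * pool[sample.int(n - 1L, k)]), numeric(1))
    exceed <- sum(abs(lagPerm) >= abs(obsLag[i]))
    p[i] <- (exceed + 1) / (nPerm + 1)
  }
  p
}

#' LISA cluster labels for a service pair
#'
#' Cells whose local statistic is significant at `alpha` are labelled by the
#' quadrant of `(z_i^x, (W z^y)_i)`: `HH` (both high) and `LL` (both low)
#' read as synergy, `HL` and `LH` as trade-off; all other cells are `NS`.
#'
#' @inheritParams permutationSignificance
#' @param alpha pseudo-significance level (default 0.05).
#' @return `data.frame` with per-cell `local` (I_i), `p`, and `label` in
#'   `{HH, LL, HL, LH, NS}`; per-label counts attached as attribute
#'   `counts`.
#' @export
lisaClassify <- function(x, y, W, alpha = 0.05, nPerm = 999L, seed = 1L) {
  zx <- zScore(x); zy <- zScore(y)
  lag <- as.vector(W@W %*% zy)
  local <- zx * lag
  p <- permutationSignificance(x, y, W, nPerm = nPerm, seed = seed)
  label <- rep("NS", length(x))
  sig <- p < alpha
  label[sig & zx > 0 & lag > 0] <- "HH"
  label[sig & zx < 0 & lag < 0] <- "LL"
  label[sig & zx > 0 & lag < 0] <- "HL"
  label[sig & zx < 0 & lag > 0] <- "LH"
  out <- data.frame(local = local, p = p,
                    label = factor(label, levels = c("HH", "LL", "HL", "LH", "NS")))
  attr(out, "counts") <- table(out$label)
  out
}

#' Trade-off/synergy report over service-category pairs
#'
#' For every unordered pair of the four service categories on the UESV
#' analysis grid: Pearson correlation, bivariate global Moran's I, and the
#' LISA cluster counts (synergy = HH + LL, trade-off = HL + LH).
#'
#' @param esvGrid grid table from [computeUesvGrid()]. The analysis runs on
#'   grid units present in the table; the contiguity weights come from the
#'   grid's row/column layout.
#' @param scheme contiguity scheme (default queen).
#' @param alpha significance level for the LISA labels.
#' @param nPerm permutations for the pseudo p-values.
#' @param seed integer seed.
#' @return `data.frame` with one row per pair: `pair`, `pearson`, `moran_i`,
#'   `hh`, `ll`, `hl`, `lh`, `ns`, `synergy`, `tradeoff`.
#' @export
servicePairReport <- function(esvGrid, scheme = "queen", alpha = 0.05,
                              nPerm = 999L, seed = 1L) {
  dims <- attr(esvGrid, "grid_dims")
  if (is.null(dims)) stop("esvGrid must come from computeUesvGrid()")
  full <- nrow(esvGrid) == prod(dims)
  if (!full)
    stop("pair report requires a complete rectangular grid (",
         prod(dims), " units, got ", nrow(esvGrid), ")")
  # order column-major to align with the weights
  ord <- order(esvGrid$grid_col, esvGrid$grid_row)
  W <- buildWeights(dims, scheme = scheme)
  cats <- c(p = "provisioning", r = "regulating", s = "supporting",
            c = "cultural")
  pairs <- utils::combn(names(cats), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- cats[[pairs[1L, j]]]; b <- cats[[pairs[2L, j]]]
    xa <- esvGrid[[a]][ord]; xb <- esvGrid[[b]][ord]
    lisa <- lisaClassify(xa, xb, W, alpha = alpha, nPerm = nPerm,
                         seed = seed + j)
    cnt <- attr(lisa, "counts")
    data.frame(pair = paste0(pairs[1L, j], "-", pairs[2L, j]),
               pearson = pearsonCorrelation(xa, xb),
               moran_i = bivariateMoran(xa, xb, W),
               hh = as.integer(cnt[["HH"]]), ll = as.integer(cnt[["LL"]]),
               hl = as.integer(cnt[["HL"]]), lh = as.integer(cnt[["LH"]]),
               ns = as.integer(cnt[["NS"]]))
  })
  out <- do.call(rbind, rows)
  out$synergy <- out$hh + out$ll
  out$tradeoff <- out$hl + out$lh
  out
}
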