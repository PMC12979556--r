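## Ripley cross-K/L co-localization suite: positive-spot calling, the
## minimum-count sample filter, the cross-K estimator with optional isotropic
## edge correction, Monte-Carlo independence envelopes, and the two effect
## sizes (Aggregation Index, Cohen's d of L(r) - r). All distances are in
## micrometers.

#' Convert pixel distances to micrometers
#'
#' Element-wise multiplication by the sample's scale; every public output of
#' the co-localization suite is in micrometers.
#'
#' @param rPixels numeric distances in full-resolution pixels.
#' @param micronsPerPixel positive scale.
#' @return numeric distances in micrometers
#' @export
toMicrons <- function(rPixels, micronsPerPixel) {
  checkPositiveScalar(micronsPerPixel, "micronsPerPixel")
  rPixels * micronsPerPixel
}

#' Call positive spots for one cell type
#'
#' A spot is positive for a cell type when its deconvolved weight strictly
#' exceeds the type's quantile over all spots of the sample (default the
#' 25th percentile, linear-interpolation convention, i.e. `quantile(type=7)`).
#' Coordinates are emitted in micrometers. When every spot carries the same
#' weight the threshold equals that weight, no spot exceeds it, and an empty
#' pattern is returned with the degenerate flag set and a warning.
#'
#' @param weights a [CellTypeWeights-class] covering the grid's spots.
#' @param grid the sample's [SpotGrid-class].
#' @param cellType a column of `weights`.
#' @param quantileThreshold quantile in (0,1), default 0.25.
#' @return a [PointPattern-class] in micrometers
#' @examples
#' g <- generateSpotLattice(2, 2)
#' w <- cellTypeWeights(matrix(c(0.1, 0.2, 0.3, 0.4, 0.9, 0.8, 0.7, 0.6), 4, 2,
#'   dimnames = list(spotIds(g), c("tumor", "stroma"))))
#' definePositiveSpots(w, g, "tumor")  # threshold 0.175 -> 3 positive spots
#' @export
definePositiveSpots <- function(weights, grid, cellType,
                                quantileThreshold = 0.25) {
  stopIfNot(quantileThreshold > 0 && quantileThreshold < 1,
            "quantileThreshold must lie in (0, 1)")
  if (!cellType %in% cellTypes(weights))
    stop("'", cellType, "' is not a column of the weight matrix", call. = FALSE)
  ids <- spotIds(grid)
  if (!all(ids %in% rownames(weights)))
    stop("the weight matrix must cover every spot of the grid", call. = FALSE)
  w <- weights@.Data[ids, cellType]
  um <- micronCoords(grid)
  win <- as.numeric(spotWindow(grid, "um"))
  degenerate <- diff(range(w)) == 0
  if (degenerate)
    warning(sprintf("all %d weights for '%s' are identical (%.6g): no positive spots",
                    length(w), cellType, w[1]))
  thr <- stats::quantile(w, quantileThreshold, names = FALSE, type = 7)
  pos <- which(w > thr)
  new("PointPattern", sampleId = grid@sampleId, cellType = cellType,
      coords = um[pos, , drop = FALSE], spotIds = ids[pos],
      window = win, degenerate = degenerate)
}

#' Minimum positive-spot filter for a sample
#'
#' A sample enters the co-localization analysis only when both cell types
#' have at least `minPositiveSpots` positive spots ("fewer than 40" fails,
#' so exactly 40 passes). Patterns must come from the same sample and
#' window.
#'
#' @param patternI,patternJ the two [PointPattern-class] objects.
#' @param minPositiveSpots minimum count per type (default 40).
#' @return list with `pass` (logical) and `reason` (character, `""` on pass)
#' @export
filterSamples <- function(patternI, patternJ, minPositiveSpots = 40L) {
  stopIfNot(minPositiveSpots >= 1, "minPositiveSpots must be >= 1")
  if (!identical(patternI@sampleId, patternJ@sampleId) ||
      max(abs(patternI@window - patternJ@window)) >
        1e-9 * max(1, abs(patternI@window)))
    stop("patterns must share the same sample and window", call. = FALSE)
  reasons <- character()
  for (p in list(patternI, patternJ)) {
    n <- nSpots(p)
    if (any(p@degenerate) && n == 0)
      reasons <- c(reasons, sprintf("'%s' is degenerate (no positive spots)",
                                    p@cellType))
    else if (n < minPositiveSpots)
      reasons <- c(reasons, sprintf("'%s' has %d positive spots (< %d)",
                                    p@cellType, n, minPositiveSpots))
  }
  pass <- length(reasons) == 0
  if (!pass)
    logStage("filterSamples", sample = patternI@sampleId, pass = FALSE,
             reason = paste(reasons, collapse = "; "))
  list(pass = pass, reason = paste(reasons, collapse = "; "))
}

#' Default distance grid for a sample
#'
#' Thirty (by default) equally spaced distances from half the lattice pitch
#' (estimated as the median nearest-neighbor spacing) up to a quarter of the
#' shorter window side.
#'
#' @param grid a [SpotGrid-class].
#' @param rSteps number of grid values.
#' @param rMaxFrac maximum distance as a fraction of the shorter window side
#'   (must be <= 0.5, where the isotropic correction stays valid).
#' @return increasing numeric vector of distances in micrometers
#' @export
defaultRGrid <- function(grid, rSteps = 30L, rMaxFrac = 0.25) {
  stopIfNot(rSteps >= 2, "rSteps must be >= 2")
  stopIfNot(rMaxFrac > 0 && rMaxFrac <= 0.5, "rMaxFrac must lie in (0, 0.5]")
  w <- spotWindow(grid, "um")
  side <- min(w[2] - w[1], w[4] - w[3])
  pitch <- 2 * halfMedianNNSpacing(micronCoords(grid))
  rMin <- if (pitch > 0) pitch / 2 else side / (2 * rSteps)
  rMax <- rMaxFrac * side
  if (rMin >= rMax) rMin <- rMax / rSteps
  seq(rMin, rMax, length.out = rSteps)
}

# Ripley isotropic correction weight for a rectangular window: the
# reciprocal of the fraction of the circle of radius d centered at (px, py)
# that lies inside the window. Valid for d <= half the shorter side, where
# the circle can cross at most the nearest vertical and horizontal edges.
ripleyIsotropicWeight <- function(px, py, d, window) {
  d1 <- pmin(px - window[1], window[2] - px)
  d2 <- pmin(py - window[3], window[4] - py)
  w <- rep(1, length(d))
  out <- d > 0 & (d > d1 | d > d2)
  if (any(out)) {
    b1 <- acos(pmin(d1[out] / d[out], 1))
    b2 <- acos(pmin(d2[out] / d[out], 1))
    corner <- d[out]^2 > d1[out]^2 + d2[out]^2
    exterior <- ifelse(corner, b1 + b2 + pi / 2, 2 * b1 + 2 * b2)
    w[out] <- 2 * pi / (2 * pi - exterior)
  }
  w
}

# K/L/D curves from flattened pair distances (and matching weights):
# K(r) = |A| / (n_i n_j) * sum of w over pairs with d <= r.
kCurvesFromDistances <- function(d, w, rGrid, area, ni, nj) {
  ord <- order(d)
  cw <- cumsum(w[ord])
  idx <- findInterval(rGrid, d[ord])
  K <- area * c(0, cw)[idx + 1] / (ni * nj)
  L <- sqrt(K / pi)
  list(K = K, L = L, D = L - rGrid)
}

#' Cross-type Ripley K and L functions
#'
#' Estimates `K_ij(r) = |A| / (n_i n_j) * sum over ordered cross pairs of
#' w(p, q) 1[d(p, q) <= r]`, with `w = 1` (no edge correction) or the
#' Ripley isotropic weight (reciprocal of the fraction of the circle through
#' q centered at p lying inside the window). Pairs at identical coordinates
#' (a spot positive for both types) are counted at distance zero — excluding
#' them would bias against co-localization at the spot scale. `L = sqrt(K/pi)`
#' and `D = L - r`; under cross-type independence `L(r) = r` in expectation.
#'
#' @param patternI,patternJ two [PointPattern-class] objects on the same
#'   window (both nonempty).
#' @param rGrid increasing positive distances (micrometers); the maximum
#'   must not exceed half the shorter window side.
#' @param edgeCorrection `"none"` (default; the Monte-Carlo null is computed
#'   on the identical window so edge bias cancels in the comparison) or
#'   `"isotropic"` for descriptive K values.
#' @return a [CrossKResult-class] with `K`, `L`, `D` and the two effect
#'   sizes filled (no envelope; see [mcEnvelope()])
#' @examples
#' w <- c(0, 10, 0, 10)
#' p1 <- new("PointPattern", sampleId = "s", cellType = "a",
#'   coords = cbind(x = 2, y = 5), spotIds = character(), window = w,
#'   degenerate = FALSE)
#' p2 <- new("PointPattern", sampleId = "s", cellType = "b",
#'   coords = cbind(x = 5, y = 1), spotIds = character(), window = w,
#'   degenerate = FALSE)
#' crossK(p1, p2, rGrid = c(4, 5))  # K jumps to |A| = 100 at r = 5
#' @export
crossK <- function(patternI, patternJ, rGrid,
                   edgeCorrection = c("none", "isotropic")) {
  edgeCorrection <- match.arg(edgeCorrection)
  ni <- nSpots(patternI); nj <- nSpots(patternJ)
  if (ni * nj == 0)
    stop("both patterns must be nonempty (apply filterSamples first)",
         call. = FALSE)
  if (max(abs(patternI@window - patternJ@window)) >
      1e-9 * max(1, abs(patternI@window)))
    stop("patterns must share the same window", call. = FALSE)
  win <- patternI@window
  side <- min(win[2] - win[1], win[4] - win[3])
  rGrid <- as.numeric(rGrid)
  if (any(rGrid <= 0) || is.unsorted(rGrid, strictly = TRUE))
    stop("rGrid must be strictly increasing and positive", call. = FALSE)
  if (max(rGrid) > side / 2 + 1e-9)
    stop("max(rGrid) must not exceed half the shorter window side",
         call. = FALSE)
  area <- (win[2] - win[1]) * (win[4] - win[3])

  a <- micronCoords(patternI); b <- micronCoords(patternJ)
  d <- as.numeric(crossDist(a, b))
  w <- if (edgeCorrection == "isotropic")
    ripleyIsotropicWeight(rep(a[, 1], times = nj), rep(a[, 2], times = nj),
                          d, win)
  else rep(1, length(d))
  cur <- kCurvesFromDistances(d, w, rGrid, area, ni, nj)
  es <- effectSizes(cur$D)
  new("CrossKResult",
      sampleId = patternI@sampleId, typeI = patternI@cellType,
      typeJ = patternJ@cellType, rGrid = rGrid,
      K = cur$K, L = cur$L, D = cur$D,
      envLo = rep(NA_real_, length(rGrid)),
      envHi = rep(NA_real_, length(rGrid)),
      nSim = 0L, nI = as.integer(ni), nJ = as.integer(nj),
      aggregationIndex = es$aggregationIndex, cohensD = es$cohensD,
      pGlobal = NA_real_, edgeCorrection = edgeCorrection,
      seed = NA_integer_)
}

#' Aggregation Index and Cohen's d of the D curve
#'
#' `aggregationIndex` is the exact fraction of grid distances at which
#' `D(r) = L(r) - r` is strictly positive; `cohensD` is `mean(D) / sd(D)`
#' with the unbiased (n-1) standard deviation. When `sd(D) = 0` Cohen's d is
#' undefined and reported as NA (never an error).
#'
#' @param x a [CrossKResult-class] or the numeric `D` curve itself
#'   (>= 2 grid points).
#' @return list with `aggregationIndex`, `cohensD` and `degenerate`
#'   (TRUE when `sd(D) = 0`)
#' @examples
#' effectSizes(c(1, 1, -1, -1))  # AI 0.5, d 0
#' effectSizes(c(1, 2, 3))       # AI 1, d 2
#' @export
effectSizes <- function(x) {
  D <- if (is(x, "CrossKResult")) x@D else as.numeric(x)
  stopIfNot(length(D) >= 2, "the D curve needs at least two grid points")
  s <- stats::sd(D)
  list(aggregationIndex = mean(D > 0),
       cohensD = if (s == 0) NA_real_ else mean(D) / s,
       degenerate = s == 0)
}

#' Monte-Carlo independence envelope and global test
#'
#' Simulates the null hypothesis of spatial independence between the two
#' cell types on the sample's own spot lattice: by default each simulation
#' redraws each type's positive set as an independent uniform random subset
#' of the spots, preserving the observed counts (`independent_relabeling`).
#' A `label_swap` variant redraws both sets from the union of the observed
#' positive spots, as a sensitivity analysis. Pointwise envelopes for
#' `D(r) = L(r) - r` discard the `floor(alpha * (nSim + 1))` most extreme
#' simulated values in each tail (`alpha = (1 - level) / 2`), so
#' `nSim = 19, level = 0.9` keeps the second-smallest and second-largest
#' values. The global p-value uses the add-one Monte-Carlo convention on
#' `T = mean(D)` so it is never zero.
#'
#' @param patternI,patternJ observed [PointPattern-class] objects whose
#'   spots belong to `grid`.
#' @param grid the sample's [SpotGrid-class] (all candidate spots).
#' @param nSim number of simulations (>= 19; default 999).
#' @param level envelope level (default 0.95).
#' @param nullModel `"independent_relabeling"` (default) or `"label_swap"`.
#' @param seed integer seed.
#' @param rGrid distance grid; default [defaultRGrid()] of the sample.
#' @param edgeCorrection passed to the estimator, identical for observed and
#'   simulated patterns.
#' @param returnSims also attach the simulated D curves and T statistics as
#'   attributes `simD`, `simT` of the result (for diagnostics).
#' @return a [CrossKResult-class] with envelopes, `pGlobal` and effect sizes
#' @export
mcEnvelope <- function(patternI, patternJ, grid, nSim = 999L, level = 0.95,
                       nullModel = c("independent_relabeling", "label_swap"),
                       seed = 1L, rGrid = NULL,
                       edgeCorrection = c("none", "isotropic"),
                       returnSims = FALSE) {
  nullModel <- match.arg(nullModel)
  edgeCorrection <- match.arg(edgeCorrection)
  nSim <- as.integer(nSim)
  stopIfNot(nSim >= 19L, "nSim must be >= 19")
  stopIfNot(level > 0 && level < 1, "level must lie in (0, 1)")
  t0 <- as.numeric(proc.time()[["elapsed"]])

  um <- micronCoords(grid)
  N <- nrow(um)
  ni <- nSpots(patternI); nj <- nSpots(patternJ)
  if (ni > N || nj > N)
    stop("pattern sizes exceed the number of spots in the grid", call. = FALSE)
  if (is.null(rGrid)) rGrid <- defaultRGrid(grid)

  obs <- crossK(patternI, patternJ, rGrid, edgeCorrection)
  idxI <- matchPatternToGrid(patternI, grid)
  idxJ <- matchPatternToGrid(patternJ, grid)

  win <- as.numeric(spotWindow(grid, "um"))
  area <- attr(spotWindow(grid, "um"), "area")
  nr <- length(rGrid)
  dFull <- if (N <= 3000) as.matrix(stats::dist(um)) else NULL
  pool <- if (nullModel == "label_swap") sort(unique(c(idxI, idxJ))) else NULL

  simD <- matrix(NA_real_, nSim, nr)
  simT <- numeric(nSim)
  withSeed(seed, {
    for (s in seq_len(nSim)) {
      if (nullModel == "independent_relabeling") {
        ii <- sample.int(N, ni); jj <- sample.int(N, nj)
      } else {
        ii <- pool[sample.int(length(pool), ni)]
        jj <- pool[sample.int(length(pool), nj)]
      }
      d <- if (!is.null(dFull)) as.numeric(dFull[ii, jj])
           else as.numeric(crossDist(um[ii, , drop = FALSE],
                                     um[jj, , drop = FALSE]))
      w <- if (edgeCorrection == "isotropic")
        ripleyIsotropicWeight(rep(um[ii, 1], times = nj),
                              rep(um[ii, 2], times = nj), d, win)
      else rep(1, length(d))
      cur <- kCurvesFromDistances(d, w, rGrid, area, ni, nj)
      simD[s, ] <- cur$D
      simT[s] <- mean(cur$D)
    }
  })

  alpha <- (1 - level) / 2
  m <- floor(alpha * (nSim + 1) + 1e-9)
  sorted <- apply(simD, 2, sort)
  envLo <- sorted[m + 1, ]
  envHi <- sorted[nSim - m, ]
  tObs <- mean(obs@D)
  pGlobal <- (1 + sum(simT >= tObs)) / (nSim + 1)

  out <- obs
  out@envLo <- envLo
  out@envHi <- envHi
  out@nSim <- nSim
  out@pGlobal <- pGlobal
  out@seed <- as.integer(seed)
  if (returnSims) {
    attr(out, "simD") <- simD
    attr(out, "simT") <- simT
  }
  logStage("mcEnvelope", sample = grid@sampleId, n_i = ni, n_j = nj,
           n_sim = nSim, null = nullModel, p_global = pGlobal,
           seed = seed, t0 = t0)
  out
}

# Map a pattern's points to row indices of the grid, by barcode when
# available, otherwise by coordinates.
matchPatternToGrid <- function(pattern, grid) {
  if (length(spotIds(pattern))) {
    idx <- match(spotIds(pattern), spotIds(grid))
    if (anyNA(idx))
      stop("pattern spots must be a subset of the grid's spots", call. = FALSE)
    return(idx)
  }
  um <- micronCoords(grid)
  key <- paste(round(um[, 1], 6), round(um[, 2], 6))
  pk <- paste(round(pattern@coords[, 1], 6), round(pattern@coords[, 2], 6))
  idx <- match(pk, key)
  if (anyNA(idx))
    stop("pattern coordinates must coincide with grid spot centers",
         call. = FALSE)
  idx
}

#' Full per-sample co-localization pipeline
#'
#' Threshold both cell types into positive-spot patterns, apply the
#' minimum-count filter, and — when the sample passes — run the cross-K
#' analysis with Monte-Carlo envelopes and effect sizes.
#'
#' @param weights a [CellTypeWeights-class].
#' @param grid the sample's [SpotGrid-class].
#' @param typeA,typeB the two cell types (columns of `weights`).
#' @param config an [AnalysisConfig-class]; supplies the quantile rule,
#'   filter threshold, simulation count, envelope level and r-grid shape.
#' @param seed integer seed for the envelope simulations.
#' @param nullModel,edgeCorrection passed to [mcEnvelope()].
#' @return list with `pass`, `reason`, and (on pass) `result`
#'   (a [CrossKResult-class])
#' @export
runColocalization <- function(weights, grid, typeA, typeB,
                              config = analysisConfig(), seed = 1L,
                              nullModel = "independent_relabeling",
                              edgeCorrection = "none") {
  pI <- definePositiveSpots(weights, grid, typeA, config@quantileThreshold)
  pJ <- definePositiveSpots(weights, grid, typeB, config@quantileThreshold)
  flt <- filterSamples(pI, pJ, config@minPositiveSpots)
  if (!flt$pass) return(list(pass = FALSE, reason = flt$reason))
  rGrid <- defaultRGrid(grid, config@rSteps, config@rMaxFrac)
  res <- mcEnvelope(pI, pJ, grid, nSim = config@nSimulations,
                    level = config@envelopeLevel, nullModel = nullModel,
                    seed = seed, rGrid = rGrid,
                    edgeCorrection = edgeCorrection)
  list(pass = TRUE, reason = "", result = res)
}
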