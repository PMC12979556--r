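# Positive-spot calling, the cross-K estimator, envelopes and effect sizes.

test_that("positive spots use the strict linear-interpolation quantile rule", {
  g <- generateSpotLattice(2, 2)
  w <- cellTypeWeights(matrix(
    c(0.1, 0.2, 0.3, 0.4, 0.9, 0.8, 0.7, 0.6), 4, 2,
    dimnames = list(spotIds(g), c("tumor", "stroma"))))
  p <- definePositiveSpots(w, g, "tumor", 0.25)
  # quantile(c(.1,.2,.3,.4), .25) = 0.175; strictly above -> 3 spots
  expect_equal(nSpots(p), 3L)
  expect_setequal(spotIds(p), spotIds(g)[c(2, 3, 4)])
  expect_false(p@degenerate)
  # coordinates come out in micrometers
  expect_equal(micronCoords(p),
               micronCoords(g)[match(spotIds(p), spotIds(g)), ])

  # q -> 0 limit with distinct weights: everything but the minimum
  p0 <- definePositiveSpots(w, g, "tumor", 1e-9)
  expect_setequal(spotIds(p0), spotIds(g)[-1])

  # identical weights: degenerate empty pattern with a warning
  wFlat <- cellTypeWeights(matrix(
    c(rep(0.5, 4), rep(0.5, 4)), 4, 2,
    dimnames = list(spotIds(g), c("a", "b"))))
  expect_warning(pf <- definePositiveSpots(wFlat, g, "a"), "identical")
  expect_equal(nSpots(pf), 0L)
  expect_true(pf@degenerate)
  expect_error(definePositiveSpots(w, g, "missing"), "not a column")
})

test_that("the minimum-count filter reads 'fewer than 40' strictly", {
  win <- c(0, 1000, 0, 1000)
  mk <- function(n, ct) makePattern(cbind(runif(n, 0, 1000),
                                          runif(n, 0, 1000)), win, ct)
  set.seed(1)
  expect_true(filterSamples(mk(40, "a"), mk(40, "b"), 40)$pass)
  f39 <- suppressMessages(filterSamples(mk(39, "a"), mk(40, "b"), 40))
  expect_false(f39$pass)
  expect_match(f39$reason, "'a' has 39")
  fEmpty <- suppressMessages(filterSamples(
    makePattern(matrix(numeric(0), 0, 2), win, "a", degenerate = TRUE),
    mk(40, "b"), 40))
  expect_false(fEmpty$pass)
  expect_match(fEmpty$reason, "degenerate")
  other <- makePattern(cbind(1, 1), c(0, 2, 0, 2), "b")
  expect_error(filterSamples(mk(40, "a"), other), "same sample and window")
})

test_that("cross-K micro-examples match the direct formula", {
  win <- c(0, 10, 0, 10)
  p1 <- makePattern(cbind(2, 5), win, "a")
  p2 <- makePattern(cbind(5, 1), win, "b")  # distance 5
  r <- crossK(p1, p2, c(4, 5))
  expect_equal(r@K, c(0, 100))
  expect_equal(r@L, c(0, sqrt(100 / pi)))
  expect_equal(r@D, c(0, sqrt(100 / pi)) - c(4, 5))

  # coincident pairs count at distance zero: identical patterns at r ~ 0
  pts <- cbind(c(1, 4, 8), c(2, 6, 9))
  pp <- makePattern(pts, win, "a")
  rc <- crossK(pp, makePattern(pts, win, "b"), c(1e-9, 5))
  expect_equal(rc@K[1], 100 * 3 / 9)  # |A| * n / n^2 = |A| / n

  expect_error(crossK(p1, p2, c(5, 4)), "increasing")
  expect_error(crossK(p1, p2, 6), "half the shorter window side")
  empt <- makePattern(matrix(numeric(0), 0, 2), win, "e", degenerate = TRUE)
  expect_error(crossK(p1, empt, 2), "nonempty")
})

test_that("cross-K equals the brute-force double loop and is symmetric", {
  set.seed(5)
  win <- c(0, 2000, 0, 1500)
  rGrid <- seq(50, 700, length.out = 12)
  for (rep in 1:3) {
    ci <- cbind(runif(150, 0, 2000), runif(150, 0, 1500))
    cj <- cbind(runif(200, 0, 2000), runif(200, 0, 1500))
    pi_ <- makePattern(ci, win, "a"); pj <- makePattern(cj, win, "b")
    K <- crossK(pi_, pj, rGrid)@K
    expect_lt(max(abs(K - bruteCrossK(ci, cj, win, rGrid))), 1e-12)
    # symmetry under pattern swap without edge correction
    expect_lt(max(abs(K - crossK(pj, pi_, rGrid)@K)), 1e-12)
    # K is nondecreasing
    expect_true(all(diff(K) >= 0))
  }
})

test_that("isotropic edge weights match a numeric circle-fraction oracle", {
  win <- c(0, 1000, 0, 800)
  # interior point, edge-crossing point, and a corner-crossing point
  cases <- rbind(c(500, 400, 100),   # fully interior: weight 1
                 c(30, 400, 100),    # crosses the left edge
                 c(25, 30, 100))     # crosses left and bottom (corner)
  for (i in seq_len(nrow(cases))) {
    w <- nichescape:::ripleyIsotropicWeight(cases[i, 1], cases[i, 2],
                                            cases[i, 3], win)
    expect_equal(w, arcFractionWeight(cases[i, 1], cases[i, 2],
                                      cases[i, 3], win),
                 tolerance = 1e-4)
  }
  # isotropic K dominates the uncorrected K near edges
  set.seed(8)
  ci <- cbind(runif(80, 0, 1000), runif(80, 0, 800))
  cj <- cbind(runif(80, 0, 1000), runif(80, 0, 800))
  pi_ <- makePattern(ci, win, "a"); pj <- makePattern(cj, win, "b")
  rGrid <- c(100, 200, 300)
  expect_true(all(crossK(pi_, pj, rGrid, "isotropic")@K >=
                  crossK(pi_, pj, rGrid, "none")@K))
})

test_that("effect sizes follow their definitions including degenerate D", {
  z <- effectSizes(c(0, 0, 0))
  expect_equal(z$aggregationIndex, 0)
  expect_true(is.na(z$cohensD))
  expect_true(z$degenerate)

  e1 <- effectSizes(c(1, 1, -1, -1))
  expect_equal(e1$aggregationIndex, 0.5)
  expect_equal(e1$cohensD, 0)

  e2 <- effectSizes(c(1, 2, 3))
  expect_equal(e2$aggregationIndex, 1)
  expect_equal(e2$cohensD, 2)  # mean 2 / sd 1 (unbiased)

  # AI is invariant to monotone transforms of the positive values
  D <- c(-2, 0.5, 3, -0.1, 0.2)
  Dt <- D; Dt[Dt > 0] <- sqrt(Dt[Dt > 0]) * 10
  expect_equal(effectSizes(D)$aggregationIndex,
               effectSizes(Dt)$aggregationIndex)
  expect_error(effectSizes(1), "at least two")
})

test_that("micron conversion is a pure scale factor", {
  expect_identical(toMicrons(c(1, 2, 3), 1), c(1, 2, 3))
  expect_equal(toMicrons(200, 0.5), 100)
  r <- c(3.7, 981.2, 0.004)
  expect_lt(max(abs(toMicrons(toMicrons(r, 0.37), 1 / 0.37) - r)), 1e-12)
  expect_error(toMicrons(1, 0), "micronsPerPixel")
})

test_that("envelope ranks follow the drop-most-extreme convention", {
  g <- generateSpotLattice(12, 12)
  pp <- generatePointPatterns(g, 30, 30, mode = "independent", seed = 3)
  res <- suppressMessages(
    mcEnvelope(pp$patterns[[1]], pp$patterns[[2]], g, nSim = 19, level = 0.9,
               seed = 3, returnSims = TRUE))
  simD <- attr(res, "simD")
  # alpha = 0.05, m = floor(0.05 * 20) = 1: second-smallest / second-largest
  expect_equal(res@envLo, apply(simD, 2, function(v) sort(v)[2]))
  expect_equal(res@envHi, apply(simD, 2, function(v) sort(v)[18]))
  # add-one p-value can never be zero and T = mean(D) defines it
  simT <- attr(res, "simT")
  expect_equal(res@pGlobal, (1 + sum(simT >= mean(res@D))) / 20)
  expect_gt(res@pGlobal, 0)
  expect_error(mcEnvelope(pp$patterns[[1]], pp$patterns[[2]], g, nSim = 5),
               "19")
})

test_that("clustered patterns are detected; the full pipeline is deterministic", {
  g <- generateSpotLattice(20, 20)
  pp <- generatePointPatterns(g, 60, 60, mode = "shared_clusters",
                              nParents = 4, clusterSdUm = 60, seed = 13)
  res <- suppressMessages(
    mcEnvelope(pp$patterns[[1]], pp$patterns[[2]], g, nSim = 99, seed = 13))
  expect_lte(res@pGlobal, 0.05)
  expect_gte(res@aggregationIndex, 0.8)
  # observed D escapes the upper envelope somewhere
  expect_true(any(res@D > res@envHi))

  # same seed, same bytes, through the whole pipeline
  w <- patternsToWeights(g, pp$patterns)
  cfg <- analysisConfig(nSimulations = 49L)
  r1 <- suppressMessages(runColocalization(w, g, "typeA", "typeB",
                                           config = cfg, seed = 7))
  r2 <- suppressMessages(runColocalization(w, g, "typeA", "typeB",
                                           config = cfg, seed = 7))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeResult(r1$result, f1, "json", config = cfg, seed = 7L)
  writeResult(r2$result, f2, "json", config = cfg, seed = 7L)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # label_swap null also runs and detects the same strong signal
  resLS <- suppressMessages(
    mcEnvelope(pp$patterns[[1]], pp$patterns[[2]], g, nSim = 49,
               nullModel = "label_swap", seed = 13))
  expect_s4_class(resLS, "CrossKResult")
})

test_that("positive-spot encoding of planted patterns inverts exactly", {
  g <- generateSpotLattice(15, 15)
  pp <- generatePointPatterns(g, 50, 60, mode = "independent", seed = 9)
  w <- patternsToWeights(g, pp$patterns)
  pA <- definePositiveSpots(w, g, "typeA")
  pB <- definePositiveSpots(w, g, "typeB")
  expect_setequal(spotIds(pA), pp$truth$positiveTruth$typeA)
  expect_setequal(spotIds(pB), pp$truth$positiveTruth$typeB)
})
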