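# Synthetic-data generators: geometry, planted structure, purity.

test_that("hex lattice geometry: offsets, spacing and neighbor structure", {
  g1 <- generateSpotLattice(1, 1)
  expect_equal(nSpots(g1), 1L)
  expect_equal(unname(micronCoords(g1)[1, ]), c(0, 0))

  g2 <- generateSpotLattice(2, 2, pitchUm = 100, micronsPerPixel = 1)
  d2 <- dist(micronCoords(g2))
  expect_equal(min(d2), 100, tolerance = 1e-12)

  g <- generateSpotLattice(30, 30, pitchUm = 100)
  expect_equal(nSpots(g), 900L)
  um <- micronCoords(g)
  dm <- as.matrix(dist(um)); diag(dm) <- Inf
  # every interior spot sits exactly one pitch from its nearest neighbor,
  # with six equidistant neighbors
  ac <- g@arrayCoords
  interior <- ac[, 1] >= 1 & ac[, 1] <= 28 & ac[, 2] >= 1 & ac[, 2] <= 28
  nn <- apply(dm[interior, ], 1, min)
  expect_lt(max(abs(nn - 100)), 1e-9)
  nNbr <- rowSums(abs(dm[interior, ] - 100) < 1e-9)
  expect_true(all(nNbr == 6))
  expect_error(generateSpotLattice(2, 2, pitchUm = 0), "pitchUm")
})

test_that("niche weights plant contiguous dominant-type structure", {
  g <- generateSpotLattice(10, 10)
  det <- generateNicheWeights(g, kTrue = 4, nTypes = 6, seed = 1,
                              deterministic = TRUE)
  # infinite-concentration limit: weights equal the niche mean exactly
  expect_equal(unname(det$weights@.Data),
               unname(det$truth$nicheMeans[det$truth$nicheLabel, ]))

  one <- generateNicheWeights(g, kTrue = 1, nTypes = 3, seed = 1)
  expect_equal(unique(unname(one$truth$nicheLabel)), 1L)

  g9 <- generateSpotLattice(30, 30)
  for (layout in c("blocks", "voronoi")) {
    nw <- generateNicheWeights(g9, kTrue = 5, nTypes = 8, dominance = 0.8,
                               layout = layout, seed = 7)
    w <- nw$weights@.Data; lab <- nw$truth$nicheLabel
    for (ni in 1:5) {
      domType <- which.max(nw$truth$nicheMeans[ni, ])
      expect_gt(mean(w[lab == ni, domType]), mean(w[lab != ni, domType]))
    }
  }
  expect_error(generateNicheWeights(g, kTrue = 200, nTypes = 3),
               "exceeds")
})

test_that("point patterns honor counts, modes and degenerate clustering", {
  g <- generateSpotLattice(15, 15)
  n <- nSpots(g)
  full <- generatePointPatterns(g, n, n, mode = "independent", seed = 1)
  expect_setequal(spotIds(full$patterns[[1]]), spotIds(g))
  expect_setequal(spotIds(full$patterns[[2]]), spotIds(g))

  # sd -> 0 with one parent: both types occupy the same spots nearest the parent
  deg <- generatePointPatterns(g, 25, 25, mode = "shared_clusters",
                               nParents = 1, clusterSdUm = 0, seed = 3)
  expect_identical(spotIds(deg$patterns[[1]]), spotIds(deg$patterns[[2]]))
  expect_equal(nSpots(deg$patterns[[1]]), 25L)

  expect_error(generatePointPatterns(g, 10, 10, mode = "shared_clusters",
                                     nParents = 0), "nParents")
})

test_that("independent-mode overlap matches the hypergeometric expectation", {
  g <- generateSpotLattice(15, 15)   # N = 225
  N <- nSpots(g); ni <- 30; nj <- 40
  reps <- 500
  ov <- vapply(seq_len(reps), function(r) {
    pp <- generatePointPatterns(g, ni, nj, mode = "independent", seed = 1000 + r)
    length(intersect(spotIds(pp$patterns[[1]]), spotIds(pp$patterns[[2]])))
  }, numeric(1))
  expected <- ni * nj / N
  vHyper <- ni * nj * (N - ni) * (N - nj) / (N^2 * (N - 1))
  expect_lt(abs(mean(ov) - expected), 3 * sqrt(vHyper / reps))
})

test_that("shared clusters pull the two types closer than independence", {
  g <- generateSpotLattice(20, 20)
  meanCrossNN <- function(pp) {
    d <- as.matrix(dist(rbind(micronCoords(pp$patterns[[1]]),
                              micronCoords(pp$patterns[[2]]))))
    n1 <- nSpots(pp$patterns[[1]])
    mean(apply(d[seq_len(n1), -seq_len(n1), drop = FALSE], 1, min))
  }
  reps <- 60
  dInd <- dClu <- numeric(reps)
  for (r in seq_len(reps)) {
    dInd[r] <- meanCrossNN(generatePointPatterns(g, 40, 40, "independent",
                                                 seed = 200 + r))
    dClu[r] <- meanCrossNN(generatePointPatterns(g, 40, 40, "shared_clusters",
                                                 seed = 200 + r))
  }
  p <- wilcox.test(dClu, dInd, paired = TRUE, alternative = "less")$p.value
  expect_lt(p, 1e-6)
})

test_that("CNV profiles plant the requested blocks", {
  flat <- generateCNVProfiles(nRef = 3, nMal = 2, nBins = 10,
                              blocks = list(), noiseSd = 0, seed = 1)
  expect_true(all(flat$cnv@values == 1))

  half <- generateCNVProfiles(nRef = 3, nMal = 2, nBins = 10,
                              blocks = list(c(1, 5, 1.5)), noiseSd = 0,
                              seed = 1)
  sc <- cnvScore(half$cnv)
  expect_equal(unname(sc[half$truth$malignantIds]), rep(0.125, 2))
  expect_equal(unname(sc[setdiff(names(sc), half$truth$malignantIds)]),
               rep(0, 3))

  planted <- generateCNVProfiles(nRef = 200, nMal = 50, nBins = 200,
                                 blocks = list(c(1, 50, 1.4)),
                                 noiseSd = 0.05, seed = 5)
  sc <- cnvScore(planted$cnv)
  mal <- names(sc) %in% planted$truth$malignantIds
  expect_gt(min(sc[mal]), max(sc[!mal]))  # disjoint score distributions

  expect_error(generateCNVProfiles(blocks = list(c(1, 10, 1.2), c(5, 20, 1.5))),
               "overlap")
  expect_error(generateCNVProfiles(blocks = list(c(1, 10, 1))), "differ from 1")
})

test_that("expression counts follow the marker mean model", {
  g <- generateSpotLattice(40, 50)  # 2000 spots
  w <- matrix(c(rep(1, 1000), rep(0, 1000),
                rep(0, 1000), rep(1, 1000)), ncol = 2,
              dimnames = list(spotIds(g), c("tumor", "stroma")))
  wts <- cellTypeWeights(w)
  ex <- generateExpression(g, wts, markersPerType = 2, markerFold = 4,
                           baseMean = 10, dispersion = 2, nNoiseGenes = 2,
                           seed = 9)
  pure <- w[, "tumor"] == 1
  mk <- ex$markerMap$tumor[1]
  # pure spots: mean = baseMean * fold; absent type: mean = baseMean
  expect_equal(mean(ex$counts[mk, pure]), 40, tolerance = 0.1)
  expect_equal(mean(ex$counts[mk, !pure]), 10, tolerance = 0.1)

  # Poisson limit: variance tracks the mean for a flat gene
  exP <- generateExpression(g, wts, markersPerType = 2, markerFold = 1,
                            baseMean = 10, dispersion = Inf, nNoiseGenes = 2,
                            seed = 9)
  flat <- exP$counts["noise_0001", ]
  expect_equal(var(flat) / mean(flat), 1, tolerance = 0.15)
})

test_that("generators are pure functions of their seed", {
  g <- generateSpotLattice(8, 8)
  a <- generateNicheWeights(g, 3, 5, seed = 11)
  b <- generateNicheWeights(g, 3, 5, seed = 11)
  expect_identical(a, b)
  expect_false(identical(
    a$weights, generateNicheWeights(g, 3, 5, seed = 12)$weights))
  p1 <- generatePointPatterns(g, 10, 10, "shared_clusters", seed = 4)
  p2 <- generatePointPatterns(g, 10, 10, "shared_clusters", seed = 4)
  expect_identical(p1, p2)
  c1 <- generateCNVProfiles(nRef = 10, nMal = 5, nBins = 20, seed = 4)
  c2 <- generateCNVProfiles(nRef = 10, nMal = 5, nBins = 20, seed = 4)
  expect_identical(c1, c2)
  # RNG state of the session is untouched
  set.seed(123); before <- .Random.seed
  invisible(generateNicheWeights(g, 3, 5, seed = 1))
  expect_identical(.Random.seed, before)
})
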