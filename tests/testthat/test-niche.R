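# Niche clustering, k selection and within-niche co-occurrence.

test_that("k selection recovers a perfectly separated planted k", {
  g <- generateSpotLattice(10, 10)
  det <- generateNicheWeights(g, kTrue = 5, nTypes = 8, seed = 2,
                              deterministic = TRUE)
  # only five distinct compositions exist: k = 6 must be skipped, not fitted
  expect_warning(
    sel <- selectK(det$weights, 2:6, nGapRefs = 10, seed = 2),
    "skipping k = 6")
  expect_true(sel$diagnostics$skipped[sel$diagnostics$k == 6])
  expect_identical(sel$recommendedK, 5L)
  expect_identical(unname(sel$votes[["ch"]]), 5L)
  expect_identical(unname(sel$votes[["gap"]]), 5L)
  expect_equal(sel$diagnostics$wss[sel$diagnostics$k == 5], 0)
  expect_error(selectK(det$weights, 5), "at least two candidate")
})

test_that("diagnostics agree with independent brute-force recomputation", {
  g <- generateSpotLattice(5, 10)  # 50 spots
  nw <- generateNicheWeights(g, kTrue = 3, nTypes = 5, seed = 8)
  sel <- selectK(nw$weights, 2:6, nGapRefs = 20, seed = 8)
  d <- sel$diagnostics
  labs <- attr(d, "fitLabels")
  refLogW <- attr(d, "refLogW")
  x <- nw$weights@.Data
  for (i in seq_len(nrow(d))) {
    expect_equal(bruteWSS(x, labs[[i]]), d$wss[i], tolerance = 1e-9)
    expect_equal(bruteCH(x, labs[[i]]), d$ch[i], tolerance = 1e-9)
    expect_equal(mean(refLogW[, i]) - log(d$wss[i]), d$gap[i],
                 tolerance = 1e-9)
    expect_equal(sd(refLogW[, i]) * sqrt(1 + 1 / nrow(refLogW)),
                 d$gap_se[i], tolerance = 1e-9)
  }
})

test_that("moderate-overlap planted k is recovered and clustering matches truth", {
  g <- generateSpotLattice(30, 30)
  nw <- generateNicheWeights(g, kTrue = 3, nTypes = 6, seed = 21)
  m <- clusterCompositions(nw$weights, 3, seed = 21)
  ari <- mclust::adjustedRandIndex(nicheLabels(m), nw$truth$nicheLabel)
  expect_gte(ari, 0.9)

  nw5 <- generateNicheWeights(g, kTrue = 5, nTypes = 8, seed = 22)
  sel <- selectK(nw5$weights, 2:8, nGapRefs = 25, seed = 22)
  expect_identical(sel$recommendedK, 5L)
})

test_that("clustering contracts: trivial split, degeneracy, permutation invariance", {
  w <- makeWeights(list(c(1, 0), c(0, 1)))
  m <- clusterCompositions(w, 2, seed = 1)
  expect_setequal(unname(nicheLabels(m)), 1:2)
  expect_equal(bruteWSS(w@.Data, nicheLabels(m)), 0)

  same <- makeWeights(rep(list(c(0.5, 0.5)), 6))
  expect_error(clusterCompositions(same, 2, seed = 1), "degenerate")

  # labels follow a row permutation (same partition, size-ordered labels)
  g <- generateSpotLattice(10, 10)
  nw <- generateNicheWeights(g, kTrue = 3, nTypes = 5, dominance = 0.8,
                             seed = 5)
  m1 <- clusterCompositions(nw$weights, 3, seed = 5)
  perm <- withr::with_seed(99, sample(nSpots(g)))
  wPerm <- cellTypeWeights(nw$weights@.Data[perm, ])
  m2 <- clusterCompositions(wPerm, 3, seed = 5)
  expect_identical(nicheLabels(m2)[names(nicheLabels(m1))],
                   nicheLabels(m1))

  # labels are size-ordered: cluster 1 is the largest
  sizes <- tabulate(nicheLabels(m1), 3)
  expect_true(all(diff(sizes) <= 0))
})

test_that("fitNiches carries the selection diagnostics into the model", {
  g <- generateSpotLattice(10, 10)
  nw <- generateNicheWeights(g, kTrue = 3, nTypes = 5, dominance = 0.8,
                             seed = 4)
  m <- fitNiches(nw$weights, k = "auto", kCandidates = 2:5, nGapRefs = 10,
                 seed = 4)
  expect_identical(m@k, recommendedK(m))
  expect_identical(m@k, 3L)
  expect_named(kVotes(m), c("ch", "gap", "elbow"))
  expect_equal(nrow(kDiagnostics(m)), 4)
  # centroids are the member means
  for (gl in seq_len(m@k))
    expect_equal(unname(nicheCentroids(m)[gl, ]),
                 unname(colMeans(nw$weights@.Data[nicheLabels(m) == gl, ])))
})

test_that("composition summaries behave at the boundaries and agree in ranking", {
  w <- makeWeights(list(c(0.7, 0.3), c(0.2, 0.8), c(0.6, 0.4)))
  one <- makeModel(rep(1, 3), w)
  s <- nicheCompositionSummary(one, w)
  expect_equal(unname(s$meanWeight[1, ]), unname(colMeans(w@.Data)))
  expect_equal(rowSums(s$meanWeight), c(niche1 = 1))
  expect_equal(rowSums(s$dominantProportion), c(niche1 = 1))

  g <- generateSpotLattice(8, 8)
  det <- generateNicheWeights(g, kTrue = 3, nTypes = 5, seed = 1,
                              deterministic = TRUE)
  m <- makeModel(det$truth$nicheLabel, det$weights)
  sDet <- nicheCompositionSummary(m, det$weights)
  for (ni in 1:3) {
    domType <- which.max(det$truth$nicheMeans[ni, ])
    expect_equal(unname(sDet$dominantProportion[ni, domType]), 1)
  }

  # mean-weight and argmax summaries agree on each niche's top type
  for (seed in 1:10) {
    nw <- generateNicheWeights(g, kTrue = 2, nTypes = 4, dominance = 0.7,
                               seed = seed)
    mm <- makeModel(nw$truth$nicheLabel, nw$weights)
    ss <- nicheCompositionSummary(mm, nw$weights)
    expect_identical(max.col(ss$meanWeight), max.col(ss$dominantProportion))
  }
})

test_that("niche distribution by group handles single samples, ties and enrichment", {
  w <- makeWeights(list(c(1, 0), c(1, 0), c(0, 1), c(0, 1),
                        c(1, 0), c(0, 1), c(1, 0), c(0, 1)))
  m <- makeModel(c(1, 1, 2, 2, 1, 2, 1, 2), w)

  # one sample: its fractions are the global fractions
  oneS <- nicheDistributionByGroup(m, rep("sampleA", 8),
                                   c(sampleA = "grp1"))
  expect_equal(oneS$perSample$fraction,
               tabulate(nicheLabels(m), 2) / 8)
  expect_true(all(is.na(oneS$tests$p)))  # a single sample cannot be tested

  # identical per-sample fraction vectors across groups: p = 1 everywhere
  spl <- rep(c("s1", "s2", "s3", "s4"), each = 2)
  grp <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  mEq <- makeModel(rep(c(1, 2), 4), w)
  eq <- nicheDistributionByGroup(mEq, spl, grp)
  expect_equal(eq$tests$p, c(1, 1))

  # planted enrichment: niche 1 occurs only in group A
  mEnr <- makeModel(c(1, 1, 1, 2, 2, 2, 2, 2), w)
  enr <- nicheDistributionByGroup(mEnr, spl, grp)
  pg <- enr$perGroup
  expect_gt(pg$fraction[pg$group == "A" & pg$niche == 1], 0)
  expect_equal(pg$fraction[pg$group == "B" & pg$niche == 1], 0)
  # per-sample fractions sum to one
  ps <- enr$perSample
  expect_equal(as.numeric(tapply(ps$fraction, ps$sample, sum)), rep(1, 4))
})

test_that("co-occurrence p-values are exactly hypergeometric", {
  # N = 4 sites, both types present on the same two spots: p_gt = 1/6
  w <- makeWeights(list(c(0.45, 0.45, 0.10), c(0.45, 0.45, 0.10),
                        c(0.05, 0.05, 0.90), c(0.05, 0.05, 0.90)))
  m <- makeModel(rep(1, 4), w)
  tab <- cooccurrenceWithinNiche(w, m, 1)
  row <- tab[tab$type_a == "type01" & tab$type_b == "type02", ]
  expect_equal(row$n_a, 2); expect_equal(row$n_b, 2)
  expect_equal(row$j_obs, 2)
  expect_equal(row$j_expected, 1)
  expect_equal(row$p_gt, 1 / 6, tolerance = 1e-12)
  expect_equal(row$p_lt, 1, tolerance = 1e-12)
  expect_identical(row$classification, "random")  # 1/6 > 0.05

  # exhaustive enumeration oracle over all placements, N <= 8
  set.seed(31)
  for (rep in 1:6) {
    N <- sample(4:8, 1)
    rows <- lapply(seq_len(N), function(i) {
      v <- runif(3); v / sum(v)
    })
    wN <- makeWeights(rows)
    mN <- makeModel(rep(1, N), wN)
    tabN <- cooccurrenceWithinNiche(wN, mN, 1)
    for (i in seq_len(nrow(tabN))) {
      ref <- enumCooccurTailProbs(tabN$n_sites[i], tabN$n_a[i], tabN$n_b[i],
                                  tabN$j_obs[i])
      expect_equal(tabN$p_gt[i], unname(ref["p_gt"]), tolerance = 1e-12)
      expect_equal(tabN$p_lt[i], unname(ref["p_lt"]), tolerance = 1e-12)
    }
  }
})

test_that("degenerate presence patterns are classified random and flagged", {
  # type03 present everywhere (all weights equal -> nobody exceeds the
  # quantile -> n = 0) and a ubiquitous type: both forced to random
  w <- makeWeights(list(c(0.50, 0.30, 0.2), c(0.45, 0.35, 0.2),
                        c(0.40, 0.40, 0.2), c(0.35, 0.45, 0.2)))
  m <- makeModel(rep(1, 4), w)
  tab <- cooccurrenceWithinNiche(w, m, 1)
  deg <- tab[tab$type_a == "type03" | tab$type_b == "type03", ]
  expect_true(all(deg$degenerate))
  expect_true(all(deg$classification == "random"))
  expect_true(all(deg$p_gt == 1 | deg$p_lt == 1))
  expect_error(cooccurrenceWithinNiche(w, m, 5), "existing niche")
})
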