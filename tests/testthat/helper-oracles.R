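# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles are deliberately naive (double loops, exhaustive
# enumeration) and never call the code paths they check.

# Naive cross-K: explicit double loop over ordered pairs, no shortcuts.
bruteCrossK <- function(coordsI, coordsJ, window, rGrid) {
  area <- (window[2] - window[1]) * (window[4] - window[3])
  ni <- nrow(coordsI); nj <- nrow(coordsJ)
  K <- numeric(length(rGrid))
  for (ri in seq_along(rGrid)) {
    cnt <- 0
    for (p in seq_len(ni)) for (q in seq_len(nj)) {
      d <- sqrt((coordsI[p, 1] - coordsJ[q, 1])^2 +
                (coordsI[p, 2] - coordsJ[q, 2])^2)
      if (d <= rGrid[ri]) cnt <- cnt + 1
    }
    K[ri] <- area * cnt / (ni * nj)
  }
  K
}

# Circle-fraction oracle for the isotropic edge weight: discretize the
# circle of radius d around (px, py) and count arc points inside the window.
arcFractionWeight <- function(px, py, d, window, nTheta = 2e5) {
  th <- (seq_len(nTheta) - 0.5) / nTheta * 2 * pi
  x <- px + d * cos(th); y <- py + d * sin(th)
  inside <- x >= window[1] & x <= window[2] & y >= window[3] & y <= window[4]
  1 / mean(inside)
}

# Within-cluster sum of squares / Calinski-Harabasz from labels, recomputed
# from first principles.
bruteWSS <- function(x, labels) {
  s <- 0
  for (g in unique(labels)) {
    m <- x[labels == g, , drop = FALSE]
    ctr <- colMeans(m)
    s <- s + sum(t(t(m) - ctr)^2)
  }
  s
}

bruteCH <- function(x, labels) {
  n <- nrow(x); k <- length(unique(labels))
  w <- bruteWSS(x, labels)
  b <- bruteWSS(x, rep(1, n)) - w
  (b / (k - 1)) / (w / (n - k))
}

# Exhaustive co-occurrence null: enumerate every placement of n_a and n_b
# presences over N sites and tabulate the joint count distribution.
enumCooccurTailProbs <- function(N, na, nb, jObs) {
  placeA <- if (na == 0) list(integer(0)) else
    asplit(utils::combn(N, na), 2)
  placeB <- if (nb == 0) list(integer(0)) else
    asplit(utils::combn(N, nb), 2)
  js <- unlist(lapply(placeA, function(a)
    vapply(placeB, function(b) length(intersect(a, b)), integer(1))))
  c(p_gt = mean(js >= jObs), p_lt = mean(js <= jObs))
}

# Manual point pattern on a given window (micrometers).
makePattern <- function(coords, window, cellType = "t", sampleId = "s",
                        degenerate = FALSE) {
  new("PointPattern", sampleId = sampleId, cellType = cellType,
      coords = cbind(x = coords[, 1], y = coords[, 2]),
      spotIds = character(), window = as.numeric(window),
      degenerate = degenerate)
}

# Weight matrix with given rows and automatic barcodes/types.
makeWeights <- function(rows, types = NULL) {
  m <- do.call(rbind, rows)
  colnames(m) <- if (is.null(types)) sprintf("type%02d", seq_len(ncol(m)))
                 else types
  rownames(m) <- sprintf("bc%03d", seq_len(nrow(m)))
  cellTypeWeights(m)
}

# NicheModel wrapper for hand-made labels (bypasses clustering).
makeModel <- function(labels, weights) {
  k <- max(labels)
  centroids <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(weights@.Data[labels == g, , drop = FALSE])))
  new("NicheModel", k = as.integer(k),
      labels = stats::setNames(as.integer(labels), rownames(weights)),
      centroids = centroids, diagnostics = data.frame(),
      recommendedK = NA_integer_, votes = integer(), seed = 1L)
}

# Run the installed command-line script; returns exit status invisibly.
runCLI <- function(...) {
  cli <- system.file("scripts", "nichescape.R", package = "nichescape")
  status <- system2(file.path(R.home("bin"), "Rscript"), c(cli, ...),
                    stdout = FALSE, stderr = FALSE)
  invisible(status)
}
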