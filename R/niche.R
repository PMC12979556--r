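## Composition-cluster (niche) analysis: k selection by three criteria,
## k-means clustering of deconvolution weights, per-niche summaries, and
## exact hypergeometric (Veech-style) cell-type co-occurrence.

# k-means with bounded retries on degenerate starts. Weights are clustered
# unscaled: they already share a compositional scale, and z-scoring would
# inflate rare-type noise.
fitKmeans <- function(x, k, nstart, maxRetry = 5L) {
  if (k == nrow(x)) {
    # every row its own cluster; only sound when all rows are distinct
    if (nrow(unique(x)) < k)
      stop(sprintf("k-means with k = %d is degenerate: fewer distinct rows than clusters", k),
           call. = FALSE)
    return(list(cluster = seq_len(k), centers = x, totss = sum(scale(x, scale = FALSE)^2),
                withinss = rep(0, k), tot.withinss = 0, size = rep(1L, k)))
  }
  for (attempt in seq_len(maxRetry)) {
    res <- tryCatch(
      stats::kmeans(x, centers = k, nstart = nstart, iter.max = 100L),
      error = function(e) e)
    if (!inherits(res, "error")) return(res)
    if (!grepl("empty cluster|more cluster centers|initial centers",
               conditionMessage(res)))
      stop(res)
  }
  stop(sprintf("k-means with k = %d is degenerate after %d retries: %s",
               k, maxRetry, conditionMessage(res)), call. = FALSE)
}

# Within-cluster sum of squares of a labeled matrix (column-mean centroids).
wssOfLabels <- function(x, labels) {
  sum(vapply(split.data.frame(x, labels), function(m)
    sum(sweep(m, 2, colMeans(m))^2), numeric(1)))
}

#' Select the number of niches by three criteria
#'
#' Fits k-means to the weight matrix for every candidate k and records the
#' within-cluster sum of squares (WSS), the Calinski-Harabasz index
#' `CH = (B/(k-1)) / (W/(n-k))`, and the gap statistic
#' `gap(k) = mean(log(WSS_ref)) - log(WSS)` over `nGapRefs` reference
#' datasets drawn uniformly over each cell type's observed range. Three
#' criteria then vote: CH takes its argmax; the gap rule takes the smallest k
#' with `gap(k) >= gap(k+1) - se(k+1)`; the elbow takes the k whose point on
#' the (min-max normalized) WSS curve is farthest from the chord joining the
#' curve's endpoints. The recommended k is the majority vote, ties broken in
#' favor of the CH winner.
#'
#' Candidate k values exceeding the number of distinct compositions are
#' skipped with a warning (CH and the fit are undefined there).
#'
#' @param weights a [CellTypeWeights-class].
#' @param kCandidates integer vector of candidate k (each >= 2 and
#'   <= nrow - 1); at least two candidates.
#' @param nGapRefs reference datasets for the gap statistic (default 50).
#' @param seed integer seed governing k-means restarts and reference draws.
#' @param nInit random restarts for each observed fit (reference fits use a
#'   single start).
#' @return list with `diagnostics` (data.frame: `k`, `wss`, `ch`, `gap`,
#'   `gap_se`, `skipped`; the per-reference log-WSS draws and the fitted
#'   per-k label vectors are attached as attributes `refLogW` and
#'   `fitLabels`, so every criterion can be recomputed independently),
#'   `votes` (named integer: `ch`, `gap`, `elbow`) and `recommendedK`
#' @seealso [clusterCompositions()], [fitNiches()]
#' @export
selectK <- function(weights, kCandidates, nGapRefs = 50L, seed = 1L,
                    nInit = 10L) {
  x <- weights@.Data
  n <- nrow(x)
  kCandidates <- sort(unique(as.integer(kCandidates)))
  if (length(kCandidates) < 2)
    stop("at least two candidate k values are required", call. = FALSE)
  if (any(kCandidates < 2L | kCandidates > n - 1L))
    stop("candidate k values must lie in 2..(n_spots - 1)", call. = FALSE)
  nDistinct <- nrow(unique(x))
  skipped <- kCandidates > nDistinct
  if (any(skipped))
    warning(sprintf("skipping k = %s: only %d distinct compositions",
                    paste(kCandidates[skipped], collapse = ", "), nDistinct))
  t0 <- as.numeric(proc.time()[["elapsed"]])

  nk <- length(kCandidates)
  wss <- ch <- gap <- gapSe <- rep(NA_real_, nk)
  refLogW <- matrix(NA_real_, nGapRefs, nk,
                    dimnames = list(NULL, paste0("k", kCandidates)))
  fitLabels <- vector("list", nk)
  names(fitLabels) <- paste0("k", kCandidates)
  withSeed(seed, {
    rngs <- apply(x, 2, range)
    refs <- lapply(seq_len(nGapRefs), function(b)
      vapply(seq_len(ncol(x)), function(j)
        stats::runif(n, rngs[1, j], rngs[2, j]), numeric(n)))
    tss <- sum(sweep(x, 2, colMeans(x))^2)
    for (i in seq_len(nk)) {
      if (skipped[i]) next
      k <- kCandidates[i]
      fit <- fitKmeans(x, k, nstart = nInit)
      fitLabels[[i]] <- fit$cluster
      wss[i] <- fit$tot.withinss
      ch[i] <- ((tss - wss[i]) / (k - 1)) / (wss[i] / (n - k))
      refLogW[, i] <- vapply(refs, function(r)
        log(fitKmeans(r, k, nstart = 1L)$tot.withinss), numeric(1))
      gap[i] <- mean(refLogW[, i]) - log(wss[i])
      gapSe[i] <- stats::sd(refLogW[, i]) * sqrt(1 + 1 / nGapRefs)
    }
  })

  ok <- which(!skipped)
  voteCH <- kCandidates[ok][which.max(ch[ok])]
  voteGap <- {
    v <- NA_integer_
    for (i in ok) {
      nxt <- ok[ok > i]
      if (!length(nxt)) { v <- kCandidates[i]; break }
      j <- nxt[1]
      if (gap[i] >= gap[j] - gapSe[j]) { v <- kCandidates[i]; break }
    }
    v
  }
  voteElbow <- {
    kk <- kCandidates[ok]; ww <- wss[ok]
    if (length(kk) < 3 || diff(range(ww)) == 0) kk[1]
    else {
      u <- (kk - kk[1]) / (kk[length(kk)] - kk[1])
      v <- (ww - ww[length(ww)]) / (ww[1] - ww[length(ww)])
      # distance from each normalized point to the chord (0,1)-(1,0)
      kk[which.max(abs(u + v - 1) / sqrt(2))]
    }
  }
  votes <- c(ch = voteCH, gap = voteGap, elbow = voteElbow)
  tab <- table(votes)
  recommendedK <- if (max(tab) >= 2)
    as.integer(names(tab)[which.max(tab)]) else as.integer(voteCH)

  diagnostics <- data.frame(k = kCandidates, wss = wss, ch = ch, gap = gap,
                            gap_se = gapSe, skipped = skipped)
  attr(diagnostics, "refLogW") <- refLogW
  attr(diagnostics, "fitLabels") <- fitLabels
  logStage("selectK", n = n, candidates = paste(range(kCandidates),
           collapse = ":"), recommended = recommendedK, seed = seed, t0 = t0)
  list(diagnostics = diagnostics, votes = votes,
       recommendedK = as.integer(recommendedK))
}

#' Cluster spots into composition clusters (niches)
#'
#' k-means on the raw (unscaled) weight rows with `nInit` random restarts,
#' keeping the fit with the lowest within-cluster sum of squares. Clusters
#' are relabeled in decreasing size order (exact size ties broken by
#' centroid composition) so that labels are deterministic and invariant to
#' row permutations of the input; centroid rows are the mean compositions of
#' their members.
#'
#' @param weights a [CellTypeWeights-class].
#' @param k number of niches (2 <= k <= number of spots).
#' @param seed integer seed.
#' @param nInit random restarts (default 10).
#' @return a [NicheModel-class] (diagnostics empty; see [selectK()] or
#'   [fitNiches()] for the k-selection curves)
#' @export
clusterCompositions <- function(weights, k, seed = 1L, nInit = 10L) {
  x <- weights@.Data
  k <- as.integer(k)
  if (k < 2L || k > nrow(x))
    stop("k must lie in 2..n_spots", call. = FALSE)
  fit <- withSeed(seed, fitKmeans(x, k, nstart = nInit))
  sizes <- tabulate(fit$cluster, k)
  ctr <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(x[fit$cluster == g, , drop = FALSE])))
  # size-ordered labels; exact size ties broken by centroid composition so
  # the relabeling is invariant to row permutations of the input
  ord <- do.call(order, c(list(-sizes),
                          lapply(seq_len(ncol(ctr)), function(j) -ctr[, j])))
  relab <- match(seq_len(k), ord)  # old label -> new label
  labels <- stats::setNames(relab[fit$cluster], rownames(x))
  centroids <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(x[labels == g, , drop = FALSE])))
  rownames(centroids) <- paste0("niche", seq_len(k))
  new("NicheModel", k = k, labels = labels, centroids = centroids,
      diagnostics = data.frame(), recommendedK = NA_integer_,
      votes = integer(), seed = as.integer(seed))
}

#' Select k and fit the niche model in one call
#'
#' Runs [selectK()] over `kCandidates` (unless `k` is given explicitly),
#' then fits [clusterCompositions()] at the chosen k and stores the
#' diagnostics and votes in the returned model.
#'
#' @param weights a [CellTypeWeights-class].
#' @param k `"auto"` (default) or an explicit integer.
#' @param kCandidates candidate k values for the automatic selection.
#' @param nGapRefs,seed,nInit passed to [selectK()] / [clusterCompositions()].
#' @return a [NicheModel-class]
#' @export
fitNiches <- function(weights, k = "auto", kCandidates = 2:10,
                      nGapRefs = 50L, seed = 1L, nInit = 10L) {
  if (identical(k, "auto")) {
    sel <- selectK(weights, kCandidates, nGapRefs = nGapRefs, seed = seed,
                   nInit = nInit)
    model <- clusterCompositions(weights, sel$recommendedK, seed = seed,
                                 nInit = nInit)
    model@diagnostics <- sel$diagnostics
    model@votes <- sel$votes
    model@recommendedK <- sel$recommendedK
    model
  } else {
    clusterCompositions(weights, as.integer(k), seed = seed, nInit = nInit)
  }
}

#' Per-niche composition summary
#'
#' Two complementary composition summaries per niche: the mean deconvolved
#' weight of each cell type over the niche's spots, and the proportion of
#' the niche's spots whose largest weight (argmax type) is each cell type.
#' Both summaries sum to one within each niche.
#'
#' @param model a [NicheModel-class].
#' @param weights the [CellTypeWeights-class] the model was fitted to.
#' @return list with matrices `meanWeight` and `dominantProportion`
#'   (niches x cell types)
#' @export
nicheCompositionSummary <- function(model, weights) {
  x <- weights@.Data
  labels <- nicheLabels(model)
  stopIfNot(identical(names(labels), rownames(x)),
            "model labels must align with the weight rows")
  k <- model@k
  types <- colnames(x)
  meanWeight <- do.call(rbind, lapply(seq_len(k), function(g)
    colMeans(x[labels == g, , drop = FALSE])))
  dominant <- max.col(x, ties.method = "first")
  dominantProportion <- do.call(rbind, lapply(seq_len(k), function(g) {
    tab <- tabulate(dominant[labels == g], ncol(x))
    tab / sum(tab)
  }))
  dimnames(meanWeight) <- dimnames(dominantProportion) <-
    list(paste0("niche", seq_len(k)), types)
  list(meanWeight = meanWeight, dominantProportion = dominantProportion)
}

#' Niche distribution across samples and groups
#'
#' Computes the fraction of each sample's spots assigned to each niche, the
#' group-level fractions (spots pooled within each group, i.e. samples
#' weighted by their spot counts), and a Kruskal-Wallis p-value per niche
#' comparing the per-sample fractions across groups. The p-value is reported
#' as NA when any group contributes fewer than two samples.
#'
#' @param model a [NicheModel-class].
#' @param sampleOfSpot character vector (named by barcode or aligned with
#'   the model's labels) giving each spot's sample.
#' @param groupOfSample named character vector mapping sample id to group.
#' @return list with data.frames `perSample` (sample, group, niche,
#'   fraction), `perGroup` (group, niche, fraction) and `tests` (niche,
#'   statistic, p)
#' @export
nicheDistributionByGroup <- function(model, sampleOfSpot, groupOfSample) {
  labels <- nicheLabels(model)
  if (!is.null(names(sampleOfSpot)))
    sampleOfSpot <- sampleOfSpot[names(labels)]
  stopIfNot(length(sampleOfSpot) == length(labels) && !anyNA(sampleOfSpot),
            "every spot must map to a sample")
  samples <- unique(sampleOfSpot)
  stopIfNot(all(samples %in% names(groupOfSample)),
            "every sample must map to a group")
  k <- model@k

  fracOf <- function(lab) tabulate(lab, k) / length(lab)
  perSampleM <- vapply(samples, function(s)
    fracOf(labels[sampleOfSpot == s]), numeric(k))  # k x n_samples
  perSample <- data.frame(
    sample = rep(samples, each = k),
    group = rep(unname(groupOfSample[samples]), each = k),
    niche = rep(seq_len(k), times = length(samples)),
    fraction = as.numeric(perSampleM))

  groups <- unique(unname(groupOfSample[samples]))
  perGroup <- do.call(rbind, lapply(groups, function(g) {
    inG <- sampleOfSpot %in% samples[groupOfSample[samples] == g]
    data.frame(group = g, niche = seq_len(k), fraction = fracOf(labels[inG]))
  }))

  sizes <- table(unname(groupOfSample[samples]))
  canTest <- length(groups) >= 2 && min(sizes) >= 2
  tests <- do.call(rbind, lapply(seq_len(k), function(ni) {
    vals <- perSampleM[ni, ]
    grp <- factor(unname(groupOfSample[samples]))
    if (!canTest)
      return(data.frame(niche = ni, statistic = NA_real_, p = NA_real_))
    if (length(unique(vals)) == 1L)
      return(data.frame(niche = ni, statistic = 0, p = 1))
    kt <- stats::kruskal.test(vals, grp)
    data.frame(niche = ni, statistic = unname(kt$statistic),
               p = unname(kt$p.value))
  }))
  list(perSample = perSample, perGroup = perGroup, tests = tests)
}

#' Probabilistic cell-type co-occurrence within a niche
#'
#' Veech-style exact co-occurrence analysis over the spots of one niche.
#' Each cell type's presence per spot is binarized by the quantile rule
#' (weight strictly above that type's within-niche quantile, default the
#' 25th percentile, linear-interpolation convention). For every unordered
#' pair the joint count j follows the exact hypergeometric law given the
#' marginals, `P(j) = C(n_a, j) C(N - n_a, n_b - j) / C(N, n_b)`;
#' `p_gt = P(X >= j_obs)` and `p_lt = P(X <= j_obs)` classify the pair as
#' positively associated (`p_gt < probTh`), negatively associated
#' (`p_lt < probTh`), or random.
#'
#' @param weights a [CellTypeWeights-class].
#' @param model a [NicheModel-class] fitted to those weights.
#' @param nicheId which niche to analyze (1..k).
#' @param quantileThreshold presence quantile in (0,1), default 0.25.
#' @param probTh probability threshold, default 0.05.
#' @return data.frame with one row per unordered type pair: `type_a`,
#'   `type_b`, `n_sites`, `n_a`, `n_b`, `j_obs`, `j_expected`
#'   (`= n_a n_b / N`), `p_lt`, `p_gt`, `classification`, `degenerate`
#' @export
cooccurrenceWithinNiche <- function(weights, model, nicheId,
                                    quantileThreshold = 0.25,
                                    probTh = 0.05) {
  x <- weights@.Data
  labels <- nicheLabels(model)
  stopIfNot(identical(names(labels), rownames(x)),
            "model labels must align with the weight rows")
  nicheId <- as.integer(nicheId)
  if (!nicheId %in% seq_len(model@k))
    stop("nicheId must name an existing niche", call. = FALSE)
  xs <- x[labels == nicheId, , drop = FALSE]
  N <- nrow(xs)
  if (N < 2) stop("the niche must contain at least two spots", call. = FALSE)
  stopIfNot(quantileThreshold > 0 && quantileThreshold < 1,
            "quantileThreshold must lie in (0, 1)")
  stopIfNot(probTh > 0 && probTh < 1, "probTh must lie in (0, 1)")

  presence <- vapply(colnames(xs), function(t) {
    thr <- stats::quantile(xs[, t], quantileThreshold, names = FALSE, type = 7)
    xs[, t] > thr
  }, logical(N))
  nPer <- colSums(presence)

  pairs <- utils::combn(colnames(xs), 2)
  out <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
    a <- pairs[1, p]; b <- pairs[2, p]
    na <- nPer[[a]]; nb <- nPer[[b]]
    j <- sum(presence[, a] & presence[, b])
    pGt <- stats::phyper(j - 1, na, N - na, nb, lower.tail = FALSE)
    pLt <- stats::phyper(j, na, N - na, nb)
    degenerate <- na == 0 || nb == 0 || na == N || nb == N
    cls <- if (pGt < probTh) "positive"
           else if (pLt < probTh) "negative" else "random"
    data.frame(type_a = a, type_b = b, n_sites = N, n_a = na, n_b = nb,
               j_obs = j, j_expected = na * nb / N, p_lt = pLt, p_gt = pGt,
               classification = cls, degenerate = degenerate)
  }))
  rownames(out) <- NULL
  out
}
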