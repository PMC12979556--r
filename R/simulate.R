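## Synthetic Visium-like samples with planted ground truth. Every generator
## is a pure function of (parameters, seed): the caller's RNG state is left
## untouched and the same seed reproduces the output bit for bit.

#' Generate a hexagonal spot lattice
#'
#' Builds a Visium-like hexagonal lattice of spot centers: odd array rows are
#' offset by half the pitch, and rows are spaced `pitch * sqrt(3)/2` apart, so
#' every interior spot has six equidistant neighbors at exactly the pitch.
#' All spots are flagged in-tissue. Pixel coordinates are micron coordinates
#' divided by `micronsPerPixel`; the window is the padded bounding box used
#' by [readTissuePositions()].
#'
#' @param nRows,nCols lattice dimensions (>= 1).
#' @param pitchUm center-to-center spot distance in micrometers (default
#'   100, the platform's nominal pitch; the 55 um spot diameter is metadata
#'   only since all statistics treat spots as points).
#' @param micronsPerPixel positive scale used to derive pixel coordinates.
#' @param sampleId sample identifier for the grid.
#' @return a [SpotGrid-class]
#' @examples
#' g <- generateSpotLattice(4, 4)
#' nSpots(g)
#' @export
generateSpotLattice <- function(nRows, nCols, pitchUm = 100,
                                micronsPerPixel = 1,
                                sampleId = "synthetic") {
  stopIfNot(nRows >= 1 && nCols >= 1, "nRows and nCols must be >= 1")
  checkPositiveScalar(pitchUm, "pitchUm")
  checkPositiveScalar(micronsPerPixel, "micronsPerPixel")
  r <- rep(seq_len(nRows) - 1L, each = nCols)
  c_ <- rep(seq_len(nCols) - 1L, times = nRows)
  xUm <- c_ * pitchUm + (r %% 2L) * pitchUm / 2
  yUm <- r * pitchUm * sqrt(3) / 2
  newSpotGrid(sampleId = sampleId,
              spotIds = sprintf("spot_r%03d_c%03d", r, c_),
              arrayCoords = cbind(row = r, col = c_),
              pixelCoords = cbind(x = xUm, y = yUm) / micronsPerPixel,
              micronsPerPixel = micronsPerPixel,
              inTissue = rep(TRUE, length(r)))
}

#' Generate niche-structured Dirichlet compositions
#'
#' Plants `kTrue` spatially contiguous niches on the lattice and draws each
#' spot's cell-type weights from its niche's Dirichlet distribution. Each
#' niche has a distinct mean composition with one dominant type (mean weight
#' `dominance` for its own type, the remainder spread evenly); `concentration`
#' is the Dirichlet precision (the sum of the alpha parameters), so larger
#' values give compositions tighter around the niche mean.
#'
#' @param grid a [SpotGrid-class].
#' @param kTrue number of planted niches (1 <= kTrue <= number of spots).
#' @param nTypes number of cell types (>= kTrue recommended so every niche
#'   can have its own dominant type).
#' @param concentration Dirichlet precision (default 30).
#' @param dominance mean weight of a niche's dominant type (default 0.6).
#' @param layout `"blocks"` (horizontal bands of equal spot count, split on
#'   the y coordinate) or `"voronoi"` (nearest-seed regions around `kTrue`
#'   randomly chosen spots); both are contiguous by construction.
#' @param seed integer seed.
#' @param deterministic when TRUE, every spot's weights equal its niche mean
#'   exactly (the infinite-concentration limit).
#' @return list with `weights` (a [CellTypeWeights-class]) and `truth`
#'   (list: `nicheLabel` named integer, `nicheMeans` matrix, `seed`)
#' @export
generateNicheWeights <- function(grid, kTrue, nTypes,
                                 concentration = 30, dominance = 0.6,
                                 layout = c("blocks", "voronoi"),
                                 seed = 1L, deterministic = FALSE) {
  layout <- match.arg(layout)
  n <- nSpots(grid)
  stopIfNot(kTrue >= 1, "kTrue must be >= 1")
  if (kTrue > n) stop("kTrue exceeds the number of spots", call. = FALSE)
  stopIfNot(nTypes >= 1, "nTypes must be >= 1")
  checkPositiveScalar(concentration, "concentration")
  stopIfNot(dominance > 0 && dominance < 1, "dominance must lie in (0, 1)")
  if (nTypes == 1 && dominance != 1) dominance <- 1

  typeNames <- sprintf("type%02d", seq_len(nTypes))
  means <- matrix((1 - dominance) / max(1, nTypes - 1), kTrue, nTypes,
                  dimnames = list(NULL, typeNames))
  for (i in seq_len(kTrue)) means[i, 1 + (i - 1) %% nTypes] <- dominance
  if (nTypes == 1) means[] <- 1
  means <- means / rowSums(means)

  um <- micronCoords(grid)
  withSeed(seed, {
    label <- if (layout == "blocks") {
      ord <- order(um[, 2], um[, 1])
      lab <- integer(n)
      lab[ord] <- rep(seq_len(kTrue), each = ceiling(n / kTrue))[seq_len(n)]
      lab
    } else {
      seeds <- sample.int(n, kTrue)
      d <- crossDist(um, um[seeds, , drop = FALSE])
      max.col(-d, ties.method = "first")
    }
    w <- if (deterministic) {
      means[label, , drop = FALSE]
    } else {
      alpha <- concentration * means
      g <- matrix(stats::rgamma(n * nTypes,
                                shape = alpha[label, , drop = FALSE]),
                  n, nTypes)
      g / rowSums(g)
    }
    colnames(w) <- typeNames
    rownames(w) <- spotIds(grid)
    list(weights = cellTypeWeights(w),
         truth = list(nicheLabel = stats::setNames(label, spotIds(grid)),
                      nicheMeans = means, layout = layout, seed = seed))
  })
}

#' Generate positive-spot point patterns with known co-localization
#'
#' Plants the positive-spot sets of two cell types on the lattice, either
#' independently (the spatial-independence null: each type's positive set is
#' a uniform random subset of spots, drawn independently of the other) or
#' co-clustered (`shared_clusters`: both types' spots gather around the same
#' `nParents` parent locations, a Neyman-Scott-style construction on the
#' lattice). In cluster mode each type draws its requested number of
#' Gaussian-displaced points (sd `clusterSdUm`) around uniformly chosen
#' shared parents, and the positive set is the requested number of spots
#' closest to those points, so both modes return exactly `nI` and `nJ` spots.
#'
#' @param grid a [SpotGrid-class].
#' @param nI,nJ positive-spot counts for the two types (<= number of spots).
#' @param mode `"independent"` or `"shared_clusters"`.
#' @param nParents number of shared parent locations (cluster mode, >= 1).
#' @param clusterSdUm Gaussian displacement sd around parents, micrometers.
#' @param seed integer seed.
#' @param typeNames labels for the two patterns.
#' @return list with `patterns` (list of two [PointPattern-class]) and
#'   `truth` (list: `colocMode`, `positiveTruth` named list of barcode
#'   vectors, `parents` matrix or NULL, `seed`)
#' @export
generatePointPatterns <- function(grid, nI, nJ,
                                  mode = c("independent", "shared_clusters"),
                                  nParents = 5, clusterSdUm = 50, seed = 1L,
                                  typeNames = c("typeA", "typeB")) {
  mode <- match.arg(mode)
  n <- nSpots(grid)
  stopIfNot(nI >= 1 && nJ >= 1 && nI <= n && nJ <= n,
            "nI and nJ must lie in 1..nSpots(grid)")
  um <- micronCoords(grid)
  w <- spotWindow(grid, "um")

  withSeed(seed, {
    parents <- NULL
    pick <- if (mode == "independent") {
      function(m) sort(sample.int(n, m))
    } else {
      if (nParents < 1) stop("nParents must be >= 1 in shared_clusters mode",
                             call. = FALSE)
      stopIfNot(clusterSdUm >= 0, "clusterSdUm must be nonnegative")
      parents <- cbind(x = stats::runif(nParents, w[1], w[2]),
                       y = stats::runif(nParents, w[3], w[4]))
      function(m) {
        pts <- parents[sample.int(nParents, m, replace = TRUE), , drop = FALSE] +
          matrix(stats::rnorm(2 * m, sd = clusterSdUm), m, 2)
        dNearest <- apply(crossDist(um, pts), 1, min)
        sort(order(dNearest)[seq_len(m)])
      }
    }
    idx <- list(pick(nI), pick(nJ))
    patterns <- lapply(1:2, function(t)
      new("PointPattern", sampleId = grid@sampleId, cellType = typeNames[t],
          coords = um[idx[[t]], , drop = FALSE],
          spotIds = spotIds(grid)[idx[[t]]],
          window = as.numeric(w), degenerate = FALSE))
    names(patterns) <- typeNames
    list(patterns = patterns,
         truth = list(colocMode = mode,
                      positiveTruth = stats::setNames(
                        lapply(idx, function(i) spotIds(grid)[i]), typeNames),
                      parents = parents, seed = seed))
  })
}

#' Generate CNV profiles with planted gain/loss blocks
#'
#' Simulates the inferred-CNV contract: reference (normal) cells are i.i.d.
#' Normal(1, `noiseSd`) in every genomic bin; malignant observation cells are
#' additionally shifted to the block level inside each planted gain or loss
#' block. Ground-truth malignant ids are recorded.
#'
#' @param nRef,nMal numbers of reference and malignant cells.
#' @param nBins number of genomic bins (>= 2).
#' @param blocks list of `c(start, end, level)` triplets; bins are 1-based
#'   and inclusive, blocks must not overlap, and at least one level must
#'   differ from 1 (an empty list gives flat profiles with no planted
#'   aberration). Default: one gain at level 1.4 over the first quarter of
#'   the bins.
#' @param noiseSd per-bin Gaussian noise sd (>= 0).
#' @param seed integer seed.
#' @return list with `cnv` (a [CNVMatrix-class]) and `truth`
#'   (list: `malignantIds`, `blocks`, `seed`)
#' @export
generateCNVProfiles <- function(nRef = 200, nMal = 50, nBins = 200,
                                blocks = list(c(1, floor(nBins / 4), 1.4)),
                                noiseSd = 0.05, seed = 1L) {
  stopIfNot(nRef >= 1 && nMal >= 1, "nRef and nMal must be >= 1")
  stopIfNot(nBins >= 2, "nBins must be >= 2")
  stopIfNot(noiseSd >= 0, "noiseSd must be nonnegative")
  stopIfNot(is.list(blocks), "blocks must be a list of c(start, end, level)")
  if (length(blocks)) {
    bl <- do.call(rbind, lapply(blocks, function(b) {
      stopIfNot(length(b) == 3, "each block must be c(start, end, level)")
      b
    }))
    if (any(bl[, 1] < 1 | bl[, 2] > nBins | bl[, 1] > bl[, 2]))
      stop("blocks must satisfy 1 <= start <= end <= nBins", call. = FALSE)
    if (all(bl[, 3] == 1))
      stop("at least one block level must differ from 1", call. = FALSE)
    covered <- unlist(lapply(blocks, function(b) b[1]:b[2]))
    if (anyDuplicated(covered)) stop("blocks must not overlap", call. = FALSE)
  }

  cellIds <- c(sprintf("ref_%04d", seq_len(nRef)),
               sprintf("mal_%04d", seq_len(nMal)))
  shift <- numeric(nBins)
  for (b in blocks) shift[b[1]:b[2]] <- b[3] - 1
  withSeed(seed, {
    v <- matrix(stats::rnorm((nRef + nMal) * nBins, mean = 1, sd = noiseSd),
                nRef + nMal, nBins,
                dimnames = list(cellIds, sprintf("bin_%04d", seq_len(nBins))))
    v[nRef + seq_len(nMal), ] <-
      v[nRef + seq_len(nMal), , drop = FALSE] +
      matrix(shift, nMal, nBins, byrow = TRUE)
    cnv <- new("CNVMatrix", values = v,
               role = c(rep("reference", nRef), rep("observation", nMal)))
    list(cnv = cnv,
         truth = list(malignantIds = cellIds[nRef + seq_len(nMal)],
                      blocks = blocks, seed = seed))
  })
}

#' Generate marker-structured spot counts
#'
#' Simulates a genes x spots count matrix tied to a composition matrix:
#' each cell type gets `markersPerType` marker genes whose expected count in
#' a spot is `baseMean * (1 + (markerFold - 1) * weight)`, where `weight` is
#' the spot's deconvolved weight for that type; non-marker genes sit flat at
#' `baseMean`. Counts are negative binomial with the mean/dispersion
#' parameterization `variance = mean + mean^2 / dispersion` (set
#' `dispersion = Inf` for the Poisson limit).
#'
#' @param grid a [SpotGrid-class] (spot order and barcodes).
#' @param weights a [CellTypeWeights-class] aligned with `grid`.
#' @param markersPerType marker genes per cell type (default 25, matching
#'   the signature size used downstream).
#' @param markerFold expected fold change of a marker in a pure spot (> 1).
#' @param baseMean baseline expected count per gene per spot.
#' @param dispersion negative-binomial dispersion (`Inf` = Poisson).
#' @param nNoiseGenes flat non-marker genes to add.
#' @param seed integer seed.
#' @return list with `counts` (genes x spots matrix), `markerMap` (named
#'   list cell type -> marker gene names) and `truth` (list with `seed`)
#' @export
generateExpression <- function(grid, weights, markersPerType = 25,
                               markerFold = 3, baseMean = 5, dispersion = 2,
                               nNoiseGenes = 100, seed = 1L) {
  stopIfNot(markersPerType >= 1, "markersPerType must be >= 1")
  stopIfNot(markerFold >= 1, "markerFold must be >= 1")
  checkPositiveScalar(baseMean, "baseMean")
  stopIfNot(dispersion > 0, "dispersion must be positive (Inf = Poisson)")
  stopIfNot(identical(rownames(weights), spotIds(grid)),
            "weights rows must match the grid's spot barcodes")
  types <- cellTypes(weights)
  markerMap <- stats::setNames(lapply(types, function(t)
    sprintf("%s_marker%02d", t, seq_len(markersPerType))), types)
  genes <- c(unlist(markerMap, use.names = FALSE),
             if (nNoiseGenes > 0) sprintf("noise_%04d", seq_len(nNoiseGenes)))
  n <- nSpots(grid)
  mu <- matrix(baseMean, length(genes), n,
               dimnames = list(genes, spotIds(grid)))
  for (t in types)
    mu[markerMap[[t]], ] <- rep(baseMean * (1 + (markerFold - 1) * weights[, t]),
                                each = markersPerType)
  withSeed(seed, {
    counts <- if (is.infinite(dispersion))
      matrix(stats::rpois(length(mu), mu), nrow(mu), ncol(mu),
             dimnames = dimnames(mu))
    else
      matrix(stats::rnbinom(length(mu), mu = mu, size = dispersion),
             nrow(mu), ncol(mu), dimnames = dimnames(mu))
    list(counts = counts, markerMap = markerMap,
         truth = list(markerMap = markerMap, markerFold = markerFold,
                      seed = seed))
  })
}

#' Write a complete synthetic sample directory
#'
#' One-call presets backing the `simulate` subcommand of the command-line
#' interface. Every preset writes a tissue-positions CSV plus the files the
#' matching analysis stage consumes, and a `truth.json` with the planted
#' ground truth.
#'
#' @param preset one of `"niches"`, `"coloc-null"`, `"coloc-clustered"`,
#'   `"cnv"`, `"expression"`.
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param nRows,nCols lattice size (default 30 x 30).
#' @param config an [AnalysisConfig-class] (spot pitch is taken from it).
#' @return invisibly, a character vector of the files written
#' @export
simulatePreset <- function(preset = c("niches", "coloc-null",
                                      "coloc-clustered", "cnv", "expression"),
                           dir, seed = 1L, nRows = 30, nCols = 30,
                           config = analysisConfig()) {
  preset <- match.arg(preset)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  files <- character()
  t0 <- as.numeric(proc.time()[["elapsed"]])

  if (preset != "cnv") {
    grid <- generateSpotLattice(nRows, nCols, pitchUm = config@pitchUm,
                                sampleId = basename(dir))
    writeTissuePositions(grid, p("tissue_positions.csv"))
    files <- c(files, p("tissue_positions.csv"))
  }

  truth <- switch(preset,
    "niches" = {
      g <- generateNicheWeights(grid, kTrue = 5, nTypes = 8, seed = seed)
      writeWeights(g$weights, p("weights.tsv"))
      files <- c(files, p("weights.tsv"))
      list(preset = preset, niche_label = as.list(g$truth$nicheLabel),
           seed = seed)
    },
    "coloc-null" = ,
    "coloc-clustered" = {
      mode <- if (preset == "coloc-null") "independent" else "shared_clusters"
      pp <- generatePointPatterns(grid, nI = 100, nJ = 100, mode = mode,
                                  seed = seed)
      writeWeights(patternsToWeights(grid, pp$patterns), p("weights.tsv"))
      files <- c(files, p("weights.tsv"))
      list(preset = preset, coloc_mode = mode,
           positive_spots = pp$truth$positiveTruth, seed = seed)
    },
    "cnv" = {
      g <- generateCNVProfiles(seed = seed)
      writeCNVMatrix(g$cnv, p("infercnv_observations.tsv"),
                     p("infercnv_references.tsv"))
      files <- c(files, p("infercnv_observations.tsv"),
                 p("infercnv_references.tsv"))
      list(preset = preset, malignant_ids = g$truth$malignantIds, seed = seed)
    },
    "expression" = {
      nw <- generateNicheWeights(grid, kTrue = 5, nTypes = 8, seed = seed)
      ex <- generateExpression(grid, nw$weights,
                               seed = childSeed(seed, 1L))
      writeWeights(nw$weights, p("weights.tsv"))
      writeCounts(ex$counts, p("counts.mtx"), p("features.txt"),
                  p("barcodes.txt"))
      writeGeneSets(ex$markerMap, p("marker_sets.gmt"))
      files <- c(files, p("weights.tsv"), p("counts.mtx"), p("features.txt"),
                 p("barcodes.txt"), p("marker_sets.gmt"))
      list(preset = preset, marker_map = ex$markerMap,
           niche_label = as.list(nw$truth$nicheLabel), seed = seed)
    })

  writeResult(truth, p("truth.json"), "json", config = config, seed = seed)
  files <- c(files, p("truth.json"))
  logStage("simulate", preset = preset, dir = dir, seed = seed, t0 = t0)
  invisible(files)
}

#' Encode planted point patterns as a weight table
#'
#' Builds a row-stochastic weight matrix whose positive-spot calls (at the
#' default 25th-percentile rule) recover the given patterns exactly:
#' positive spots carry weight 0.5 for their type, all other spots 0.05,
#' and a background column absorbs the remainder.
#'
#' @param grid the [SpotGrid-class] the patterns live on.
#' @param patterns named list of [PointPattern-class] objects (e.g. from
#'   [generatePointPatterns()]).
#' @return a [CellTypeWeights-class] with one column per pattern plus
#'   `background`
#' @export
patternsToWeights <- function(grid, patterns) {
  n <- nSpots(grid)
  w <- matrix(0.05, n, length(patterns) + 1,
              dimnames = list(spotIds(grid),
                              c(names(patterns), "background")))
  for (t in names(patterns))
    w[spotIds(grid) %in% spotIds(patterns[[t]]), t] <- 0.5
  w[, "background"] <- 1 - rowSums(w[, names(patterns), drop = FALSE])
  cellTypeWeights(w)
}
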