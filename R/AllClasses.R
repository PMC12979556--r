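#' @import methods
NULL

#' SpotGrid: spot geometry for one spatial sample
#'
#' Holds the spot identities and coordinates of one spot-based spatial
#' transcriptomics sample (Visium-style), together with the pixel-to-micron
#' scale and the rectangular observation window used by all spatial
#' statistics. Coordinates are stored in full-resolution pixels; micron
#' coordinates are derived via a single multiplicative scale per sample.
#' Spots are treated as points (their centers); the 55 um capture diameter
#' is metadata, not geometry.
#'
#' @slot sampleId single sample identifier.
#' @slot spotIds character vector of unique spot barcodes.
#' @slot arrayCoords integer matrix (n x 2, columns `row`, `col`) of array
#'   lattice indices.
#' @slot pixelCoords numeric matrix (n x 2, columns `x`, `y`) of spot centers
#'   in full-resolution pixels (`x` = image column, `y` = image row).
#' @slot micronsPerPixel positive scalar converting pixels to micrometers.
#' @slot inTissue logical vector, whether each retained spot overlaps tissue.
#' @slot window numeric length-4 vector `c(xmin, xmax, ymin, ymax)` in pixel
#'   units; the axis-aligned observation window containing all spot centers.
#'
#' @seealso [readTissuePositions()], [generateSpotLattice()],
#'   [micronCoords()], [spotWindow()]
#' @export
setClass("SpotGrid", representation(
  sampleId        = "character",
  spotIds         = "character",
  arrayCoords     = "matrix",
  pixelCoords     = "matrix",
  micronsPerPixel = "numeric",
  inTissue        = "logical",
  window          = "numeric"
))

setValidity("SpotGrid", function(object) {
  msg <- character()
  n <- length(object@spotIds)
  if (anyDuplicated(object@spotIds))
    msg <- c(msg, "spot barcodes must be unique within a sample")
  if (nrow(object@pixelCoords) != n || nrow(object@arrayCoords) != n ||
      length(object@inTissue) != n)
    msg <- c(msg, "coordinate and flag lengths must match the number of spots")
  if (length(object@micronsPerPixel) != 1 || !is.finite(object@micronsPerPixel) ||
      object@micronsPerPixel <= 0)
    msg <- c(msg, "micronsPerPixel must be a single positive number")
  if (length(object@window) != 4 || any(!is.finite(object@window)))
    msg <- c(msg, "window must be c(xmin, xmax, ymin, ymax)")
  else {
    w <- object@window
    if (w[2] < w[1] || w[4] < w[3])
      msg <- c(msg, "window must have xmax >= xmin and ymax >= ymin")
    nd <- nrow(unique(object@pixelCoords))
    if (n >= 2 && nd >= 2 && (w[2] - w[1]) * (w[4] - w[3]) <= 0)
      msg <- c(msg, "window area must be positive when >= 2 distinct spot positions exist")
    if (n > 0) {
      eps <- 1e-9 * max(1, abs(w))
      x <- object@pixelCoords[, 1]; y <- object@pixelCoords[, 2]
      if (any(x < w[1] - eps | x > w[2] + eps | y < w[3] - eps | y > w[4] + eps))
        msg <- c(msg, "all spot centers must lie inside the window")
    }
  }
  if (length(msg)) msg else TRUE
})

#' CellTypeWeights: per-spot deconvolved cell-type composition
#'
#' A spot x cell-type matrix of deconvolution weights (e.g. RCTD output):
#' rows are spots (barcodes as rownames), columns are cell types, entries are
#' nonnegative and each row sums to one. This is the input contract for
#' niche clustering, co-occurrence and positive-spot calling.
#'
#' @slot .Data numeric matrix, row-stochastic with unique rownames.
#' @seealso [readWeights()], [generateNicheWeights()], [clusterCompositions()]
#' @export
setClass("CellTypeWeights", contains = "matrix")

setValidity("CellTypeWeights", function(object) {
  m <- object@.Data
  msg <- character()
  if (!is.numeric(m)) msg <- c(msg, "weights must be numeric")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    msg <- c(msg, "rows must carry unique spot barcodes")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    msg <- c(msg, "columns must carry unique cell-type names")
  if (is.numeric(m) && nrow(m) > 0) {
    if (any(!is.finite(m))) msg <- c(msg, "weights must be finite")
    else {
      if (min(m) < -1e-12) msg <- c(msg, "weights must be nonnegative")
      rs <- rowSums(m)
      if (any(abs(rs - 1) > 1e-8)) {
        worst <- which.max(abs(rs - 1))
        msg <- c(msg, sprintf(
          "rows must sum to 1 (worst: '%s', sum = %.10f)",
          rownames(m)[worst], rs[worst]))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' AnalysisConfig: the tuning constants of the pipeline
#'
#' One object holding every stated tuning constant of the analysis suite, so
#' that a result can snapshot the exact configuration that produced it.
#' Defaults are the published values: positive spots exceed the 25th
#' percentile of a type's weights; samples with fewer than 40 positive spots
#' for either type are excluded; Monte-Carlo envelopes at the 95% level;
#' co-occurrence probability threshold 0.05; CNV reference = top 5% of
#' aberration scores; malignant call = similarity > 0.20 and within the top
#' 20%; gene sets = top 25 markers.
#'
#' @slot quantileThreshold quantile in (0,1) defining positive spots (0.25).
#' @slot minPositiveSpots minimum positive spots per type per sample (40).
#' @slot nSimulations Monte-Carlo simulations for envelopes (999).
#' @slot envelopeLevel pointwise envelope level (0.95).
#' @slot rMaxFrac r-grid maximum as a fraction of the shorter window side (0.25).
#' @slot rSteps number of r-grid values (30).
#' @slot kmeansNInit random restarts for the observed k-means fits (10).
#' @slot gapRefs reference datasets for the gap statistic (50).
#' @slot cooccurProbTh co-occurrence probability threshold (0.05).
#' @slot cnvRefTopFrac fraction of top-scoring cells forming the malignant
#'   reference (0.05).
#' @slot cnvSimilarityThreshold similarity threshold for malignant calls (0.20).
#' @slot cnvCallTopFrac top fraction of similarity scores eligible for
#'   malignant calls (0.20).
#' @slot markerTopN markers per cell type in signature gene sets (25).
#' @slot pitchUm center-to-center spot pitch in micrometers for synthetic
#'   lattices (100).
#' @seealso [analysisConfig()]
#' @export
setClass("AnalysisConfig", representation(
  quantileThreshold      = "numeric",
  minPositiveSpots       = "integer",
  nSimulations           = "integer",
  envelopeLevel          = "numeric",
  rMaxFrac               = "numeric",
  rSteps                 = "integer",
  kmeansNInit            = "integer",
  gapRefs                = "integer",
  cooccurProbTh          = "numeric",
  cnvRefTopFrac          = "numeric",
  cnvSimilarityThreshold = "numeric",
  cnvCallTopFrac         = "numeric",
  markerTopN             = "integer",
  pitchUm                = "numeric"
), prototype(
  quantileThreshold      = 0.25,
  minPositiveSpots       = 40L,
  nSimulations           = 999L,
  envelopeLevel          = 0.95,
  rMaxFrac               = 0.25,
  rSteps                 = 30L,
  kmeansNInit            = 10L,
  gapRefs                = 50L,
  cooccurProbTh          = 0.05,
  cnvRefTopFrac          = 0.05,
  cnvSimilarityThreshold = 0.20,
  cnvCallTopFrac         = 0.20,
  markerTopN             = 25L,
  pitchUm                = 100
))

setValidity("AnalysisConfig", function(object) {
  msg <- character()
  inOpen01 <- function(x) length(x) == 1 && is.finite(x) && x > 0 && x < 1
  for (s in c("quantileThreshold", "envelopeLevel", "cooccurProbTh",
              "cnvRefTopFrac", "cnvCallTopFrac", "rMaxFrac"))
    if (!inOpen01(slot(object, s)))
      msg <- c(msg, sprintf("%s must lie in (0, 1)", s))
  if (object@minPositiveSpots < 1L) msg <- c(msg, "minPositiveSpots must be >= 1")
  if (object@nSimulations < 19L) msg <- c(msg, "nSimulations must be >= 19")
  if (object@rSteps < 2L) msg <- c(msg, "rSteps must be >= 2")
  if (object@kmeansNInit < 1L) msg <- c(msg, "kmeansNInit must be >= 1")
  if (object@gapRefs < 2L) msg <- c(msg, "gapRefs must be >= 2")
  if (abs(object@cnvSimilarityThreshold) >= 1)
    msg <- c(msg, "cnvSimilarityThreshold must lie in (-1, 1)")
  if (object@markerTopN < 1L) msg <- c(msg, "markerTopN must be >= 1")
  if (object@pitchUm <= 0) msg <- c(msg, "pitchUm must be positive")
  if (length(msg)) msg else TRUE
})

#' PointPattern: positive spots of one cell type, in micrometers
#'
#' The planar point pattern of the spots called positive for one cell type in
#' one sample. Coordinates and the rectangular window are in micrometers; all
#' cross-K statistics operate on these patterns.
#'
#' @slot sampleId sample identifier.
#' @slot cellType cell-type label the pattern refers to.
#' @slot coords numeric matrix (n x 2, columns `x`, `y`) in micrometers.
#' @slot spotIds barcodes of the positive spots (parallel to `coords`).
#' @slot window numeric `c(xmin, xmax, ymin, ymax)` in micrometers.
#' @slot degenerate flag set when thresholding was degenerate (e.g. all
#'   weights identical), in which case the pattern may be empty.
#' @seealso [definePositiveSpots()], [crossK()]
#' @export
setClass("PointPattern", representation(
  sampleId   = "character",
  cellType   = "character",
  coords     = "matrix",
  spotIds    = "character",
  window     = "numeric",
  degenerate = "logical"
))

setValidity("PointPattern", function(object) {
  msg <- character()
  n <- nrow(object@coords)
  if (ncol(object@coords) != 2) msg <- c(msg, "coords must have two columns (x, y)")
  if (length(object@spotIds) && length(object@spotIds) != n)
    msg <- c(msg, "spotIds must be empty or parallel to coords")
  if (length(object@window) != 4 || any(!is.finite(object@window)))
    msg <- c(msg, "window must be c(xmin, xmax, ymin, ymax)")
  else if (n > 0) {
    w <- object@window
    eps <- 1e-9 * max(1, abs(w))
    if (any(object@coords[, 1] < w[1] - eps | object@coords[, 1] > w[2] + eps |
            object@coords[, 2] < w[3] - eps | object@coords[, 2] > w[4] + eps))
      msg <- c(msg, "all points must lie inside the window")
  }
  if (n == 0 && !isTRUE(object@degenerate))
    msg <- c(msg, "an empty pattern must carry the degenerate flag")
  if (length(msg)) msg else TRUE
})

#' NicheModel: composition clusters of spots
#'
#' The fitted k-means partition of spots into niches (composition clusters)
#' plus the cluster-number diagnostics used to choose k: the within-cluster
#' sum of squares (WSS), Calinski-Harabasz index and gap statistic across the
#' candidate k values, and the per-criterion votes.
#'
#' @slot k number of niches in the fitted model.
#' @slot labels integer vector in 1..k, named by spot barcode; label 1 is the
#'   largest cluster (size-ordered relabeling).
#' @slot centroids k x n_types matrix; row i is the mean composition of niche i.
#' @slot diagnostics data.frame with one row per candidate k (columns `k`,
#'   `wss`, `ch`, `gap`, `gap_se`, `skipped`); empty when k was fixed by the
#'   caller.
#' @slot recommendedK the majority-vote recommended k (NA when not computed).
#' @slot votes named integer vector of per-criterion recommended k
#'   (`ch`, `gap`, `elbow`); empty when not computed.
#' @slot seed integer seed the fit was run under.
#' @seealso [selectK()], [clusterCompositions()]
#' @export
setClass("NicheModel", representation(
  k            = "integer",
  labels       = "integer",
  centroids    = "matrix",
  diagnostics  = "data.frame",
  recommendedK = "integer",
  votes        = "integer",
  seed         = "integer"
))

setValidity("NicheModel", function(object) {
  msg <- character()
  k <- object@k
  if (length(k) != 1 || k < 1) msg <- c(msg, "k must be a single positive integer")
  if (length(object@labels)) {
    if (is.null(names(object@labels))) msg <- c(msg, "labels must be named by barcode")
    if (any(object@labels < 1 | object@labels > k))
      msg <- c(msg, "labels must lie in 1..k")
    else if (!all(seq_len(k) %in% object@labels))
      msg <- c(msg, "every cluster 1..k must be non-empty")
    if (nrow(object@centroids) != k)
      msg <- c(msg, "centroids must have one row per cluster")
  }
  if (length(msg)) msg else TRUE
})

#' CrossKResult: cross-type Ripley K/L statistics with envelopes
#'
#' The full output of the cross-K co-localization analysis for one ordered
#' pair of cell types in one sample: the distance grid (micrometers), the
#' Kcross / Lcross / D = L(r) - r curves, pointwise Monte-Carlo envelope
#' bounds under the independence null, the Aggregation Index (fraction of
#' distances with D(r) > 0), Cohen's d of the D curve, and the global
#' Monte-Carlo p-value.
#'
#' @slot sampleId sample identifier.
#' @slot typeI,typeJ the two cell-type labels (K_ij counts type-j neighbors
#'   around type-i points).
#' @slot rGrid increasing positive distances in micrometers.
#' @slot K,L,D numeric curves on `rGrid`; `D = L - r`.
#' @slot envLo,envHi pointwise envelope bounds for D (NA when no envelope was
#'   computed).
#' @slot nSim number of Monte-Carlo simulations (0 without envelope).
#' @slot nI,nJ pattern sizes.
#' @slot aggregationIndex fraction of grid distances with D(r) > 0.
#' @slot cohensD mean(D)/sd(D) (unbiased sd); NA when sd(D) = 0.
#' @slot pGlobal add-one Monte-Carlo p-value of T = mean(D); NA without
#'   envelope.
#' @slot edgeCorrection "none" or "isotropic".
#' @slot seed seed used for the envelope simulations (NA without envelope).
#' @seealso [crossK()], [mcEnvelope()], [effectSizes()]
#' @export
setClass("CrossKResult", representation(
  sampleId         = "character",
  typeI            = "character",
  typeJ            = "character",
  rGrid            = "numeric",
  K                = "numeric",
  L                = "numeric",
  D                = "numeric",
  envLo            = "numeric",
  envHi            = "numeric",
  nSim             = "integer",
  nI               = "integer",
  nJ               = "integer",
  aggregationIndex = "numeric",
  cohensD          = "numeric",
  pGlobal          = "numeric",
  edgeCorrection   = "character",
  seed             = "integer"
))

setValidity("CrossKResult", function(object) {
  msg <- character()
  r <- object@rGrid
  if (any(r <= 0) || is.unsorted(r, strictly = TRUE))
    msg <- c(msg, "rGrid must be strictly increasing and positive")
  nr <- length(r)
  for (s in c("K", "L", "D"))
    if (length(slot(object, s)) != nr)
      msg <- c(msg, sprintf("%s must have one value per grid distance", s))
  if (length(object@K) == nr) {
    if (any(object@K < -1e-12, na.rm = TRUE)) msg <- c(msg, "K must be nonnegative")
    if (is.unsorted(object@K, na.rm = TRUE)) msg <- c(msg, "K must be nondecreasing in r")
  }
  if (!object@edgeCorrection %in% c("none", "isotropic"))
    msg <- c(msg, "edgeCorrection must be 'none' or 'isotropic'")
  if (length(msg)) msg else TRUE
})

#' CNVMatrix: per-cell inferred copy-number profiles
#'
#' A cells x genomic-bin matrix of inferred copy-number values centered at 1
#' (the inferCNV observations/references contract), with each cell labeled as
#' an observation (eligible for malignant calls) or a normal reference.
#'
#' @slot values numeric matrix, cells in rows (unique rownames), bins in
#'   columns; no missing values; at least two bins.
#' @slot role character per cell, "observation" or "reference".
#' @seealso [readCNVMatrix()], [generateCNVProfiles()], [callMalignancy()]
#' @export
setClass("CNVMatrix", representation(
  values = "matrix",
  role   = "character"
))

setValidity("CNVMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v) || any(!is.finite(v)))
    msg <- c(msg, "CNV values must be finite numbers")
  if (ncol(v) < 2) msg <- c(msg, "at least two genomic bins are required")
  if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
    msg <- c(msg, "cells must carry unique ids (rownames)")
  if (length(object@role) != nrow(v))
    msg <- c(msg, "one role per cell is required")
  else {
    if (!all(object@role %in% c("observation", "reference")))
      msg <- c(msg, "roles must be 'observation' or 'reference'")
    if (!any(object@role == "observation"))
      msg <- c(msg, "at least one observation cell is required")
  }
  if (length(msg)) msg else TRUE
})

#' MalignancyCall: per-cell malignancy classification
#'
#' Per-cell output of the CNV-similarity classifier: the CNV aberration score
#' (mean squared deviation from the neutral level 1), Pearson similarity to
#' the mean profile of the top-scoring reference-malignant cells, and the
#' binary malignant call.
#'
#' @slot cellIds cell identifiers.
#' @slot score nonnegative CNV aberration score per cell.
#' @slot similarity Pearson correlation with the malignant reference profile,
#'   in [-1, 1] (0 with `degenerate` set for flat profiles).
#' @slot isReferenceMalignant whether the cell is in the top-5% aberration
#'   reference set.
#' @slot isMalignant the final call (always FALSE for reference-role cells).
#' @slot degenerate per-cell flag for zero-variance profiles.
#' @slot role the cell roles carried over from the [CNVMatrix-class].
#' @slot policy "both", "threshold_only" or "top_frac_only".
#' @slot threshold,topFrac the similarity threshold and top-fraction used.
#' @seealso [callMalignancy()], [classifyMalignant()]
#' @export
setClass("MalignancyCall", representation(
  cellIds              = "character",
  score                = "numeric",
  similarity           = "numeric",
  isReferenceMalignant = "logical",
  isMalignant          = "logical",
  degenerate           = "logical",
  role                 = "character",
  policy               = "character",
  threshold            = "numeric",
  topFrac              = "numeric"
))

setValidity("MalignancyCall", function(object) {
  n <- length(object@cellIds)
  msg <- character()
  for (s in c("score", "similarity", "isReferenceMalignant", "isMalignant",
              "degenerate", "role"))
    if (length(slot(object, s)) != n)
      msg <- c(msg, sprintf("%s must have one entry per cell", s))
  if (length(object@score) == n && any(object@score < 0, na.rm = TRUE))
    msg <- c(msg, "CNV scores must be nonnegative")
  if (length(object@similarity) == n &&
      any(abs(object@similarity) > 1 + 1e-12))
    msg <- c(msg, "similarities must lie in [-1, 1]")
  if (any(object@isMalignant & object@role == "reference"))
    msg <- c(msg, "reference cells are never eligible for malignant calls")
  if (length(msg)) msg else TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "SpotGrid", function(object) {
  cat("SpotGrid '", object@sampleId, "': ", length(object@spotIds),
      " spots (", sum(object@inTissue), " in tissue), ",
      format(object@micronsPerPixel), " um/px\n", sep = "")
  w <- object@window * object@micronsPerPixel
  cat(sprintf("  window: [%.1f, %.1f] x [%.1f, %.1f] um (area %.3g um^2)\n",
              w[1], w[2], w[3], w[4], (w[2] - w[1]) * (w[4] - w[3])))
})

setMethod("show", "CellTypeWeights", function(object) {
  cat("CellTypeWeights: ", nrow(object), " spots x ", ncol(object),
      " cell types\n  types: ", paste(utils::head(colnames(object), 6),
      collapse = ", "),
      if (ncol(object) > 6) ", ..." else "", "\n", sep = "")
})

setMethod("show", "PointPattern", function(object) {
  cat("PointPattern '", object@cellType, "' in sample '", object@sampleId,
      "': n = ", nrow(object@coords),
      if (any(object@degenerate)) " [degenerate]" else "", "\n", sep = "")
})

setMethod("show", "NicheModel", function(object) {
  cat("NicheModel: k = ", object@k, ", ", length(object@labels), " spots\n",
      sep = "")
  if (length(object@votes))
    cat("  votes: ", paste(names(object@votes), object@votes, sep = "=",
        collapse = ", "), "; recommended k = ", object@recommendedK, "\n",
        sep = "")
  if (length(object@labels))
    cat("  cluster sizes: ", paste(tabulate(object@labels, object@k),
        collapse = ", "), "\n", sep = "")
})

setMethod("show", "CrossKResult", function(object) {
  cat("CrossKResult ", object@typeI, " ~ ", object@typeJ, " (sample '",
      object@sampleId, "'): n_i = ", object@nI, ", n_j = ", object@nJ,
      ", ", length(object@rGrid), " distances up to ",
      format(max(object@rGrid), digits = 4), " um\n", sep = "")
  cat(sprintf("  AI = %.3f, Cohen's d = %s, p_global = %s (n_sim = %d, edge = %s)\n",
              object@aggregationIndex,
              if (is.na(object@cohensD)) "NA" else sprintf("%.3f", object@cohensD),
              if (is.na(object@pGlobal)) "NA" else format(object@pGlobal),
              object@nSim, object@edgeCorrection))
})

setMethod("show", "CNVMatrix", function(object) {
  cat("CNVMatrix: ", nrow(object@values), " cells (",
      sum(object@role == "observation"), " observation, ",
      sum(object@role == "reference"), " reference) x ",
      ncol(object@values), " bins\n", sep = "")
})

setMethod("show", "MalignancyCall", function(object) {
  cat("MalignancyCall: ", length(object@cellIds), " cells, ",
      sum(object@isMalignant), " malignant (policy '", object@policy,
      "', threshold ", object@threshold, ", top fraction ", object@topFrac,
      ")\n", sep = "")
})

setMethod("show", "AnalysisConfig", function(object) {
  cat("AnalysisConfig:\n")
  for (s in slotNames(object))
    cat("  ", s, " = ", format(slot(object, s)), "\n", sep = "")
})
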