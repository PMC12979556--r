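## CNV-similarity malignant-cell classifier, downstream of CNV inference:
## per-cell aberration score, top-5% reference set, Pearson similarity to
## the mean reference profile, and the 0.20-threshold / top-20% call.

#' Per-cell CNV aberration score
#'
#' `score(cell) = mean over bins of (value - 1)^2`: the mean squared
#' deviation of the inferred copy-number profile from the neutral level 1.
#' Using the mean (not the sum) keeps scores comparable across matrices with
#' different bin counts. The score is nonnegative and zero exactly when the
#' profile is identically 1.
#'
#' @param cnv a [CNVMatrix-class].
#' @return named numeric vector of scores, one per cell
#' @examples
#' v <- rbind(flat = c(1, 1, 1, 1), gained = c(1.5, 1.5, 1, 1))
#' colnames(v) <- paste0("bin", 1:4)
#' cnvScore(new("CNVMatrix", values = v, role = rep("observation", 2)))
#' # flat 0, gained 0.125
#' @export
cnvScore <- function(cnv) {
  stopifnot(is(cnv, "CNVMatrix"))
  rowMeans((cnv@values - 1)^2)
}

#' Select the reference-malignant cell set
#'
#' The `ceiling(topFrac * n)` observation cells with the highest CNV
#' aberration scores, ties at the cut broken deterministically by cell id
#' order. Reference-role cells are never candidates. When every candidate
#' has the same score the selection is flagged with a warning (the cut is
#' arbitrary up to id order).
#'
#' @param scores named numeric vector from [cnvScore()].
#' @param role per-cell roles (parallel to `scores`), or NULL to treat all
#'   cells as observations.
#' @param topFrac fraction in (0,1), default 0.05.
#' @return character vector of selected cell ids
#' @export
selectReferenceMalignant <- function(scores, role = NULL, topFrac = 0.05) {
  stopIfNot(topFrac > 0 && topFrac < 1, "topFrac must lie in (0, 1)")
  stopIfNot(!is.null(names(scores)), "scores must be named by cell id")
  if (is.null(role)) role <- rep("observation", length(scores))
  obs <- scores[role == "observation"]
  n <- length(obs)
  stopIfNot(n >= 1, "at least one observation cell is required")
  m <- max(1L, as.integer(ceiling(topFrac * n)))
  if (length(unique(obs)) == 1L)
    warning("all observation scores are tied; reference-malignant set is arbitrary up to cell id order")
  ord <- order(-obs, names(obs))
  names(obs)[ord[seq_len(m)]]
}

#' Similarity of every cell to the malignant reference profile
#'
#' Pearson correlation between each cell's CNV profile and the element-wise
#' mean profile of the reference-malignant set. Cells inside the reference
#' set are scored like any other (their similarity is high by construction).
#' Zero-variance (flat) profiles — of a cell, or of the mean reference
#' profile itself — have undefined correlation and are reported as 0 with
#' the degenerate flag.
#'
#' @param cnv a [CNVMatrix-class].
#' @param referenceMalignant nonempty character vector of cell ids in `cnv`.
#' @return data.frame with `cell_id`, `similarity`, `degenerate`
#' @export
similarityToMalignant <- function(cnv, referenceMalignant) {
  stopifnot(is(cnv, "CNVMatrix"))
  stopIfNot(length(referenceMalignant) >= 1,
            "the reference-malignant set must be nonempty")
  v <- cnv@values
  if (!all(referenceMalignant %in% rownames(v)))
    stop("reference-malignant ids must be cells of the matrix", call. = FALSE)
  refProfile <- colMeans(v[referenceMalignant, , drop = FALSE])
  refSd <- stats::sd(refProfile)
  cellSd <- apply(v, 1, stats::sd)
  degenerate <- cellSd == 0 | refSd == 0
  sim <- numeric(nrow(v))
  if (refSd > 0 && any(!degenerate))
    sim[!degenerate] <- as.numeric(
      stats::cor(t(v[!degenerate, , drop = FALSE]), refProfile))
  data.frame(cell_id = rownames(v), similarity = sim,
             degenerate = degenerate, row.names = NULL)
}

#' Classify cells as malignant from their similarity scores
#'
#' Default policy `both`: a cell is malignant iff its similarity strictly
#' exceeds `threshold` AND its similarity rank falls within the top
#' `ceiling(topFrac * n)` of all scored cells (ties broken by cell id).
#' The `threshold_only` and `top_frac_only` policies expose each rule alone
#' for sensitivity analysis. Reference-role cells participate in the ranking
#' but are never called malignant.
#'
#' @param similarity data.frame from [similarityToMalignant()], or a named
#'   numeric vector of similarities.
#' @param role per-cell roles, or NULL for all-observation.
#' @param threshold similarity threshold in (-1, 1), default 0.20.
#' @param topFrac top fraction in (0, 1), default 0.20.
#' @param policy `"both"`, `"threshold_only"` or `"top_frac_only"`.
#' @param scores optional named score vector (stored in the result).
#' @param referenceMalignant optional id set (stored in the result).
#' @return a [MalignancyCall-class]
#' @export
classifyMalignant <- function(similarity, role = NULL, threshold = 0.20,
                              topFrac = 0.20,
                              policy = c("both", "threshold_only",
                                         "top_frac_only"),
                              scores = NULL, referenceMalignant = character()) {
  policy <- match.arg(policy)
  stopIfNot(threshold > -1 && threshold < 1, "threshold must lie in (-1, 1)")
  stopIfNot(topFrac > 0 && topFrac < 1, "topFrac must lie in (0, 1)")
  if (is.data.frame(similarity)) {
    ids <- as.character(similarity$cell_id)
    sim <- stats::setNames(similarity$similarity, ids)
    degenerate <- similarity$degenerate
  } else {
    stopIfNot(!is.null(names(similarity)), "similarities must be named by cell id")
    ids <- names(similarity)
    sim <- similarity
    degenerate <- rep(FALSE, length(sim))
  }
  n <- length(sim)
  if (is.null(role)) role <- rep("observation", n)
  stopIfNot(length(role) == n, "one role per cell is required")

  m <- as.integer(ceiling(topFrac * n))
  inTop <- logical(n)
  inTop[order(-sim, ids)[seq_len(m)]] <- TRUE
  aboveThr <- sim > threshold
  call <- switch(policy,
                 both = aboveThr & inTop,
                 threshold_only = aboveThr,
                 top_frac_only = inTop)
  call <- call & role == "observation"

  if (is.null(scores)) scores <- rep(NA_real_, n)
  else scores <- unname(scores[ids])
  new("MalignancyCall",
      cellIds = ids, score = scores, similarity = unname(sim),
      isReferenceMalignant = ids %in% referenceMalignant,
      isMalignant = unname(call), degenerate = degenerate, role = role,
      policy = policy, threshold = threshold, topFrac = topFrac)
}

#' Full malignant-cell classification pipeline
#'
#' Runs the classifier end to end on a [CNVMatrix-class]: per-cell CNV
#' aberration scores, selection of the top-`cnvRefTopFrac` (5%) of
#' observation cells as the malignant reference, Pearson similarity of every
#' cell to the mean reference profile, and the final call (similarity above
#' `cnvSimilarityThreshold` and within the top `cnvCallTopFrac` of all
#' scored cells; observation cells only). Deterministic given the matrix and
#' configuration.
#'
#' @param cnv a [CNVMatrix-class].
#' @param config an [AnalysisConfig-class] supplying the three constants.
#' @param policy call policy, see [classifyMalignant()].
#' @return a [MalignancyCall-class]
#' @examples
#' sim <- generateCNVProfiles(nRef = 20, nMal = 10, nBins = 40, seed = 7)
#' call <- callMalignancy(sim$cnv)
#' table(called = call@isMalignant,
#'       truth = call@cellIds %in% sim$truth$malignantIds)
#' @export
callMalignancy <- function(cnv, config = analysisConfig(), policy = "both") {
  stopifnot(is(cnv, "CNVMatrix"))
  t0 <- as.numeric(proc.time()[["elapsed"]])
  scores <- cnvScore(cnv)
  refMal <- selectReferenceMalignant(scores, cnv@role,
                                     topFrac = config@cnvRefTopFrac)
  sim <- similarityToMalignant(cnv, refMal)
  out <- classifyMalignant(sim, role = cnv@role,
                           threshold = config@cnvSimilarityThreshold,
                           topFrac = config@cnvCallTopFrac, policy = policy,
                           scores = scores, referenceMalignant = refMal)
  logStage("callMalignancy", cells = length(scores),
           malignant = sum(out@isMalignant), t0 = t0)
  out
}
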