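## Per-spot single-sample gene-set scoring (rank-based, ssGSEA-style) and
## the correlation / rank-test utilities shared across analyses.

#' Build top-N marker gene sets
#'
#' Per cell type: keep genes whose adjusted significance is below
#' `sigThreshold`, sort by descending log fold change (ties broken
#' alphabetically by gene name, deterministically), and take the top
#' `topN`. Types with no significant gene are omitted with a warning.
#'
#' @param markerTable data.frame with columns `gene`, `type`, `logFC`,
#'   `p_adj`.
#' @param topN genes per set (default 25).
#' @param sigThreshold adjusted-significance cutoff (default 0.05).
#' @return named list of character vectors (one set per type), with
#'   attribute `provenance`
#' @export
topMarkers <- function(markerTable, topN = 25L, sigThreshold = 0.05) {
  need <- c("gene", "type", "logFC", "p_adj")
  if (!all(need %in% names(markerTable)))
    stop("markerTable must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  stopIfNot(topN >= 1, "topN must be >= 1")
  sig <- markerTable[markerTable$p_adj < sigThreshold, , drop = FALSE]
  types <- unique(markerTable$type)
  sets <- lapply(types, function(t) {
    tab <- sig[sig$type == t, , drop = FALSE]
    if (!nrow(tab)) return(NULL)
    tab <- tab[order(-tab$logFC, tab$gene), , drop = FALSE]
    utils::head(as.character(tab$gene), topN)
  })
  names(sets) <- types
  empty <- vapply(sets, is.null, logical(1))
  if (any(empty))
    warning("no significant markers for: ",
            paste(types[empty], collapse = ", "), "; set(s) omitted")
  sets <- sets[!empty]
  attr(sets, "provenance") <-
    sprintf("top %d significant markers by logFC (p_adj < %g)",
            topN, sigThreshold)
  sets
}

#' One-vs-rest rank-sum marker discovery
#'
#' A simple marker test for synthetic data: per cell type, each gene is
#' compared between that type's spots and all others with a Wilcoxon
#' rank-sum test; the log fold change is `log2` of the ratio of
#' pseudocounted means, and p-values are Benjamini-Hochberg adjusted within
#' each type.
#'
#' @param expr genes x units expression matrix.
#' @param group per-unit type labels.
#' @return data.frame with columns `gene`, `type`, `logFC`, `p_adj`
#'   (input for [topMarkers()])
#' @export
rankSumMarkers <- function(expr, group) {
  stopIfNot(ncol(expr) == length(group), "one group label per column is required")
  group <- as.character(group)
  out <- do.call(rbind, lapply(unique(group), function(t) {
    inT <- group == t
    p <- apply(expr, 1, function(g)
      if (length(unique(g)) == 1L) 1
      else stats::wilcox.test(g[inT], g[!inT], exact = FALSE)$p.value)
    lfc <- log2((rowMeans(expr[, inT, drop = FALSE]) + 1) /
                (rowMeans(expr[, !inT, drop = FALSE]) + 1))
    data.frame(gene = rownames(expr), type = t, logFC = unname(lfc),
               p_adj = stats::p.adjust(p, "BH"), row.names = NULL)
  }))
  out
}

#' Per-spot single-sample gene-set enrichment scores
#'
#' Rank-based single-sample enrichment in the ssGSEA spirit. Within each
#' spot, genes are ranked by expression (average ranks for ties; the walk
#' down the ranking breaks ties deterministically by gene name). With in-set
#' genes weighted by `rank^exponent`, the score is the running difference
#' between the weighted cumulative distribution of in-set genes and the
#' unweighted cumulative distribution of out-set genes, summed along the
#' ranking and divided by the number of measured genes. Two normalizations
#' make the score exactly centered: the in-set cumulative mass is divided by
#' its expectation under random gene-set placement (total rank-weight times
#' `|S|/N`) rather than by the realized in-set weight, and the analytic
#' expectation of the running difference (the all-gene weighted cumulative
#' distribution minus the uniform one) is subtracted. The score therefore
#' has exactly mean zero when expression is randomly permuted across genes,
#' and is maximal when the set's genes occupy the top `|S|` ranks. Scores
#' depend on the expression values only through their ranks, so any strictly
#' increasing transform of a spot's values (e.g. `log1p`, depth scaling)
#' leaves its scores unchanged.
#'
#' Genes of a set absent from the matrix are dropped (the effective gene
#' count is tracked); a set with no measured gene, or covering every
#' measured gene, is an error.
#'
#' @param expr genes x spots matrix of counts or normalized values.
#' @param sets named list of character vectors (e.g. from [topMarkers()]).
#' @param exponent rank-weighting exponent >= 0 (default 0.25; `0` gives
#'   unweighted cumulative distributions).
#' @return list with `scores` (spots x sets matrix), `effectiveGenes`
#'   (named integer, per-set overlap with measured genes), `exponent` and
#'   `method`
#' @export
scoreSpots <- function(expr, sets, exponent = 0.25) {
  stopIfNot(is.matrix(expr) && nrow(expr) >= 2,
            "expr must be a matrix with at least two genes")
  stopIfNot(!is.null(rownames(expr)), "expr must carry gene names")
  stopIfNot(is.list(sets) && length(sets) >= 1 && !is.null(names(sets)),
            "sets must be a nonempty named list")
  stopIfNot(exponent >= 0, "exponent must be >= 0")
  genes <- rownames(expr)
  nGenes <- length(genes)
  inSet <- lapply(names(sets), function(nm) {
    ov <- intersect(sets[[nm]], genes)
    if (!length(ov))
      stop("gene set '", nm, "' has no overlap with the measured genes",
           call. = FALSE)
    if (length(ov) == nGenes)
      stop("gene set '", nm, "' covers every measured gene; the score is undefined",
           call. = FALSE)
    genes %in% ov
  })
  names(inSet) <- names(sets)
  effective <- vapply(inSet, sum, integer(1))

  nSpots <- ncol(expr)
  scores <- matrix(NA_real_, nSpots, length(sets),
                   dimnames = list(colnames(expr), names(sets)))
  iN <- seq_len(nGenes) / nGenes
  for (s in seq_len(nSpots)) {
    x <- expr[, s]
    r <- rank(x, ties.method = "average")
    ord <- order(-x, genes)
    w <- r[ord]^exponent
    wTot <- sum(w)
    pall <- cumsum(w) / wTot
    for (j in seq_along(inSet)) {
      m <- inSet[[j]][ord]
      pin <- cumsum(w * m) / (wTot * effective[j] / nGenes)
      pout <- cumsum(!m) / (nGenes - effective[j])
      scores[s, j] <- sum(pin - pout - pall + iN) / nGenes
    }
  }
  list(scores = scores, effectiveGenes = effective, exponent = exponent,
       method = "ssgsea_rank")
}

#' Correlation between two score vectors
#'
#' Pearson or Spearman correlation with a two-sided p-value from the t
#' approximation, after listwise removal of non-finite pairs. Zero variance
#' in either vector leaves the correlation undefined (NA, flagged).
#'
#' @param scoreA,scoreB paired numeric vectors (>= 3 complete pairs).
#' @param method `"pearson"` or `"spearman"`.
#' @return list with `r`, `p`, `n` (complete pairs used), `method`,
#'   `degenerate`
#' @examples
#' correlateScores(c(1, 2, 3, 4), c(2, 1, 4, 3), "spearman")  # rho 0.6
#' @export
correlateScores <- function(scoreA, scoreB,
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopIfNot(length(scoreA) == length(scoreB), "vectors must be paired")
  ok <- is.finite(scoreA) & is.finite(scoreB)
  a <- scoreA[ok]; b <- scoreB[ok]
  n <- length(a)
  if (n < 3) stop("at least 3 complete pairs are required", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n, method = method,
                degenerate = TRUE))
  ct <- stats::cor.test(a, b, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = n, method = method,
       degenerate = FALSE)
}

#' Rank-based group comparison with optional BH correction
#'
#' Wilcoxon rank-sum (exactly two groups) or Kruskal-Wallis (two or more)
#' tests per feature. The Wilcoxon p-value uses the exact rank-sum null when
#' the combined sample size is at most 20 and there are no ties, and the
#' normal approximation with tie correction otherwise. With
#' `correction = "bh"` p-values are Benjamini-Hochberg adjusted across the
#' features of the call (the requested family).
#'
#' @param values numeric vector (one feature) or features x units matrix.
#' @param groups per-unit group labels (>= 2 groups, each nonempty).
#' @param test `"wilcoxon"` or `"kruskal"`.
#' @param correction `"none"` or `"bh"`.
#' @return data.frame with columns `feature`, `statistic`, `p`,
#'   `p_adjusted`
#' @examples
#' compareGroups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' # exact two-sided rank-sum p = 0.1
#' @export
compareGroups <- function(values, groups, test = c("wilcoxon", "kruskal"),
                          correction = c("none", "bh")) {
  test <- match.arg(test)
  correction <- match.arg(correction)
  if (is.null(dim(values)))
    values <- matrix(values, nrow = 1,
                     dimnames = list("feature1", names(values)))
  stopIfNot(ncol(values) == length(groups),
            "one group label per unit is required")
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("at least two groups are required", call. = FALSE)
  if (any(tabulate(groups) == 0)) stop("every group must be nonempty", call. = FALSE)
  if (test == "wilcoxon" && nlevels(groups) != 2)
    stop("the Wilcoxon rank-sum test requires exactly two groups", call. = FALSE)

  rows <- lapply(seq_len(nrow(values)), function(i) {
    v <- values[i, ]
    if (test == "wilcoxon") {
      x <- v[groups == levels(groups)[1]]
      y <- v[groups == levels(groups)[2]]
      useExact <- length(v) <= 20 && !anyDuplicated(v)
      ht <- stats::wilcox.test(x, y, exact = useExact)
      data.frame(feature = rownames(values)[i],
                 statistic = unname(ht$statistic), p = ht$p.value)
    } else {
      if (length(unique(v)) == 1L)
        data.frame(feature = rownames(values)[i], statistic = 0, p = 1)
      else {
        ht <- stats::kruskal.test(v, groups)
        data.frame(feature = rownames(values)[i],
                   statistic = unname(ht$statistic), p = ht$p.value)
      }
    }
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (correction == "bh") stats::p.adjust(out$p, "BH")
                    else out$p
  out
}
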