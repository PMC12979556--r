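#' Read a Visium tissue-positions table
#'
#' Parses both dialects of the 10x tissue-positions file: the header-less
#' legacy `tissue_positions_list.csv` and the headered `tissue_positions.csv`.
#' Either way the columns are barcode, in_tissue, array_row, array_col,
#' pxl_row_in_fullres, pxl_col_in_fullres. Pixel rows become `y` and pixel
#' columns `x`. The observation window is the bounding box of the retained
#' spot centers, expanded on each side by half the median nearest-neighbor
#' spacing, so that every spot owns a margin of roughly half a lattice cell.
#'
#' @param path path to the comma-separated positions file.
#' @param micronsPerPixel positive scalar, micrometers per full-resolution
#'   pixel for this sample.
#' @param keepAll keep spots with `in_tissue == 0` as well (default drops
#'   them).
#' @param sampleId sample identifier; defaults to the file's directory name.
#' @return a [SpotGrid-class]
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("AAA-1,1,0,0,100,200", "AAC-1,1,0,2,100,400",
#'              "AAG-1,1,1,1,273,300", "AAT-1,0,1,3,273,500"), f)
#' readTissuePositions(f, micronsPerPixel = 0.5)
#' @export
readTissuePositions <- function(path, micronsPerPixel, keepAll = FALSE,
                                sampleId = basename(dirname(normalizePath(path)))) {
  checkPositiveScalar(micronsPerPixel, "micronsPerPixel")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty tissue-positions file: ", path, call. = FALSE)
  hasHeader <- grepl("barcode", lines[[1]], ignore.case = TRUE)
  dataLines <- if (hasHeader) lines[-1] else lines
  firstRow <- if (hasHeader) 2L else 1L
  if (!length(dataLines)) stop("no spot rows in ", path, call. = FALSE)

  parts <- strsplit(dataLines, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L)) {
    off <- which(nf != 6L)[1]
    stop(sprintf("malformed tissue-positions row at line %d of '%s': expected 6 comma-separated fields, found %d",
                 off + firstRow - 1L, path, nf[off]), call. = FALSE)
  }
  tab <- do.call(rbind, parts)
  num <- suppressWarnings(apply(tab[, 2:6, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 5)
  if (any(!is.finite(num))) {
    off <- which(apply(num, 1, function(r) any(!is.finite(r))))[1]
    stop(sprintf("non-numeric coordinate at line %d of '%s'",
                 off + firstRow - 1L, path), call. = FALSE)
  }
  barcode <- trimws(tab[, 1])
  keep <- if (keepAll) rep(TRUE, nrow(num)) else num[, 1] != 0
  if (!any(keep))
    stop("zero in-tissue spots in '", path, "'", call. = FALSE)

  newSpotGrid(sampleId = sampleId,
              spotIds = barcode[keep],
              arrayCoords = cbind(row = as.integer(num[keep, 2]),
                                  col = as.integer(num[keep, 3])),
              pixelCoords = cbind(x = num[keep, 5], y = num[keep, 4]),
              micronsPerPixel = micronsPerPixel,
              inTissue = num[keep, 1] != 0)
}

# Shared SpotGrid construction: computes the padded bounding-box window.
newSpotGrid <- function(sampleId, spotIds, arrayCoords, pixelCoords,
                        micronsPerPixel, inTissue) {
  pad <- halfMedianNNSpacing(pixelCoords)
  w <- c(min(pixelCoords[, 1]) - pad, max(pixelCoords[, 1]) + pad,
         min(pixelCoords[, 2]) - pad, max(pixelCoords[, 2]) + pad)
  new("SpotGrid", sampleId = as.character(sampleId),
      spotIds = as.character(spotIds),
      arrayCoords = arrayCoords, pixelCoords = pixelCoords,
      micronsPerPixel = micronsPerPixel,
      inTissue = as.logical(inTissue), window = w)
}

# Half the median nearest-neighbor distance; 0 for a single spot.
halfMedianNNSpacing <- function(coords) {
  n <- nrow(coords)
  if (n < 2) return(0)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  stats::median(nn[is.finite(nn)]) / 2
}

#' Write a SpotGrid back to a tissue-positions CSV
#'
#' @param grid a [SpotGrid-class]
#' @param path output path
#' @param dialect `"headered"` (tissue_positions.csv) or `"legacy"`
#'   (header-less tissue_positions_list.csv)
#' @return invisibly, `path`
#' @export
writeTissuePositions <- function(grid, path,
                                 dialect = c("headered", "legacy")) {
  dialect <- match.arg(dialect)
  ac <- grid@arrayCoords; pc <- pixelCoords(grid)
  rows <- sprintf("%s,%d,%d,%d,%s,%s", spotIds(grid),
                  as.integer(inTissue(grid)), ac[, 1], ac[, 2],
                  format(pc[, 2], digits = 17, trim = TRUE, scientific = FALSE),
                  format(pc[, 1], digits = 17, trim = TRUE, scientific = FALSE))
  if (dialect == "headered")
    rows <- c("barcode,in_tissue,array_row,array_col,pxl_row_in_fullres,pxl_col_in_fullres",
              rows)
  writeLines(rows, path)
  invisible(path)
}

#' Read a spot x cell-type weight table
#'
#' Reads the deconvolution contract: a TSV or CSV whose first column is the
#' spot barcode and whose remaining columns are cell-type weights. Rows must
#' be nonnegative and sum to one; sums deviating by at most 1e-6 are silently
#' renormalized, larger deviations are rejected naming the worst row.
#'
#' @param path path to the table; the separator (tab or comma) is detected
#'   from the header line.
#' @return a [CellTypeWeights-class]
#' @export
readWeights <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("weight table needs a barcode column plus at least one cell type",
                          call. = FALSE)
  bc <- as.character(tab[[1]])
  if (anyDuplicated(bc))
    stop("duplicate spot barcodes in weight table: ",
         paste(unique(bc[duplicated(bc)])[1:min(3, sum(duplicated(bc)))],
               collapse = ", "), call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- bc
  cellTypeWeights(m)
}

#' Construct CellTypeWeights from a matrix
#'
#' Validates the deconvolution contract and renormalizes row sums within
#' `tolerance` of one.
#'
#' @param m numeric matrix, spots in rows (unique rownames), cell types in
#'   columns.
#' @param tolerance maximum absolute row-sum deviation that is renormalized
#'   rather than rejected (1e-6).
#' @return a [CellTypeWeights-class]
#' @export
cellTypeWeights <- function(m, tolerance = 1e-6) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("weights must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(m))) stop("weights must be finite", call. = FALSE)
  if (min(m) < 0) {
    bad <- which(apply(m, 1, min) < 0)[1]
    stop("negative weight in row '", rownames(m)[bad], "'", call. = FALSE)
  }
  rs <- rowSums(m)
  dev <- abs(rs - 1)
  if (any(dev > tolerance)) {
    worst <- which.max(dev)
    stop(sprintf("row sums must equal 1 within %g (worst: '%s', sum = %.9f)",
                 tolerance, rownames(m)[worst], rs[worst]), call. = FALSE)
  }
  m <- m / rs
  new("CellTypeWeights", m)
}

#' Write a weight matrix as TSV
#' @param weights a [CellTypeWeights-class]
#' @param path output path
#' @return invisibly, `path`
#' @export
writeWeights <- function(weights, path) {
  df <- data.frame(barcode = rownames(weights),
                   as.data.frame(weights@.Data, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read inferred CNV profiles
#'
#' Reads dense TSV matrices of inferred copy-number values centered at 1
#' (cells in rows, first column the cell id, genomic bins in columns) for the
#' observation cells and, optionally, the normal reference cells, into one
#' [CNVMatrix-class].
#'
#' @param observationsPath TSV of observation cells.
#' @param referencesPath optional TSV of reference cells (same bins).
#' @return a [CNVMatrix-class]
#' @export
readCNVMatrix <- function(observationsPath, referencesPath = NULL) {
  readOne <- function(p) {
    tab <- utils::read.table(p, header = TRUE, sep = "\t",
                             check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE]); storage.mode(m) <- "double"
    rownames(m) <- as.character(tab[[1]])
    m
  }
  obs <- readOne(observationsPath)
  if (is.null(referencesPath))
    return(new("CNVMatrix", values = obs,
               role = rep("observation", nrow(obs))))
  ref <- readOne(referencesPath)
  if (!identical(colnames(obs), colnames(ref)))
    stop("observation and reference matrices must share the same bins",
         call. = FALSE)
  new("CNVMatrix", values = rbind(obs, ref),
      role = c(rep("observation", nrow(obs)), rep("reference", nrow(ref))))
}

#' Write a CNVMatrix to observation/reference TSV files
#' @param cnv a [CNVMatrix-class]
#' @param observationsPath,referencesPath output TSV paths
#'   (`referencesPath` may be NULL when there are no reference cells)
#' @return invisibly, the paths written
#' @export
writeCNVMatrix <- function(cnv, observationsPath, referencesPath = NULL) {
  writeOne <- function(m, p) {
    df <- data.frame(cell_id = rownames(m),
                     as.data.frame(m, check.names = FALSE), check.names = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  obs <- cnv@values[cnv@role == "observation", , drop = FALSE]
  writeOne(obs, observationsPath)
  if (any(cnv@role == "reference")) {
    if (is.null(referencesPath))
      stop("referencesPath is required when reference cells are present",
           call. = FALSE)
    writeOne(cnv@values[cnv@role == "reference", , drop = FALSE],
             referencesPath)
  }
  invisible(c(observationsPath, referencesPath))
}

#' Read a genes x spots count matrix
#'
#' Either a MatrixMarket triplet file with side files of gene and barcode
#' names, or a dense TSV with genes in rows (first column gene id).
#'
#' @param path path to `.mtx` or `.tsv` file.
#' @param featuresPath,barcodesPath one-name-per-line side files; required
#'   for the MatrixMarket route, ignored for TSV.
#' @return a base matrix (genes x spots) with dimnames
#' @export
readCounts <- function(path, featuresPath = NULL, barcodesPath = NULL) {
  if (grepl("\\.mtx$", path)) {
    if (is.null(featuresPath) || is.null(barcodesPath))
      stop("featuresPath and barcodesPath are required for MatrixMarket input",
           call. = FALSE)
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(featuresPath, warn = FALSE)
    colnames(m) <- readLines(barcodesPath, warn = FALSE)
    return(m)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE]); storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  m
}

#' Write a count matrix as MatrixMarket triplet plus name files
#' @param counts genes x spots matrix
#' @param mtxPath,featuresPath,barcodesPath output paths
#' @return invisibly, the paths written
#' @export
writeCounts <- function(counts, mtxPath, featuresPath, barcodesPath) {
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "generalMatrix"), mtxPath)
  writeLines(rownames(counts), featuresPath)
  writeLines(colnames(counts), barcodesPath)
  invisible(c(mtxPath, featuresPath, barcodesPath))
}

#' Read gene sets in GMT format
#' @param path GMT file (set name, description, then genes, tab-separated)
#' @return named list of character vectors
#' @export
readGeneSets <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE))
    stop("reading GMT files requires the fgsea package", call. = FALSE)
  fgsea::gmtPathways(path)
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors
#' @param path output path
#' @return invisibly, `path`
#' @export
writeGeneSets <- function(sets, path) {
  stopIfNot(is.list(sets) && !is.null(names(sets)), "sets must be a named list")
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, "nichescape", sets[[nm]]), collapse = "\t"), character(1)),
    path)
  invisible(path)
}

## ---- result serialization --------------------------------------------

provenanceBlock <- function(config, seed) {
  list(package = "nichescape",
       version = as.character(utils::packageVersion("nichescape")),
       seed = if (is.na(seed)) NULL else as.integer(seed),
       config = if (is.null(config)) NULL else configAsList(config))
}

writeJSONDeterministic <- function(x, path) {
  # I(17) significant digits: doubles round-trip exactly through the text
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

naToNull <- function(v) if (all(is.na(v))) NULL else v

#' @describeIn writeResult CrossKResult: JSON with all curves, envelopes,
#'   effect sizes and provenance; TSV with one row per grid distance.
#' @export
setMethod("writeResult", "CrossKResult",
  function(result, path, format = c("json", "tsv"), config = NULL,
           seed = NA_integer_) {
    format <- match.arg(format)
    if (format == "tsv") {
      df <- as.data.frame(result)
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      return(invisible(path))
    }
    x <- list(
      type = "CrossKResult",
      sample_id = result@sampleId,
      type_i = result@typeI, type_j = result@typeJ,
      n_i = result@nI, n_j = result@nJ,
      edge_correction = result@edgeCorrection,
      r_grid = result@rGrid, K = result@K, L = result@L, D = result@D,
      env_lo = naToNull(result@envLo), env_hi = naToNull(result@envHi),
      n_sim = result@nSim,
      aggregation_index = result@aggregationIndex,
      cohens_d = result@cohensD,
      p_global = result@pGlobal,
      envelope_seed = if (is.na(result@seed)) NULL else result@seed,
      provenance = provenanceBlock(config, seed))
    writeJSONDeterministic(x, path)
  })

#' Rebuild a CrossKResult from its JSON serialization
#' @param path JSON file written by [writeResult()]
#' @return a [CrossKResult-class]
#' @export
readCrossKResult <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  nr <- length(x$r_grid)
  asNum <- function(v) if (is.null(v)) rep(NA_real_, nr) else as.numeric(v)
  new("CrossKResult",
      sampleId = x$sample_id, typeI = x$type_i, typeJ = x$type_j,
      rGrid = as.numeric(x$r_grid), K = as.numeric(x$K),
      L = as.numeric(x$L), D = as.numeric(x$D),
      envLo = asNum(x$env_lo), envHi = asNum(x$env_hi),
      nSim = as.integer(x$n_sim), nI = as.integer(x$n_i),
      nJ = as.integer(x$n_j),
      aggregationIndex = as.numeric(x$aggregation_index),
      cohensD = if (is.null(x$cohens_d)) NA_real_ else as.numeric(x$cohens_d),
      pGlobal = if (is.null(x$p_global)) NA_real_ else as.numeric(x$p_global),
      edgeCorrection = x$edge_correction,
      seed = if (is.null(x$envelope_seed)) NA_integer_ else as.integer(x$envelope_seed))
}

#' @export
#' @method as.data.frame CrossKResult
as.data.frame.CrossKResult <- function(x, ...) {
  data.frame(r = x@rGrid, K = x@K, L = x@L, D = x@D,
             env_lo = x@envLo, env_hi = x@envHi)
}
setMethod("as.data.frame", "CrossKResult", as.data.frame.CrossKResult)

#' @describeIn writeResult NicheModel: JSON with labels, centroids,
#'   diagnostics and votes; TSV with barcode and niche columns.
#' @export
setMethod("writeResult", "NicheModel",
  function(result, path, format = c("json", "tsv"), config = NULL,
           seed = NA_integer_) {
    format <- match.arg(format)
    if (format == "tsv") {
      df <- data.frame(barcode = names(result@labels),
                       niche = unname(result@labels))
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      return(invisible(path))
    }
    x <- list(
      type = "NicheModel",
      k = result@k,
      recommended_k = if (is.na(result@recommendedK)) NULL else result@recommendedK,
      votes = if (length(result@votes)) as.list(result@votes) else NULL,
      barcodes = names(result@labels),
      labels = unname(result@labels),
      cell_types = colnames(result@centroids),
      centroids = apply(result@centroids, 1, as.numeric, simplify = FALSE),
      diagnostics = if (nrow(result@diagnostics)) result@diagnostics else NULL,
      model_seed = result@seed,
      provenance = provenanceBlock(config, seed))
    writeJSONDeterministic(x, path)
  })

#' @describeIn writeResult MalignancyCall: JSON with the per-cell table and
#'   call parameters; TSV with one row per cell.
#' @export
setMethod("writeResult", "MalignancyCall",
  function(result, path, format = c("json", "tsv"), config = NULL,
           seed = NA_integer_) {
    format <- match.arg(format)
    df <- as.data.frame(result)
    if (format == "tsv") {
      utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
      return(invisible(path))
    }
    x <- list(type = "MalignancyCall",
              policy = result@policy,
              similarity_threshold = result@threshold,
              call_top_frac = result@topFrac,
              n_cells = length(result@cellIds),
              n_malignant = sum(result@isMalignant),
              cells = df,
              provenance = provenanceBlock(config, seed))
    writeJSONDeterministic(x, path)
  })

#' @export
#' @method as.data.frame MalignancyCall
as.data.frame.MalignancyCall <- function(x, ...) {
  data.frame(cell_id = x@cellIds, role = x@role, cnv_score = x@score,
             similarity = x@similarity,
             is_reference_malignant = x@isReferenceMalignant,
             is_malignant = x@isMalignant, degenerate = x@degenerate)
}
setMethod("as.data.frame", "MalignancyCall", as.data.frame.MalignancyCall)

#' @describeIn writeResult data.frame: TSV table, or JSON records plus
#'   provenance.
#' @export
setMethod("writeResult", "data.frame",
  function(result, path, format = c("json", "tsv"), config = NULL,
           seed = NA_integer_) {
    format <- match.arg(format)
    if (format == "tsv") {
      utils::write.table(result, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      return(invisible(path))
    }
    writeJSONDeterministic(list(type = "table", rows = result,
                                provenance = provenanceBlock(config, seed)),
                           path)
  })

#' @describeIn writeResult list: JSON object plus provenance (TSV is not
#'   supported for free-form lists).
#' @export
setMethod("writeResult", "list",
  function(result, path, format = c("json", "tsv"), config = NULL,
           seed = NA_integer_) {
    format <- match.arg(format)
    if (format == "tsv")
      stop("TSV serialization is not defined for free-form lists", call. = FALSE)
    result$provenance <- provenanceBlock(config, seed)
    writeJSONDeterministic(result, path)
  })
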