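## Accessor generics. Slots are never reached into from user code.

#' Spot barcodes
#' @param x a [SpotGrid-class], [CellTypeWeights-class] or
#'   [PointPattern-class]
#' @return character vector of barcodes
#' @export
setGeneric("spotIds", function(x) standardGeneric("spotIds"))

#' @rdname spotIds
#' @export
setMethod("spotIds", "SpotGrid", function(x) x@spotIds)

#' @rdname spotIds
#' @export
setMethod("spotIds", "CellTypeWeights", function(x) rownames(x))

#' @rdname spotIds
#' @export
setMethod("spotIds", "PointPattern", function(x) x@spotIds)

#' Number of spots / points
#' @param x a [SpotGrid-class] or [PointPattern-class]
#' @return integer count
#' @export
setGeneric("nSpots", function(x) standardGeneric("nSpots"))

#' @rdname nSpots
#' @export
setMethod("nSpots", "SpotGrid", function(x) length(x@spotIds))

#' @rdname nSpots
#' @export
setMethod("nSpots", "PointPattern", function(x) nrow(x@coords))

#' Spot center coordinates in full-resolution pixels
#' @param x a [SpotGrid-class]
#' @return numeric matrix with columns `x`, `y`
#' @export
setGeneric("pixelCoords", function(x) standardGeneric("pixelCoords"))

#' @rdname pixelCoords
#' @export
setMethod("pixelCoords", "SpotGrid", function(x) x@pixelCoords)

#' Coordinates in micrometers
#'
#' For a [SpotGrid-class] this is `pixelCoords(x) * micronsPerPixel(x)`; for a
#' [PointPattern-class] the stored coordinates (already in micrometers).
#' @param x a [SpotGrid-class] or [PointPattern-class]
#' @return numeric matrix with columns `x`, `y`, in micrometers
#' @export
setGeneric("micronCoords", function(x) standardGeneric("micronCoords"))

#' @rdname micronCoords
#' @export
setMethod("micronCoords", "SpotGrid",
          function(x) x@pixelCoords * x@micronsPerPixel)

#' @rdname micronCoords
#' @export
setMethod("micronCoords", "PointPattern", function(x) x@coords)

#' Pixel-to-micron scale of a sample
#' @param x a [SpotGrid-class]
#' @return positive scalar, micrometers per full-resolution pixel
#' @export
setGeneric("micronsPerPixel", function(x) standardGeneric("micronsPerPixel"))

#' @rdname micronsPerPixel
#' @export
setMethod("micronsPerPixel", "SpotGrid", function(x) x@micronsPerPixel)

#' Observation window
#'
#' The axis-aligned rectangle `c(xmin, xmax, ymin, ymax)` that all spatial
#' statistics condition on.
#' @param x a [SpotGrid-class] or [PointPattern-class]
#' @param units `"um"` (default) or, for grids, `"px"`
#' @return numeric length-4 vector with attribute `area`
#' @export
setGeneric("spotWindow", function(x, units = "um") standardGeneric("spotWindow"))

.windowWithArea <- function(w) {
  structure(w, names = c("xmin", "xmax", "ymin", "ymax"),
            area = (w[[2]] - w[[1]]) * (w[[4]] - w[[3]]))
}

#' @rdname spotWindow
#' @export
setMethod("spotWindow", "SpotGrid", function(x, units = "um") {
  units <- match.arg(units, c("um", "px"))
  w <- if (units == "um") x@window * x@micronsPerPixel else x@window
  .windowWithArea(w)
})

#' @rdname spotWindow
#' @export
setMethod("spotWindow", "PointPattern", function(x, units = "um") {
  .windowWithArea(x@window)
})

#' Whether each spot overlaps tissue
#' @param x a [SpotGrid-class]
#' @return logical vector
#' @export
setGeneric("inTissue", function(x) standardGeneric("inTissue"))

#' @rdname inTissue
#' @export
setMethod("inTissue", "SpotGrid", function(x) x@inTissue)

#' Cell-type names of a weight matrix
#' @param x a [CellTypeWeights-class]
#' @return character vector
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname cellTypes
#' @export
setMethod("cellTypes", "CellTypeWeights", function(x) colnames(x))

#' Per-spot niche labels
#' @param x a [NicheModel-class]
#' @return integer vector in 1..k named by barcode
#' @export
setGeneric("nicheLabels", function(x) standardGeneric("nicheLabels"))

#' @rdname nicheLabels
#' @export
setMethod("nicheLabels", "NicheModel", function(x) x@labels)

#' Niche centroid compositions
#' @param x a [NicheModel-class]
#' @return k x n_types matrix of mean compositions
#' @export
setGeneric("nicheCentroids", function(x) standardGeneric("nicheCentroids"))

#' @rdname nicheCentroids
#' @export
setMethod("nicheCentroids", "NicheModel", function(x) x@centroids)

#' Cluster-number diagnostics
#' @param x a [NicheModel-class]
#' @return data.frame with columns `k`, `wss`, `ch`, `gap`, `gap_se`,
#'   `skipped`
#' @export
setGeneric("kDiagnostics", function(x) standardGeneric("kDiagnostics"))

#' @rdname kDiagnostics
#' @export
setMethod("kDiagnostics", "NicheModel", function(x) x@diagnostics)

#' Recommended number of niches and per-criterion votes
#' @param x a [NicheModel-class]
#' @return `recommendedK`: integer; `kVotes`: named integer vector
#'   (`ch`, `gap`, `elbow`)
#' @export
setGeneric("recommendedK", function(x) standardGeneric("recommendedK"))

#' @rdname recommendedK
#' @export
setMethod("recommendedK", "NicheModel", function(x) x@recommendedK)

#' @rdname recommendedK
#' @export
setGeneric("kVotes", function(x) standardGeneric("kVotes"))

#' @rdname recommendedK
#' @export
setMethod("kVotes", "NicheModel", function(x) x@votes)

#' Serialize a result to JSON or TSV
#'
#' Lossless, deterministic serialization: the same object and seed always
#' produce identical bytes. JSON output embeds a provenance block (package
#' version, configuration snapshot, seed) but no timestamps.
#'
#' @param result the object to write
#' @param path output file path
#' @param format `"json"` or `"tsv"`
#' @param config optional [AnalysisConfig-class] snapshot to embed
#' @param seed optional integer seed to record
#' @return invisibly, the path written
#' @export
setGeneric("writeResult",
           function(result, path, format = c("json", "tsv"),
                    config = NULL, seed = NA_integer_)
             standardGeneric("writeResult"))

#' Turn a result object into a tidy data.frame
#' @param x a package result object
#' @param ... unused
#' @return data.frame
#' @name as.data.frame-methods
NULL
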