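#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-`
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   `colData<-` assayNames
NULL

# ---------------------------------------------------------------------------
# SpotExperiment
# ---------------------------------------------------------------------------

#' Container for one hexagonal-lattice spatial transcriptomics section
#'
#' `SpotExperiment` extends [SummarizedExperiment::SummarizedExperiment] with
#' the spot geometry of a Visium-style capture area: every spot (column)
#' carries hex array coordinates (`array_row`, `array_col`, sharing parity as
#' in the Space Ranger convention), full-resolution pixel coordinates
#' (`pixel_x`, `pixel_y`; origin top-left, y increasing downward), an
#' `in_tissue` flag, and optionally a `cluster` label. The `counts` assay
#' holds non-negative integer UMI-like counts, genes in rows and spots in
#' columns.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#'
#' @export
setClass("SpotExperiment", contains = "SummarizedExperiment")

.validSpotExperiment <- function(object) {
    msg <- NULL
    cd <- colData(object)
    need <- c("array_row", "array_col", "pixel_x", "pixel_y", "in_tissue")
    missing <- setdiff(need, colnames(cd))
    if (length(missing))
        msg <- c(msg, paste0("colData lacks column(s): ",
                             paste(missing, collapse = ", ")))
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "spot ids (colnames) must be present and unique")
    if (is.null(msg)) {
        par <- (cd$array_row + cd$array_col) %% 2L
        if (any(par != 0L))
            msg <- c(msg, "array_row + array_col must be even for every spot")
        if (!all(is.finite(cd$pixel_x)) || !all(is.finite(cd$pixel_y)))
            msg <- c(msg, "pixel coordinates must be finite")
    }
    if (is.null(msg)) TRUE else msg
}
setValidity("SpotExperiment", .validSpotExperiment)

#' Construct a SpotExperiment
#'
#' @param counts gene x spot matrix (dense or sparse) of non-negative
#'   integer counts.
#' @param spotData data.frame or DataFrame with one row per spot and the
#'   columns `array_row`, `array_col`, `pixel_x`, `pixel_y`, `in_tissue`,
#'   optionally `cluster` and `section`. Row names (or a `spot_id` column)
#'   give the barcodes.
#' @param metadata optional list stored in the object metadata.
#' @return A `SpotExperiment`.
#' @export
SpotExperiment <- function(counts, spotData, metadata = list()) {
    spotData <- as(spotData, "DataFrame")
    if ("spot_id" %in% colnames(spotData)) {
        rownames(spotData) <- spotData$spot_id
        spotData$spot_id <- NULL
    }
    if (is.null(colnames(counts)))
        colnames(counts) <- rownames(spotData)
    stopifnot(identical(colnames(counts), rownames(spotData)))
    se <- SummarizedExperiment(assays = list(counts = counts),
                               colData = spotData, metadata = metadata)
    new("SpotExperiment", se)
}

#' @describeIn SpotExperiment hex array coordinates (spots x 2 matrix).
#' @param x a `SpotExperiment`.
#' @export
arrayCoords <- function(x) {
    cd <- colData(x)
    cbind(array_row = cd$array_row, array_col = cd$array_col)
}

#' @describeIn SpotExperiment pixel coordinates (spots x 2 matrix).
#' @export
pixelCoords <- function(x) {
    cd <- colData(x)
    cbind(pixel_x = cd$pixel_x, pixel_y = cd$pixel_y)
}

#' @describeIn SpotExperiment logical in-tissue flag per spot.
#' @export
inTissue <- function(x) colData(x)$in_tissue

#' @describeIn SpotExperiment cluster labels (character, or NULL if absent).
#' @export
spotClusters <- function(x) {
    cd <- colData(x)
    if ("cluster" %in% colnames(cd)) as.character(cd$cluster) else NULL
}

#' @describeIn SpotExperiment replace cluster labels.
#' @param value character vector of cluster labels, one per spot.
#' @export
`spotClusters<-` <- function(x, value) {
    stopifnot(length(value) == ncol(x))
    colData(x)$cluster <- as.character(value)
    x
}

#' @describeIn SpotExperiment centre-to-centre spot pitch in pixels,
#'   estimated from the lattice geometry.
#' @export
spotPitch <- function(x) {
    cd <- colData(x)
    # adjacent spots in one row differ by 2 in array_col
    i <- order(cd$array_row, cd$array_col)
    dr <- diff(cd$array_row[i]); dc <- diff(cd$array_col[i])
    dx <- diff(cd$pixel_x[i])
    j <- which(dr == 0L & dc == 2L)
    if (!length(j)) stop("cannot estimate pitch: no row-adjacent spot pair")
    stats::median(abs(dx[j]))
}

setMethod("show", "SpotExperiment", function(object) {
    callNextMethod()
    cl <- spotClusters(object)
    cat("spots in tissue:", sum(inTissue(object)), "/", ncol(object), "\n")
    if (!is.null(cl))
        cat("clusters:", paste(sort(unique(cl)), collapse = " "), "\n")
})

# ---------------------------------------------------------------------------
# SignatureSet
# ---------------------------------------------------------------------------

#' A named collection of TME signature gene sets
#'
#' Each signature has a gene list, a category — `"tumor-feature"` (states of
#' the tumor cells themselves, e.g. well-differentiated, proliferative,
#' invasive) or `"microenvironment-feature"` (immune and stromal context,
#' e.g. B cell, T cell, fibroblast-CAF, macrophage) — and a class tag, the
#' feature label that spot classification assigns when that signature wins.
#'
#' @slot signatures named list of character gene vectors; names unique,
#'   lists non-empty.
#' @slot category named character, `"tumor-feature"` or
#'   `"microenvironment-feature"` per signature.
#' @slot classTag named character, the feature label per signature.
#' @export
setClass("SignatureSet", slots = c(signatures = "list",
                                   category = "character",
                                   classTag = "character"))

setValidity("SignatureSet", function(object) {
    msg <- NULL
    sg <- object@signatures
    if (is.null(names(sg)) || anyDuplicated(names(sg)))
        msg <- c(msg, "signature names must be present and unique")
    if (any(!vapply(sg, length, 1L)))
        msg <- c(msg, "every signature must have at least one gene")
    for (sl in c("category", "classTag")) {
        v <- slot(object, sl)
        if (!identical(names(v), names(sg)))
            msg <- c(msg, paste0(sl, " must be named like the signatures"))
    }
    ok <- object@category %in% c("tumor-feature", "microenvironment-feature")
    if (length(object@category) && !all(ok))
        msg <- c(msg, "category must be tumor-feature or microenvironment-feature")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SignatureSet
#'
#' @param signatures named list of character gene vectors.
#' @param category character vector (recycled if length 1): per-signature
#'   category.
#' @param classTag character vector of feature labels; defaults to the
#'   signature names.
#' @return A `SignatureSet`.
#' @export
SignatureSet <- function(signatures, category, classTag = names(signatures)) {
    category <- rep_len(category, length(signatures))
    names(category) <- names(signatures)
    classTag <- rep_len(classTag, length(signatures))
    names(classTag) <- names(signatures)
    new("SignatureSet", signatures = lapply(signatures, as.character),
        category = category, classTag = classTag)
}

#' @describeIn SignatureSet signature names.
#' @param x a `SignatureSet`.
#' @export
signatureNames <- function(x) names(x@signatures)

#' @describeIn SignatureSet gene list of one signature.
#' @param name signature name.
#' @export
signatureGenes <- function(x, name) {
    if (!name %in% names(x@signatures))
        stop("unknown signature: ", name)
    x@signatures[[name]]
}

#' @describeIn SignatureSet per-signature category, named character.
#' @export
signatureCategory <- function(x) x@category

#' @describeIn SignatureSet per-signature feature label, named character.
#' @export
signatureClass <- function(x) x@classTag

setMethod("show", "SignatureSet", function(object) {
    cat("SignatureSet with", length(object@signatures), "signatures\n")
    n <- vapply(object@signatures, length, 1L)
    for (nm in names(object@signatures))
        cat(sprintf("  %-24s %-26s %3d genes  [%s]\n", nm,
                    paste0("(", object@classTag[[nm]], ")"), n[[nm]],
                    object@category[[nm]]))
})

setMethod("length", "SignatureSet", function(x) length(x@signatures))

# ---------------------------------------------------------------------------
# ScoreTable
# ---------------------------------------------------------------------------

#' Per-spot, per-signature enrichment scores
#'
#' Produced by [pageScores()]. Holds the spot x signature score matrix, a
#' per-spot degeneracy flag (spots whose fold-change spread is zero score 0
#' rather than propagating NaN), the number of signature genes retained
#' after intersecting with the count matrix, and the normalisation used, so
#' a score table is self-describing.
#'
#' @slot scores numeric matrix, spots x signatures.
#' @slot degenerate logical per spot.
#' @slot nGenes named integer, genes per signature after intersection.
#' @slot normalization character scalar description.
#' @export
setClass("ScoreTable", slots = c(scores = "matrix", degenerate = "logical",
                                 nGenes = "integer",
                                 normalization = "character"))

setValidity("ScoreTable", function(object) {
    msg <- NULL
    if (!all(is.finite(object@scores)))
        msg <- c(msg, "scores must be finite (degenerate spots carry a flag)")
    if (length(object@degenerate) != nrow(object@scores))
        msg <- c(msg, "one degeneracy flag per spot required")
    if (!identical(names(object@nGenes), colnames(object@scores)))
        msg <- c(msg, "nGenes must be named by signature")
    if (is.null(msg)) TRUE else msg
})

#' @describeIn ScoreTable the spot x signature score matrix.
#' @param x a `ScoreTable`.
#' @export
scoreMatrix <- function(x) x@scores

#' @describeIn ScoreTable logical flag per spot: TRUE where the spot was
#'   degenerate (zero fold-change spread) and scored 0 by convention.
#' @export
degenerateSpots <- function(x) x@degenerate

setMethod("show", "ScoreTable", function(object) {
    cat("ScoreTable:", nrow(object@scores), "spots x",
        ncol(object@scores), "signatures\n")
    cat("normalization:", object@normalization, "\n")
    cat("degenerate spots:", sum(object@degenerate), "\n")
})

setMethod("dim", "ScoreTable", function(x) dim(x@scores))

# ---------------------------------------------------------------------------
# TrajectoryPath
# ---------------------------------------------------------------------------

#' A spatial trajectory through ordered cluster centroids
#'
#' The polyline connecting the pixel-space centroids of a user-ordered
#' cluster sequence, with cumulative arc length normalised to t in [0, 1].
#'
#' @slot clusterIds ordered cluster labels.
#' @slot vertices numeric matrix (clusters x 2) of centroid pixel
#'   coordinates.
#' @slot tVertex normalised cumulative arc length at each vertex.
#' @slot totalLength polyline length in pixels.
#' @export
setClass("TrajectoryPath", slots = c(clusterIds = "character",
                                     vertices = "matrix",
                                     tVertex = "numeric",
                                     totalLength = "numeric"))

setValidity("TrajectoryPath", function(object) {
    msg <- NULL
    if (length(object@clusterIds) < 2L)
        msg <- c(msg, "a trajectory needs at least 2 clusters")
    if (nrow(object@vertices) != length(object@clusterIds))
        msg <- c(msg, "one vertex per cluster required")
    if (any(diff(object@tVertex) <= 0))
        msg <- c(msg, "t must be strictly increasing vertex to vertex")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "TrajectoryPath", function(object) {
    cat("TrajectoryPath:", paste(object@clusterIds, collapse = " -> "), "\n")
    cat("total length:", round(object@totalLength, 2), "px;  vertex t:",
        paste(round(object@tVertex, 3), collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# SimilarityTransform
# ---------------------------------------------------------------------------

#' A similarity (scale-rotation-translation) mapping between two rasters
#'
#' Forward convention, applied about `center`: p' = s * R(theta) * (p -
#' center) + center + t, with R the counter-clockwise rotation matrix in
#' (x, y) coordinates. Direction records which raster maps onto which.
#'
#' @slot scale positive scalar.
#' @slot thetaDeg rotation in degrees.
#' @slot tx,ty translation in pixels.
#' @slot center rotation/scale centre (x, y) in pixels.
#' @slot direction free-text provenance, default "AtoB".
#' @export
setClass("SimilarityTransform",
         slots = c(scale = "numeric", thetaDeg = "numeric",
                   tx = "numeric", ty = "numeric", center = "numeric",
                   direction = "character"))

setValidity("SimilarityTransform", function(object) {
    msg <- NULL
    v <- c(object@scale, object@thetaDeg, object@tx, object@ty, object@center)
    if (!all(is.finite(v))) msg <- c(msg, "transform parameters must be finite")
    if (object@scale <= 0) msg <- c(msg, "scale must be > 0")
    if (length(object@center) != 2L) msg <- c(msg, "center must be length 2")
    if (is.null(msg)) TRUE else msg
})

#' Construct a SimilarityTransform
#'
#' @param scale scale factor (> 0).
#' @param thetaDeg rotation in degrees (counter-clockwise in x/y).
#' @param tx,ty translation in pixels.
#' @param center centre of rotation and scaling, default the origin.
#' @param direction provenance tag.
#' @return A `SimilarityTransform`.
#' @export
similarityTransform <- function(scale = 1, thetaDeg = 0, tx = 0, ty = 0,
                                center = c(0, 0), direction = "AtoB") {
    new("SimilarityTransform", scale = scale, thetaDeg = thetaDeg,
        tx = tx, ty = ty, center = as.numeric(center), direction = direction)
}

setMethod("show", "SimilarityTransform", function(object) {
    cat(sprintf(
        "SimilarityTransform (%s): scale %.4f, rotation %.3f deg, t = (%.2f, %.2f), center = (%.1f, %.1f)\n",
        object@direction, object@scale, object@thetaDeg, object@tx,
        object@ty, object@center[1], object@center[2]))
})
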