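#' Analysis configuration
#'
#' Bundles every tunable constant of the pipeline in one validated list so
#' results are reproducible and self-describing. The thresholding constants
#' of the possibly-malignant region caller (`fracOfMax = 0.7`, `floor = 10`,
#' `minRegionSpots = 15`) are the section-level classification rule:
#' threshold = 70 percent of the section's highest local enrichment score,
#' floored at 10, with only connected regions of more than 15 spots
#' reported. The other defaults are package choices, recorded in outputs.
#'
#' @param minScore minimum winning PAGE score for a spot to receive a
#'   feature label (z-like scale; default 2).
#' @param slopeThreshold minimum |slope| (score units per unit normalised
#'   trajectory length) for a monotone run to count as a TME change;
#'   default 0.02. May be a named vector for per-signature thresholds.
#' @param corridorWidth half-width, in pixels, of the corridor around the
#'   trajectory polyline inside which spots are projected; default
#'   `NULL` = 2 x spot pitch, resolved at projection time.
#' @param nBins number of equal-length trajectory bins (default 100).
#' @param smoothWindow odd width of the centred moving-average smoother
#'   (default 5).
#' @param kernelRadius maximum hex ring R of the local-enrichment kernel
#'   (default 2).
#' @param kernelWeights strictly decreasing weights for rings 0..R
#'   (default 3, 2, 1).
#' @param fracOfMax fraction of the section maximum defining the region
#'   threshold (default 0.7).
#' @param floor lower bound of the region threshold (default 10).
#' @param minRegionSpots regions must exceed this many spots (default 15).
#' @param fdrLevel Benjamini-Hochberg level used when reporting DEGs
#'   (default 0.05).
#' @param seed default seed for stochastic steps (module-score control
#'   draws); default 1.
#' @return a validated list of class `tme_config`.
#' @export
analysisConfig <- function(minScore = 2,
                           slopeThreshold = 0.02,
                           corridorWidth = NULL,
                           nBins = 100L,
                           smoothWindow = 5L,
                           kernelRadius = 2L,
                           kernelWeights = c(3, 2, 1),
                           fracOfMax = 0.7,
                           floor = 10,
                           minRegionSpots = 15L,
                           fdrLevel = 0.05,
                           seed = 1L) {
    .assertScalarNumber(fracOfMax, "fracOfMax", lower = 1e-12, upper = 1)
    .assertScalarNumber(floor, "floor", lower = 0)
    .assertScalarNumber(minRegionSpots, "minRegionSpots", lower = 1)
    if (length(kernelWeights) != kernelRadius + 1L)
        stop("kernelWeights must have length kernelRadius + 1")
    if (any(diff(kernelWeights) >= 0))
        stop("kernelWeights must be strictly decreasing with ring")
    if (smoothWindow %% 2L != 1L)
        stop("smoothWindow must be odd")
    structure(list(minScore = minScore, slopeThreshold = slopeThreshold,
                   corridorWidth = corridorWidth, nBins = as.integer(nBins),
                   smoothWindow = as.integer(smoothWindow),
                   kernelRadius = as.integer(kernelRadius),
                   kernelWeights = kernelWeights, fracOfMax = fracOfMax,
                   floor = floor, minRegionSpots = as.integer(minRegionSpots),
                   fdrLevel = fdrLevel, seed = as.integer(seed)),
              class = "tme_config")
}

#' Default TME signature set
#'
#' A compact, illustrative signature collection covering the seven feature
#' classes the scoring stage distinguishes: three tumor-cell features
#' (well-differentiated, proliferative, invasive) and four microenvironment
#' features (B cell, T cell, fibroblast-CAF, macrophage). The gene lists
#' are plausible marker panels assembled for demonstration and testing;
#' they are stand-ins, not a curated resource, and real analyses should
#' supply study-specific lists via [readSignatures()].
#'
#' @return a [SignatureSet].
#' @export
defaultSignatures <- function() {
    sig <- list(
        `well-differentiated` = c("SFTPC", "SFTPB", "SFTPA1", "NAPSA",
                                  "SCGB3A2", "NKX2-1"),
        proliferative = c("MKI67", "TOP2A", "CCNB1", "WEE1", "PCNA", "FOS"),
        invasive      = c("MMP7", "TNC", "TGFBI", "SPINK1", "VIM", "RHOB"),
        `B cell`      = c("MS4A1", "CD79A", "CD19", "IGHM", "CXCR5"),
        `T cell`      = c("CD3E", "CD3D", "CD2", "TRAC", "IL7R"),
        `fibroblast-CAF` = c("COL1A1", "COL1A2", "ACTA2", "SPARC", "PDGFRB"),
        macrophage    = c("CD68", "MARCO", "LYZ", "SPP1", "MRC1"))
    SignatureSet(sig,
                 category = c(rep("tumor-feature", 3),
                              rep("microenvironment-feature", 4)),
                 classTag = names(sig))
}
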