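#' Distance-weighted local enrichment of a target feature class
#'
#' For every spot s the local enrichment score is the weighted count of
#' target-class spots in its hex neighbourhood:
#'
#'   score(s) = sum over target spots u with hexdist(s, u) <= R of
#'              weights[hexdist(s, u) + 1],
#'
#' with hexdist the Visium lattice graph distance. The spot counts itself
#' at ring 0 when it carries the target label, so a dense enclave scores
#' its own members highest. The field is additive over target spots by
#' construction. Default kernel: R = 2 with strictly decreasing ring
#' weights (3, 2, 1); for enclave-scale detection the radius should be
#' matched to the expected enclave diameter (see the package vignette).
#'
#' @param x a [SpotExperiment].
#' @param labels per-spot feature labels (character vector aligned with
#'   the spots, or the DataFrame from [classifySpots()]).
#' @param targetClass feature class to count, e.g. `"invasive"` or
#'   `"proliferative"`.
#' @param R maximum hex ring (>= 0).
#' @param weights strictly decreasing weights for rings 0..R.
#' @return data.frame with `spot_id`, `score`, and the kernel recorded in
#'   attributes `kernelRadius` / `kernelWeights`.
#' @export
localEnrichment <- function(x, labels, targetClass,
                            R = 2L, weights = c(3, 2, 1)) {
    if (R < 0) stop("R must be >= 0")
    if (length(weights) != R + 1L)
        stop("weights must have length R + 1")
    if (R > 0 && any(diff(weights) >= 0))
        stop("weights must be strictly decreasing with ring")
    if (is(labels, "DataFrame")) labels <- labels$label
    stopifnot(length(labels) == ncol(x))
    ac <- arrayCoords(x)
    target <- which(labels == targetClass)
    score <- numeric(ncol(x))
    if (length(target)) {
        d <- hexDistance(ac[, 1], ac[, 2],
                         ac[target, 1], ac[target, 2])
        d <- matrix(d, nrow = nrow(ac))
        within <- d <= R
        w <- matrix(0, nrow(d), ncol(d))
        w[within] <- weights[d[within] + 1L]
        score <- rowSums(w)
    }
    out <- data.frame(spot_id = colnames(x), score = score)
    attr(out, "kernelRadius") <- R
    attr(out, "kernelWeights") <- weights
    attr(out, "targetClass") <- targetClass
    out
}

#' Section-level classification threshold for local enrichment
#'
#' threshold = 70 percent of the section's highest local enrichment score;
#' when that value is less than the floor (10), the floor is used. An
#' all-zero field yields the floor with a warning, since no spot can pass.
#'
#' @param field output of [localEnrichment()] (or a numeric score vector).
#' @param fracOfMax fraction of the maximum (default 0.7).
#' @param floor lower bound of the threshold (default 10).
#' @return the numeric threshold.
#' @export
enrichmentThreshold <- function(field, fracOfMax = 0.7, floor = 10) {
    score <- if (is.data.frame(field)) field$score else field
    if (!length(score)) stop("empty enrichment field")
    m <- max(score)
    if (m == 0)
        warning("all-zero enrichment field: threshold is the floor, ",
                "no regions can pass")
    thr <- fracOfMax * m
    if (thr < floor) thr <- floor
    thr
}

#' Extract possibly malignant regions from an enrichment field
#'
#' Keeps spots whose local enrichment score is strictly greater than the
#' threshold, splits them into connected components under ring-1 hex
#' adjacency, and reports components with strictly more than
#' `minRegionSpots` members as possibly malignant regions of the field's
#' target class.
#'
#' @param x the [SpotExperiment] the field was computed on.
#' @param field output of [localEnrichment()].
#' @param threshold from [enrichmentThreshold()].
#' @param minRegionSpots region size cut (default 15; "more than 15" is
#'   strict, so a 16-spot component is the smallest reported).
#' @return list of regions, each `list(class, spots, size, threshold)`;
#'   empty list when nothing passes.
#' @export
extractRegions <- function(x, field, threshold, minRegionSpots = 15L) {
    cls <- attr(field, "targetClass")
    idx <- which(field$score > threshold)
    if (!length(idx)) return(list())
    ac <- arrayCoords(x)[idx, , drop = FALSE]
    comp <- .hexComponents(ac[, 1], ac[, 2])
    keep <- names(which(table(comp) > minRegionSpots))
    lapply(keep, function(k) {
        members <- idx[comp == as.integer(k)]
        list(class = paste0("possibly malignant-", cls),
             spots = field$spot_id[members],
             size = length(members),
             threshold = threshold)
    })
}

#' Library-size log normalisation
#'
#' Per spot, x -> ln(1 + x * scale / librarySize) with scale 10,000 —
#' the standard log-normalisation used before differential expression.
#' Zero-library spots are flagged with a warning and normalised to zeros.
#'
#' @param counts gene x spot non-negative count matrix.
#' @param scale library scale factor (default 1e4).
#' @return dense numeric matrix of the same shape.
#' @export
logNormalize <- function(counts, scale = 1e4) {
    counts <- as.matrix(counts)
    if (any(counts < 0)) stop("counts must be non-negative")
    lib <- colSums(counts)
    if (any(lib == 0))
        warning(sum(lib == 0), " spot(s) with zero library size ",
                "normalised to zeros")
    sf <- ifelse(lib > 0, scale / lib, 0)
    log1p(sweep(counts, 2, sf, "*"))
}

#' Wilcoxon rank-sum differential expression between two spot groups
#'
#' Per gene: two-sided rank-sum p-value comparing normalised expression
#' inside vs outside the region mask, Benjamini-Hochberg adjustment, and
#' a log2 fold change computed on de-logged means,
#' log2((mean(expm1(in)) + pseudo) / (mean(expm1(out)) + pseudo)) with
#' pseudo = 1.
#'
#' @param normalized gene x spot matrix from [logNormalize()].
#' @param inRegion logical mask over spots (TRUE = region member).
#' @param pseudo pseudocount used in the fold-change ratio (default 1).
#' @return data.frame: `gene`, `log2FC`, `p`, `pAdj`, sorted by p.
#' @export
degWilcoxon <- function(normalized, inRegion, pseudo = 1) {
    stopifnot(length(inRegion) == ncol(normalized))
    if (sum(inRegion) < 3L || sum(!inRegion) < 3L)
        stop("both groups need at least 3 spots")
    a <- normalized[, inRegion, drop = FALSE]
    b <- normalized[, !inRegion, drop = FALSE]
    p <- vapply(seq_len(nrow(normalized)), function(g) {
        suppressWarnings(stats::wilcox.test(a[g, ], b[g, ])$p.value)
    }, 0)
    lfc <- log2((rowMeans(expm1(a)) + pseudo) /
                (rowMeans(expm1(b)) + pseudo))
    out <- data.frame(gene = rownames(normalized), log2FC = lfc,
                      p = p, pAdj = stats::p.adjust(p, "BH"))
    out[order(out$p), ]
}

#' Compare per-section maximum enrichment scores between two groups
#'
#' Two-sided Wilcoxon rank-sum test on the highest local enrichment score
#' of each section, one group per disease stage (no multiple-comparison
#' adjustment).
#'
#' @param maxima numeric vector: one maximum per section.
#' @param group two-level factor/character aligned with `maxima`.
#' @return the two-sided p-value.
#' @export
compareSectionMaxima <- function(maxima, group) {
    group <- as.factor(group)
    if (nlevels(group) != 2L)
        stop("exactly two groups required")
    n <- table(group)
    if (any(n < 2L)) stop("each group needs at least 2 sections")
    split_ <- split(maxima, group)
    suppressWarnings(stats::wilcox.test(split_[[1]], split_[[2]])$p.value)
}
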