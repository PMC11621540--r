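#' Normalise counts for signature scoring
#'
#' Scales each spot to the median library size of the section and applies
#' log2(x + 1). This is the normalisation behind [pageScores()] and
#' [moduleScore()]; it is recorded in the resulting [ScoreTable] so scores
#' are self-describing.
#'
#' @param counts gene x spot count matrix (dense or sparse).
#' @return dense numeric matrix of log2 normalised expression.
#' @export
normalizeForScoring <- function(counts) {
    counts <- as.matrix(counts)
    lib <- colSums(counts)
    target <- stats::median(lib)
    sf <- ifelse(lib > 0, target / lib, 0)
    log2(sweep(counts, 2, sf, "*") + 1)
}

#' Per-spot signature enrichment by the PAGE statistic
#'
#' For each spot s, let f_gs be the fold change of gene g: its log2
#' normalised expression in s minus the gene's mean across spots. With mu
#' and delta the mean and standard deviation of f over all genes in s, and
#' Sm the mean of f over the m signature genes present in the matrix, the
#' enrichment score is
#'
#'   score = (Sm - mu) * sqrt(m) / delta,
#'
#' a z-like statistic comparing the signature's mean fold change with the
#' transcriptome background. Spots with delta = 0 (no fold-change spread,
#' e.g. empty spots) are flagged degenerate and score 0 for every
#' signature rather than propagating NaN.
#'
#' @param x a [SpotExperiment] or gene x spot count matrix.
#' @param signatures a [SignatureSet]; every signature must share at least
#'   one gene with the matrix.
#' @return a [ScoreTable] (spots x signatures).
#' @export
pageScores <- function(x, signatures) {
    counts <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else x
    if (ncol(counts) < 2L)
        stop("PAGE scoring needs at least 2 spots")
    expr <- normalizeForScoring(counts)
    fold <- expr - rowMeans(expr)            # genes x spots
    mu <- colMeans(fold)
    delta <- apply(fold, 2, stats::sd)
    degenerate <- !is.finite(delta) | delta == 0

    nms <- signatureNames(signatures)
    m <- integer(length(nms)); names(m) <- nms
    scores <- matrix(0, nrow = ncol(counts), ncol = length(nms),
                     dimnames = list(colnames(counts), nms))
    for (nm in nms) {
        gs <- intersect(signatureGenes(signatures, nm), rownames(counts))
        if (!length(gs))
            stop("signature has no genes in the matrix: ", nm)
        m[nm] <- length(gs)
        Sm <- colMeans(fold[gs, , drop = FALSE])
        sc <- (Sm - mu) * sqrt(length(gs)) / delta
        sc[degenerate] <- 0
        scores[, nm] <- sc
    }
    new("ScoreTable", scores = scores, degenerate = unname(degenerate),
        nGenes = m,
        normalization = "median library size scaling, log2(x+1)")
}

#' Module score of a gene set with expression-matched controls
#'
#' Mean normalised expression of the gene set minus the mean of control
#' genes, where each set gene contributes `nCtrl` controls drawn from its
#' own average-expression bin (equal-frequency binning across spots). A
#' positive score means the set is expressed above genes of comparable
#' abundance.
#'
#' @param x a [SpotExperiment] or gene x spot count matrix.
#' @param geneSet character vector of genes.
#' @param nBins number of average-expression bins (default 24, >= 2).
#' @param nCtrl controls drawn per set gene (default 100).
#' @param seed integer seed for the control draw.
#' @param controlPool optional character vector restricting the control
#'   candidates (by default, each set gene's expression bin). Supplying
#'   the gene set itself makes the score identically zero, a useful
#'   null check.
#' @return named numeric vector, one score per spot.
#' @export
moduleScore <- function(x, geneSet, nBins = 24L, nCtrl = 100L, seed = 1L,
                        controlPool = NULL) {
    counts <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else x
    if (nBins < 2L) stop("nBins must be >= 2")
    geneSet <- intersect(geneSet, rownames(counts))
    if (!length(geneSet)) stop("gene set empty after intersection")
    expr <- normalizeForScoring(counts)
    avg <- rowMeans(expr)
    nBins <- min(as.integer(nBins), length(avg))
    # equal-frequency bins on average expression (ties broken by rank)
    bin <- cut(rank(avg, ties.method = "first"),
               breaks = nBins, labels = FALSE)
    names(bin) <- names(avg)
    .withSeed(seed, {
        ctrl <- unlist(lapply(geneSet, function(g) {
            pool <- if (is.null(controlPool)) names(bin)[bin == bin[[g]]]
                    else intersect(controlPool, rownames(counts))
            pool <- setdiff(pool, g)
            if (!length(pool)) return(character(0))
            sample(pool, min(nCtrl, length(pool)), replace = FALSE)
        }))
    })
    ctrl <- unique(ctrl)
    ctrlMean <- if (length(ctrl))
        colMeans(expr[ctrl, , drop = FALSE]) else 0
    colMeans(expr[geneSet, , drop = FALSE]) - ctrlMean
}

#' Classify each spot into its dominant TME feature
#'
#' Assigns the class tag of the highest-scoring signature when that score
#' reaches `minScore`, else `"unassigned"`. Exact ties are broken by a
#' fixed priority: tumor features before microenvironment features, then
#' lexicographic signature name.
#'
#' @param scores a [ScoreTable] from [pageScores()].
#' @param signatures the [SignatureSet] the scores were computed from.
#' @param config an [analysisConfig()]; `minScore` is used.
#' @return a [S4Vectors::DataFrame] with per-spot `label`, `signature`
#'   (winning signature or NA) and `score` (the winning score).
#' @export
classifySpots <- function(scores, signatures,
                          config = analysisConfig()) {
    sm <- scoreMatrix(scores)
    cat_ <- signatureCategory(signatures)[colnames(sm)]
    prio <- order(cat_ != "tumor-feature", colnames(sm))
    smp <- sm[, prio, drop = FALSE]
    win <- apply(smp, 1, which.max)           # first max in priority order
    winScore <- smp[cbind(seq_len(nrow(smp)), win)]
    winSig <- colnames(smp)[win]
    label <- signatureClass(signatures)[winSig]
    unassigned <- winScore < config$minScore
    label[unassigned] <- "unassigned"
    winSig[unassigned] <- NA_character_
    DataFrame(label = unname(label), signature = winSig,
              score = winScore, row.names = rownames(sm))
}

#' Per-section proportions of TME feature labels
#'
#' @param labeling output of [classifySpots()] (or any vector of labels).
#' @param section optional factor splitting spots into sections; one
#'   section assumed when NULL.
#' @return data.frame with columns section, label, n, proportion;
#'   proportions sum to 1 within each section.
#' @export
featureProportions <- function(labeling, section = NULL) {
    labels <- if (is(labeling, "DataFrame")) labeling$label else labeling
    if (!length(labels)) stop("empty section: no spots to summarise")
    if (is.null(section)) section <- rep("section1", length(labels))
    out <- do.call(rbind, lapply(split(seq_along(labels), section),
                                 function(i) {
        tab <- table(labels[i])
        data.frame(section = section[i[1]], label = names(tab),
                   n = as.integer(tab),
                   proportion = as.numeric(tab) / length(i))
    }))
    rownames(out) <- NULL
    out
}
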