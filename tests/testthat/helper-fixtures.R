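# shared fixtures and independent oracles, built in code at test time

# minimal SpotExperiment from explicit array coordinates
makeSpotSE <- function(arrayRow, arrayCol, pixelX = NULL, pixelY = NULL,
                       cluster = NULL, counts = NULL, pitch = 100) {
    n <- length(arrayRow)
    if (is.null(pixelX)) pixelX <- arrayCol * pitch / 2
    if (is.null(pixelY)) pixelY <- arrayRow * pitch * sqrt(3) / 2
    sd <- data.frame(spot_id = sprintf("S%03d", seq_len(n)),
                     array_row = arrayRow, array_col = arrayCol,
                     pixel_x = pixelX, pixel_y = pixelY, in_tissue = TRUE)
    if (!is.null(cluster)) sd$cluster <- cluster
    if (is.null(counts))
        counts <- matrix(1L, nrow = 2, ncol = n,
                         dimnames = list(c("G1", "G2"), sd$spot_id))
    SpotExperiment(counts, sd)
}

# a full lattice SpotExperiment with no planted structure
makeLatticeSE <- function(nRows, nCols, counts = NULL) {
    g <- hexGrid(nRows, nCols)
    if (is.null(counts))
        counts <- matrix(1L, nrow = 2, ncol = nrow(g),
                         dimnames = list(c("G1", "G2"), g$spot_id))
    SpotExperiment(counts, g)
}

makeScoreTable <- function(scores) {
    new("ScoreTable", scores = scores,
        degenerate = rep(FALSE, nrow(scores)),
        nGenes = stats::setNames(rep(1L, ncol(scores)), colnames(scores)),
        normalization = "fixture")
}

# independent PAGE oracle: explicit element-wise arithmetic, no shared code
pageOracle <- function(counts, genes) {
    lib <- colSums(counts)
    norm <- counts
    for (s in seq_len(ncol(counts)))
        norm[, s] <- counts[, s] * stats::median(lib) / lib[s]
    le <- log2(norm + 1)
    fold <- le
    for (g in seq_len(nrow(le)))
        fold[g, ] <- le[g, ] - mean(le[g, ])
    sapply(seq_len(ncol(counts)), function(s) {
        f <- fold[, s]
        mu <- mean(f); delta <- stats::sd(f)
        Sm <- mean(f[genes])
        (Sm - mu) * sqrt(length(genes)) / delta
    })
}

# exact two-sided rank-sum p by full enumeration of group assignments,
# following the U-statistic convention with the two-sided doubling rule
rankSumExact <- function(x, y) {
    nx <- length(x); ny <- length(y)
    all_ <- c(x, y)
    u0 <- sum(rank(all_)[seq_len(nx)]) - nx * (nx + 1) / 2
    combos <- utils::combn(nx + ny, nx)
    us <- apply(combos, 2, function(i)
        sum(rank(all_)[i]) - nx * (nx + 1) / 2)
    min(1, 2 * min(mean(us <= u0), mean(us >= u0)))
}

# recover the top-overlap (invasive, B cell) pair on a gradient section;
# profile settings chosen for 100-bin lattice resolution (see vignette)
recoverGradientPair <- function(seed) {
    se <- genSection(gradientSectionConfig(seed = seed))
    st <- pageScores(se, defaultSignatures())
    path <- buildTrajectory(se, paste0("c", 1:8))
    pr <- projectSpots(path, se, corridorWidth = 8 * spotPitch(se))
    prof <- extractProfile(st, pr, nBins = 100, window = 9,
                           signatures = c("invasive", "B cell"))
    segs <- rbind(
        findChangeSegments(prof$invasive, 0.02, "invasive"),
        findChangeSegments(prof$`B cell`, 0.02, "B cell"))
    pairs <- pairChanges(segs)
    if (!nrow(pairs)) return(NULL)
    pairs[order(-pairs$overlapLength), ][1, ]
}
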