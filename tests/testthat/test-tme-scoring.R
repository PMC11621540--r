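test_that("PAGE scores match an independently coded direct evaluation", {
    set.seed(21)
    counts <- matrix(rpois(24, 8), nrow = 6,
                     dimnames = list(paste0("G", 1:6), paste0("S", 1:4)))
    sigs <- SignatureSet(list(two = c("G2", "G5")), "tumor-feature")
    got <- scoreMatrix(pageScores(counts, sigs))[, "two"]
    want <- pageOracle(counts, c(2L, 5L))
    expect_equal(unname(got), want, tolerance = 1e-10)
})

test_that("the whole-transcriptome signature scores exactly zero", {
    set.seed(22)
    counts <- matrix(rpois(60, 6), nrow = 6,
                     dimnames = list(paste0("G", 1:6), paste0("S", 1:10)))
    sigs <- SignatureSet(list(all = paste0("G", 1:6)), "tumor-feature")
    expect_equal(unname(scoreMatrix(pageScores(counts, sigs))[, "all"]),
                 rep(0, 10))
})

test_that("degenerate spots are flagged and scored zero, not NaN", {
    counts <- matrix(5L, nrow = 4, ncol = 3,
                     dimnames = list(paste0("G", 1:4), paste0("S", 1:3)))
    sigs <- SignatureSet(list(s = c("G1", "G2")), "tumor-feature")
    st <- pageScores(counts, sigs)
    expect_true(all(degenerateSpots(st)))
    expect_equal(unname(scoreMatrix(st)[, "s"]), rep(0, 3))
    expect_error(pageScores(counts, SignatureSet(list(gone = "NOPE"),
                                                 "tumor-feature")),
                 "gone")
})

test_that("PAGE is equivariant under gene and spot permutation", {
    set.seed(23)
    counts <- matrix(rpois(200, 4), nrow = 20,
                     dimnames = list(paste0("G", 1:20), paste0("S", 1:10)))
    sigs <- SignatureSet(list(s = c("G3", "G7", "G11")), "tumor-feature")
    base <- scoreMatrix(pageScores(counts, sigs))
    gp <- sample(nrow(counts)); sp <- sample(ncol(counts))
    perm <- scoreMatrix(pageScores(counts[gp, sp], sigs))
    expect_equal(perm[colnames(counts), ], base[, 1][colnames(counts)],
                 tolerance = 1e-12)

    # a zero-variance gene in the signature does not break scoring
    counts2 <- rbind(counts, FLAT = 3L)
    sigs2 <- SignatureSet(list(s = c("G3", "G7", "FLAT")), "tumor-feature")
    expect_silent(st <- pageScores(counts2, sigs2))
    expect_true(all(is.finite(scoreMatrix(st))))
})

test_that("module scores vanish under self-controls and recover planting", {
    set.seed(24)
    counts <- matrix(rpois(300, 5), nrow = 30,
                     dimnames = list(paste0("G", 1:30), paste0("S", 1:10)))
    gs <- c("G1", "G2", "G3")
    ms <- moduleScore(counts, gs, nCtrl = 10, seed = 1, controlPool = gs)
    expect_equal(unname(ms), rep(0, 10), tolerance = 1e-12)

    expect_error(moduleScore(counts, character(0)), "empty")
    expect_error(moduleScore(counts, gs, nBins = 1), "nBins")
    expect_identical(moduleScore(counts, gs, seed = 7),
                     moduleScore(counts, gs, seed = 7))

    # planted 4x elevation in half the spots of a 200-spot section
    se <- genSection(sectionConfig(
        nRows = 10, nCols = 20,
        clusterLayout = list(hot = list(rows = c(0, 9), cols = c(0, 9))),
        signaturePlan = data.frame(cluster = "hot",
                                   signature = "proliferative", log2fc = 2),
        seed = 25))
    ms <- moduleScore(se, c("MKI67", "TOP2A", "CCNB1"), seed = 1)
    hot <- spotClusters(se) == "hot"
    expect_lt(stats::wilcox.test(ms[hot], ms[!hot],
                                 alternative = "greater")$p.value, 0.01)
})

test_that("spot classification follows argmax with floor and fixed ties", {
    sigs <- defaultSignatures()
    sm <- rbind(c(2.0, 5.1, 1.0),
                c(1.2, 1.4, 1.1),
                c(3.0, 3.0, 3.0))
    colnames(sm) <- c("proliferative", "invasive", "B cell")
    rownames(sm) <- paste0("S", 1:3)
    lab <- classifySpots(makeScoreTable(sm), sigs,
                         analysisConfig(minScore = 1.5))
    expect_identical(lab$label[1], "invasive")
    expect_identical(lab$label[2], "unassigned")
    # exact three-way tie: tumor features beat microenvironment features,
    # then lexicographic -> invasive
    expect_identical(lab$label[3], "invasive")

    sm2 <- sm[, c("B cell", "proliferative", "invasive")]  # column order
    lab2 <- classifySpots(makeScoreTable(sm2), sigs,
                          analysisConfig(minScore = 1.5))
    expect_identical(lab2$label, lab$label)
})

test_that("feature proportions count correctly and sum to one", {
    lab <- c(rep("invasive", 60), rep("B cell", 40))
    fp <- featureProportions(lab)
    expect_equal(fp$proportion[fp$label == "invasive"], 0.6)
    expect_equal(fp$proportion[fp$label == "B cell"], 0.4)

    expect_error(featureProportions(character(0)), "empty")
    fp1 <- featureProportions(rep("T cell", 5))
    expect_equal(fp1$proportion, 1)

    set.seed(26)
    lab <- sample(c("a", "b", "c", "unassigned"), 200, replace = TRUE)
    sec <- sample(c("s1", "s2"), 200, replace = TRUE)
    fp <- featureProportions(lab, sec)
    sums <- tapply(fp$proportion, fp$section, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("the planted-elevated signature wins inside its footprint", {
    sigs <- defaultSignatures()
    se <- genSection(sectionConfig(
        nRows = 10, nCols = 20,
        clusterLayout = list(fp = list(rows = c(0, 9), cols = c(0, 9))),
        signaturePlan = data.frame(cluster = "fp", signature = "B cell",
                                   log2fc = 2),
        seed = 27), sigs)
    sm <- scoreMatrix(pageScores(se, sigs))
    inside <- spotClusters(se) == "fp"
    meansInside <- colMeans(sm[inside, ])
    expect_identical(names(which.max(meansInside)), "B cell")
})
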