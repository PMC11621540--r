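test_that("the default kernel scores rings 0/1/2 as 3/2/1 and is additive", {
    se <- makeLatticeSE(9, 9)
    ac <- arrayCoords(se)
    centre <- which(ac[, "array_row"] == 4 & ac[, "array_col"] == 8)
    lab <- rep("other", ncol(se)); lab[centre] <- "invasive"
    f <- localEnrichment(se, lab, "invasive")
    d <- hexDistance(ac[, 1], ac[, 2], ac[centre, 1], ac[centre, 2])
    expect_equal(f$score[d == 0], 3)
    expect_equal(f$score[d == 1], rep(2, 6))
    expect_equal(f$score[d == 2], rep(1, 12))
    expect_equal(f$score[d > 2], rep(0, sum(d > 2)))

    # two adjacent targets: each scores 3 + 2; field is additive
    nb <- which(d == 1)[1]
    lab2 <- lab; lab2[nb] <- "invasive"
    f2 <- localEnrichment(se, lab2, "invasive")
    expect_equal(f2$score[centre], 5)
    expect_equal(f2$score[nb], 5)
    labB <- rep("other", ncol(se)); labB[nb] <- "invasive"
    fB <- localEnrichment(se, labB, "invasive")
    expect_equal(f2$score, f$score + fB$score)

    expect_error(localEnrichment(se, lab, "invasive", R = -1), "R must")
    expect_error(localEnrichment(se, lab, "invasive", R = 2,
                                 weights = c(1, 2, 3)),
                 "decreasing")
})

test_that("the section threshold is fraction-of-max floored at 10", {
    expect_equal(enrichmentThreshold(c(0, 5, 20)), 14)
    expect_equal(enrichmentThreshold(c(1, 12)), 10)       # 8.4 < 10
    expect_equal(enrichmentThreshold(10 / 0.7), 10)       # exact boundary
    expect_warning(thr <- enrichmentThreshold(c(0, 0, 0)), "all-zero")
    expect_equal(thr, 10)
})

test_that("region extraction is strict on score and on size", {
    # a connected chain of n above-threshold spots: 15 fails, 16 reports
    for (n in c(15L, 16L)) {
        se <- makeLatticeSE(3, 20)
        ac <- arrayCoords(se)
        chain <- which(ac[, "array_row"] == 1)[seq_len(n)]
        field <- data.frame(spot_id = colnames(se),
                            score = ifelse(seq_len(ncol(se)) %in% chain,
                                           1, 0))
        attr(field, "targetClass") <- "invasive"
        regs <- extractRegions(se, field, threshold = 0.5)
        expect_length(regs, as.integer(n == 16L))
        if (n == 16L) {
            expect_equal(regs[[1]]$size, 16L)
            expect_identical(regs[[1]]$class,
                             "possibly malignant-invasive")
            expect_setequal(regs[[1]]$spots, colnames(se)[chain])
        }
    }

    # spots exactly at the threshold do not pass ("greater than" is strict)
    se <- makeLatticeSE(3, 20)
    field <- data.frame(spot_id = colnames(se), score = 0.5)
    attr(field, "targetClass") <- "invasive"
    expect_length(extractRegions(se, field, threshold = 0.5), 0L)
})

test_that("raising the threshold never grows regions", {
    se <- genSection(enclaveSectionConfig(seed = 6))
    gt <- metadata(se)$groundTruth
    f <- localEnrichment(se, unname(gt$feature), "invasive",
                         R = 7L, weights = 8:1)
    prev <- Inf
    for (thr in c(50, 100, 150, 200)) {
        regs <- extractRegions(se, f, thr, minRegionSpots = 5)
        tot <- sum(vapply(regs, `[[`, 1L, "size"))
        expect_lte(tot, prev)
        prev <- tot
        # every member's score strictly exceeds the threshold
        for (r in regs)
            expect_true(all(f$score[match(r$spots, f$spot_id)] > thr))
    }
})

test_that("planted enclaves are recovered as one covering region", {
    for (seed in c(1, 2, 3)) {
        se <- genSection(enclaveSectionConfig(seed = seed))
        gt <- metadata(se)$groundTruth
        f <- localEnrichment(se, unname(gt$feature), "invasive",
                             R = 7L, weights = 8:1)
        regs <- extractRegions(se, f, enrichmentThreshold(f))
        expect_length(regs, 1L)
        planted <- gt$enclaves[[1]]$spots
        expect_gte(mean(planted %in% regs[[1]]$spots), 0.8)
    }
})

test_that("log normalisation matches its closed form and invariances", {
    m <- matrix(0L, 3, 2, dimnames = list(paste0("G", 1:3), c("a", "b")))
    expect_warning(z <- logNormalize(m), "zero library")
    expect_equal(unname(z), matrix(0, 3, 2))

    one <- matrix(c(10L, 90L), 2, 1,
                  dimnames = list(c("G1", "G2"), "s"))
    got <- logNormalize(one)
    expect_equal(unname(got[, 1]), c(log(1 + 1000), log(1 + 9000)))

    set.seed(41)
    m <- matrix(rpois(50, 5), 10, 5,
                dimnames = list(paste0("G", 1:10), paste0("S", 1:5)))
    n1 <- logNormalize(m)
    m2 <- m; m2[, 3] <- m2[, 3] * 2L
    n2 <- logNormalize(m2)
    expect_equal(n1[, 3], n2[, 3])
})

test_that("rank-sum DE matches the exact enumeration oracle at small n", {
    set.seed(42)
    norm <- matrix(rnorm(30, 5, 1), nrow = 3,
                   dimnames = list(paste0("G", 1:3), paste0("S", 1:10)))
    mask <- rep(c(TRUE, FALSE), each = 5)
    res <- degWilcoxon(norm, mask)
    for (g in rownames(norm)) {
        want <- rankSumExact(norm[g, mask], norm[g, !mask])
        expect_equal(res$p[res$gene == g], want, tolerance = 1e-10)
    }

    # identical groups: fold change 0 and p = 1 everywhere
    dup <- cbind(norm[, 1:5], norm[, 1:5])
    res0 <- degWilcoxon(dup, rep(c(TRUE, FALSE), each = 5))
    expect_equal(res0$log2FC, rep(0, 3))
    expect_equal(res0$p, rep(1, 3))

    expect_error(degWilcoxon(norm, c(TRUE, TRUE, rep(FALSE, 8))),
                 "at least 3")
})

test_that("a planted fold change is the top DE hit at n = 100 vs 100", {
    set.seed(43)
    n <- 200
    counts <- matrix(rnbinom(50 * n, mu = 5, size = 2), nrow = 50,
                     dimnames = list(paste0("G", 1:50), paste0("S", 1:n)))
    mask <- seq_len(n) <= 100
    counts["G7", mask] <- rnbinom(100, mu = 20, size = 2)
    res <- degWilcoxon(logNormalize(counts), mask)
    expect_identical(res$gene[which.max(abs(res$log2FC))], "G7")
    expect_lt(res$pAdj[res$gene == "G7"], 0.01)
})

test_that("section maxima compare by the exact two-sided rank-sum test", {
    p <- compareSectionMaxima(c(1, 2, 3, 10, 11, 12),
                              rep(c("early", "invasive"), each = 3))
    expect_equal(p, rankSumExact(c(1, 2, 3), c(10, 11, 12)),
                 tolerance = 1e-12)
    # label swap leaves the two-sided p unchanged
    p2 <- compareSectionMaxima(c(1, 2, 3, 10, 11, 12),
                               rep(c("invasive", "early"), each = 3))
    expect_equal(p, p2)
    expect_error(compareSectionMaxima(1:4, c("a", "a", "a", "b")),
                 "at least 2")
    expect_error(compareSectionMaxima(1:4, rep("a", 4)), "two groups")
})
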