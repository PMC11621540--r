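test_that("trajectories normalise cumulative centroid arc length", {
    se <- makeSpotSE(arrayRow = c(0L, 0L), arrayCol = c(0L, 2L),
                     pixelX = c(0, 3), pixelY = c(0, 4),
                     cluster = c("a", "b"))
    path <- buildTrajectory(se, c("a", "b"))
    expect_equal(path@totalLength, 5)
    expect_equal(path@tVertex, c(0, 1))

    se3 <- makeSpotSE(arrayRow = rep(0L, 3), arrayCol = c(0L, 2L, 4L),
                      pixelX = c(0, 1, 4), pixelY = c(0, 0, 0),
                      cluster = c("a", "b", "c"))
    path3 <- buildTrajectory(se3, c("a", "b", "c"))
    expect_equal(path3@tVertex, c(0, 0.25, 1))

    expect_error(buildTrajectory(se, "a"), "at least 2")
    expect_error(buildTrajectory(se, c("a", "zz")), "no spots")
    seDup <- makeSpotSE(arrayRow = c(0L, 0L), arrayCol = c(0L, 2L),
                        pixelX = c(1, 1), pixelY = c(1, 1),
                        cluster = c("a", "b"))
    expect_error(buildTrajectory(seDup, c("a", "b")), "coincident")
})

test_that("spot projection matches a dense-sampling oracle", {
    se <- makeSpotSE(arrayRow = rep(0L, 4), arrayCol = c(0L, 2L, 4L, 6L),
                     pixelX = c(0, 100, 100, 0), pixelY = c(0, 0, 80, 80),
                     cluster = c("a", "b", "c", "d"))
    path <- buildTrajectory(se, c("a", "b", "c", "d"))

    set.seed(31)
    pts <- cbind(runif(40, -10, 110), runif(40, -10, 90))
    # oracle: nearest of 1e5 densely sampled polyline points
    dense <- do.call(rbind, lapply(1:3, function(k) {
        u <- seq(0, 1, length.out = 33334)
        v0 <- path@vertices[k, ]; v1 <- path@vertices[k + 1, ]
        cbind(v0[1] + u * (v1[1] - v0[1]), v0[2] + u * (v1[2] - v0[2]),
              path@tVertex[k] + u * (path@tVertex[k + 1] - path@tVertex[k]))
    }))
    seP <- makeSpotSE(arrayRow = rep(0L, 40), arrayCol = seq(0L, 78L, 2L),
                      pixelX = pts[, 1], pixelY = pts[, 2])
    pr <- projectSpots(path, seP, corridorWidth = 1e6)
    for (i in seq_len(40)) {
        d <- sqrt((dense[, 1] - pts[i, 1])^2 + (dense[, 2] - pts[i, 2])^2)
        expect_lt(abs(pr$t[i] - dense[which.min(d), 3]), 1e-3)
    }

    # vertex spot maps to the vertex t; corridor boundary is inclusive
    seV <- makeSpotSE(arrayRow = c(0L, 0L), arrayCol = c(0L, 2L),
                      pixelX = c(100, 50), pixelY = c(0, 30))
    prV <- projectSpots(path, seV, corridorWidth = 30)
    expect_equal(prV$t[1], path@tVertex[2])
    expect_true(prV$included[2])       # exactly at corridor distance
    prV2 <- projectSpots(path, seV, corridorWidth = 30 - 1e-9)
    expect_false(prV2$included[2])     # corridor + epsilon away

    expect_error(projectSpots(path, seV, corridorWidth = 0), "corridorWidth")
})

test_that("profiles preserve constants and planted linear fields", {
    se <- makeLatticeSE(20, 20)
    cl <- rep("a", ncol(se)); cl[colData(se)$array_row >= 10] <- "b"
    spotClusters(se) <- cl
    path <- buildTrajectory(se, c("a", "b"))
    pr <- projectSpots(path, se, corridorWidth = 1e6)

    sm <- matrix(2.5, ncol(se), 1, dimnames = list(colnames(se), "flat"))
    prof <- extractProfile(makeScoreTable(sm), pr, nBins = 20, window = 5)
    expect_equal(prof$flat$smoothed, rep(2.5, 20))

    smLin <- matrix(3 * pr$t, ncol(se), 1,
                    dimnames = list(colnames(se), "lin"))
    profL <- extractProfile(makeScoreTable(smLin), pr, nBins = 20,
                            window = 5)
    interior <- 4:17
    fit <- stats::lm(smoothed ~ tMid, data = profL$lin[interior, ])
    expect_lt(max(abs(stats::resid(fit))) / diff(range(profL$lin$smoothed)),
              0.02)

    # window 1 is the identity smoother
    prof1 <- extractProfile(makeScoreTable(smLin), pr, nBins = 20,
                            window = 1)
    expect_identical(prof1$lin$smoothed, prof1$lin$raw)
})

test_that("change segments come from trend reversals above threshold", {
    n <- 100L
    tMid <- (seq_len(n) - 0.5) / n
    v <- ifelse(tMid < 0.2, 0, ifelse(tMid < 0.6, (tMid - 0.2) / 0.4, 1))
    prof <- data.frame(bin = seq_len(n), tMid = tMid, nSpots = 1L,
                       raw = v, smoothed = v)
    segs <- findChangeSegments(prof, 0.5, "x")
    expect_equal(nrow(segs), 1L)
    expect_lt(abs(segs$t0 - 0.2), 0.02)
    expect_lt(abs(segs$t1 - 0.6), 0.02)
    expect_lt(abs(segs$slope - 2.5), 0.1)

    expect_equal(nrow(findChangeSegments(prof, 3.0, "x")), 0L)
    flat <- within(prof, {smoothed <- 1; raw <- 1})
    expect_equal(nrow(findChangeSegments(flat, 0.01, "x")), 0L)
})

test_that("pairing requires strictly positive interval overlap", {
    segs <- data.frame(signature = c("A", "B"), t0 = c(0.1, 0.3),
                       t1 = c(0.4, 0.6), v0 = 0, v1 = 1,
                       slope = c(1, 2), sign = 1L)
    p <- pairChanges(segs)
    expect_equal(nrow(p), 1L)
    expect_equal(p$overlapT0, 0.3)
    expect_equal(p$overlapT1, 0.4)
    expect_equal(p$overlapLength, 0.1)

    segs$t0 <- c(0.1, 0.5); segs$t1 <- c(0.4, 0.9)  # disjoint
    expect_equal(nrow(pairChanges(segs)), 0L)
    segs$t0 <- c(0.1, 0.3); segs$t1 <- c(0.3, 0.5)  # touching
    expect_equal(nrow(pairChanges(segs)), 0L)
    # same-signature segments never pair
    segs2 <- data.frame(signature = "A", t0 = c(0.1, 0.2),
                        t1 = c(0.4, 0.5), v0 = 0, v1 = 1, slope = 1,
                        sign = 1L)
    expect_equal(nrow(pairChanges(segs2)), 0L)
})

test_that("cor_st adds absolute slopes with the sign-agreement rule", {
    expect_equal(corSt(0.026, 0.028), 0.054)
    expect_equal(corSt(0.03, -0.02), -0.05)
    expect_equal(corSt(-0.03, -0.02), 0.05)   # same-sign convention
    # symmetry in the two segments
    set.seed(33)
    sx <- runif(50, -1, 1); sy <- runif(50, -1, 1)
    expect_equal(corSt(sx, sy), corSt(sy, sx))
})

test_that("reversing the cluster order negates slopes, |cor_st| unchanged", {
    se <- genSection(gradientSectionConfig(seed = 4))
    st <- pageScores(se, defaultSignatures())
    run <- function(order_) {
        path <- buildTrajectory(se, order_)
        pr <- projectSpots(path, se, corridorWidth = 8 * spotPitch(se))
        prof <- extractProfile(st, pr, nBins = 100, window = 9,
                               signatures = c("invasive", "B cell"))
        rbind(findChangeSegments(prof$invasive, 0.02, "invasive"),
              findChangeSegments(prof$`B cell`, 0.02, "B cell"))
    }
    fwd <- run(paste0("c", 1:8))
    rev_ <- run(paste0("c", 8:1))
    # matched segments appear mirrored in t with negated slopes
    key <- function(s) paste(s$signature,
                             round(pmin(1 - s$t1, 1 - s$t0), 6),
                             round(pmax(1 - s$t1, 1 - s$t0), 6))
    fwdKey <- paste(fwd$signature, round(fwd$t0, 6), round(fwd$t1, 6))
    revKey <- key(rev_)
    shared <- intersect(fwdKey, revKey)
    expect_gt(length(shared), 0)
    for (k in shared) {
        sF <- fwd$slope[fwdKey == k]
        sR <- rev_$slope[revKey == k]
        expect_equal(sF, -sR, tolerance = 1e-8)
    }
})

test_that("aggregation keeps sign-consistent pairs and sums contributions", {
    pairs <- data.frame(
        specimen = c("s1", "s1", "s2", "s2"),
        sigX = c("A", "A", "A", "A"),
        sigY = c("B", "C", "B", "C"),
        overlapT0 = 0, overlapT1 = 0.1, overlapLength = 0.1,
        slopeX = 1, slopeY = 1,
        corSt = c(0.5, 0.4, 0.7, -0.2))
    agg <- aggregatePairs(pairs)
    expect_equal(nrow(agg$full), 2L)
    ab <- agg$full[agg$full$sigY == "B", ]
    expect_true(ab$consistent)
    expect_equal(ab$total, 1.2)
    expect_equal(sum(unlist(ab$contributions)), ab$total)
    # A-C flips sign between specimens -> excluded from the consistent set
    expect_identical(agg$consistent$sigY, "B")

    one <- aggregatePairs(pairs[pairs$specimen == "s1", ])
    expect_equal(nrow(one$consistent), 2L)
})

test_that("opposing planted gradients yield a negative cor_st pair", {
    top <- recoverGradientPair(1)
    expect_false(is.null(top))
    expect_lt(top$corSt, 0)
    expect_identical(sort(c(top$sigX, top$sigY)),
                     sort(c("invasive", "B cell")))
})
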