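#' Configuration for a synthetic hex-lattice section
#'
#' Describes a Visium-like section with planted ground truth: rectangular
#' cluster footprints in array space, per-cluster elevated signatures,
#' monotone score gradients along an ordered cluster path, dense
#' proliferative/invasive enclaves, scattered single feature spots, and an
#' overdispersed (negative-binomial) UMI count model.
#'
#' @param nRows,nCols lattice extent (rows x spots per row).
#' @param pitch spot centre-to-centre distance in pixels.
#' @param clusterLayout named list: cluster id -> `list(rows = c(r0, r1),
#'   cols = c(j0, j1))`, inclusive 0-based ranges over lattice row index
#'   and within-row spot index. Spots not covered fall in
#'   `backgroundCluster`. Footprints of different clusters must not
#'   overlap.
#' @param signaturePlan data.frame with columns `cluster`, `signature`,
#'   `log2fc`: signature genes get their negative-binomial mean multiplied
#'   by `2^log2fc` inside the cluster footprint.
#' @param gradientPlan `NULL`, or `list(path = <ordered cluster ids>,
#'   signatures = data.frame(signature, direction, t0, t1, log2fc))` with
#'   `direction` in `"rising"`/`"falling"`: along the path (normalised
#'   position t from projecting spots onto the centroid polyline) the
#'   multiplier ramps from 1 to `2^log2fc` (rising) or the reverse
#'   (falling) across `[t0, t1]`.
#' @param enclavePlan `NULL` or data.frame with columns `class`
#'   (`"proliferative"`/`"invasive"`), `centerRow`, `centerCol` (array
#'   coordinates), `nSpots`, `log2fc`: the `nSpots` lattice spots nearest
#'   the centre (hex distance, deterministic tie-break) form a dense
#'   enclave whose class signatures are elevated.
#' @param scatterPlan `NULL` or data.frame with columns `class`, `n`,
#'   `log2fc`, `minDistance`: `n` isolated spots of the class, drawn
#'   uniformly among spots at hex distance `>= minDistance` from every
#'   enclave spot and pairwise non-adjacent.
#' @param noise list with `meanLog`, `sdLog` (log-normal draw of per-gene
#'   baseline means) and `dispersion` (NB dispersion; 0 = Poisson).
#' @param nBackgroundGenes number of unplanted background genes.
#' @param backgroundCluster label of uncovered spots.
#' @param seed integer seed; identical seeds reproduce identical sections.
#' @return a validated list of class `section_config`.
#' @export
sectionConfig <- function(nRows = 20L, nCols = 20L, pitch = 100,
                          clusterLayout = list(),
                          signaturePlan = NULL,
                          gradientPlan = NULL,
                          enclavePlan = NULL,
                          scatterPlan = NULL,
                          noise = list(meanLog = 0, sdLog = 0.6,
                                       dispersion = 0.5),
                          nBackgroundGenes = 150L,
                          backgroundCluster = "c0",
                          seed = 1L) {
    stopifnot(nRows >= 1, nCols >= 1)
    if (nRows * nCols <= 0) stop("section must contain at least one spot")
    # different clusters must not claim the same lattice cell
    if (length(clusterLayout) > 1) {
        cells <- lapply(clusterLayout, function(fp) {
            expand.grid(r = fp$rows[1]:fp$rows[2], j = fp$cols[1]:fp$cols[2])
        })
        ids <- rep(names(clusterLayout), vapply(cells, nrow, 1L))
        cells <- do.call(rbind, cells)
        key <- paste(cells$r, cells$j)
        if (any(tapply(ids, key, function(x) length(unique(x))) > 1L))
            stop("overlapping footprints of different clusters in clusterLayout")
    }
    if (!is.null(enclavePlan)) {
        bad <- enclavePlan$centerRow < 0 | enclavePlan$centerRow >= nRows |
            enclavePlan$centerCol < 0 | enclavePlan$centerCol >= 2L * nCols
        if (any(bad))
            stop("enclave centre outside the lattice")
        if (!all(enclavePlan$class %in% c("proliferative", "invasive")))
            stop("enclave class must be proliferative or invasive")
    }
    structure(list(nRows = as.integer(nRows), nCols = as.integer(nCols),
                   pitch = pitch, clusterLayout = clusterLayout,
                   signaturePlan = signaturePlan,
                   gradientPlan = gradientPlan, enclavePlan = enclavePlan,
                   scatterPlan = scatterPlan, noise = noise,
                   nBackgroundGenes = as.integer(nBackgroundGenes),
                   backgroundCluster = backgroundCluster,
                   seed = as.integer(seed)),
              class = "section_config")
}

.rampMultiplier <- function(t, direction, t0, t1, log2fc) {
    ramp <- pmin(1, pmax(0, (t - t0) / (t1 - t0)))
    if (direction == "falling") ramp <- 1 - ramp
    2 ^ (log2fc * ramp)
}

#' Generate a synthetic section with recorded ground truth
#'
#' Samples a gene x spot count matrix from the configured layout. Cluster,
#' enclave, scatter and gradient effects act multiplicatively on the
#' per-gene negative-binomial mean; counts are drawn once, so identical
#' seeds yield bit-identical sections. Ground truth (true cluster, true
#' feature class per spot, planted enclave memberships, gradient intervals
#' and each spot's planted trajectory position) is stored in
#' `metadata(x)$groundTruth`.
#'
#' @param config a [sectionConfig()].
#' @param signatures the [SignatureSet] the plans refer to.
#' @return a [SpotExperiment] with a `counts` assay, cluster labels in
#'   `colData`, and ground truth in metadata.
#' @export
genSection <- function(config, signatures = defaultSignatures()) {
    stopifnot(inherits(config, "section_config"))
    planned <- unique(c(config$signaturePlan$signature,
                        config$gradientPlan$signatures$signature))
    unknown <- setdiff(planned, signatureNames(signatures))
    if (length(unknown))
        stop("plan references unknown signature(s): ",
             paste(unknown, collapse = ", "))

    grid <- hexGrid(config$nRows, config$nCols, config$pitch)
    grid$j <- (grid$array_col - grid$array_row %% 2L) %/% 2L
    nS <- nrow(grid)

    # cluster assignment from rectangular footprints
    cluster <- rep(config$backgroundCluster, nS)
    for (id in names(config$clusterLayout)) {
        fp <- config$clusterLayout[[id]]
        sel <- grid$array_row >= fp$rows[1] & grid$array_row <= fp$rows[2] &
            grid$j >= fp$cols[1] & grid$j <= fp$cols[2]
        cluster[sel] <- id
    }

    sigGenes <- unique(unlist(signatures@signatures))
    genes <- c(sigGenes,
               sprintf("BG%04d", seq_len(config$nBackgroundGenes)))

    .withSeed(config$seed, {
        baseMean <- stats::rlnorm(length(genes), config$noise$meanLog,
                                  config$noise$sdLog)
        names(baseMean) <- genes
        mult <- matrix(1, nrow = length(genes), ncol = nS,
                       dimnames = list(genes, grid$spot_id))

        # per-cluster elevated signatures
        sp <- config$signaturePlan
        if (!is.null(sp)) for (k in seq_len(nrow(sp))) {
            gs <- intersect(signatureGenes(signatures, sp$signature[k]), genes)
            sel <- cluster == sp$cluster[k]
            mult[gs, sel] <- mult[gs, sel] * 2 ^ sp$log2fc[k]
        }

        # dense enclaves: nearest nSpots around the centre, feature class set
        feature <- rep("unassigned", nS)
        enclaves <- list()
        ep <- config$enclavePlan
        if (!is.null(ep)) for (k in seq_len(nrow(ep))) {
            d <- hexDistance(grid$array_row, grid$array_col,
                             ep$centerRow[k], ep$centerCol[k])
            if (ep$nSpots[k] > nS)
                stop("enclave footprint does not fit inside the lattice")
            ord <- order(d, grid$array_row, grid$array_col)
            members <- ord[seq_len(ep$nSpots[k])]
            feature[members] <- ep$class[k]
            cls <- names(which(signatureClass(signatures) == ep$class[k]))
            gs <- intersect(unique(unlist(signatures@signatures[cls])), genes)
            mult[gs, members] <- mult[gs, members] * 2 ^ ep$log2fc[k]
            enclaves[[k]] <- list(class = ep$class[k],
                                  spots = grid$spot_id[members])
        }

        # scattered single feature spots, away from enclaves, non-adjacent
        scatter <- list()
        stp <- config$scatterPlan
        if (!is.null(stp)) for (k in seq_len(nrow(stp))) {
            enclaveSpots <- unlist(lapply(enclaves, `[[`, "spots"))
            free <- which(feature == "unassigned")
            if (length(enclaveSpots)) {
                ei <- match(enclaveSpots, grid$spot_id)
                dmin <- apply(hexDistance(grid$array_row[free],
                                          grid$array_col[free],
                                          grid$array_row[ei],
                                          grid$array_col[ei]), 1, min)
                free <- free[dmin >= stp$minDistance[k]]
            }
            chosen <- integer(0)
            cand <- sample(free)
            for (s in cand) {
                if (length(chosen) >= stp$n[k]) break
                if (!length(chosen) ||
                    min(hexDistance(grid$array_row[chosen],
                                    grid$array_col[chosen],
                                    grid$array_row[s],
                                    grid$array_col[s])) > 2)
                    chosen <- c(chosen, s)
            }
            feature[chosen] <- stp$class[k]
            cls <- names(which(signatureClass(signatures) == stp$class[k]))
            gs <- intersect(unique(unlist(signatures@signatures[cls])), genes)
            mult[gs, chosen] <- mult[gs, chosen] * 2 ^ stp$log2fc[k]
            scatter[[stp$class[k]]] <- grid$spot_id[chosen]
        }

        # monotone gradients along the planted cluster path
        spotT <- rep(NA_real_, nS)
        gp <- config$gradientPlan
        if (!is.null(gp)) {
            cent <- t(vapply(gp$path, function(id) {
                sel <- cluster == id
                if (!any(sel)) stop("gradient path cluster has no spots: ", id)
                c(mean(grid$pixel_x[sel]), mean(grid$pixel_y[sel]))
            }, numeric(2)))
            onPath <- cluster %in% gp$path
            pr <- .projectToPolyline(cbind(grid$pixel_x[onPath],
                                           grid$pixel_y[onPath]), cent)
            spotT[onPath] <- pr$t
            gs <- gp$signatures
            for (k in seq_len(nrow(gs))) {
                gg <- intersect(signatureGenes(signatures, gs$signature[k]),
                                genes)
                m <- .rampMultiplier(spotT[onPath], gs$direction[k],
                                     gs$t0[k], gs$t1[k], gs$log2fc[k])
                mult[gg, onPath] <- mult[gg, onPath] *
                    rep(m, each = length(gg))
            }
        }

        mu <- baseMean * mult
        disp <- config$noise$dispersion
        counts <- if (disp > 0) {
            matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / disp),
                   nrow = length(genes), dimnames = dimnames(mult))
        } else {
            matrix(stats::rpois(length(mu), lambda = mu),
                   nrow = length(genes), dimnames = dimnames(mult))
        }

        truth <- list(cluster = stats::setNames(cluster, grid$spot_id),
                      feature = stats::setNames(feature, grid$spot_id),
                      enclaves = enclaves, scatter = scatter,
                      gradients = if (is.null(gp)) NULL else gp$signatures,
                      path = if (is.null(gp)) NULL else gp$path,
                      spotT = stats::setNames(spotT, grid$spot_id))

        grid$j <- NULL
        grid$cluster <- cluster
        SpotExperiment(counts, grid,
                       metadata = list(groundTruth = truth, config = config))
    })
}

# ---------------------------------------------------------------------------
# canned study conditions used by the recovery experiments
# ---------------------------------------------------------------------------

#' Canned section: opposing score gradients along a cluster path
#'
#' Eight block clusters tiling a 30 x 30 lattice, visited by a snaking
#' trajectory c1 -> ... -> c8 (down one column block, across, up the
#' next), as spatial tumor-progression paths typically wind through a
#' section. Along the path's normalised position t, the invasive
#' signature rises and the B-cell signature falls (log2 fold change 2)
#' across the same interval [0.2, 0.8]. This is the standard fixture for
#' trajectory-landscape recovery: the pipeline should report the
#' (invasive, B cell) pair with negative cor_st.
#'
#' @param seed integer seed.
#' @return a [sectionConfig()].
#' @export
gradientSectionConfig <- function(seed = 1L) {
    colBlocks <- list(c(0, 7), c(8, 14), c(15, 22), c(23, 29))
    topRows <- c(0, 14); bottomRows <- c(15, 29)
    layout <- list(
        c1 = list(rows = topRows,    cols = colBlocks[[1]]),
        c2 = list(rows = bottomRows, cols = colBlocks[[1]]),
        c3 = list(rows = bottomRows, cols = colBlocks[[2]]),
        c4 = list(rows = topRows,    cols = colBlocks[[2]]),
        c5 = list(rows = topRows,    cols = colBlocks[[3]]),
        c6 = list(rows = bottomRows, cols = colBlocks[[3]]),
        c7 = list(rows = bottomRows, cols = colBlocks[[4]]),
        c8 = list(rows = topRows,    cols = colBlocks[[4]]))
    sectionConfig(
        nRows = 30L, nCols = 30L,
        clusterLayout = layout,
        gradientPlan = list(
            path = paste0("c", 1:8),
            signatures = data.frame(
                signature = c("invasive", "B cell"),
                direction = c("rising", "falling"),
                t0 = 0.2, t1 = 0.8, log2fc = 2)),
        seed = seed)
}

#' Canned section: one dense invasive enclave plus scattered spots
#'
#' A 40 x 40 lattice with a 40-spot invasive enclave (log2 fold change 2 on
#' invasive signature genes) and 5 scattered isolated invasive spots far
#' from it. Standard fixture for possibly-malignant region recovery.
#'
#' @param seed integer seed.
#' @param nEnclaveSpots enclave size (default 40).
#' @param nScatter number of scattered invasive spots (default 5).
#' @return a [sectionConfig()].
#' @export
enclaveSectionConfig <- function(seed = 1L, nEnclaveSpots = 40L,
                                 nScatter = 5L) {
    sectionConfig(
        nRows = 40L, nCols = 40L,
        enclavePlan = data.frame(class = "invasive", centerRow = 20,
                                 centerCol = 40, nSpots = nEnclaveSpots,
                                 log2fc = 2),
        scatterPlan = if (nScatter > 0)
            data.frame(class = "invasive", n = nScatter, log2fc = 2,
                       minDistance = 12) else NULL,
        seed = seed)
}

# ---------------------------------------------------------------------------
# mask pairs
# ---------------------------------------------------------------------------

#' Generate a registered pair of binary masks with known transform
#'
#' Draws an asymmetric tissue blob (union of random discs around an
#' ellipse), renders it as mask A together with `nFiducials` small
#' disc-shaped fiducial artifacts in the border frame (emulating the
#' printed alignment dots around a capture area), and produces mask B by
#' applying the requested similarity transform to the blob alone.  The
#' true transform, the fiducial geometry and the de-fiducialed content
#' mask are returned as ground truth.
#'
#' @param shape raster dimensions c(ny, nx) in pixels.
#' @param scale,thetaDeg,tx,ty the true A-to-B similarity transform
#'   (about the raster centre); `|thetaDeg| <= 180`, `scale > 0`.
#' @param nFiducials number of fiducial discs on mask A.
#' @param seed integer seed.
#' @return list with logical matrices `maskA`, `maskB` and `truth` (the
#'   [similarityTransform()], `content` mask, fiducial centres/radius).
#' @export
genMaskPair <- function(shape = c(192L, 192L), scale = 1, thetaDeg = 0,
                        tx = 0, ty = 0, nFiducials = 0L, seed = 1L) {
    stopifnot(abs(thetaDeg) <= 180, scale > 0)
    ny <- shape[1]; nx <- shape[2]
    .withSeed(seed, {
        # asymmetric blob: ellipse plus satellite discs, kept off-centre
        cx <- nx * 0.45; cy <- ny * 0.55
        xs <- matrix(rep(seq_len(nx), each = ny), ny)
        ys <- matrix(rep(seq_len(ny), nx), ny)
        a <- nx * 0.18; b <- ny * 0.26; phi <- stats::runif(1, 0, pi)
        xr <- (xs - cx) * cos(phi) + (ys - cy) * sin(phi)
        yr <- -(xs - cx) * sin(phi) + (ys - cy) * cos(phi)
        content <- (xr / a)^2 + (yr / b)^2 <= 1
        nd <- 5L
        ang <- stats::runif(nd, 0, 2 * pi)
        rad <- stats::runif(nd, 0.06, 0.14) * min(nx, ny)
        dd <- stats::runif(nd, 0.6, 1.15)
        for (k in seq_len(nd)) {
            dcx <- cx + cos(ang[k]) * dd[k] * a * 1.4
            dcy <- cy + sin(ang[k]) * dd[k] * b * 1.2
            content <- content | ((xs - dcx)^2 + (ys - dcy)^2 <= rad[k]^2)
        }

        tf <- similarityTransform(scale, thetaDeg, tx, ty,
                                  center = c((nx + 1) / 2, (ny + 1) / 2))
        maskB <- transformMask(content, tf, dim = c(ny, nx))
        if (!any(maskB))
            stop("transform maps the tissue fully outside the raster")

        maskA <- content
        fid <- NULL
        fidRadius <- round(min(nx, ny) * 0.02)
        if (nFiducials > 0) {
            margin <- round(min(nx, ny) * 0.06)
            per <- seq(0, 1, length.out = nFiducials + 1L)[-1L]
            fx <- fy <- numeric(nFiducials)
            for (k in seq_len(nFiducials)) {
                p <- per[k] * 4
                if (p <= 1) { fx[k] <- margin + p * (nx - 2 * margin); fy[k] <- margin }
                else if (p <= 2) { fx[k] <- nx - margin; fy[k] <- margin + (p - 1) * (ny - 2 * margin) }
                else if (p <= 3) { fx[k] <- nx - margin - (p - 2) * (nx - 2 * margin); fy[k] <- ny - margin }
                else { fx[k] <- margin; fy[k] <- ny - margin - (p - 3) * (ny - 2 * margin) }
                maskA <- maskA | ((xs - fx[k])^2 + (ys - fy[k])^2 <= fidRadius^2)
            }
            fid <- data.frame(x = fx, y = fy, radius = fidRadius)
        }
        list(maskA = maskA, maskB = maskB,
             truth = list(transform = tf, content = content,
                          fiducials = fid))
    })
}

# ---------------------------------------------------------------------------
# cell intensity tables
# ---------------------------------------------------------------------------

#' Generate a segmented-cell marker intensity table with planted outliers
#'
#' Per-cell, per-marker mean intensities are drawn log-normally; a fraction
#' of cells is planted as total-intensity outliers (all markers multiplied
#' by `outlierFactor`), emulating segmentation artifacts that the
#' percentile filter is meant to remove.
#'
#' @param nCells number of cells (>= 10).
#' @param nMarkers number of markers.
#' @param outlierFraction fraction in [0, 0.5) of planted outlier cells.
#' @param seed integer seed.
#' @param outlierFactor multiplicative inflation of outlier cells.
#' @return list with `table` (data.frame: cell_id, x, y, one column per
#'   marker) and `outliers` (named logical ground-truth flags).
#' @export
genCellTable <- function(nCells, nMarkers = 10L, outlierFraction = 0,
                         seed = 1L, outlierFactor = 8) {
    if (nCells < 10)
        stop("need at least 10 cells for a defined percentile filter")
    if (outlierFraction < 0 || outlierFraction >= 0.5)
        stop("outlierFraction must be in [0, 0.5)")
    .withSeed(seed, {
        markers <- sprintf("MK%02d", seq_len(nMarkers))
        base <- matrix(stats::rlnorm(nCells * nMarkers, log(50), 0.4),
                       nrow = nCells, dimnames = list(NULL, markers))
        nOut <- floor(nCells * outlierFraction)
        flags <- rep(FALSE, nCells)
        if (nOut > 0) {
            idx <- sample.int(nCells, nOut)
            base[idx, ] <- base[idx, ] * outlierFactor
            flags[idx] <- TRUE
        }
        ids <- sprintf("CELL%05d", seq_len(nCells))
        tab <- data.frame(cell_id = ids,
                          x = stats::runif(nCells, 0, 1000),
                          y = stats::runif(nCells, 0, 1000),
                          base, check.names = FALSE)
        list(table = tab, outliers = stats::setNames(flags, ids))
    })
}
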