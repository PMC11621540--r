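# nearest-point projection of points onto a polyline; returns normalised
# arc-length position t and perpendicular distance. Exact ties in distance
# resolve to the lower t.
.projectToPolyline <- function(points, vertices) {
    seg <- diff(vertices)
    segLen <- sqrt(rowSums(seg^2))
    if (any(segLen == 0)) stop("coincident consecutive vertices")
    cum <- c(0, cumsum(segLen))
    total <- cum[length(cum)]
    n <- nrow(points)
    bestD <- rep(Inf, n); bestT <- rep(NA_real_, n)
    for (k in seq_len(nrow(seg))) {
        v <- seg[k, ]
        rel <- sweep(points, 2, vertices[k, ])
        u <- pmin(1, pmax(0, as.vector(rel %*% v) / segLen[k]^2))
        px <- vertices[k, 1] + u * v[1]
        py <- vertices[k, 2] + u * v[2]
        d <- sqrt((points[, 1] - px)^2 + (points[, 2] - py)^2)
        tk <- (cum[k] + u * segLen[k]) / total
        better <- d < bestD - 1e-12 |
            (abs(d - bestD) <= 1e-12 & tk < bestT)
        bestD[better] <- d[better]
        bestT[better] <- tk[better]
    }
    list(t = bestT, dist = bestD, totalLength = total)
}

#' Build a spatial trajectory through ordered cluster centroids
#'
#' Connects the pixel-space centroid of each cluster in the user-supplied
#' order (the cluster order is a manual input, typically derived from a
#' pseudotime analysis plus inspection of the spatial plot) into a
#' polyline whose cumulative arc length is normalised to t in [0, 1].
#'
#' @param x a [SpotExperiment] with cluster labels.
#' @param clusterOrder character vector (>= 2) of cluster ids, root first.
#' @return a [TrajectoryPath].
#' @export
buildTrajectory <- function(x, clusterOrder) {
    clusterOrder <- as.character(clusterOrder)
    if (length(clusterOrder) < 2L)
        stop("a trajectory needs at least 2 clusters")
    cl <- spotClusters(x)
    if (is.null(cl)) stop("x carries no cluster labels")
    px <- pixelCoords(x)
    vertices <- t(vapply(clusterOrder, function(id) {
        sel <- cl == id
        if (!any(sel)) stop("cluster has no spots: ", id)
        colMeans(px[sel, , drop = FALSE])
    }, numeric(2)))
    seg <- diff(vertices)
    segLen <- sqrt(rowSums(seg^2))
    if (any(segLen == 0))
        stop("coincident consecutive cluster centroids")
    cum <- unname(c(0, cumsum(segLen)))
    new("TrajectoryPath", clusterIds = unname(clusterOrder),
        vertices = vertices, tVertex = cum / cum[length(cum)],
        totalLength = cum[length(cum)])
}

#' Project spots onto a trajectory corridor
#'
#' Each spot maps to the normalised position t of its nearest point on the
#' trajectory polyline if its perpendicular distance does not exceed
#' `corridorWidth`; farther spots are excluded. Nearest-segment
#' assignment; exact distance ties resolve to the lower t.
#'
#' @param path a [TrajectoryPath].
#' @param x the [SpotExperiment] the path was built on.
#' @param corridorWidth corridor half-width in pixels; default (NULL) is
#'   twice the spot pitch.
#' @return [S4Vectors::DataFrame] with per-spot `t`, `dist`, `included`.
#' @export
projectSpots <- function(path, x, corridorWidth = NULL) {
    if (is.null(corridorWidth)) corridorWidth <- 2 * spotPitch(x)
    if (corridorWidth <= 0) stop("corridorWidth must be > 0")
    pr <- .projectToPolyline(pixelCoords(x), path@vertices)
    DataFrame(t = pr$t, dist = pr$dist,
              included = pr$dist <= corridorWidth,
              row.names = colnames(x))
}

#' Extract and smooth per-signature score profiles along a trajectory
#'
#' Bins included spots into `nBins` equal-length t bins, averages each
#' signature's score per bin, fills empty bins by linear interpolation
#' from their neighbours, and smooths with a centred moving average of odd
#' width `window` (shrinking symmetrically at the profile edges, so a
#' constant profile is preserved exactly).
#'
#' @param scores a [ScoreTable].
#' @param projection output of [projectSpots()] for the same spots.
#' @param nBins number of bins partitioning [0, 1] (default 100).
#' @param window odd moving-average width (default 5); 1 disables
#'   smoothing.
#' @param signatures optional character subset of signatures.
#' @return named list (per signature) of data.frames with `bin`, `tMid`,
#'   `nSpots`, `raw`, `smoothed`.
#' @export
extractProfile <- function(scores, projection, nBins = 100L, window = 5L,
                           signatures = NULL) {
    if (window %% 2L != 1L) stop("window must be odd")
    sm <- scoreMatrix(scores)
    keep <- projection$included & !is.na(projection$t)
    if (!any(keep)) stop("no spots projected onto the trajectory")
    t <- projection$t[keep]
    sm <- sm[keep, , drop = FALSE]
    bin <- pmin(as.integer(floor(t * nBins)) + 1L, nBins)
    occupied <- tabulate(bin, nBins) > 0L
    if (sum(occupied) < nBins / 2)
        stop("fewer than half of the trajectory bins contain spots")
    if (is.null(signatures)) signatures <- colnames(sm)
    tMid <- (seq_len(nBins) - 0.5) / nBins
    half <- (window - 1L) %/% 2L
    out <- lapply(signatures, function(nm) {
        raw <- rep(NA_real_, nBins)
        agg <- tapply(sm[, nm], bin, mean)
        raw[as.integer(names(agg))] <- agg
        if (anyNA(raw))    # interpolate empty bins from flanking bins
            raw <- stats::approx(tMid[!is.na(raw)], raw[!is.na(raw)],
                                 xout = tMid, rule = 2)$y
        smoothed <- vapply(seq_len(nBins), function(i) {
            h <- min(half, i - 1L, nBins - i)   # symmetric edge shrink
            mean(raw[(i - h):(i + h)])
        }, 0)
        data.frame(bin = seq_len(nBins), tMid = tMid,
                   nSpots = tabulate(bin, nBins), raw = raw,
                   smoothed = smoothed)
    })
    names(out) <- signatures
    out
}

#' Detect TME-change segments from a smoothed score profile
#'
#' Breakpoints are the profile endpoints plus every trend reversal of the
#' smoothed series (bins where the sign of the first difference changes,
#' including into or out of flat stretches). Between consecutive
#' breakpoints the segment slope is the score change divided by the t
#' span; segments whose |slope| reaches `slopeThreshold` are reported as
#' TME changes.
#'
#' @param profile one profile data.frame from [extractProfile()].
#' @param slopeThreshold minimum |slope| (score units per unit t).
#' @param signature optional signature name recorded in the output.
#' @return data.frame of segments: `signature`, `t0`, `t1`, `v0`, `v1`,
#'   `slope`, `sign`, ordered by t and non-overlapping.
#' @export
findChangeSegments <- function(profile, slopeThreshold = 0.02,
                               signature = NA_character_) {
    v <- profile$smoothed
    t <- profile$tMid
    d <- sign(diff(v))
    empty <- data.frame(signature = character(0), t0 = numeric(0),
                        t1 = numeric(0), v0 = numeric(0), v1 = numeric(0),
                        slope = numeric(0), sign = integer(0))
    if (!length(d) || all(d == 0)) return(empty)
    breaks <- c(1L, which(d[-1] != d[-length(d)]) + 1L, length(v))
    breaks <- unique(breaks)
    segs <- lapply(seq_len(length(breaks) - 1L), function(k) {
        i0 <- breaks[k]; i1 <- breaks[k + 1L]
        slope <- (v[i1] - v[i0]) / (t[i1] - t[i0])
        data.frame(signature = signature, t0 = t[i0], t1 = t[i1],
                   v0 = v[i0], v1 = v[i1], slope = slope,
                   sign = as.integer(sign(slope)))
    })
    segs <- do.call(rbind, segs)
    segs <- segs[abs(segs$slope) >= slopeThreshold, , drop = FALSE]
    rownames(segs) <- NULL
    segs
}

#' Signed association score of two co-located TME changes
#'
#' The magnitude is the sum of the absolute slopes of the two changes;
#' the sign is positive when the slopes agree in direction (both rising
#' or both falling) and negative when they oppose. The printed definition
#' covers slopes of equal and of opposite sign with one rising; the
#' both-falling case follows the same agreement rule (documented
#' extension).
#'
#' @param slopeX,slopeY finite non-zero slopes of the paired changes.
#' @return signed numeric, vectorised over its arguments.
#' @export
corSt <- function(slopeX, slopeY) {
    ifelse(sign(slopeX) == sign(slopeY), 1, -1) *
        (abs(slopeX) + abs(slopeY))
}

#' Pair overlapping TME changes on one trajectory
#'
#' Two change segments of different signatures form a TME pair when their
#' t intervals overlap with positive length; touching intervals (zero
#' overlap) do not pair. Each pair carries the overlap interval, its
#' length, and the signed [corSt()] association score.
#'
#' @param segments data.frame of segments (from [findChangeSegments()],
#'   possibly rbind-ed across signatures) from a single trajectory.
#' @return data.frame with one row per pair: `sigX`, `sigY`, `overlapT0`,
#'   `overlapT1`, `overlapLength`, `slopeX`, `slopeY`, `corSt`.
#' @export
pairChanges <- function(segments) {
    empty <- data.frame(sigX = character(0), sigY = character(0),
                        overlapT0 = numeric(0), overlapT1 = numeric(0),
                        overlapLength = numeric(0), slopeX = numeric(0),
                        slopeY = numeric(0), corSt = numeric(0))
    if (is.null(segments) || nrow(segments) < 2L) return(empty)
    out <- list()
    for (i in seq_len(nrow(segments) - 1L)) for (j in (i + 1L):nrow(segments)) {
        if (identical(segments$signature[i], segments$signature[j])) next
        o0 <- max(segments$t0[i], segments$t0[j])
        o1 <- min(segments$t1[i], segments$t1[j])
        if (o1 - o0 <= 0) next
        # report with signatures in a canonical (sorted) order
        ij <- if (segments$signature[i] <= segments$signature[j])
            c(i, j) else c(j, i)
        out[[length(out) + 1L]] <- data.frame(
            sigX = segments$signature[ij[1]],
            sigY = segments$signature[ij[2]],
            overlapT0 = o0, overlapT1 = o1, overlapLength = o1 - o0,
            slopeX = segments$slope[ij[1]], slopeY = segments$slope[ij[2]],
            corSt = corSt(segments$slope[ij[1]], segments$slope[ij[2]]))
    }
    if (!length(out)) return(empty)
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Aggregate TME pairs across trajectories and specimens
#'
#' Sums per-specimen cor_st contributions for every feature pair and
#' separates the pairs whose association keeps one sign across every
#' trajectory they appear on (the consistent set); the full table is
#' returned alongside.
#'
#' @param pairs data.frame of TME pairs (rbind of [pairChanges()]
#'   outputs) with an added `specimen` column.
#' @return list with `full` (per pair x specimen contributions and the
#'   pair total) and `consistent` (pairs with a single association sign
#'   across all observations).
#' @export
aggregatePairs <- function(pairs) {
    stopifnot("specimen" %in% colnames(pairs))
    if (!nrow(pairs))
        return(list(full = pairs, consistent = pairs))
    key <- paste(pairs$sigX, pairs$sigY, sep = " || ")
    rows <- lapply(split(seq_len(nrow(pairs)), key), function(i) {
        contrib <- tapply(pairs$corSt[i], pairs$specimen[i], sum)
        data.frame(sigX = pairs$sigX[i[1]], sigY = pairs$sigY[i[1]],
                   nTrajectories = length(i),
                   consistent = length(unique(sign(pairs$corSt[i]))) == 1L,
                   total = sum(pairs$corSt[i]),
                   contributions = I(list(contrib)))
    })
    full <- do.call(rbind, rows)
    rownames(full) <- NULL
    list(full = full,
         consistent = full[full$consistent, , drop = FALSE])
}
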