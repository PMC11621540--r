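#' Apply a similarity transform to point coordinates
#'
#' Forward order is scale, then rotation, then translation, about the
#' transform's centre: p' = s * R(theta) * (p - c) + c + t. The inverse
#' direction applies the exact algebraic inverse.
#'
#' @param transform a [similarityTransform()].
#' @param points numeric matrix (n x 2) of (x, y) coordinates.
#' @param direction `"forward"` (A to B) or `"inverse"`.
#' @return transformed n x 2 matrix.
#' @export
transformCoords <- function(transform, points,
                            direction = c("forward", "inverse")) {
    direction <- match.arg(direction)
    points <- matrix(as.numeric(points), ncol = 2)
    th <- transform@thetaDeg * pi / 180
    Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
    c_ <- transform@center
    t_ <- c(transform@tx, transform@ty)
    if (direction == "forward") {
        out <- transform@scale * t(Rm %*% t(sweep(points, 2, c_)))
        sweep(out, 2, c_ + t_, "+")
    } else {
        rel <- sweep(points, 2, c_ + t_)
        out <- t(t(Rm) %*% t(rel)) / transform@scale
        sweep(out, 2, c_, "+")
    }
}

#' Resample a binary mask under a similarity transform
#'
#' Produces the transformed mask on a target raster by inverse mapping
#' with nearest-neighbour sampling, keeping the operation set-based (no
#' gray fringe), which is what the IoU alignment objective assumes.
#'
#' @param mask logical matrix, row = y, column = x.
#' @param transform a [similarityTransform()] (applied forward).
#' @param dim output raster c(ny, nx); defaults to `dim(mask)`.
#' @return logical matrix of dimension `dim`.
#' @export
transformMask <- function(mask, transform, dim = base::dim(mask)) {
    ny <- dim[1]; nx <- dim[2]
    xs <- rep(seq_len(nx), each = ny)
    ys <- rep(seq_len(ny), nx)
    src <- transformCoords(transform, cbind(xs, ys), "inverse")
    xi <- round(src[, 1]); yi <- round(src[, 2])
    ok <- xi >= 1 & xi <= ncol(mask) & yi >= 1 & yi <= nrow(mask)
    out <- matrix(FALSE, ny, nx)
    out[cbind(ys[ok], xs[ok])] <- mask[cbind(yi[ok], xi[ok])]
    out
}

#' Intersection over union of two binary masks
#'
#' @param a,b logical matrices of equal dimension.
#' @return IoU in [0, 1]; 0 when the union is empty.
#' @export
maskIoU <- function(a, b) {
    u <- sum(a | b)
    if (u == 0) return(0)
    sum(a & b) / u
}

#' Binarise a modality image into a registration mask
#'
#' H&E path: collapse channels to grayscale, Otsu-threshold (foreground
#' side configurable), then detect and remove fiducial artifacts — small,
#' near-circular foreground components whose centroid lies in the border
#' frame — and drop sub-speck components. Multiplexed path: pixelwise
#' maximum of the selected channels, then Otsu threshold (bright
#' foreground).
#'
#' @param image numeric matrix (grayscale) or ny x nx x channel array,
#'   values in [0, 1], row = y.
#' @param modality `"he"` or `"multiplexed"`.
#' @param channels channel indices used by the multiplexed path (default
#'   all).
#' @param foreground `"bright"` or `"dark"`: which side of the H&E
#'   threshold is tissue.
#' @param fiducial list of detector bounds: `minSize`/`maxSize` (px
#'   area), `minCircularity` (4*pi*A/P^2), `borderFrac` (border-band
#'   width as fraction of the short raster side).
#' @param minSpeck foreground components smaller than this many pixels
#'   are removed as noise.
#' @return logical mask (row = y), with attribute `removedFiducials` =
#'   number of components removed by the fiducial detector.
#' @export
makeMask <- function(image, modality = c("he", "multiplexed"),
                     channels = NULL, foreground = c("bright", "dark"),
                     fiducial = list(minSize = 4, maxSize = 400,
                                     minCircularity = 0.6,
                                     borderFrac = 0.12),
                     minSpeck = 4) {
    modality <- match.arg(modality)
    foreground <- match.arg(foreground)
    if (modality == "multiplexed") {
        if (length(dim(image)) == 3) {
            if (is.null(channels)) channels <- seq_len(dim(image)[3])
            gray <- apply(image[, , channels, drop = FALSE], c(1, 2), max)
        } else gray <- image
        thr <- EBImage::otsu(t(gray))
        mask <- gray > thr
    } else {
        gray <- if (length(dim(image)) == 3) apply(image, c(1, 2), mean)
                else image
        thr <- EBImage::otsu(t(gray))
        mask <- if (foreground == "bright") gray > thr else gray < thr
    }
    if (!any(mask)) stop("empty foreground after thresholding")

    # component bookkeeping in EBImage's [x, y] convention
    lab <- EBImage::bwlabel(t(mask))
    nRemoved <- 0L
    if (max(lab) > 0) {
        shape <- EBImage::computeFeatures.shape(lab)
        mom <- EBImage::computeFeatures.moment(lab)
        area <- shape[, "s.area"]
        per <- pmax(shape[, "s.perimeter"], 1)
        circ <- pmin(4 * pi * area / per^2, 1.5)
        band <- fiducial$borderFrac * min(dim(mask))
        cx <- mom[, "m.cx"]; cy <- mom[, "m.cy"]
        nearBorder <- cx <= band | cy <= band |
            cx >= ncol(mask) - band | cy >= nrow(mask) - band
        isFiducial <- modality == "he" &
            area >= fiducial$minSize & area <= fiducial$maxSize &
            circ >= fiducial$minCircularity & nearBorder
        isSpeck <- area < minSpeck
        drop_ <- which(isFiducial | isSpeck)
        nRemoved <- sum(isFiducial)
        if (length(drop_)) {
            lab[lab %in% drop_] <- 0L
            mask <- t(lab > 0)
        }
    }
    if (!any(mask)) stop("empty foreground after cleanup")
    attr(mask, "removedFiducials") <- nRemoved
    mask
}

# block-maximum downsampling of a logical mask by integer factor
.downsampleMask <- function(mask, f) {
    ny <- floor(nrow(mask) / f) * f
    nx <- floor(ncol(mask) / f) * f
    m <- mask[seq_len(ny), seq_len(nx)]
    dim(m) <- c(f, ny / f, f, nx / f)
    apply(m, c(2, 4), any)
}

# best integer shift of a (transformed) mask onto b via FFT
# cross-correlation; returns list(dx, dy, overlap)
.bestShift <- function(a, b, maxShift) {
    ny <- nrow(a); nx <- ncol(a)
    P <- 2^ceiling(log2(max(ny, nx) + 2 * maxShift))
    pa <- pb <- matrix(0, P, P)
    pa[seq_len(ny), seq_len(nx)] <- a
    pb[seq_len(ny), seq_len(nx)] <- b
    cc <- Re(stats::fft(stats::fft(pb) * Conj(stats::fft(pa)),
                        inverse = TRUE)) / P^2
    sh <- c(0:(P / 2 - 1), -(P / 2):-1)
    okx <- abs(sh) <= maxShift; oky <- abs(sh) <= maxShift
    sub <- cc[oky, okx, drop = FALSE]
    best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    # A'(p) aligned with B(p + d): shifting A' by +d maximises overlap
    list(dy = sh[oky][best[1]], dx = sh[okx][best[2]],
         overlap = max(sub))
}

.alignObjective <- function(maskA, maskB, s, th, tx, ty, center) {
    tf <- similarityTransform(s, th, tx, ty, center = center)
    maskIoU(transformMask(maskA, tf, dim = dim(maskB)), maskB)
}

#' Align two binary masks by maximising intersection over union
#'
#' Coarse-to-fine search for the similarity transform mapping mask A onto
#' mask B: a grid over scale and rotation with the translation resolved
#' by FFT cross-correlation on block-downsampled masks, followed by a
#' shrinking-step pattern search on all four parameters at full
#' resolution. Deterministic given the search-space configuration. When
#' the achieved IoU stays below `minIoU` the result is flagged as a
#' failure rather than silently returned.
#'
#' @param maskA,maskB logical masks (row = y); A is moved onto B.
#' @param scaleRange,scaleStep coarse scale grid (default 0.8..1.25 by
#'   0.025).
#' @param thetaRange,thetaStep coarse rotation grid in degrees (default
#'   -20..20 by 1).
#' @param downsample integer block factor for the coarse stage.
#' @param maxShift largest translation magnitude searched, in full-res
#'   pixels.
#' @param minIoU acceptance floor for the achieved IoU.
#' @return list with `transform` ([similarityTransform()], A to B),
#'   `iou`, `ok` (logical), and the coarse-stage candidate.
#' @export
alignMasks <- function(maskA, maskB,
                       scaleRange = c(0.8, 1.25), scaleStep = 0.025,
                       thetaRange = c(-20, 20), thetaStep = 1,
                       downsample = 4L, maxShift = 40, minIoU = 0.5) {
    if (!any(maskA) || !any(maskB)) stop("masks must be non-empty")
    f <- as.integer(downsample)
    dsA <- .downsampleMask(maskA, f)
    dsB <- .downsampleMask(maskB, f)
    centerDs <- c((ncol(dsA) + 1) / 2, (nrow(dsA) + 1) / 2)
    center <- c((ncol(maskB) + 1) / 2, (nrow(maskB) + 1) / 2)
    sumB <- sum(dsB)

    scales <- seq(scaleRange[1], scaleRange[2], by = scaleStep)
    thetas <- seq(thetaRange[1], thetaRange[2], by = thetaStep)
    best <- list(iou = -1)
    for (s in scales) for (th in thetas) {
        tf <- similarityTransform(s, th, 0, 0, center = centerDs)
        tA <- transformMask(dsA, tf, dim = dim(dsB))
        sh <- .bestShift(tA, dsB, ceiling(maxShift / f))
        iou <- sh$overlap / (sum(tA) + sumB - sh$overlap)
        if (iou > best$iou)
            best <- list(s = s, th = th, dx = sh$dx * f, dy = sh$dy * f,
                         iou = iou)
    }

    # full-resolution pattern search, monotone in the objective
    par <- c(best$s, best$th, best$dx, best$dy)
    step <- c(scaleStep / 2, thetaStep / 2, f, f)
    minStep <- c(0.0025, 0.1, 0.5, 0.5)
    cur <- .alignObjective(maskA, maskB, par[1], par[2], par[3], par[4],
                           center)
    repeat {
        improved <- FALSE
        for (i in 1:4) for (dir in c(-1, 1)) {
            cand <- par
            cand[i] <- cand[i] + dir * step[i]
            # refinement stays inside the declared search space
            if (cand[1] < scaleRange[1] || cand[1] > scaleRange[2] ||
                cand[2] < thetaRange[1] || cand[2] > thetaRange[2] ||
                abs(cand[3]) > maxShift || abs(cand[4]) > maxShift) next
            val <- .alignObjective(maskA, maskB, cand[1], cand[2],
                                   cand[3], cand[4], center)
            if (val > cur) { par <- cand; cur <- val; improved <- TRUE }
        }
        if (!improved) {
            if (all(step <= minStep)) break
            step <- pmax(step / 2, minStep)
        }
    }
    tf <- similarityTransform(par[1], par[2], par[3], par[4],
                              center = center)
    list(transform = tf, iou = cur, ok = cur >= minIoU,
         coarse = best)
}

#' Positionally integrate cell (or pixel) signals with a spot section
#'
#' Maps each cell centroid from the partner modality's coordinates into
#' the spot image with the registered transform, assigns it to the
#' nearest spot within one spot radius (half the lattice pitch; farther
#' cells stay unassigned), and summarises mean marker intensity per spot.
#'
#' @param x a [SpotExperiment].
#' @param cells data.frame with `cell_id`, `x`, `y` and marker columns,
#'   in modality-B pixel coordinates.
#' @param alignment result of [alignMasks()] where A is the spot-image
#'   modality and B the cell modality; a failed alignment is refused.
#' @param markers marker column names (default: every numeric column
#'   except x/y).
#' @param maxRadius assignment radius in spot-image pixels (default half
#'   the spot pitch).
#' @return list with `cells` (input plus mapped coordinates and assigned
#'   `spot_id`) and `spotMeans` (spot x marker mean intensities for
#'   covered spots).
#' @export
mapSignals <- function(x, cells, alignment, markers = NULL,
                       maxRadius = NULL) {
    if (is.list(alignment) && !is.null(alignment$ok) && !alignment$ok)
        stop("refusing to map signals across a failed alignment")
    tf <- if (is(alignment, "SimilarityTransform")) alignment
          else alignment$transform
    if (is.null(markers))
        markers <- setdiff(colnames(cells)[vapply(cells, is.numeric, TRUE)],
                           c("x", "y"))
    if (is.null(maxRadius)) maxRadius <- spotPitch(x) / 2
    mapped <- transformCoords(tf, cbind(cells$x, cells$y), "inverse")
    px <- pixelCoords(x)
    # nearest spot within maxRadius
    assign_ <- vapply(seq_len(nrow(mapped)), function(i) {
        d2 <- (px[, 1] - mapped[i, 1])^2 + (px[, 2] - mapped[i, 2])^2
        j <- which.min(d2)
        if (sqrt(d2[j]) <= maxRadius) j else NA_integer_
    }, 1L)
    cells$mapped_x <- mapped[, 1]
    cells$mapped_y <- mapped[, 2]
    cells$spot_id <- ifelse(is.na(assign_), NA_character_,
                            colnames(x)[assign_])
    covered <- !is.na(assign_)
    spotMeans <- NULL
    if (any(covered)) {
        agg <- stats::aggregate(cells[covered, markers, drop = FALSE],
                                by = list(spot_id = cells$spot_id[covered]),
                                FUN = mean)
        spotMeans <- agg
    }
    list(cells = cells, spotMeans = spotMeans)
}
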