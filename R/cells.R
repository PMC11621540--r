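#' Remove total-intensity outlier cells
#'
#' Computes each cell's total signal (row sum over marker columns) and
#' removes cells whose total is at or above the 99th percentile or at or
#' below the 1st percentile of the totals — the standard guard against
#' segmentation artifacts (merged cells, debris) before clustering.
#' Percentiles use linear interpolation (`stats::quantile` type 7). When
#' the two percentiles coincide (essentially constant totals) filtering
#' is skipped with a warning, since the rule would be degenerate.
#'
#' @param cells data.frame with `cell_id` and numeric marker columns
#'   (any `x`/`y` centroid columns are ignored for the total).
#' @param lower,upper percentile probabilities (defaults 0.01 and 0.99).
#' @return list with `cells` (filtered table), `removed` (cell ids) and
#'   the percentile values used.
#' @export
filterOutlierCells <- function(cells, lower = 0.01, upper = 0.99) {
    if (nrow(cells) < 10L)
        stop("percentile filter undefined below 10 cells")
    markers <- setdiff(colnames(cells)[vapply(cells, is.numeric, TRUE)],
                       c("x", "y"))
    totals <- rowSums(cells[, markers, drop = FALSE])
    q <- stats::quantile(totals, c(lower, upper), type = 7, names = FALSE)
    if (q[1] == q[2]) {
        warning("1st and 99th percentile coincide; filtering skipped")
        return(list(cells = cells, removed = character(0),
                    q = q, totals = totals))
    }
    drop_ <- totals >= q[2] | totals <= q[1]
    list(cells = cells[!drop_, , drop = FALSE],
         removed = cells$cell_id[drop_], q = q, totals = totals)
}

#' Centred log-ratio normalisation of marker intensities
#'
#' Applies, per marker across cells (margin 2 in the usual toolchain
#' parlance), y = ln(1 + x) - mean over cells of ln(1 + x). log1p keeps
#' zero intensities defined; each normalised marker column has mean 0 by
#' construction. The alternative per-cell centring is available via
#' `margin = 1`.
#'
#' @param cells data.frame with `cell_id` and numeric marker columns.
#' @param margin 2 (default): centre each marker over cells; 1: centre
#'   each cell over markers.
#' @return the table with marker columns replaced by their CLR values.
#' @export
clrNormalize <- function(cells, margin = 2) {
    markers <- setdiff(colnames(cells)[vapply(cells, is.numeric, TRUE)],
                       c("x", "y"))
    m <- log1p(as.matrix(cells[, markers, drop = FALSE]))
    if (margin == 2)
        m <- sweep(m, 2, colMeans(m))
    else
        m <- sweep(m, 1, rowMeans(m))
    cells[, markers] <- m
    cells
}
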