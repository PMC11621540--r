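#' Hexagonal-lattice helpers
#'
#' The Visium array convention stores spots on a pointy-packed hex lattice
#' where `array_row` and `array_col` share parity: within a row, adjacent
#' spots differ by 2 in `array_col`, and the six ring-1 neighbours of
#' (r, c) are (r, c +/- 2) and (r +/- 1, c +/- 1). Converting to axial hex
#' coordinates q = (c - r) / 2, r makes the lattice graph distance a closed
#' form, which all neighbourhood statistics in the package share.
#'
#' @name hex-lattice
NULL

#' Build an empty hex spot grid
#'
#' @param nRows,nCols lattice extent: `nRows` rows with `nCols` spots each.
#' @param pitch centre-to-centre spot distance in pixels (default 100).
#' @return data.frame with spot_id, array_row, array_col, pixel_x, pixel_y,
#'   in_tissue.
#' @export
hexGrid <- function(nRows, nCols, pitch = 100) {
    stopifnot(nRows >= 1, nCols >= 1)
    i <- rep(seq_len(nRows) - 1L, each = nCols)
    j <- rep(seq_len(nCols) - 1L, times = nRows)
    col <- 2L * j + i %% 2L
    data.frame(
        spot_id = sprintf("SPOT-%04d-%04d", i, col),
        array_row = i, array_col = col,
        pixel_x = col * pitch / 2,
        pixel_y = i * pitch * sqrt(3) / 2,
        in_tissue = TRUE,
        stringsAsFactors = FALSE)
}

#' Hex-lattice graph distance between spot coordinate sets
#'
#' Vectorised over both arguments (outer combination when `b` has several
#' rows): distance 1 corresponds to the six ring-1 neighbours.
#'
#' @param rowA,colA integer vectors of array coordinates.
#' @param rowB,colB integer vectors of array coordinates.
#' @return if `length(rowB) == 1`, a vector of distances from each A spot;
#'   otherwise a `length(rowA)` x `length(rowB)` matrix.
#' @export
hexDistance <- function(rowA, colA, rowB, colB) {
    qA <- (colA - rowA) / 2; rA <- rowA
    qB <- (colB - rowB) / 2; rB <- rowB
    if (length(rB) == 1L) {
        dq <- qA - qB; dr <- rA - rB
        return((abs(dq) + abs(dr) + abs(dq + dr)) / 2)
    }
    dq <- outer(qA, qB, "-"); dr <- outer(rA, rB, "-")
    (abs(dq) + abs(dr) + abs(dq + dr)) / 2
}

# connected components of a spot subset under ring-1 hex adjacency;
# returns an integer component id per selected spot
.hexComponents <- function(arrayRow, arrayCol) {
    n <- length(arrayRow)
    if (n == 0L) return(integer(0))
    d <- hexDistance(arrayRow, arrayCol, arrayRow, arrayCol)
    adj <- which(d == 1, arr.ind = TRUE)
    adj <- adj[adj[, 1] < adj[, 2], , drop = FALSE]
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (nrow(adj)) g <- igraph::add_edges(g, t(adj))
    as.integer(igraph::components(g)$membership)
}
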