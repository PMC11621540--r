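#' Write a section in the Space Ranger on-disk dialect
#'
#' Writes the familiar trio — `matrix.mtx` (genes x barcodes, Matrix
#' Market), `features.tsv`, `barcodes.tsv` — plus `tissue_positions.csv`
#' (header variant: barcode, in_tissue, array_row, array_col,
#' pxl_row_in_fullres, pxl_col_in_fullres) and, when cluster labels are
#' present, a `clusters.csv`.
#'
#' @param x a [SpotExperiment].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCounts <- function(x, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    m <- Matrix::Matrix(assay(x, "counts"), sparse = TRUE)
    Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
    utils::write.table(
        data.frame(id = rownames(x), name = rownames(x),
                   type = "Gene Expression"),
        file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    writeLines(colnames(x), file.path(dir, "barcodes.tsv"))
    cd <- colData(x)
    utils::write.csv(
        data.frame(barcode = colnames(x), in_tissue = as.integer(cd$in_tissue),
                   array_row = cd$array_row, array_col = cd$array_col,
                   pxl_row_in_fullres = cd$pixel_y,
                   pxl_col_in_fullres = cd$pixel_x),
        file.path(dir, "tissue_positions.csv"), row.names = FALSE,
        quote = FALSE)
    if (!is.null(spotClusters(x)))
        utils::write.csv(data.frame(barcode = colnames(x),
                                    cluster = spotClusters(x)),
                         file.path(dir, "clusters.csv"), row.names = FALSE,
                         quote = FALSE)
    invisible(dir)
}

#' Read a Space Ranger-dialect section directory
#'
#' Accepts both the header-bearing `tissue_positions.csv` and the legacy
#' six-column headerless `tissue_positions_list.csv`. Duplicated gene ids
#' are deduplicated deterministically with a numeric suffix
#' (`make.unique`). All spots present in the barcode list are retained,
#' in matrix order, whether in tissue or not.
#'
#' @param dir directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` and a tissue positions file.
#' @return a [SpotExperiment].
#' @export
readCounts <- function(dir) {
    need <- c("matrix.mtx", "features.tsv", "barcodes.tsv")
    for (f in need)
        if (!file.exists(file.path(dir, f)))
            stop("missing required file: ", f)
    posFile <- file.path(dir, "tissue_positions.csv")
    if (!file.exists(posFile))
        posFile <- file.path(dir, "tissue_positions_list.csv")
    if (!file.exists(posFile))
        stop("missing required file: tissue_positions.csv (or legacy ",
             "tissue_positions_list.csv)")

    m <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
    feats <- utils::read.table(file.path(dir, "features.tsv"), sep = "\t",
                               header = FALSE, stringsAsFactors = FALSE)
    barcodes <- readLines(file.path(dir, "barcodes.tsv"))
    if (nrow(feats) != nrow(m) || length(barcodes) != ncol(m))
        stop("matrix dimensions do not match features/barcodes files")
    rownames(m) <- make.unique(feats[[1]], sep = ".")
    colnames(m) <- barcodes

    firstLine <- readLines(posFile, n = 1L)
    hasHeader <- grepl("barcode", firstLine, fixed = TRUE)
    pos <- utils::read.csv(posFile, header = hasHeader,
                           stringsAsFactors = FALSE)
    colnames(pos) <- c("barcode", "in_tissue", "array_row", "array_col",
                       "pxl_row_in_fullres", "pxl_col_in_fullres")
    missing <- setdiff(barcodes, pos$barcode)
    if (length(missing))
        stop("barcodes absent from tissue positions: ",
             paste(utils::head(missing, 5), collapse = ", "),
             if (length(missing) > 5) " ...")
    pos <- pos[match(barcodes, pos$barcode), ]

    spotData <- data.frame(spot_id = barcodes,
                           array_row = as.integer(pos$array_row),
                           array_col = as.integer(pos$array_col),
                           pixel_x = pos$pxl_col_in_fullres,
                           pixel_y = pos$pxl_row_in_fullres,
                           in_tissue = pos$in_tissue != 0)
    clFile <- file.path(dir, "clusters.csv")
    if (file.exists(clFile)) {
        cl <- utils::read.csv(clFile, stringsAsFactors = FALSE)
        spotData$cluster <- cl$cluster[match(barcodes, cl$barcode)]
    }
    SpotExperiment(m, spotData)
}

#' Read a signature set from JSON or TSV
#'
#' JSON: either `{"name": ["GENE1", ...], ...}` or the full form
#' `{"name": {"genes": [...], "category": "...", "class": "..."}, ...}`.
#' TSV: columns `signature`, `gene`, optionally `category` and `class`
#' (with header). Genes unknown to any particular count matrix are
#' retained — intersection happens at scoring time.
#'
#' @param file path to a `.json` or `.tsv`/`.txt` file.
#' @param defaultCategory category used when the file does not state one.
#' @return a [SignatureSet].
#' @export
readSignatures <- function(file, defaultCategory = "tumor-feature") {
    if (grepl("\\.json$", file, ignore.case = TRUE)) {
        raw <- jsonlite::read_json(file, simplifyVector = TRUE)
        if (anyDuplicated(names(raw)))
            stop("duplicate signature name in ", file)
        full <- is.list(raw[[1]]) && !is.null(raw[[1]]$genes)
        if (full) {
            genes <- lapply(raw, function(e) as.character(e$genes))
            category <- vapply(raw, function(e)
                if (is.null(e$category)) defaultCategory else e$category, "")
            classTag <- vapply(raw, function(e)
                if (is.null(e$class)) NA_character_ else e$class, "")
        } else {
            genes <- lapply(raw, as.character)
            category <- rep(defaultCategory, length(genes))
            classTag <- rep(NA_character_, length(genes))
        }
    } else {
        tab <- utils::read.table(file, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
        if (!all(c("signature", "gene") %in% colnames(tab)))
            stop("TSV signatures need 'signature' and 'gene' columns")
        genes <- split(tab$gene, tab$signature)
        genes <- genes[unique(tab$signature)]   # preserve file order
        pick <- function(col, default) vapply(names(genes), function(nm) {
            v <- tab[tab$signature == nm, col]
            if (is.null(v) || !length(v) || all(is.na(v))) default else v[1]
        }, "")
        category <- if ("category" %in% colnames(tab))
            pick("category", defaultCategory)
        else rep(defaultCategory, length(genes))
        classTag <- if ("class" %in% colnames(tab)) pick("class", NA_character_)
        else rep(NA_character_, length(genes))
    }
    if (any(!vapply(genes, length, 1L)))
        stop("signature with empty gene list in ", file)
    classTag[is.na(classTag)] <- names(genes)[is.na(classTag)]
    SignatureSet(genes, category = unname(category),
                 classTag = unname(classTag))
}

#' Write a signature set as JSON
#'
#' @param signatures a [SignatureSet].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
writeSignatures <- function(signatures, file) {
    out <- lapply(signatureNames(signatures), function(nm) list(
        genes = signatureGenes(signatures, nm),
        category = unname(signatureCategory(signatures)[nm]),
        class = unname(signatureClass(signatures)[nm])))
    names(out) <- signatureNames(signatures)
    jsonlite::write_json(out, file, auto_unbox = TRUE, pretty = TRUE)
    invisible(file)
}

#' Write a named list of result tables as CSV files
#'
#' @param tables named list of data.frames.
#' @param dir output directory.
#' @return the written paths, invisibly.
#' @export
writeResults <- function(tables, dir) {
    stopifnot(is.list(tables), !is.null(names(tables)))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- vapply(names(tables), function(nm) {
        p <- file.path(dir, paste0(nm, ".csv"))
        utils::write.csv(tables[[nm]], p, row.names = FALSE)
        p
    }, "")
    invisible(paths)
}

#' Read and write binary masks / grayscale rasters (PNG or TIFF)
#'
#' `readImageRaster` returns a numeric matrix (or ny x nx x channels array)
#' in [0, 1], row = y (top-left origin). `writeMask` stores a logical mask
#' as an 8-bit grayscale image.
#'
#' @param file image path, extension `.png`, `.tif` or `.tiff`.
#' @return numeric array for `readImageRaster`; `file` invisibly for
#'   `writeMask`.
#' @export
readImageRaster <- function(file) {
    if (grepl("\\.png$", file, ignore.case = TRUE))
        png::readPNG(file)
    else if (grepl("\\.tiff?$", file, ignore.case = TRUE))
        tiff::readTIFF(file)
    else stop("unsupported image format: ", file)
}

#' @rdname readImageRaster
#' @param mask logical matrix (TRUE = foreground).
#' @export
writeMask <- function(mask, file) {
    img <- matrix(as.numeric(mask), nrow = nrow(mask))
    if (grepl("\\.png$", file, ignore.case = TRUE))
        png::writePNG(img, file)
    else if (grepl("\\.tiff?$", file, ignore.case = TRUE))
        tiff::writeTIFF(img, file)
    else stop("unsupported image format: ", file)
    invisible(file)
}
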