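#' Write a dataset as a 10x-convention Matrix Market bundle
#'
#' Writes \code{matrix.mtx} (Matrix Market coordinate integer, 1-based
#' indices), \code{features.tsv} (gene id, gene name, "Gene Expression"),
#' \code{barcodes.tsv}, and \code{cell_metadata.tsv} (barcode, sample,
#' condition, cell_type, plus any further colData columns). When the object
#' carries simulation ground truth in its metadata, it is written alongside
#' as \code{ground_truth.json}. [read10x()] reproduces the matrix exactly.
#'
#' @param sce a \linkS4class{SingleCellExperiment} with a \code{counts} assay
#'   and colData columns \code{sample}, \code{condition}, \code{cell_type}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write10x <- function(sce, dir) {
    counts <- SummarizedExperiment::assay(sce, "counts")
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
    tm <- methods::as(methods::as(counts, "CsparseMatrix"), "TsparseMatrix")
    con <- file(file.path(dir, "matrix.mtx"), "w")
    on.exit(close(con), add = TRUE)
    writeLines(c("%%MatrixMarket matrix coordinate integer general",
                 "%",
                 paste(nrow(counts), ncol(counts), length(tm@x))), con)
    if (length(tm@x))
        writeLines(paste(tm@i + 1L, tm@j + 1L, as.integer(tm@x)), con)
    genes <- rownames(counts)
    utils::write.table(
        data.frame(genes, genes, "Gene Expression"),
        file.path(dir, "features.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    writeLines(as.character(colnames(counts)), file.path(dir, "barcodes.tsv"))
    cd <- as.data.frame(SummarizedExperiment::colData(sce))
    meta <- cbind(data.frame(barcode = colnames(counts)), cd)
    utils::write.table(meta, file.path(dir, "cell_metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    gt <- S4Vectors::metadata(sce)$ground_truth
    if (!is.null(gt))
        jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                             dataframe = "columns", auto_unbox = TRUE,
                             digits = NA)
    invisible(dir)
}

#' Read a 10x-convention Matrix Market bundle
#'
#' Counterpart of [write10x()]: reads \code{matrix.mtx}, \code{features.tsv},
#' \code{barcodes.tsv} and (when present) \code{cell_metadata.tsv} into a
#' \linkS4class{SingleCellExperiment}.
#'
#' @param dir directory containing the bundle.
#' @return a \linkS4class{SingleCellExperiment} with sparse \code{counts}.
#' @export
read10x <- function(dir) {
    mtx <- file.path(dir, "matrix.mtx")
    if (!file.exists(mtx)) stop("matrix.mtx not found in ", dir)
    counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    feats <- utils::read.delim(file.path(dir, "features.tsv"), header = FALSE,
                               stringsAsFactors = FALSE)
    bcFile <- file.path(dir, "barcodes.tsv")
    barcodes <- if (file.info(bcFile)$size > 0) readLines(bcFile) else character()
    if (nrow(feats) && nrow(feats) != nrow(counts))
        stop("features.tsv has ", nrow(feats), " rows but matrix has ",
             nrow(counts))
    if (length(barcodes) != ncol(counts))
        stop("barcodes.tsv has ", length(barcodes), " entries but matrix has ",
             ncol(counts), " columns")
    dimnames(counts) <- list(if (nrow(feats)) feats[[1]] else NULL, barcodes)
    cd <- S4Vectors::DataFrame(row.names = barcodes)
    metaFile <- file.path(dir, "cell_metadata.tsv")
    if (file.exists(metaFile) && length(barcodes)) {
        meta <- utils::read.delim(metaFile, stringsAsFactors = FALSE)
        if (nrow(meta)) {
            if (!"barcode" %in% names(meta))
                stop("cell_metadata.tsv must have a barcode column")
            if (!setequal(meta$barcode, barcodes))
                stop("cell_metadata.tsv barcodes do not match barcodes.tsv")
            meta <- meta[match(barcodes, meta$barcode), , drop = FALSE]
            cd <- S4Vectors::DataFrame(meta[, setdiff(names(meta), "barcode"),
                                            drop = FALSE],
                                       row.names = barcodes)
        }
    }
    SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts), colData = cd)
}
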