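.getCounts <- function(x) {
    if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x, "counts")
    else x
}

#' Per-cell quality-control metrics
#'
#' For every cell: the number of detected genes (count > 0), the total
#' counts, and the percentage of counts in mitochondrial (\code{MT-}
#' prefixed) and ribosomal (\code{^RP[SL]}) genes. Percentages use total
#' counts over all genes as denominator; cells with zero total counts get
#' 0\% for both.
#'
#' @param x a \linkS4class{SingleCellExperiment} with a \code{counts} assay,
#'   or a (sparse) gene x cell count matrix with rownames.
#' @param mito_prefix prefix identifying mitochondrial genes.
#' @param ribo_pattern regular expression identifying ribosomal genes.
#' @return data.frame with one row per cell: \code{barcode},
#'   \code{n_genes_detected}, \code{total_counts}, \code{pct_mito},
#'   \code{pct_ribo}.
#' @examples
#' m <- Matrix::Matrix(c(5, 5), nrow = 2, sparse = TRUE,
#'                     dimnames = list(c("MT-CO1", "ACTB"), "cell1"))
#' computeQCMetrics(m)
#' @export
computeQCMetrics <- function(x, mito_prefix = "MT-", ribo_pattern = "^RP[SL]") {
    counts <- .getCounts(x)
    if (nrow(counts) == 0L) stop("count matrix has no genes")
    if (is.null(rownames(counts))) stop("count matrix must have gene rownames")
    total <- Matrix::colSums(counts)
    detected <- Matrix::colSums(counts > 0)
    mito <- startsWith(rownames(counts), mito_prefix)
    ribo <- grepl(ribo_pattern, rownames(counts))
    pctOf <- function(sel) {
        s <- if (any(sel)) Matrix::colSums(counts[sel, , drop = FALSE]) else 0
        ifelse(total > 0, 100 * s / total, 0)
    }
    data.frame(barcode = colnames(counts) %||% as.character(seq_along(total)),
               n_genes_detected = as.integer(detected),
               total_counts = as.integer(round(total)),
               pct_mito = as.numeric(pctOf(mito)),
               pct_ribo = as.numeric(pctOf(ribo)),
               stringsAsFactors = FALSE)
}

#' Cell filtering on QC metrics
#'
#' A cell is kept iff its mitochondrial percentage is at most
#' \code{max_pct_mito} and its detected-gene count lies in
#' \code{[min_genes, max_genes]}. Exclusion is by strict inequality, so
#' boundary cells (exactly 20\% mitochondrial, exactly 200 or 6,000 detected
#' genes under the defaults) are kept. Ribosomal percentage is reported by
#' [computeQCMetrics()] but not filtered on. The operation is idempotent.
#'
#' @param metrics data.frame from [computeQCMetrics()].
#' @param max_pct_mito maximum mitochondrial percentage (default 20).
#' @param min_genes,max_genes detected-gene bounds (defaults 200 and 6,000).
#' @return logical keep-mask over cells, named by barcode.
#' @export
filterCells <- function(metrics, max_pct_mito = 20, min_genes = 200,
                        max_genes = 6000) {
    stopifnot(max_pct_mito > 0, min_genes > 0, max_genes > 0,
              min_genes < max_genes)
    keep <- metrics$pct_mito <= max_pct_mito &
        metrics$n_genes_detected >= min_genes &
        metrics$n_genes_detected <= max_genes
    stats::setNames(keep, metrics$barcode)
}

#' Log-normalize a count matrix
#'
#' Per-cell normalization: each count is divided by the cell's total counts,
#' multiplied by \code{scale_factor}, and transformed with the natural
#' \code{log1p}, i.e. \code{value = ln(1 + count / total * scale_factor)}.
#' Zeros are preserved exactly, and scaling all counts of a cell by a common
#' factor leaves its normalized values unchanged.
#'
#' @param x a \linkS4class{SingleCellExperiment} (a \code{logcounts} assay is
#'   added) or a sparse/dense count matrix (a matrix of the same class is
#'   returned).
#' @param scale_factor scale factor (default 10,000).
#' @return same type as \code{x}, carrying the log-normalized values.
#' @examples
#' m <- Matrix::Matrix(c(1, 3), nrow = 2, sparse = TRUE,
#'                     dimnames = list(c("g1", "g2"), "cell1"))
#' logNormalizeCounts(m)["g1", 1]  # ln(1 + 1/4 * 1e4) = 7.82444
#' @export
logNormalizeCounts <- function(x, scale_factor = 10000) {
    stopifnot(scale_factor > 0)
    counts <- .getCounts(x)
    total <- Matrix::colSums(counts)
    if (ncol(counts) && any(total == 0))
        stop("cell(s) with zero total counts: ",
             paste(utils::head(colnames(counts)[total == 0], 5), collapse = ", "),
             " -- apply QC filtering (filterCells) before normalizing")
    if (is(counts, "CsparseMatrix")) {
        norm <- counts
        if (length(norm@x)) {
            colIdx <- rep.int(seq_len(ncol(norm)), diff(norm@p))
            norm@x <- log1p(norm@x * (scale_factor / total)[colIdx])
        }
    } else {
        norm <- log1p(sweep(as.matrix(counts), 2, scale_factor / total, `*`))
    }
    if (is(x, "SummarizedExperiment")) {
        SingleCellExperiment::logcounts(x) <- norm
        x
    } else norm
}

#' Highly variable gene selection (variance-stabilizing transformation)
#'
#' The standard "vst" recipe: per gene, compute the mean and variance of raw
#' counts; fit a mean-variance trend by local polynomial regression (degree
#' 2, span 0.3) of log10 variance on log10 mean; standardize each gene's
#' counts with the trend-predicted standard deviation; clip standardized
#' values at \code{sqrt(N)} (N = number of cells); and rank genes by the
#' variance of the clipped standardized values. Constant genes get
#' standardized variance 0 and rank last; ties are broken by gene symbol so
#' the order is deterministic.
#'
#' @param x a \linkS4class{SingleCellExperiment} or count matrix (raw counts).
#' @param n_top number of genes to return (default 2,000; all genes if
#'   fewer).
#' @param span loess span for the trend fit.
#' @return data.frame of the top \code{n_top} genes in rank order with
#'   columns \code{gene}, \code{mean}, \code{variance},
#'   \code{variance_standardized}.
#' @export
selectHVG <- function(x, n_top = 2000, span = 0.3) {
    if (n_top < 1) stop("n_top must be >= 1")
    counts <- as.matrix(.getCounts(x))
    if (ncol(counts) < 2L) stop("HVG selection needs at least 2 cells")
    n <- ncol(counts)
    mu <- rowMeans(counts)
    v <- apply(counts, 1L, stats::var)
    sdExp <- rep(0, nrow(counts))
    fit <- v > 0 & mu > 0
    if (sum(fit) >= 30L) {
        lo <- stats::loess(log10(v[fit]) ~ log10(mu[fit]), span = span,
                           degree = 2)
        sdExp[fit] <- sqrt(10^stats::fitted(lo))
    } else if (sum(fit) >= 2L) {
        # too few genes for a local fit: fall back to a global quadratic
        # trend, which the local regression approaches in this regime
        lx <- log10(mu[fit])
        lf <- stats::lm(log10(v[fit]) ~ stats::poly(lx, min(2L, sum(fit) - 1L)))
        sdExp[fit] <- sqrt(10^stats::fitted(lf))
    }
    clipMax <- sqrt(n)
    vStd <- rep(0, nrow(counts))
    for (g in which(sdExp > 0)) {
        z <- (counts[g, ] - mu[g]) / sdExp[g]
        z[z > clipMax] <- clipMax
        vStd[g] <- stats::var(z)
    }
    genes <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
    ord <- order(-vStd, genes)
    out <- data.frame(gene = genes[ord], mean = mu[ord], variance = v[ord],
                      variance_standardized = vStd[ord],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    utils::head(out, n_top)
}
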