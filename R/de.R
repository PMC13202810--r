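.getLogcounts <- function(x, assay = "logcounts") {
    if (is(x, "SummarizedExperiment")) {
        if (!assay %in% SummarizedExperiment::assayNames(x))
            stop("assay '", assay, "' not found; run logNormalizeCounts() first")
        SummarizedExperiment::assay(x, assay)
    } else x
}

.cellAnnotation <- function(x) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    need <- c("condition", "cell_type")
    if (!all(need %in% names(cd)))
        stop("colData must contain columns: ", paste(need, collapse = ", "))
    cd
}

#' Wilcoxon rank-sum differential expression within one cell type
#'
#' Compares one condition against the control within a single cell type on
#' log-normalized expression. A gene is tested iff its expressing fraction
#' (value > 0) is at least \code{min_pct} in at least one of the two groups.
#' P-values come from the two-sided Wilcoxon rank-sum test with normal
#' approximation, tie correction and continuity correction; when every value
#' is tied across both groups the test is at its null center and p = 1.
#' Benjamini-Hochberg adjustment is applied across the genes tested within
#' this one comparison. The fold change is computed on the expression scale:
#' \code{log2fc = log2((m1 + pc) / (m2 + pc))} with \code{m} the group mean
#' of \code{expm1(value)} and pseudocount \code{pc = 1e-9}.
#'
#' @param x a \linkS4class{SingleCellExperiment} with \code{logcounts} and
#'   colData columns \code{condition}, \code{cell_type}.
#' @param cell_type cell type to subset to before testing.
#' @param condition,control condition labels to compare (condition vs
#'   control).
#' @param min_pct minimum expressing fraction in either group (default 0.1).
#' @param assay assay holding log-normalized values.
#' @return data.frame with one row per tested gene: \code{cell_type},
#'   \code{condition}, \code{gene}, \code{pct_group1}, \code{pct_group2},
#'   \code{log2fc}, \code{p_value}, \code{p_adjusted}.
#' @seealso [summarizeDEGs()], [topDEGs()]
#' @export
wilcoxonDE <- function(x, cell_type, condition, control, min_pct = 0.1,
                       assay = "logcounts") {
    ann <- .cellAnnotation(x)
    if (!cell_type %in% ann$cell_type) stop("unknown cell type: ", cell_type)
    for (lbl in c(condition, control))
        if (!lbl %in% ann$condition) stop("unknown condition: ", lbl)
    sel1 <- ann$cell_type == cell_type & ann$condition == condition
    sel2 <- ann$cell_type == cell_type & ann$condition == control
    if (sum(sel1) < 2L || sum(sel2) < 2L)
        stop("each group needs at least 2 cells after subsetting to ",
             cell_type, " (", condition, ": ", sum(sel1), ", ", control, ": ",
             sum(sel2), ")")
    norm <- .getLogcounts(x, assay)
    x1 <- as.matrix(norm[, sel1, drop = FALSE])
    x2 <- as.matrix(norm[, sel2, drop = FALSE])
    pct1 <- rowMeans(x1 > 0)
    pct2 <- rowMeans(x2 > 0)
    test <- pmax(pct1, pct2) >= min_pct
    genes <- rownames(norm)[test]
    if (!length(genes))
        return(data.frame(cell_type = character(), condition = character(),
                          gene = character(), pct_group1 = numeric(),
                          pct_group2 = numeric(), log2fc = numeric(),
                          p_value = numeric(), p_adjusted = numeric()))
    x1 <- x1[test, , drop = FALSE]; x2 <- x2[test, , drop = FALSE]
    pc <- 1e-9
    m1 <- rowMeans(expm1(x1)); m2 <- rowMeans(expm1(x2))
    p <- vapply(seq_along(genes), function(i) {
        pv <- suppressWarnings(stats::wilcox.test(
            x1[i, ], x2[i, ], exact = FALSE, correct = TRUE)$p.value)
        if (is.na(pv)) 1 else pv            # all-tied: statistic at null center
    }, numeric(1))
    out <- data.frame(cell_type = cell_type, condition = condition,
                      gene = genes,
                      pct_group1 = as.numeric(pct1[test]),
                      pct_group2 = as.numeric(pct2[test]),
                      log2fc = log2((m1 + pc) / (m2 + pc)),
                      p_value = p,
                      p_adjusted = stats::p.adjust(p, method = "BH"),
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
}

#' Run Wilcoxon DE for several cell types and conditions
#'
#' Convenience wrapper around [wilcoxonDE()]: every non-control condition is
#' compared against the control within every requested cell type, skipping
#' (with a message) combinations where either group has fewer than 2 cells.
#'
#' @inheritParams wilcoxonDE
#' @param cell_types cell types to test (default: all in the annotation).
#' @param conditions conditions to compare (default: all but the control).
#' @return row-bound data.frame of [wilcoxonDE()] results.
#' @export
runDE <- function(x, control, cell_types = NULL, conditions = NULL,
                  min_pct = 0.1, assay = "logcounts") {
    ann <- .cellAnnotation(x)
    if (is.null(cell_types)) cell_types <- sort(unique(ann$cell_type))
    if (is.null(conditions))
        conditions <- setdiff(unique(ann$condition), control)
    out <- list()
    for (ct in cell_types) for (cond in conditions) {
        n1 <- sum(ann$cell_type == ct & ann$condition == cond)
        n2 <- sum(ann$cell_type == ct & ann$condition == control)
        if (n1 < 2L || n2 < 2L) {
            message("skipping ", ct, " / ", cond, ": fewer than 2 cells in a group")
            next
        }
        out[[paste(ct, cond)]] <-
            wilcoxonDE(x, ct, cond, control, min_pct = min_pct, assay = assay)
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Summarize DEG counts per cell type and condition
#'
#' Counts significantly up- and downregulated genes (adjusted p below
#' \code{alpha}, split by fold-change sign) per (cell type, condition).
#'
#' @param records data.frame from [wilcoxonDE()] / [runDE()].
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @return data.frame with columns \code{cell_type}, \code{condition},
#'   \code{n_up}, \code{n_down}, \code{n_tested}.
#' @export
summarizeDEGs <- function(records, alpha = 0.05) {
    if (is.null(records) || nrow(records) == 0L)
        return(data.frame(cell_type = character(), condition = character(),
                          n_up = integer(), n_down = integer(),
                          n_tested = integer()))
    sig <- records$p_adjusted < alpha
    key <- interaction(records$cell_type, records$condition, drop = TRUE)
    out <- do.call(rbind, lapply(levels(key), function(k) {
        r <- records[key == k, ]
        data.frame(cell_type = r$cell_type[1], condition = r$condition[1],
                   n_up = sum(r$p_adjusted < alpha & r$log2fc > 0),
                   n_down = sum(r$p_adjusted < alpha & r$log2fc < 0),
                   n_tested = nrow(r), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
}

#' Top-k differentially expressed genes
#'
#' Orders records by adjusted p ascending, breaking ties by absolute fold
#' change descending and then gene symbol ascending, and returns the first
#' \code{k} gene symbols (all if fewer).
#'
#' @param records data.frame from [wilcoxonDE()].
#' @param k number of genes (e.g. 50 per cell type, 200 for overall
#'   comparisons).
#' @return character vector of gene symbols.
#' @export
topDEGs <- function(records, k) {
    if (k < 1) stop("k must be >= 1")
    if (nrow(records) == 0L) return(character())
    ord <- order(records$p_adjusted, -abs(records$log2fc), records$gene)
    utils::head(records$gene[ord], k)
}

# deterministic leaf order of an hclust merge tree: at every internal node
# the subtree containing the smaller original row index comes first
.leafOrder <- function(merge) {
    if (is.null(merge) || nrow(merge) == 0L) return(1L)
    ord <- vector("list", nrow(merge))
    nodeMin <- integer(nrow(merge))
    for (k in seq_len(nrow(merge))) {
        a <- merge[k, 1]; b <- merge[k, 2]
        la <- if (a < 0) -a else ord[[a]]
        ma <- if (a < 0) -a else nodeMin[a]
        lb <- if (b < 0) -b else ord[[b]]
        mb <- if (b < 0) -b else nodeMin[b]
        if (mb < ma) { tmp <- la; la <- lb; lb <- tmp; nodeMin[k] <- mb }
        else nodeMin[k] <- ma
        ord[[k]] <- c(la, lb)
    }
    ord[[nrow(merge)]]
}

#' Z-scored group-mean expression matrix with hierarchical row order
#'
#' Computes the mean log-normalized expression of each requested gene in each
#' cell group, z-scores every gene row across groups (constant rows become
#' all zeros), and orders rows by agglomerative complete-linkage clustering
#' with Euclidean distance on the z-scored rows. The leaf order is
#' deterministic: at every merge the subtree containing the smaller original
#' row index is placed first.
#'
#' @param x a \linkS4class{SingleCellExperiment} with \code{logcounts}, or a
#'   normalized matrix.
#' @param genes genes to include (must be present).
#' @param groups factor/character vector of length \code{ncol(x)} assigning
#'   each cell to a group, or the name(s) of colData columns to combine.
#' @param assay assay holding log-normalized values.
#' @return list with \code{matrix} (z-scored gene x group means, rows in
#'   clustered order), \code{row_order} (gene names) and \code{hclust} (the
#'   clustering object, \code{NULL} for a single gene).
#' @export
heatmapMatrix <- function(x, genes, groups, assay = "logcounts") {
    norm <- .getLogcounts(x, assay)
    if (is.character(groups) && length(groups) < ncol(norm) &&
        is(x, "SummarizedExperiment")) {
        cd <- as.data.frame(SummarizedExperiment::colData(x))
        if (!all(groups %in% names(cd)))
            stop("unknown colData column(s): ",
                 paste(setdiff(groups, names(cd)), collapse = ", "))
        groups <- interaction(cd[groups], drop = FALSE, sep = "_")
    }
    if (!is.factor(groups)) groups <- factor(groups)
    if (length(groups) != ncol(norm))
        stop("groups must assign every cell to a group")
    if (any(table(groups) == 0L))
        stop("group(s) with 0 cells: ",
             paste(names(which(table(groups) == 0L)), collapse = ", "))
    miss <- setdiff(genes, rownames(norm))
    if (length(miss)) stop("gene(s) not in matrix: ", paste(miss, collapse = ", "))
    sub <- as.matrix(norm[genes, , drop = FALSE])
    means <- vapply(levels(groups), function(g)
        rowMeans(sub[, groups == g, drop = FALSE]), numeric(length(genes)))
    means <- matrix(means, nrow = length(genes),
                    dimnames = list(genes, levels(groups)))
    z <- t(apply(means, 1L, function(r) {
        s <- stats::sd(r)
        if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
    }))
    dimnames(z) <- dimnames(means)
    if (nrow(z) < 2L)
        return(list(matrix = z, row_order = rownames(z), hclust = NULL))
    hc <- stats::hclust(stats::dist(z, method = "euclidean"),
                        method = "complete")
    ord <- .leafOrder(hc$merge)
    list(matrix = z[ord, , drop = FALSE], row_order = rownames(z)[ord],
         hclust = hc)
}
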