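#' Cell-type proportions per condition
#'
#' @param x a \linkS4class{SingleCellExperiment} (annotation in colData) or a
#'   data.frame with columns \code{condition}, \code{cell_type}.
#' @return data.frame with columns \code{condition}, \code{cell_type},
#'   \code{n}, \code{prop}; within each condition the proportions sum to 1.
#' @export
cellTypeProportions <- function(x) {
    ann <- if (is(x, "SummarizedExperiment")) .cellAnnotation(x) else x
    if (nrow(ann) == 0L) stop("annotation is empty")
    tab <- table(condition = ann$condition, cell_type = ann$cell_type)
    out <- as.data.frame(tab, stringsAsFactors = FALSE)
    names(out)[3] <- "n"
    tot <- rowSums(tab)
    out$prop <- out$n / tot[out$condition]
    out <- out[out$condition %in% names(tot)[tot > 0], ]
    out <- out[order(out$condition, out$cell_type), ]
    rownames(out) <- NULL
    out
}

.sigCode <- function(fdr) {
    ifelse(fdr < 0.001, "***", ifelse(fdr < 0.01, "**",
                                      ifelse(fdr < 0.05, "*", "ns")))
}

#' Condition-versus-control compositional shifts
#'
#' For each cell type and each non-control condition, tests the 2x2 table
#' (cells in type vs all other types) x (condition vs control) with
#' two-sided Fisher's exact test, applies Benjamini-Hochberg correction
#' across cell types within each condition, and reports the proportion fold
#' change \code{log2((prop_cond + eps) / (prop_ctrl + eps))} clamped to
#' \code{[-cap, +cap]}.
#'
#' @inheritParams cellTypeProportions
#' @param control control condition label (default \code{"Donor"}).
#' @param cap fold-change cap in log2 units (default 3).
#' @param eps pseudo-proportion guarding zero proportions (default 1e-6).
#' @return data.frame with columns \code{cell_type}, \code{condition},
#'   \code{prop_condition}, \code{prop_control}, \code{log2fc} (capped),
#'   \code{p_value}, \code{fdr}, \code{significance}.
#' @export
compositionTest <- function(x, control = "Donor", cap = 3, eps = 1e-6) {
    ann <- if (is(x, "SummarizedExperiment")) .cellAnnotation(x) else x
    if (!control %in% ann$condition)
        stop("control condition '", control, "' not present in annotation")
    conds <- setdiff(unique(ann$condition), control)
    types <- sort(unique(ann$cell_type))
    inCtrl <- ann$condition == control
    nCtrl <- sum(inCtrl)
    out <- list()
    for (cond in conds) {
        inCond <- ann$condition == cond
        nCond <- sum(inCond)
        if (nCond == 0L) {
            warning("condition '", cond, "' has zero cells; skipped")
            next
        }
        rows <- do.call(rbind, lapply(types, function(ct) {
            a <- sum(inCond & ann$cell_type == ct)
            c0 <- sum(inCtrl & ann$cell_type == ct)
            tab <- matrix(c(a, nCond - a, c0, nCtrl - c0), nrow = 2)
            p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
            pc <- a / nCond; pctl <- c0 / nCtrl
            lfc <- log2((pc + eps) / (pctl + eps))
            data.frame(cell_type = ct, condition = cond,
                       prop_condition = pc, prop_control = pctl,
                       log2fc = max(min(lfc, cap), -cap), p_value = p,
                       stringsAsFactors = FALSE)
        }))
        rows$fdr <- stats::p.adjust(rows$p_value, method = "BH")
        out[[cond]] <- rows
    }
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    if (is.null(res))
        return(data.frame(cell_type = character(), condition = character(),
                          prop_condition = numeric(), prop_control = numeric(),
                          log2fc = numeric(), p_value = numeric(),
                          fdr = numeric(), significance = character()))
    res$significance <- .sigCode(res$fdr)
    res
}
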