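#' Default directed sender-receiver cell-type pairs
#'
#' The four directions examined by the cardiac analysis: CF to CM, CM to EC,
#' EC to CM, and CM to CF. Additional populations are analysed by simply
#' listing extra directions.
#'
#' @return data.frame with columns \code{sender}, \code{receiver}.
#' @export
defaultDirections <- function() {
    data.frame(sender = c("CF", "CM", "EC", "CM"),
               receiver = c("CM", "EC", "CM", "CF"),
               stringsAsFactors = FALSE)
}

.pickCells <- function(norm, cells) {
    if (is.logical(cells)) which(cells) else cells
}

.geneRow <- function(norm, gene) {
    if (!gene %in% rownames(norm)) stop("gene not in matrix: ", gene)
    norm[gene, ]
}

#' Crosstalk Potential for one ligand-receptor pair
#'
#' The product of the mean normalized ligand expression over the sender
#' cells and the mean normalized receptor expression over the receiver
#' cells. For a homophilic pair the same gene is evaluated as ligand in the
#' senders and as receptor in the receivers.
#'
#' @param norm normalized gene x cell matrix (or a
#'   \linkS4class{SingleCellExperiment} with \code{logcounts}).
#' @param sender_cells,receiver_cells non-empty cell indices, barcodes, or
#'   logical masks.
#' @param pair a single-row [LRTable-class] (or a pair subset thereof).
#' @return non-negative numeric(1).
#' @examples
#' m <- matrix(c(1, 2, 3, 0, 4, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("L", "R"), paste0("c", 1:3)))
#' crosstalkPotential(m, 1:3, 2:3, LRTable("L", "R", "demo"))  # 2 * 2 = 4
#' @export
crosstalkPotential <- function(norm, sender_cells, receiver_cells, pair) {
    norm <- .getLogcounts(norm)
    if (length(sender_cells) == 0L || length(receiver_cells) == 0L)
        stop("sender and receiver cell sets must be non-empty")
    lig <- .geneRow(norm, ligands(pair)[1])
    rec <- .geneRow(norm, receptors(pair)[1])
    mean(lig[.pickCells(norm, sender_cells)]) *
        mean(rec[.pickCells(norm, receiver_cells)])
}

#' Crosstalk Score for one ligand-receptor pair
#'
#' The square root of the product of expressing-cell percentages:
#' \code{sqrt(pct_ligand x pct_receptor)}, where each percentage (0-100
#' scale) is the share of cells with normalized value > 0 among the sender
#' (ligand) or receiver (receptor) cells. The score lies in [0, 100] and is
#' 0 iff either side has no expressing cell.
#'
#' @inheritParams crosstalkPotential
#' @return numeric(1) in [0, 100].
#' @examples
#' m <- matrix(c(1, 1, 1, 2, 0, 0), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("L", "R"), paste0("c", 1:3)))
#' crosstalkScore(m, 1:3, 1:2, LRTable("L", "R", "demo"))  # sqrt(100*50)
#' @export
crosstalkScore <- function(norm, sender_cells, receiver_cells, pair) {
    norm <- .getLogcounts(norm)
    if (length(sender_cells) == 0L || length(receiver_cells) == 0L)
        stop("sender and receiver cell sets must be non-empty")
    lig <- .geneRow(norm, ligands(pair)[1])[.pickCells(norm, sender_cells)]
    rec <- .geneRow(norm, receptors(pair)[1])[.pickCells(norm, receiver_cells)]
    sqrt(100 * mean(lig > 0) * 100 * mean(rec > 0))
}

#' Accessors for CrosstalkResults
#' @rdname CrosstalkResults-class
#' @export
setMethod("crosstalkRecords", "CrosstalkResults", function(x) x@records)
#' @rdname CrosstalkResults-class
#' @export
setMethod("lrPairs", "CrosstalkResults", function(x) x@pairs)

setMethod("show", "CrosstalkResults", function(object) {
    r <- object@records
    cat("CrosstalkResults:", nrow(r), "records (",
        sum(r$valid), "valid ) over", length(unique(r$condition)),
        "condition(s),", nrow(object@directions), "direction(s),",
        length(object@pairs), "pair(s); min cells =", object@minCells, "\n")
    invisible(NULL)
})

#' Crosstalk Potential and Score over all conditions, directions and pairs
#'
#' Emits one record per (condition, sender-receiver direction,
#' ligand-receptor pair). A record is valid only when both the sender and
#' the receiver cell type have at least \code{min_cells} cells in that
#' condition (the minimum-cell rule); invalid records carry \code{NA}
#' statistics. Means are taken over log-normalized values by default; set
#' \code{expression_scale = "linear"} to average de-logged
#' (\code{expm1}) values instead.
#'
#' @param x a \linkS4class{SingleCellExperiment} with \code{logcounts} and
#'   colData columns \code{condition}, \code{cell_type}.
#' @param pairs an [LRTable-class]; pairs whose genes are absent from the
#'   matrix should be removed first with [restrictToUniverse()].
#' @param directions data.frame with columns \code{sender}, \code{receiver}
#'   (default [defaultDirections()]).
#' @param min_cells minimum cells per type per condition (default 10).
#' @param expression_scale \code{"log"} or \code{"linear"}.
#' @param assay assay holding log-normalized values.
#' @return a [CrosstalkResults-class].
#' @seealso [foldChangeVsControl()], [categorySummary()],
#'   [topInteractions()], [buildCommNetwork()]
#' @export
computeCrosstalk <- function(x, pairs = cardiacLRPairs(),
                             directions = defaultDirections(),
                             min_cells = 10,
                             expression_scale = c("log", "linear"),
                             assay = "logcounts") {
    expression_scale <- match.arg(expression_scale)
    if (length(pairs) == 0L) stop("empty ligand-receptor pair list")
    ann <- .cellAnnotation(x)
    types <- unique(c(directions$sender, directions$receiver))
    missTypes <- setdiff(types, unique(ann$cell_type))
    if (length(missTypes))
        stop("direction cell type(s) not in annotation: ",
             paste(missTypes, collapse = ", "))
    norm <- .getLogcounts(x, assay)
    genes <- unique(c(ligands(pairs), receptors(pairs)))
    missGenes <- setdiff(genes, rownames(norm))
    if (length(missGenes))
        stop("pair gene(s) not in matrix (use restrictToUniverse): ",
             paste(missGenes, collapse = ", "))
    sub <- as.matrix(norm[genes, , drop = FALSE])
    if (expression_scale == "linear") sub <- expm1(sub)
    conditions <- unique(ann$condition)

    # per-(condition, type): group size, per-gene mean and expressing pct
    groupStats <- list()
    for (cond in conditions) for (ct in types) {
        cells <- which(ann$condition == cond & ann$cell_type == ct)
        key <- paste(cond, ct, sep = "\r")
        if (length(cells) == 0L) {
            groupStats[[key]] <- list(n = 0L)
        } else {
            block <- sub[, cells, drop = FALSE]
            groupStats[[key]] <- list(n = length(cells),
                                      mean = rowMeans(block),
                                      pct = 100 * rowMeans(block > 0))
        }
    }

    nPair <- length(pairs)
    rows <- vector("list", length(conditions) * nrow(directions))
    ri <- 0L
    for (cond in conditions) for (d in seq_len(nrow(directions))) {
        sKey <- paste(cond, directions$sender[d], sep = "\r")
        rKey <- paste(cond, directions$receiver[d], sep = "\r")
        gs <- groupStats[[sKey]]; gr <- groupStats[[rKey]]
        valid <- gs$n >= min_cells && gr$n >= min_cells
        if (valid) {
            mL <- gs$mean[ligands(pairs)]; mR <- gr$mean[receptors(pairs)]
            pL <- gs$pct[ligands(pairs)]; pR <- gr$pct[receptors(pairs)]
            pot <- as.numeric(mL * mR)
            sco <- sqrt(as.numeric(pL) * as.numeric(pR))
        } else {
            pot <- sco <- pL <- pR <- rep(NA_real_, nPair)
        }
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
            condition = cond, sender = directions$sender[d],
            receiver = directions$receiver[d], pair_id = pairIds(pairs),
            potential = pot, score = sco, pct_ligand = as.numeric(pL),
            pct_receptor = as.numeric(pR), n_sender = gs$n, n_receiver = gr$n,
            valid = valid, stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    new("CrosstalkResults", records = records, pairs = pairs,
        directions = directions, minCells = as.integer(min_cells),
        assayScale = expression_scale)
}

.recordsOf <- function(x) {
    if (is(x, "CrosstalkResults")) crosstalkRecords(x) else x
}

#' Log2 fold change of crosstalk potential versus the control condition
#'
#' For every (direction, pair, condition) computes
#' \code{log2((potential_cond + eps) / (potential_ctrl + eps))}. Comparisons
#' where either record is invalid under the minimum-cell rule propagate as
#' \code{NA}, never as zero. The control compared with itself gives exactly
#' 0.
#'
#' @param x a [CrosstalkResults-class] (or its records data.frame).
#' @param control control condition label (default \code{"Donor"}).
#' @param eps pseudo-potential (default 1e-6).
#' @return data.frame with columns \code{sender}, \code{receiver},
#'   \code{pair_id}, \code{condition}, \code{potential},
#'   \code{potential_control}, \code{log2fc}.
#' @export
foldChangeVsControl <- function(x, control = "Donor", eps = 1e-6) {
    rec <- .recordsOf(x)
    if (!control %in% rec$condition)
        stop("control condition '", control, "' absent from records")
    ctrl <- rec[rec$condition == control, ]
    key <- function(r) paste(r$sender, r$receiver, r$pair_id, sep = "\r")
    ctrlPot <- stats::setNames(ctrl$potential, key(ctrl))
    ctrlValid <- stats::setNames(ctrl$valid, key(ctrl))
    out <- rec[, c("sender", "receiver", "pair_id", "condition", "potential")]
    k <- key(rec)
    out$potential_control <- as.numeric(ctrlPot[k])
    ok <- rec$valid & !is.na(ctrlValid[k]) & ctrlValid[k]
    out$log2fc <- ifelse(ok,
                         log2((rec$potential + eps) /
                              (out$potential_control + eps)),
                         NA_real_)
    rownames(out) <- NULL
    out
}

#' Functional-category summaries of crosstalk remodelling
#'
#' Per (condition, category): the unweighted mean of pair-level log2 fold
#' changes versus the control (over valid comparisons across all
#' directions), and the total communication strength as a percentage of the
#' control baseline, \code{100 * sum(potential_cond) / sum(potential_ctrl)}
#' with both sums over valid records of the category. The control's own
#' percentage is exactly 100.
#'
#' @inheritParams foldChangeVsControl
#' @param pairs the [LRTable-class] supplying category labels (taken from
#'   \code{x} when it is a [CrosstalkResults-class]).
#' @return data.frame with columns \code{condition}, \code{category},
#'   \code{mean_log2fc}, \code{pct_of_baseline}, \code{n_comparisons}.
#'   Categories with zero valid control potential get \code{NA} with a
#'   warning.
#' @export
categorySummary <- function(x, pairs = NULL, control = "Donor", eps = 1e-6) {
    rec <- .recordsOf(x)
    if (is.null(pairs)) {
        if (!is(x, "CrosstalkResults"))
            stop("supply 'pairs' when x is a plain records data.frame")
        pairs <- lrPairs(x)
    }
    cat_of <- stats::setNames(categories(pairs), pairIds(pairs))
    if (anyNA(cat_of[unique(rec$pair_id)]))
        stop("every pair must have a category")
    fc <- foldChangeVsControl(rec, control = control, eps = eps)
    rec$category <- as.character(cat_of[rec$pair_id])
    fc$category <- as.character(cat_of[fc$pair_id])
    conds <- unique(rec$condition)
    cats <- sort(unique(rec$category))
    out <- list()
    for (cond in conds) for (cg in cats) {
        rc <- rec[rec$condition == cond & rec$category == cg & rec$valid, ]
        r0 <- rec[rec$condition == control & rec$category == cg & rec$valid, ]
        fcc <- fc[fc$condition == cond & fc$category == cg & !is.na(fc$log2fc), ]
        base <- sum(r0$potential)
        pct <- if (cond == control) {
            100
        } else if (nrow(r0) == 0L || base == 0) {
            warning("category '", cg, "': no valid control potential; ",
                    "pct_of_baseline is NA for ", cond)
            NA_real_
        } else 100 * sum(rc$potential) / base
        out[[paste(cond, cg)]] <- data.frame(
            condition = cond, category = cg,
            mean_log2fc = if (nrow(fcc)) mean(fcc$log2fc) else NA_real_,
            pct_of_baseline = pct, n_comparisons = nrow(fcc),
            stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
    rownames(res) <- NULL
    res
}

#' Rank ligand-receptor pairs by overall communication potential
#'
#' Pairs are ranked by the unweighted mean of their valid potentials across
#' all conditions and directions (descending; ties broken by pair id
#' ascending). Per-condition mean potentials are reported alongside.
#'
#' @inheritParams foldChangeVsControl
#' @param n number of pairs to return (default 25; all if fewer).
#' @return data.frame with columns \code{rank}, \code{pair_id},
#'   \code{mean_potential}, then one \code{potential_<condition>} column per
#'   condition.
#' @export
topInteractions <- function(x, n = 25) {
    if (n < 1) stop("n must be >= 1")
    rec <- .recordsOf(x)
    v <- rec[rec$valid, ]
    ids <- sort(unique(rec$pair_id))
    overall <- vapply(ids, function(p) {
        pv <- v$potential[v$pair_id == p]
        if (length(pv)) mean(pv) else NA_real_
    }, numeric(1))
    conds <- unique(rec$condition)
    perCond <- vapply(conds, function(cc) {
        vapply(ids, function(p) {
            pv <- v$potential[v$pair_id == p & v$condition == cc]
            if (length(pv)) mean(pv) else NA_real_
        }, numeric(1))
    }, numeric(length(ids)))
    perCond <- matrix(perCond, nrow = length(ids),
                      dimnames = list(ids, paste0("potential_", conds)))
    ord <- order(-overall, ids)
    out <- data.frame(rank = seq_along(ids), pair_id = ids[ord],
                      mean_potential = as.numeric(overall[ord]),
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(perCond[ord, , drop = FALSE]))
    rownames(out) <- NULL
    utils::head(out, n)
}
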