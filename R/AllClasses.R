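#' @import methods
NULL

#' Curated ligand-receptor pair table
#'
#' An S4 container for a directed ligand-receptor pair catalogue. Each row is
#' one pair: a ligand gene, a receptor gene, a functional-category label (e.g.
#' \code{"growth_factor"}, \code{"notch"}), a unique \code{pair_id}, and a
#' \code{homophilic} flag that is \code{TRUE} exactly when ligand and receptor
#' are the same gene (self-binding adhesion molecules such as PTPRM).
#'
#' Only single-gene ligands and receptors are supported; multi-subunit
#' complexes (fields joined with \code{"+"}) are rejected at construction.
#'
#' @slot pairs data.frame with columns \code{pair_id}, \code{ligand},
#'   \code{receptor}, \code{category}, \code{homophilic}.
#'
#' @seealso [LRTable()], [readLRTable()], [cardiacLRPairs()]
#' @export
setClass("LRTable", slots = c(pairs = "data.frame"))

setValidity("LRTable", function(object) {
    p <- object@pairs
    need <- c("pair_id", "ligand", "receptor", "category", "homophilic")
    if (!all(need %in% names(p)))
        return(paste("pairs must have columns:", paste(need, collapse = ", ")))
    msgs <- character()
    genes <- c(p$ligand, p$receptor)
    if (anyDuplicated(p$pair_id))
        msgs <- c(msgs, paste("duplicate pair_id:",
                              paste(unique(p$pair_id[duplicated(p$pair_id)]),
                                    collapse = ", ")))
    if (length(genes) && (any(!nzchar(genes)) || any(grepl("[[:space:]]", genes))))
        msgs <- c(msgs, "gene symbols must be non-empty and whitespace-free")
    if (length(genes) && any(grepl("\\+", genes, fixed = FALSE)))
        msgs <- c(msgs, "multi-subunit complexes ('+'-joined genes) are not supported")
    if (!identical(p$homophilic, p$ligand == p$receptor))
        msgs <- c(msgs, "homophilic flag must equal (ligand == receptor)")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Crosstalk statistics over (condition, sender, receiver, pair)
#'
#' Holds one record per combination of condition, directed sender-receiver
#' cell-type pair, and ligand-receptor pair: the Crosstalk Potential (mean
#' ligand expression in the sender type times mean receptor expression in the
#' receiver type), the Crosstalk Score (square root of the product of
#' expressing-cell percentages), the expressing percentages themselves, the
#' group sizes and a validity flag implementing the minimum-cell rule.
#'
#' @slot records data.frame of per-record statistics (see
#'   [crosstalkRecords()]).
#' @slot pairs the [LRTable-class] the records were computed from.
#' @slot directions data.frame with columns \code{sender}, \code{receiver}.
#' @slot minCells integer(1), minimum cells per type per condition for a
#'   record to be valid.
#' @slot assayScale \code{"log"} (log-normalized values) or \code{"linear"}
#'   (de-logged, \code{expm1}) for the means entering the potential.
#'
#' @seealso [computeCrosstalk()]
#' @export
setClass("CrosstalkResults",
         slots = c(records = "data.frame", pairs = "LRTable",
                   directions = "data.frame", minCells = "integer",
                   assayScale = "character"))

setValidity("CrosstalkResults", function(object) {
    need <- c("condition", "sender", "receiver", "pair_id", "potential",
              "score", "pct_ligand", "pct_receptor", "n_sender", "n_receiver",
              "valid")
    if (!all(need %in% names(object@records)))
        return(paste("records must have columns:", paste(need, collapse = ", ")))
    r <- object@records[object@records$valid, , drop = FALSE]
    if (nrow(r)) {
        if (any(r$potential < 0)) return("valid potentials must be >= 0")
        if (any(abs(r$score - sqrt(r$pct_ligand * r$pct_receptor)) > 1e-12))
            return("score must equal sqrt(pct_ligand * pct_receptor)")
    }
    if (length(object@minCells) != 1L || object@minCells < 1L)
        return("minCells must be a single positive integer")
    TRUE
})

#' Directed weighted cell-cell communication network
#'
#' One network per condition: nodes are cell types, one directed edge per
#' configured sender-receiver direction that has at least one valid crosstalk
#' record, with edge weight equal to the mean Crosstalk Potential over that
#' direction's valid ligand-receptor records.
#'
#' @slot condition character(1) condition label.
#' @slot nodes character vector of cell-type labels.
#' @slot edges data.frame with columns \code{sender}, \code{receiver},
#'   \code{weight}.
#' @slot directions data.frame of the configured directions (used by
#'   [networkMetrics()] to compute fragmentation).
#'
#' @seealso [buildCommNetwork()], [networkMetrics()], [exportNetwork()]
#' @export
setClass("CommNetwork",
         slots = c(condition = "character", nodes = "character",
                   edges = "data.frame", directions = "data.frame"))

setValidity("CommNetwork", function(object) {
    if (length(object@condition) != 1L) return("condition must be length 1")
    e <- object@edges
    if (!all(c("sender", "receiver", "weight") %in% names(e)))
        return("edges must have columns sender, receiver, weight")
    if (nrow(e) && any(e$weight < 0)) return("edge weights must be >= 0")
    if (nrow(e) && !all(c(e$sender, e$receiver) %in% object@nodes))
        return("edge endpoints must be listed in nodes")
    TRUE
})

#' Simulation configuration for the synthetic snRNA-seq generator
#'
#' Describes a synthetic study: gene panel size (including mitochondrial
#' \code{MT-*} and ribosomal \code{RPL*}/\code{RPS*} genes), cell types and
#' per-type cell counts per condition (first condition = control), the
#' negative-binomial baseline means and dispersion, mean-preserving log-normal
#' library-size heterogeneity, planted multiplicative ligand-receptor effects,
#' counts of QC-violating outlier cells, and the seed that fully determines
#' the output.
#'
#' @slot nGenes total number of genes (>= ligand-receptor + mito + ribo genes).
#' @slot nMito,nRibo number of \code{MT-}-prefixed and \code{RPL}/\code{RPS}-
#'   prefixed genes in the panel.
#' @slot cellTypes character vector of cell-type labels.
#' @slot conditions character vector of condition labels; the first is the
#'   control.
#' @slot cells integer matrix (cell type x condition) of cell counts.
#' @slot baselineMean NB mean for background genes (scalar) or per-gene vector
#'   of length \code{nGenes}.
#' @slot lrBaselineMean NB mean used for ligand/receptor genes when
#'   \code{baselineMean} is scalar.
#' @slot dispersion NB size parameter (shared across genes).
#' @slot sizeFactorSd sdlog of the per-cell size factor distribution.
#' @slot effects data.frame of planted effects with columns \code{condition},
#'   \code{cell_type}, \code{pair_id}, \code{gene}, \code{side},
#'   \code{multiplier}.
#' @slot qcOutliers named integer vector with entries \code{high_mito},
#'   \code{low_genes}, \code{high_genes}.
#' @slot seed integer seed.
#'
#' @seealso [simConfig()], [simulateCounts()]
#' @export
setClass("SimConfig",
         slots = c(nGenes = "integer", nMito = "integer", nRibo = "integer",
                   cellTypes = "character", conditions = "character",
                   cells = "matrix", baselineMean = "numeric",
                   lrBaselineMean = "numeric", dispersion = "numeric",
                   sizeFactorSd = "numeric", effects = "data.frame",
                   qcOutliers = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
    msgs <- character()
    if (object@nGenes < 1L) msgs <- c(msgs, "nGenes must be positive")
    if (anyDuplicated(object@conditions))
        msgs <- c(msgs, "condition labels must be unique (first is the control)")
    if (anyDuplicated(object@cellTypes))
        msgs <- c(msgs, "cell-type labels must be unique")
    if (any(object@cells < 0)) msgs <- c(msgs, "cell counts must be >= 0")
    if (!identical(dim(object@cells),
                   c(length(object@cellTypes), length(object@conditions))))
        msgs <- c(msgs, "cells must be a cellTypes x conditions matrix")
    if (any(object@baselineMean <= 0) || any(object@lrBaselineMean <= 0))
        msgs <- c(msgs, "baseline means must be > 0")
    if (!length(object@baselineMean) %in% c(1L, object@nGenes))
        msgs <- c(msgs, "baselineMean must be scalar or length nGenes")
    if (object@dispersion <= 0) msgs <- c(msgs, "dispersion must be > 0")
    if (object@sizeFactorSd < 0) msgs <- c(msgs, "sizeFactorSd must be >= 0")
    if (nrow(object@effects)) {
        need <- c("condition", "cell_type", "pair_id", "gene", "side", "multiplier")
        if (!all(need %in% names(object@effects)))
            msgs <- c(msgs, paste("effects needs columns:",
                                  paste(need, collapse = ", ")))
        else {
            if (any(object@effects$multiplier <= 0))
                msgs <- c(msgs, "effect multipliers must be > 0")
            if (!all(object@effects$side %in% c("ligand", "receptor", "both", "gene")))
                msgs <- c(msgs, "effect side must be ligand/receptor/both/gene")
            if (!all(object@effects$condition %in% object@conditions))
                msgs <- c(msgs, "effect conditions must appear in conditions")
            if (!all(object@effects$cell_type %in% object@cellTypes))
                msgs <- c(msgs, "effect cell types must appear in cellTypes")
        }
    }
    if (!all(c("high_mito", "low_genes", "high_genes") %in% names(object@qcOutliers)) ||
        any(object@qcOutliers < 0))
        msgs <- c(msgs, "qcOutliers must name non-negative high_mito/low_genes/high_genes")
    if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
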