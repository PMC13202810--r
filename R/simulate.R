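#' Build a planted-effect table for the simulator
#'
#' Each row plants one multiplicative effect on the negative-binomial mean of
#' one or two genes, in one cell type under one condition. Effects can be
#' addressed by ligand-receptor pair (with \code{side} selecting the ligand
#' gene, the receptor gene, or both) or directly by gene symbol
#' (\code{side = "gene"}).
#'
#' @param condition,cell_type labels the effect applies to.
#' @param pair_id pair identifier resolved against the pair table given to
#'   [simulateCounts()]; \code{NA} when \code{gene} is used.
#' @param gene gene symbol for \code{side = "gene"} effects; \code{NA} otherwise.
#' @param side one of \code{"ligand"}, \code{"receptor"}, \code{"both"},
#'   \code{"gene"}.
#' @param multiplier positive multiplier applied to the NB mean.
#' @return data.frame suitable for the \code{effects} slot of
#'   [SimConfig-class].
#' @export
plantedEffects <- function(condition = character(), cell_type = character(),
                           pair_id = NA_character_, gene = NA_character_,
                           side = "ligand", multiplier = numeric()) {
    n <- length(condition)
    data.frame(condition = as.character(condition),
               cell_type = rep_len(as.character(cell_type), n),
               pair_id = rep_len(as.character(pair_id), n),
               gene = rep_len(as.character(gene), n),
               side = rep_len(as.character(side), n),
               multiplier = rep_len(as.numeric(multiplier), n),
               stringsAsFactors = FALSE)
}

#' Create a simulation configuration
#'
#' Defaults describe the package's reference synthetic study: the four
#' cardiac cell types entering the communication analysis (CM, CF, EC,
#' ENDOC), six diagnostic conditions with \code{"Donor"} as control, 100
#' cells per cell type per condition, a 1,000-gene panel containing the
#' bundled ligand-receptor genes plus mitochondrial (\code{MT-*}) and
#' ribosomal (\code{RPL*}/\code{RPS*}) genes, negative-binomial counts with
#' shared dispersion (size) 2, background gene mean 0.5 and ligand/receptor
#' gene mean 2, and mean-preserving log-normal library-size heterogeneity
#' (sdlog 0.3).
#'
#' @param nGenes,nMito,nRibo gene panel composition.
#' @param cellTypes,conditions group labels; the first condition is the
#'   control.
#' @param cellsPerGroup scalar, or cell type x condition matrix, of cell
#'   counts.
#' @param baselineMean background-gene NB mean (scalar) or per-gene vector.
#' @param lrBaselineMean NB mean for ligand/receptor genes (used when
#'   \code{baselineMean} is scalar).
#' @param dispersion shared NB size parameter.
#' @param sizeFactorSd sdlog of per-cell size factors (0 disables).
#' @param effects planted effects, see [plantedEffects()].
#' @param qcOutliers named counts of planted QC-violating cells
#'   (\code{high_mito}, \code{low_genes}, \code{high_genes}).
#' @param seed integer seed; fully determines [simulateCounts()] output.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(nGenes = 1000L, nMito = 10L, nRibo = 20L,
                      cellTypes = c("CM", "CF", "EC", "ENDOC"),
                      conditions = c("Donor", "TOF", "Neo_HLHS", "IF_HLHS",
                                     "DCM", "HCM"),
                      cellsPerGroup = 100L,
                      baselineMean = 0.5, lrBaselineMean = 2,
                      dispersion = 2, sizeFactorSd = 0.3,
                      effects = plantedEffects(),
                      qcOutliers = c(high_mito = 0L, low_genes = 0L,
                                     high_genes = 0L),
                      seed = 1L) {
    if (is.matrix(cellsPerGroup)) {
        cells <- cellsPerGroup
    } else {
        cells <- matrix(as.integer(cellsPerGroup), nrow = length(cellTypes),
                        ncol = length(conditions))
    }
    dimnames(cells) <- list(cellTypes, conditions)
    storage.mode(cells) <- "integer"
    out <- c(high_mito = 0L, low_genes = 0L, high_genes = 0L)
    out[names(qcOutliers)] <- as.integer(qcOutliers)
    new("SimConfig", nGenes = as.integer(nGenes), nMito = as.integer(nMito),
        nRibo = as.integer(nRibo), cellTypes = cellTypes,
        conditions = conditions, cells = cells,
        baselineMean = as.numeric(baselineMean),
        lrBaselineMean = as.numeric(lrBaselineMean),
        dispersion = as.numeric(dispersion),
        sizeFactorSd = as.numeric(sizeFactorSd),
        effects = effects, qcOutliers = out, seed = as.integer(seed))
}

#' Read a simulation configuration from YAML
#'
#' Field names mirror the [simConfig()] arguments (snake_case accepted);
#' \code{effects} is a list of mappings with keys \code{condition},
#' \code{cell_type}, \code{pair_id} or \code{gene}, \code{side},
#' \code{multiplier}.
#'
#' @param path YAML file path.
#' @return a [SimConfig-class].
#' @export
readSimConfig <- function(path) {
    y <- yaml::read_yaml(path)
    pick <- function(...) {
        for (k in c(...)) if (!is.null(y[[k]])) return(y[[k]])
        NULL
    }
    args <- list()
    map <- list(nGenes = c("nGenes", "n_genes"), nMito = c("nMito", "genes_mito"),
                nRibo = c("nRibo", "genes_ribo"),
                cellTypes = c("cellTypes", "cell_types"),
                conditions = "conditions",
                cellsPerGroup = c("cellsPerGroup", "cells_per_group"),
                baselineMean = c("baselineMean", "baseline_mean"),
                lrBaselineMean = c("lrBaselineMean", "lr_baseline_mean"),
                dispersion = "dispersion",
                sizeFactorSd = c("sizeFactorSd", "size_factor_sd"),
                seed = "seed")
    for (nm in names(map)) {
        v <- do.call(pick, as.list(map[[nm]]))
        if (!is.null(v)) args[[nm]] <- unlist(v)
    }
    qc <- pick("qcOutliers", "qc_outliers")
    if (!is.null(qc)) args$qcOutliers <- unlist(qc)
    eff <- pick("effects", "planted_effects")
    if (!is.null(eff) && length(eff)) {
        bad <- vapply(eff, function(e)
            is.null(e$condition) || is.null(e$cell_type) || is.null(e$multiplier) ||
                (is.null(e$pair_id) && is.null(e$gene)), logical(1))
        if (any(bad))
            stop("invalid simulation config: effects entries ",
                 paste(which(bad), collapse = ", "),
                 " need condition, cell_type, multiplier, and pair_id or gene")
        args$effects <- do.call(rbind, lapply(eff, function(e)
            plantedEffects(condition = e$condition, cell_type = e$cell_type,
                           pair_id = e$pair_id %||% NA_character_,
                           gene = e$gene %||% NA_character_,
                           side = e$side %||% if (is.null(e$pair_id)) "gene" else "ligand",
                           multiplier = e$multiplier)))
    }
    do.call(simConfig, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.mitoNames <- function(n) {
    canon <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6",
               "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6",
               "MT-CYB")
    if (n <= length(canon)) canon[seq_len(n)]
    else c(canon, sprintf("MT-G%d", seq_len(n - length(canon))))
}

.riboNames <- function(n) {
    i <- seq_len(n)
    ifelse(i %% 2L == 1L, sprintf("RPL%d", (i + 1L) %/% 2L),
           sprintf("RPS%d", i %/% 2L))
}

#' Gene panel implied by a simulation configuration
#'
#' Ligand/receptor genes first, then mitochondrial and ribosomal genes, then
#' background filler genes, to a total of \code{nGenes}.
#'
#' @param config a [SimConfig-class].
#' @param pairs [LRTable-class] whose genes are included in the panel.
#' @return character vector of length \code{nGenes}.
#' @export
simGenePanel <- function(config, pairs = cardiacLRPairs()) {
    lr <- unique(c(ligands(pairs), receptors(pairs)))
    fixed <- length(lr) + config@nMito + config@nRibo
    if (config@nGenes < fixed)
        stop("nGenes (", config@nGenes, ") must be >= ligand-receptor + mito ",
             "+ ribo genes (", fixed, ")")
    c(lr, .mitoNames(config@nMito), .riboNames(config@nRibo),
      sprintf("GENE%05d", seq_len(config@nGenes - fixed)))
}

.resolveEffects <- function(effects, pairs, genes) {
    if (nrow(effects) == 0L)
        return(data.frame(condition = character(), cell_type = character(),
                          gene = character(), multiplier = numeric(),
                          stringsAsFactors = FALSE))
    rows <- lapply(seq_len(nrow(effects)), function(i) {
        e <- effects[i, ]
        if (e$side == "gene") {
            g <- e$gene
        } else {
            j <- match(e$pair_id, pairIds(pairs))
            if (is.na(j))
                stop("planted effect references unknown pair_id: ", e$pair_id)
            g <- switch(e$side,
                        ligand = ligands(pairs)[j],
                        receptor = receptors(pairs)[j],
                        both = unique(c(ligands(pairs)[j], receptors(pairs)[j])))
        }
        if (any(!g %in% genes))
            stop("planted effect targets gene(s) not in the simulated panel: ",
                 paste(setdiff(g, genes), collapse = ", "))
        data.frame(condition = e$condition, cell_type = e$cell_type, gene = g,
                   multiplier = e$multiplier, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Simulate a sparse snRNA-seq count matrix with known ground truth
#'
#' Counts are drawn gene-wise from a negative binomial whose mean for each
#' (gene, cell type, condition) block is the baseline mean times all planted
#' multipliers applying to that block, further scaled per cell by a
#' mean-preserving log-normal size factor. Mitochondrial and ribosomal genes
#' carry \code{MT-} / \code{RPL}/\code{RPS} prefixes so the QC stage can be
#' exercised; configured QC-violating outlier cells are appended with
#' annotation flags. The configuration seed fully determines the output.
#'
#' @param config a [SimConfig-class].
#' @param pairs [LRTable-class] used to resolve pair-addressed planted
#'   effects and to seed the gene panel.
#'
#' @return a \linkS4class{SingleCellExperiment} with a sparse integer
#'   \code{counts} assay; colData columns \code{sample}, \code{condition},
#'   \code{cell_type}, \code{qc_planted}; and
#'   \code{metadata()$ground_truth} holding the realized per-gene effect
#'   table, per-cell QC-violation flags, and per-(cell type, condition) true
#'   DE gene sets.
#' @examples
#' sce <- simulateCounts(simConfig(cellsPerGroup = 20, seed = 7))
#' dim(sce)
#' @export
simulateCounts <- function(config, pairs = cardiacLRPairs()) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    genes <- simGenePanel(config, pairs)
    nG <- config@nGenes
    base <- if (length(config@baselineMean) == 1L) {
        b <- rep(config@baselineMean, nG)
        nLR <- length(unique(c(ligands(pairs), receptors(pairs))))
        b[seq_len(nLR)] <- config@lrBaselineMean
        b
    } else config@baselineMean
    eff <- .resolveEffects(config@effects, pairs, genes)

    set.seed(config@seed)
    blocks <- list(); bc <- list(); ann <- list()
    for (cond in config@conditions) {
        for (ct in config@cellTypes) {
            n <- config@cells[ct, cond]
            if (n == 0L) next
            mu <- base
            sel <- eff$condition == cond & eff$cell_type == ct
            if (any(sel)) for (k in which(sel)) {
                j <- match(eff$gene[k], genes)
                mu[j] <- mu[j] * eff$multiplier[k]
            }
            sf <- if (config@sizeFactorSd > 0)
                stats::rlnorm(n, meanlog = -config@sizeFactorSd^2 / 2,
                              sdlog = config@sizeFactorSd) else rep(1, n)
            m <- matrix(stats::rnbinom(nG * n, mu = outer(mu, sf),
                                       size = config@dispersion),
                        nrow = nG, ncol = n)
            blocks[[length(blocks) + 1L]] <- m
            bc[[length(bc) + 1L]] <- paste(ct, cond, seq_len(n), sep = "_")
            ann[[length(ann) + 1L]] <-
                data.frame(sample = paste0(cond, "_s1"), condition = cond,
                           cell_type = ct, qc_planted = "none",
                           stringsAsFactors = FALSE)[rep(1L, n), ]
        }
    }
    # planted QC violators, appended in the control condition's first cell type
    ct0 <- config@cellTypes[1L]; cond0 <- config@conditions[1L]
    addOutlier <- function(rule, i) {
        sf <- stats::rlnorm(1, -config@sizeFactorSd^2 / 2, config@sizeFactorSd)
        v <- stats::rnbinom(nG, mu = base * sf, size = config@dispersion)
        if (rule == "high_mito") {
            mito <- grep("^MT-", genes)[1L]
            v[mito] <- v[mito] + max(sum(v), 1L)      # mito fraction > 50%
        } else if (rule == "low_genes") {
            keep <- sample.int(nG, min(150L, nG))
            v[-keep] <- 0L                            # < 200 detected genes
        } else if (rule == "high_genes") {
            v <- v + 1L                               # all nGenes detected
        }
        blocks[[length(blocks) + 1L]] <<- matrix(v, ncol = 1L)
        bc[[length(bc) + 1L]] <<- paste(ct0, cond0, rule, i, sep = "_")
        ann[[length(ann) + 1L]] <<-
            data.frame(sample = paste0(cond0, "_s1"), condition = cond0,
                       cell_type = ct0, qc_planted = rule,
                       stringsAsFactors = FALSE)
    }
    for (rule in c("high_mito", "low_genes", "high_genes"))
        for (i in seq_len(config@qcOutliers[[rule]])) addOutlier(rule, i)
    if (config@qcOutliers[["high_genes"]] > 0L && nG <= 6000L)
        warning("high_genes outliers only violate the default QC rule when ",
                "nGenes > 6000 (panel has ", nG, " genes)")

    counts <- methods::as(do.call(cbind, blocks), "CsparseMatrix")
    barcodes <- unlist(bc)
    dimnames(counts) <- list(genes, barcodes)
    coldata <- do.call(rbind, ann)
    rownames(coldata) <- barcodes

    deTruth <- unique(eff[, c("condition", "cell_type", "gene")])
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(coldata))
    S4Vectors::metadata(sce)$sim_config <- config
    S4Vectors::metadata(sce)$ground_truth <- list(
        effects = eff,
        qc_flags = stats::setNames(coldata$qc_planted, barcodes),
        de_status = deTruth)
    sce
}
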