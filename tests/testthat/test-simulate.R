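test_that("identical config and seed reproduce the dataset bit for bit", {
    cfg <- simConfig(cellsPerGroup = 15, seed = 11,
                     qcOutliers = c(high_mito = 1, low_genes = 1))
    a <- simulateCounts(cfg)
    b <- simulateCounts(cfg)
    expect_identical(as.matrix(SummarizedExperiment::assay(a, "counts")),
                     as.matrix(SummarizedExperiment::assay(b, "counts")))
    expect_identical(colnames(a), colnames(b))

    cfg2 <- simConfig(cellsPerGroup = 15, seed = 12,
                      qcOutliers = c(high_mito = 1, low_genes = 1))
    c2 <- simulateCounts(cfg2)
    expect_identical(dim(a), dim(c2))
    expect_false(identical(as.matrix(SummarizedExperiment::assay(a, "counts")),
                           as.matrix(SummarizedExperiment::assay(c2, "counts"))))
})

test_that("negative-binomial means recover the configured values", {
    # single group of 2000 cells, configured gene mean 5, dispersion 10
    cfg <- simConfig(nGenes = 60, nMito = 2, nRibo = 2,
                     cellTypes = "CM", conditions = "Donor",
                     cellsPerGroup = 2000, baselineMean = 5,
                     lrBaselineMean = 5, dispersion = 10, seed = 42)
    sce <- simulateCounts(cfg)
    counts <- SummarizedExperiment::assay(sce, "counts")
    se <- sqrt((5 + 25 / 10) / 2000)
    expect_lt(abs(mean(counts["GENE00001", ]) - 5), 3 * se)

    # a planted ligand multiplier scales the raw-count mean ~4x vs control
    cfg4 <- simConfig(nGenes = 60, nMito = 2, nRibo = 2,
                      cellTypes = c("CM", "CF"), conditions = c("Donor", "D"),
                      cellsPerGroup = 2000, dispersion = 10, seed = 7,
                      effects = plantedEffects("D", "CF",
                                               pair_id = "IGF2_IGF1R",
                                               side = "ligand",
                                               multiplier = 4))
    s4 <- simulateCounts(cfg4)
    cd <- SummarizedExperiment::colData(s4)
    cts <- SummarizedExperiment::assay(s4, "counts")
    x1 <- cts["IGF2", cd$condition == "D" & cd$cell_type == "CF"]
    x0 <- cts["IGF2", cd$condition == "Donor" & cd$cell_type == "CF"]
    ratio <- mean(x1) / mean(x0)
    seRatio <- ratio * sqrt(var(x1) / length(x1) / mean(x1)^2 +
                            var(x0) / length(x0) / mean(x0)^2)
    expect_lt(abs(ratio - 4), 3 * seRatio)
    # the receptor side is untouched
    expect_false("IGF1R" %in%
        S4Vectors::metadata(s4)$ground_truth$effects$gene)
})

test_that("low-mean low-dispersion settings give a sparse matrix", {
    cfg <- simConfig(nGenes = 200, nMito = 2, nRibo = 2, cellTypes = "CM",
                     conditions = "Donor", cellsPerGroup = 200,
                     baselineMean = 1, lrBaselineMean = 1, dispersion = 1,
                     seed = 5)
    counts <- SummarizedExperiment::assay(simulateCounts(cfg), "counts")
    expect_gte(mean(as.matrix(counts) == 0), 0.5)
})

test_that("QC outliers are planted, flagged, and violate the rules", {
    cfg <- simConfig(cellsPerGroup = 20, seed = 2,
                     qcOutliers = c(high_mito = 2, low_genes = 3))
    sce <- simulateCounts(cfg)
    gt <- S4Vectors::metadata(sce)$ground_truth
    expect_identical(sum(gt$qc_flags == "high_mito"), 2L)
    expect_identical(sum(gt$qc_flags == "low_genes"), 3L)
    qc <- computeQCMetrics(sce)
    hm <- qc$barcode[gt$qc_flags == "high_mito"]
    expect_true(all(qc$pct_mito[qc$barcode %in% hm] > 20))
    lg <- qc$barcode[gt$qc_flags == "low_genes"]
    expect_true(all(qc$n_genes_detected[qc$barcode %in% lg] < 200))
})

test_that("planted effects must reference simulated genes", {
    expect_error(
        simulateCounts(simConfig(
            effects = plantedEffects("TOF", "CF", gene = "NOPE",
                                     side = "gene", multiplier = 2))),
        "not in the simulated panel")
    expect_error(
        simulateCounts(simConfig(
            effects = plantedEffects("TOF", "CF", pair_id = "FAKE_PAIR",
                                     multiplier = 2))),
        "unknown pair_id")
    # every resolved effect maps to >= 1 gene present in the matrix
    sce <- simulateCounts(simConfig(
        cellsPerGroup = 5,
        effects = plantedEffects("TOF", "CF", pair_id = "FN1_SDC4",
                                 side = "both", multiplier = 2)))
    eff <- S4Vectors::metadata(sce)$ground_truth$effects
    expect_true(all(eff$gene %in% rownames(sce)))
    expect_setequal(eff$gene, c("FN1", "SDC4"))
})

test_that("10x bundle writing round-trips exactly", {
    dir <- withr::local_tempdir()
    cfg <- simConfig(cellsPerGroup = 8, seed = 3)
    sce <- simulateCounts(cfg)
    write10x(sce, dir)
    back <- read10x(dir)
    expect_identical(as.matrix(SummarizedExperiment::assay(back, "counts")),
                     as.matrix(SummarizedExperiment::assay(sce, "counts")))
    expect_identical(rownames(back), rownames(sce))
    expect_identical(colnames(back), colnames(sce))
    expect_identical(back$condition, sce$condition)
    expect_identical(back$cell_type, sce$cell_type)
    expect_true(file.exists(file.path(dir, "ground_truth.json")))
    header <- readLines(file.path(dir, "matrix.mtx"), n = 1)
    expect_match(header, "coordinate integer general")
})

test_that("an empty matrix writes and reads back as header-only files", {
    dir <- withr::local_tempdir()
    m <- Matrix::Matrix(0L, nrow = 3, ncol = 0, sparse = TRUE,
                        dimnames = list(c("A", "B", "C"), NULL))
    sce <- SingleCellExperiment::SingleCellExperiment(
        assays = list(counts = m))
    write10x(sce, dir)
    back <- read10x(dir)
    expect_identical(dim(back), c(3L, 0L))
    expect_identical(rownames(back), c("A", "B", "C"))
})

test_that("the mtx body lists exactly the nonzero entries", {
    dir <- withr::local_tempdir()
    m <- matrix(0L, 3, 2, dimnames = list(c("A", "B", "C"), c("c1", "c2")))
    m[1, 1] <- 2L; m[3, 2] <- 1L
    sce <- makeSCE(m, condition = c("Donor", "Donor"),
                   cell_type = c("CM", "CM"))
    write10x(sce, dir)
    lines <- readLines(file.path(dir, "matrix.mtx"))
    body <- lines[-(1:3)]
    expect_identical(sort(body), sort(c("1 1 2", "3 2 1")))
    expect_identical(lines[3], "3 2 2")
})

test_that("YAML simulation configs parse into equivalent objects", {
    path <- withr::local_tempfile(fileext = ".yaml")
    writeLines(c("n_genes: 120", "genes_mito: 3", "genes_ribo: 4",
                 "cell_types: [CM, CF]", "conditions: [Donor, TOF]",
                 "cells_per_group: 12", "dispersion: 1.5", "seed: 9",
                 "planted_effects:",
                 "  - condition: TOF", "    cell_type: CF",
                 "    pair_id: IGF2_IGF1R", "    side: ligand",
                 "    multiplier: 4"), path)
    cfg <- readSimConfig(path)
    expect_s4_class(cfg, "SimConfig")
    expect_identical(cfg@nGenes, 120L)
    expect_identical(cfg@effects$pair_id, "IGF2_IGF1R")
    expect_identical(cfg@effects$multiplier, 4)
    a <- simulateCounts(cfg)
    expect_identical(dim(a), c(120L, 48L))

    writeLines(c("planted_effects:", "  - condition: TOF"), path)
    expect_error(readSimConfig(path), "effects entries")
})
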