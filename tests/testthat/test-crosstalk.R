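pairLR <- function(l = "L", r = "R") LRTable(l, r, "demo")

test_that("potential and score reproduce their worked examples", {
    m <- matrix(c(1, 2, 3, 0, 4, 0), nrow = 2, byrow = TRUE,
                dimnames = list(c("L", "R"), paste0("c", 1:3)))
    expect_equal(crosstalkPotential(m, 1:3, 2:3, pairLR()), 4)      # 2 * 2
    m0 <- m; m0["L", ] <- 0
    expect_equal(crosstalkPotential(m0, 1:3, 2:3, pairLR()), 0)

    m2 <- matrix(c(1, 1, 1, 2, 0, 0), nrow = 2, byrow = TRUE,
                 dimnames = list(c("L", "R"), paste0("c", 1:3)))
    expect_equal(crosstalkScore(m2, 1:3, 1:2, pairLR()), sqrt(100 * 50))
    expect_equal(crosstalkScore(m2, 1:3, 3, pairLR()), 0)           # no receptor
    m3 <- matrix(1, 2, 3, dimnames = dimnames(m2))
    expect_equal(crosstalkScore(m3, 1:3, 1:3, pairLR()), 100)       # upper bound

    expect_error(crosstalkPotential(m, integer(), 1:2, pairLR()), "non-empty")
    expect_error(crosstalkPotential(m, 1:2, 1:2, pairLR("L", "NOPE")),
                 "not in matrix")
})

test_that("statistics equal the brute-force per-cell oracle", {
    set.seed(30)
    m <- randomNormMatrix(50, 40)
    pairs <- LRTable(paste0("G", 1:10), paste0("G", 11:20), "demo")
    sender <- sample(colnames(m), 15)
    receiver <- sample(colnames(m), 12)
    for (i in 1:10) {
        p <- pairs[i]
        expect_equal(crosstalkPotential(m, sender, receiver, p),
                     oraclePotential(m, sender, receiver, ligands(p),
                                     receptors(p)),
                     tolerance = 1e-10)
        expect_equal(crosstalkScore(m, sender, receiver, p),
                     oracleScore(m, sender, receiver, ligands(p),
                                 receptors(p)),
                     tolerance = 1e-10)
    }
})

# small annotated dataset: 2 conditions x 3 types, controllable group sizes
makeXtSCE <- function(nPer = c(CM = 20, CF = 20, EC = 20),
                      conds = c("Donor", "D"), seed = 31) {
    set.seed(seed)
    types <- rep(rep(names(nPer), nPer), length(conds))
    cond <- rep(conds, each = sum(nPer))
    genes <- c("L", "R", "X1", "X2")
    m <- matrix(abs(rnorm(length(genes) * length(types))), length(genes),
                dimnames = list(genes, NULL))
    makeSCE(m, condition = cond, cell_type = types, normalized = TRUE)
}

test_that("the minimum-cell rule flags undersized groups as invalid", {
    sce <- makeXtSCE(nPer = c(CM = 20, CF = 9, EC = 20))
    pairs <- pairLR()
    res <- computeCrosstalk(sce, pairs,
                            directions = data.frame(sender = c("CF", "EC"),
                                                    receiver = c("CM", "CM")),
                            min_cells = 10)
    rec <- crosstalkRecords(res)
    cf <- rec[rec$sender == "CF", ]
    expect_true(all(!cf$valid))
    expect_true(all(is.na(cf$potential)))
    ec <- rec[rec$sender == "EC", ]
    expect_true(all(ec$valid))
    expect_true(all(is.finite(ec$potential)))
    # exactly 10 cells is enough
    res10 <- computeCrosstalk(makeXtSCE(nPer = c(CM = 10, CF = 10, EC = 10)),
                              pairs,
                              directions = data.frame(sender = "CF",
                                                      receiver = "CM"))
    expect_true(all(crosstalkRecords(res10)$valid))
})

test_that("record grid covers conditions x directions x pairs", {
    sce <- makeXtSCE()
    pairs <- LRTable(c("L", "X1"), c("R", "X2"), c("a", "b"))
    dirs <- data.frame(sender = c("CF", "CM", "EC"),
                       receiver = c("CM", "EC", "CM"))
    res <- computeCrosstalk(sce, pairs, directions = dirs)
    expect_identical(nrow(crosstalkRecords(res)), 2L * 3L * 2L)
    expect_error(computeCrosstalk(sce, pairs[integer()]), "empty")
    expect_error(computeCrosstalk(sce, pairs,
                                  directions = data.frame(sender = "ZZ",
                                                          receiver = "CM")),
                 "not in annotation")
})

test_that("homophilic pairs use the same gene on both sides", {
    sce <- makeXtSCE()
    m <- SingleCellExperiment::logcounts(sce)
    ann <- as.data.frame(SummarizedExperiment::colData(sce))
    hp <- LRTable("L", "L", "adhesion_junction")
    res <- computeCrosstalk(sce, hp,
                            directions = data.frame(sender = "EC",
                                                    receiver = "CM"))
    rec <- crosstalkRecords(res)
    don <- rec[rec$condition == "Donor", ]
    expected <- mean(m["L", ann$condition == "Donor" & ann$cell_type == "EC"]) *
        mean(m["L", ann$condition == "Donor" & ann$cell_type == "CM"])
    expect_equal(don$potential, expected, tolerance = 1e-12)
})

test_that("fold changes follow the epsilon-guarded log2 formula", {
    rec <- rbind(
        makeRecords("Donor", "CF", "CM", c("P1", "P2", "P3"), c(2, 0, 1)),
        makeRecords("D", "CF", "CM", c("P1", "P2", "P3"), c(4, 1, NA),
                    valid = c(TRUE, TRUE, FALSE)))
    fc <- foldChangeVsControl(rec, control = "Donor")
    get <- function(p, cond) fc$log2fc[fc$pair_id == p & fc$condition == cond]
    expect_equal(get("P1", "D"), 1, tolerance = 1e-5)        # 4 vs 2
    expect_equal(get("P1", "Donor"), 0)                      # control vs itself
    expect_equal(get("P2", "D"), log2((1 + 1e-6) / 1e-6), tolerance = 1e-6)
    expect_true(is.na(get("P3", "D")))                       # invalid, not 0
    expect_error(foldChangeVsControl(rec, control = "HCM"), "absent")
})

test_that("category summaries average fold changes and total strength", {
    pairs <- LRTable(c("A", "B", "C"), c("A2", "B2", "C2"),
                     c("cat1", "cat1", "cat2"))
    rec <- rbind(
        makeRecords("Donor", "CF", "CM", c("A_A2", "B_B2", "C_C2"), c(2, 4, 5)),
        makeRecords("D", "CF", "CM", c("A_A2", "B_B2", "C_C2"), c(4, 8, 5)))
    cs <- categorySummary(rec, pairs = pairs, control = "Donor")
    d1 <- cs[cs$condition == "D" & cs$category == "cat1", ]
    expect_equal(d1$mean_log2fc, 1, tolerance = 1e-6)        # both doubled
    expect_equal(d1$pct_of_baseline, 200, tolerance = 1e-6)
    d2 <- cs[cs$condition == "D" & cs$category == "cat2", ]
    expect_equal(d2$mean_log2fc, 0, tolerance = 1e-6)
    expect_equal(d2$pct_of_baseline, 100, tolerance = 1e-6)
    don <- cs[cs$condition == "Donor", ]
    expect_equal(don$pct_of_baseline, c(100, 100))           # exactly
    expect_equal(don$mean_log2fc, c(0, 0))

    # hand-computed mean over {1, 2, 3}
    rec2 <- rbind(
        makeRecords("Donor", "CF", "CM", c("A_A2", "B_B2", "C_C2"), c(1, 1, 1)),
        makeRecords("D", "CF", "CM", c("A_A2", "B_B2", "C_C2"), c(2, 4, 8)))
    pairs2 <- LRTable(c("A", "B", "C"), c("A2", "B2", "C2"), "one")
    cs2 <- categorySummary(rec2, pairs = pairs2, control = "Donor")
    expect_equal(cs2$mean_log2fc[cs2$condition == "D"], 2, tolerance = 1e-6)

    # zero valid control potential propagates NA with a warning
    rec3 <- rbind(makeRecords("Donor", "CF", "CM", "A_A2", NA, valid = FALSE),
                  makeRecords("D", "CF", "CM", "A_A2", 3))
    expect_warning(cs3 <- categorySummary(rec3, pairs = pairs2[1],
                                          control = "Donor"),
                   "no valid control")
    expect_true(is.na(cs3$pct_of_baseline[cs3$condition == "D"]))
})

test_that("interaction ranking means valid potentials and breaks ties by id", {
    rec <- rbind(
        makeRecords("Donor", "CF", "CM", c("PB", "PA", "PC"), c(10, 1, 5)),
        makeRecords("D", "CF", "CM", c("PB", "PA", "PC"), c(10, 1, NA),
                    valid = c(TRUE, TRUE, FALSE)))
    top <- topInteractions(rec, n = 25)
    expect_identical(nrow(top), 3L)                          # clamp
    expect_identical(top$pair_id, c("PB", "PC", "PA"))
    expect_equal(top$mean_potential, c(10, 5, 1))
    # tie on overall mean: id ascending
    recTie <- makeRecords("Donor", "CF", "CM", c("ZZ", "AA"), c(2, 2))
    expect_identical(topInteractions(recTie)$pair_id, c("AA", "ZZ"))
    # brute-force oracle on a random table
    set.seed(32)
    recR <- makeRecords("Donor", "CF", "CM", sprintf("P%02d", 1:12),
                        runif(12, 0, 10))
    oracle <- sort(tapply(recR$potential, recR$pair_id, mean),
                   decreasing = TRUE)
    expect_identical(topInteractions(recR, 5)$pair_id, names(oracle)[1:5])
    expect_error(topInteractions(recR, 0), "n must be")
})

test_that("potential is bilinear and score depends only on support", {
    set.seed(33)
    m <- randomNormMatrix(10, 30)
    p <- LRTable("G1", "G2", "demo")
    sender <- 1:15; receiver <- 16:30
    base <- crosstalkPotential(m, sender, receiver, p)
    m2 <- m; m2["G1", sender] <- 3 * m2["G1", sender]
    expect_equal(crosstalkPotential(m2, sender, receiver, p), 3 * base,
                 tolerance = 1e-12)
    m3 <- m; m3[m3 > 0] <- m3[m3 > 0] * 7.7                  # same support
    expect_equal(crosstalkScore(m3, sender, receiver, p),
                 crosstalkScore(m, sender, receiver, p), tolerance = 1e-12)
})

test_that("cell permutations within groups leave records unchanged", {
    sce <- makeXtSCE()
    pairs <- LRTable(c("L", "X1"), c("R", "X2"), c("a", "b"))
    set.seed(34)
    perm <- sample(ncol(sce))
    res2 <- computeCrosstalk(sce[, perm], pairs)
    r1 <- crosstalkRecords(computeCrosstalk(sce, pairs))
    r2 <- crosstalkRecords(res2)
    key <- function(r) paste(r$condition, r$sender, r$receiver, r$pair_id)
    r2 <- r2[match(key(r1), key(r2)), ]
    expect_equal(r1$potential, r2$potential, tolerance = 1e-12)
    expect_equal(r1$score, r2$score, tolerance = 1e-12)
})
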