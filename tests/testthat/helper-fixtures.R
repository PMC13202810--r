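# Fixture builders and independent oracles used across the suite.

# SingleCellExperiment from a dense matrix + annotation vectors
makeSCE <- function(m, condition, cell_type,
                    sample = paste0(condition, "_s1"), normalized = FALSE) {
    m <- Matrix::Matrix(m, sparse = TRUE)
    if (is.null(colnames(m)))
        colnames(m) <- paste0("cell", seq_len(ncol(m)))
    if (is.null(rownames(m)))
        rownames(m) <- paste0("g", seq_len(nrow(m)))
    cd <- S4Vectors::DataFrame(sample = sample, condition = condition,
                               cell_type = cell_type,
                               row.names = colnames(m))
    assays <- if (normalized) list(counts = m, logcounts = m)
              else list(counts = m)
    SingleCellExperiment::SingleCellExperiment(assays = assays, colData = cd)
}

# random normalized matrix with gene names, for formula oracles
randomNormMatrix <- function(n_genes, n_cells, zero_frac = 0.4) {
    m <- matrix(stats::runif(n_genes * n_cells, 0, 5), n_genes, n_cells)
    m[stats::runif(length(m)) < zero_frac] <- 0
    dimnames(m) <- list(paste0("G", seq_len(n_genes)),
                        paste0("c", seq_len(n_cells)))
    m
}

# --- crosstalk oracles: naive per-cell accumulation ------------------------

oraclePotential <- function(m, sender, receiver, lig, rec) {
    sl <- 0
    for (cc in sender) sl <- sl + m[lig, cc]
    sr <- 0
    for (cc in receiver) sr <- sr + m[rec, cc]
    (sl / length(sender)) * (sr / length(receiver))
}

oracleScore <- function(m, sender, receiver, lig, rec) {
    nl <- 0
    for (cc in sender) if (m[lig, cc] > 0) nl <- nl + 1
    nr <- 0
    for (cc in receiver) if (m[rec, cc] > 0) nr <- nr + 1
    sqrt((100 * nl / length(sender)) * (100 * nr / length(receiver)))
}

# --- exact permutation oracle for the two-sided rank-sum test --------------

permWilcoxP <- function(x, y) {
    pooled <- c(x, y)
    r <- rank(pooled)
    n1 <- length(x)
    obs <- sum(r[seq_len(n1)])
    combos <- utils::combn(length(pooled), n1)
    stats <- apply(combos, 2L, function(idx) sum(r[idx]))
    ctr <- n1 * (length(pooled) + 1) / 2
    mean(abs(stats - ctr) >= abs(obs - ctr) - 1e-12)
}

# --- hypergeometric enumeration oracle for Fisher's exact test -------------

fisherOracleP <- function(a, b, c, d) {
    m <- a + b          # margin of row 1 (condition)
    n <- c + d          # margin of row 2 (control)
    k <- a + c          # column margin (in type)
    support <- max(0, k - n):min(k, m)
    dens <- stats::dhyper(support, m, n, k)
    dObs <- stats::dhyper(a, m, n, k)
    sum(dens[dens <= dObs * (1 + 1e-7)])
}

# --- naive O(n^3) agglomerative complete linkage ---------------------------
# returns the leaf order with the same deterministic rule the package
# documents: at every merge the subtree holding the smaller original index
# goes first

naiveCompleteLinkageOrder <- function(m) {
    n <- nrow(m)
    d <- as.matrix(stats::dist(m, method = "euclidean"))
    clusters <- lapply(seq_len(n), identity)   # ordered leaves per cluster
    while (length(clusters) > 1L) {
        best <- c(NA, NA); bestD <- Inf
        for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
            if (i >= j) next
            dc <- max(d[clusters[[i]], clusters[[j]]])
            if (dc < bestD - 1e-12) { bestD <- dc; best <- c(i, j) }
        }
        a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
        merged <- if (min(b) < min(a)) c(b, a) else c(a, b)
        clusters <- c(clusters[-best], list(merged))
    }
    clusters[[1]]
}

# crosstalk records data.frame built by hand (for summary-level tests)
makeRecords <- function(condition, sender, receiver, pair_id, potential,
                        score = 0, pct_ligand = 0, pct_receptor = 0,
                        n_sender = 100L, n_receiver = 100L, valid = TRUE) {
    data.frame(condition = condition, sender = sender, receiver = receiver,
               pair_id = pair_id, potential = potential, score = score,
               pct_ligand = pct_ligand, pct_receptor = pct_receptor,
               n_sender = n_sender, n_receiver = n_receiver, valid = valid,
               stringsAsFactors = FALSE)
}
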