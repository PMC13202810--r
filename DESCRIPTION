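Package: cardioCrosstalk
Title: Ligand-Receptor Crosstalk Analysis for Cardiac Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for quantifying intercellular communication in
    cardiac single-nucleus RNA-seq data. Starting from sparse gene-by-cell
    count matrices with per-cell condition and cell-type labels, it performs
    per-cell quality control and log-normalization, Wilcoxon rank-sum
    differential expression with Benjamini-Hochberg correction, cell-type
    compositional testing (Fisher's exact test), and ligand-receptor
    Crosstalk Potential and Crosstalk Score statistics over directed
    sender-receiver cell-type pairs, with condition-versus-control fold
    changes, functional-category summaries, and directed weighted
    communication networks. A negative-binomial single-cell count simulator
    with planted ligand-receptor effects makes every stage testable without
    access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
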