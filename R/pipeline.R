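#' Assemble a pipeline configuration
#'
#' Collects input locations, the control condition, and every stage
#' parameter (QC thresholds, normalization scale factor, DE settings,
#' minimum-cell rule, directions, fold-change pseudo-potential, ranking
#' depth) into a validated configuration list for [runPipeline()].
#'
#' @param input_dir directory with the 10x-convention bundle (see
#'   [read10x()]).
#' @param output_dir directory for the result bundle.
#' @param lr_table path to a ligand-receptor TSV ([readLRTable()]), or
#'   \code{NULL} for the bundled [cardiacLRPairs()].
#' @param control_condition control label (default \code{"Donor"}).
#' @param max_pct_mito,min_genes,max_genes QC thresholds (defaults 20, 200,
#'   6,000), see [filterCells()].
#' @param scale_factor normalization scale factor (default 10,000).
#' @param n_hvg number of highly variable genes to report (default 2,000).
#' @param min_pct DE expressing-fraction threshold (default 0.1).
#' @param alpha DE adjusted-p threshold (default 0.05).
#' @param min_cells minimum-cell rule for crosstalk (default 10).
#' @param directions sender-receiver directions data.frame (default
#'   [defaultDirections()]).
#' @param eps fold-change pseudo-count (default 1e-6).
#' @param top_n interaction-ranking depth (default 25).
#' @param de_cell_types cell types to test in the DE stage (\code{NULL} =
#'   all).
#' @param write_filtered_matrix also write the QC-filtered matrix as a 10x
#'   bundle under \code{output_dir/filtered/}.
#' @param seed integer seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return validated configuration list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(input_dir, output_dir, lr_table = NULL,
                           control_condition = "Donor", max_pct_mito = 20,
                           min_genes = 200, max_genes = 6000,
                           scale_factor = 10000, n_hvg = 2000, min_pct = 0.1,
                           alpha = 0.05, min_cells = 10,
                           directions = defaultDirections(), eps = 1e-6,
                           top_n = 25, de_cell_types = NULL,
                           write_filtered_matrix = FALSE, seed = 1L) {
    cfg <- list(input_dir = input_dir, output_dir = output_dir,
                lr_table = lr_table, control_condition = control_condition,
                max_pct_mito = max_pct_mito, min_genes = min_genes,
                max_genes = max_genes, scale_factor = scale_factor,
                n_hvg = n_hvg, min_pct = min_pct, alpha = alpha,
                min_cells = min_cells, directions = directions, eps = eps,
                top_n = top_n, de_cell_types = de_cell_types,
                write_filtered_matrix = isTRUE(write_filtered_matrix),
                seed = as.integer(seed))
    for (f in c("max_pct_mito", "min_genes", "max_genes", "scale_factor",
                "min_pct", "alpha", "min_cells", "eps", "top_n", "n_hvg"))
        if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
            stop("pipeline parameter '", f, "' must be positive")
    if (cfg$min_genes >= cfg$max_genes) stop("min_genes must be < max_genes")
    if (!all(c("sender", "receiver") %in% names(cfg$directions)))
        stop("directions must have columns sender, receiver")
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Parse a compact direction specification
#'
#' Turns \code{"CF:CM,CM:EC"} into a directions data.frame.
#'
#' @param spec character(1) of comma-separated \code{sender:receiver} pairs.
#' @return data.frame with columns \code{sender}, \code{receiver}.
#' @export
parseDirections <- function(spec) {
    parts <- strsplit(strsplit(spec, ",")[[1]], ":")
    if (any(lengths(parts) != 2L))
        stop("directions must be 'SENDER:RECEIVER' pairs, comma-separated")
    data.frame(sender = trimws(vapply(parts, `[`, "", 1L)),
               receiver = trimws(vapply(parts, `[`, "", 2L)),
               stringsAsFactors = FALSE)
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the [pipelineConfig()] arguments; \code{directions} may be a
#' compact string (\code{"CF:CM,CM:EC,EC:CM,CM:CF"}) or a list of
#' \code{{sender, receiver}} mappings.
#'
#' @param path YAML file path.
#' @param ... overrides taking precedence over the file.
#' @return a \code{"PipelineConfig"} list.
#' @export
readPipelineConfig <- function(path, ...) {
    y <- yaml::read_yaml(path)
    if (!is.null(y$directions)) {
        y$directions <- if (is.character(y$directions))
            parseDirections(y$directions)
        else do.call(rbind, lapply(y$directions, function(d)
            data.frame(sender = d$sender, receiver = d$receiver,
                       stringsAsFactors = FALSE)))
    }
    dots <- list(...)
    y[names(dots)] <- dots
    do.call(pipelineConfig, y)
}

.writeCsv <- function(df, dir, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
    nrow(df)
}

#' Run the full crosstalk pipeline
#'
#' Executes, in order: input loading, per-cell QC and filtering,
#' log-normalization, highly-variable-gene ranking, per-cell-type Wilcoxon
#' differential expression against the control, cell-type composition
#' testing, ligand-receptor crosstalk statistics with fold changes, category
#' summaries and interaction ranking, and per-condition communication
#' networks with topology metrics. Every stage logs its elapsed time and
#' record count; all outputs are written as CSV/JSON under
#' \code{output_dir}, together with \code{config.json} and a
#' \code{manifest.json} (config hash, seed, versions, per-stage row counts)
#' that suffices to re-run identically. Identical configuration yields
#' byte-identical outputs. A stage failure aborts with the stage name and
#' writes \code{incomplete.json} flagging the partial bundle.
#'
#' @param config a \code{"PipelineConfig"} from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param sce optionally, an already-loaded \linkS4class{SingleCellExperiment}
#'   (bypasses \code{input_dir}).
#' @return invisibly, a list with the main result objects and the manifest.
#' @export
runPipeline <- function(config, sce = NULL) {
    stopifnot(inherits(config, "PipelineConfig"))
    out <- config$output_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    set.seed(config$seed)
    counts_of <- list()
    t0 <- proc.time()[["elapsed"]]
    stage <- function(name, expr) {
        s <- proc.time()[["elapsed"]]
        res <- tryCatch(force(expr), error = function(e) {
            jsonlite::write_json(
                list(incomplete = TRUE, failed_stage = name,
                     error = conditionMessage(e)),
                file.path(out, "incomplete.json"), auto_unbox = TRUE)
            stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE)
        })
        message(sprintf("[%s] done in %.2fs", name,
                        proc.time()[["elapsed"]] - s))
        res
    }

    # -- load + validate -----------------------------------------------------
    inputs <- stage("load", {
        if (is.null(sce)) sce <- read10x(config$input_dir)
        pairs <- if (is.null(config$lr_table)) cardiacLRPairs()
                 else readLRTable(config$lr_table)
        ann <- .cellAnnotation(sce)
        if (!config$control_condition %in% ann$condition)
            stop("control condition '", config$control_condition,
                 "' not present in cell metadata")
        list(sce = sce, pairs = pairs)
    })
    sce <- inputs$sce; pairs <- inputs$pairs

    # -- qc -------------------------------------------------------------------
    qc <- stage("qc", {
        metrics <- computeQCMetrics(sce)
        keep <- filterCells(metrics, max_pct_mito = config$max_pct_mito,
                            min_genes = config$min_genes,
                            max_genes = config$max_genes)
        metrics$kept <- as.logical(keep)
        counts_of$qc_metrics <- .writeCsv(metrics, out, "qc_metrics.csv")
        sce[, keep]
    })
    if (config$write_filtered_matrix)
        stage("write_filtered", write10x(qc, file.path(out, "filtered")))

    # -- normalize + hvg ------------------------------------------------------
    norm <- stage("normalize", logNormalizeCounts(qc, config$scale_factor))
    stage("hvg", {
        hvg <- selectHVG(norm, n_top = config$n_hvg)
        counts_of$hvg <- .writeCsv(hvg, out, "hvg.csv")
        hvg
    })

    # -- differential expression ---------------------------------------------
    de <- stage("de", {
        rec <- runDE(norm, control = config$control_condition,
                     cell_types = config$de_cell_types,
                     min_pct = config$min_pct)
        if (is.null(rec)) rec <- summarizeDEGs(NULL)[0, ]
        counts_of$de_records <- .writeCsv(rec, out, "de_records.csv")
        smry <- summarizeDEGs(rec, alpha = config$alpha)
        counts_of$de_summary <- .writeCsv(smry, out, "de_summary.csv")
        list(records = rec, summary = smry)
    })

    # -- composition ----------------------------------------------------------
    comp <- stage("composition", {
        props <- cellTypeProportions(norm)
        counts_of$proportions <- .writeCsv(props, out, "proportions.csv")
        ct <- compositionTest(norm, control = config$control_condition,
                              eps = config$eps)
        counts_of$composition <- .writeCsv(ct, out, "composition.csv")
        ct
    })

    # -- crosstalk ------------------------------------------------------------
    xt <- stage("crosstalk", {
        uni <- restrictToUniverse(pairs, rownames(norm))
        if (nrow(uni$dropped))
            message("dropped ", nrow(uni$dropped),
                    " pair(s) with genes absent from the matrix")
        res <- computeCrosstalk(norm, pairs = uni$kept,
                                directions = config$directions,
                                min_cells = config$min_cells)
        counts_of$crosstalk_records <-
            .writeCsv(crosstalkRecords(res), out, "crosstalk_records.csv")
        fc <- foldChangeVsControl(res, control = config$control_condition,
                                  eps = config$eps)
        counts_of$foldchange <- .writeCsv(fc, out, "foldchange.csv")
        cs <- categorySummary(res, control = config$control_condition,
                              eps = config$eps)
        counts_of$category_summary <-
            .writeCsv(cs, out, "category_summary.csv")
        ti <- topInteractions(res, n = config$top_n)
        counts_of$top_interactions <-
            .writeCsv(ti, out, "top_interactions.csv")
        list(results = res, foldchange = fc, categories = cs, top = ti)
    })

    # -- networks -------------------------------------------------------------
    nets <- stage("network", {
        conds <- unique(crosstalkRecords(xt$results)$condition)
        nets <- list(); metricRows <- list()
        for (cond in conds) {
            net <- buildCommNetwork(xt$results, cond)
            nets[[cond]] <- net
            exportNetwork(net, file.path(out, paste0("network_", cond, ".json")),
                          format = "json")
            if (nrow(networkEdges(net))) {
                m <- networkMetrics(net)
                metricRows[[cond]] <- data.frame(
                    condition = cond, centralization = m$centralization,
                    fragmentation = m$fragmentation,
                    total_weight = sum(networkEdges(net)$weight),
                    n_edges = nrow(networkEdges(net)),
                    stringsAsFactors = FALSE)
            }
        }
        mdf <- do.call(rbind, c(metricRows, list(make.row.names = FALSE)))
        if (is.null(mdf))
            mdf <- data.frame(condition = character(),
                              centralization = numeric(),
                              fragmentation = numeric(),
                              total_weight = numeric(), n_edges = integer())
        counts_of$network_metrics <- .writeCsv(mdf, out, "network_metrics.csv")
        nets
    })

    # -- manifest -------------------------------------------------------------
    manifest <- stage("manifest", {
        cfgOut <- config
        cfgOut$directions <- as.list(cfgOut$directions)
        jsonlite::write_json(unclass(cfgOut), file.path(out, "config.json"),
                             auto_unbox = TRUE, digits = NA, null = "null")
        man <- list(
            pipeline = "cardioCrosstalk",
            version = as.character(utils::packageVersion("cardioCrosstalk")),
            r_version = paste(R.version$major, R.version$minor, sep = "."),
            seed = config$seed,
            config_md5 = unname(tools::md5sum(file.path(out, "config.json"))),
            stage_counts = counts_of,
            total_elapsed_s = NULL)
        jsonlite::write_json(man, file.path(out, "manifest.json"),
                             auto_unbox = TRUE, digits = NA, null = "null")
        man
    })
    message(sprintf("pipeline complete in %.2fs",
                    proc.time()[["elapsed"]] - t0))
    unlink(file.path(out, "incomplete.json"))
    invisible(list(sce = norm, qc = qc, de = de, composition = comp,
                   crosstalk = xt, networks = nets, manifest = manifest))
}
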