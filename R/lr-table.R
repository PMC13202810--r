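#' Construct a ligand-receptor pair table
#'
#' @param ligand,receptor character vectors of gene symbols (HGNC-style,
#'   matched case-sensitively downstream).
#' @param category character vector of functional-category labels; the
#'   vocabulary is open (e.g. \code{"growth_factor"}, \code{"ecm_structural"},
#'   \code{"ecm_adhesive"}, \code{"notch"}, \code{"morphogen"},
#'   \code{"metabolic"}, \code{"adhesion_junction"}).
#' @param pair_id optional unique identifiers; derived as
#'   \code{"LIGAND_RECEPTOR"} when missing.
#'
#' @return an [LRTable-class] with homophilic flags computed.
#' @examples
#' lr <- LRTable(c("IGF2", "PTPRM"), c("IGF1R", "PTPRM"),
#'               c("growth_factor", "adhesion_junction"))
#' isHomophilic(lr)
#' @export
LRTable <- function(ligand, receptor, category, pair_id = NULL) {
    ligand <- as.character(ligand); receptor <- as.character(receptor)
    stopifnot(length(ligand) == length(receptor))
    category <- rep_len(as.character(category), length(ligand))
    if (is.null(pair_id)) pair_id <- paste(ligand, receptor, sep = "_")
    pairs <- data.frame(pair_id = as.character(pair_id), ligand = ligand,
                        receptor = receptor, category = category,
                        homophilic = ligand == receptor,
                        stringsAsFactors = FALSE)
    rownames(pairs) <- NULL
    new("LRTable", pairs = pairs)
}

#' @rdname LRTable-class
#' @export
setMethod("pairIds", "LRTable", function(x) x@pairs$pair_id)
#' @rdname LRTable-class
#' @export
setMethod("ligands", "LRTable", function(x) x@pairs$ligand)
#' @rdname LRTable-class
#' @export
setMethod("receptors", "LRTable", function(x) x@pairs$receptor)
#' @rdname LRTable-class
#' @export
setMethod("categories", "LRTable", function(x) x@pairs$category)
#' @rdname LRTable-class
#' @export
setMethod("isHomophilic", "LRTable", function(x) x@pairs$homophilic)

#' @describeIn LRTable-class number of pairs.
#' @export
setMethod("length", "LRTable", function(x) nrow(x@pairs))

#' @describeIn LRTable-class subset by position, logical mask, or pair_id.
#' @param i index vector.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "LRTable", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@pairs$pair_id)
    if (anyNA(i)) stop("unknown pair_id in subset")
    p <- x@pairs[i, , drop = FALSE]
    rownames(p) <- NULL
    new("LRTable", pairs = p)
})

#' @describeIn LRTable-class the underlying data.frame.
#' @param row.names,optional passed on.
#' @export
setMethod("as.data.frame", "LRTable",
          function(x, row.names = NULL, optional = FALSE, ...) x@pairs)

setMethod("show", "LRTable", function(object) {
    p <- object@pairs
    cat("LRTable with", nrow(p), "ligand-receptor pair(s)\n")
    if (nrow(p)) {
        cat("  categories:", paste(sort(unique(p$category)), collapse = ", "), "\n")
        cat("  homophilic:", sum(p$homophilic), "of", nrow(p), "\n")
        print(utils::head(p, 5L))
        if (nrow(p) > 5L) cat("  ...", nrow(p) - 5L, "more\n")
    }
    invisible(NULL)
})

#' Read a ligand-receptor table from TSV
#'
#' Expects a UTF-8 tab-separated file with header columns \code{ligand},
#' \code{receptor}, \code{category} and optionally \code{pair_id} (derived as
#' \code{"LIGAND_RECEPTOR"} when absent). Rows with the wrong number of
#' fields are rejected with the offending line number; duplicate pair ids are
#' a validation error.
#'
#' @param path path to the TSV file.
#' @return an [LRTable-class].
#' @seealso [writeLRTable()], [cardiacLRPairs()]
#' @export
readLRTable <- function(path) {
    if (!file.exists(path)) stop("ligand-receptor table not found: ", path)
    nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
    if (length(nf) == 0L) stop("empty ligand-receptor table (no header): ", path)
    bad <- which(nf != nf[1L])
    if (length(bad))
        stop("malformed ligand-receptor table row(s) at line(s) ",
             paste(bad, collapse = ", "), ": expected ", nf[1L], " fields")
    tab <- utils::read.delim(path, sep = "\t", quote = "",
                             stringsAsFactors = FALSE, check.names = TRUE)
    need <- c("ligand", "receptor", "category")
    if (!all(need %in% names(tab)))
        stop("ligand-receptor table must have header columns: ",
             paste(need, collapse = ", "))
    LRTable(tab$ligand, tab$receptor, tab$category,
            pair_id = if ("pair_id" %in% names(tab)) tab$pair_id else NULL)
}

#' Write a ligand-receptor table to TSV
#'
#' Inverse of [readLRTable()]: a write/read round trip reproduces the table.
#'
#' @param x an [LRTable-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeLRTable <- function(x, path) {
    stopifnot(is(x, "LRTable"))
    utils::write.table(x@pairs[, c("ligand", "receptor", "category", "pair_id")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Bundled cardiac ligand-receptor pair table
#'
#' The default pair catalogue shipped with the package: 15 single-gene
#' cardiac ligand-receptor pairs (homophilic adhesion molecules PTPRM, NEGR1,
#' NCAM1 and CD99; IGF2 to IGF1R/IGF2R growth-factor signalling; collagen,
#' fibronectin and thrombospondin pairs on CD44/CD36/SDC4; JAG2/DLL1 to
#' NOTCH2), each assigned a functional category.
#'
#' @return an [LRTable-class] with 15 pairs.
#' @examples
#' cardiacLRPairs()
#' @export
cardiacLRPairs <- function() {
    readLRTable(system.file("extdata", "cardiac_lr_pairs.tsv",
                            package = "cardioCrosstalk", mustWork = TRUE))
}

#' Restrict a pair table to a gene universe
#'
#' A pair is kept iff both its ligand and its receptor gene are present in
#' \code{gene_universe}; a homophilic pair needs its single gene present.
#' Matching is case-sensitive exact match by default (HGNC symbols are
#' uppercase; silent case-folding hides data errors); set
#' \code{ignore_case = TRUE} for a case-insensitive fallback.
#'
#' @param x an [LRTable-class].
#' @param gene_universe non-empty character vector of gene symbols (e.g.
#'   rownames of a count matrix).
#' @param ignore_case match gene symbols case-insensitively.
#'
#' @return list with elements \code{kept} (an [LRTable-class]) and
#'   \code{dropped} (data.frame with \code{pair_id} and \code{reason}).
#'   Warns when no pair survives.
#' @export
restrictToUniverse <- function(x, gene_universe, ignore_case = FALSE) {
    stopifnot(is(x, "LRTable"))
    if (length(gene_universe) == 0L) stop("gene_universe must be non-empty")
    uni <- if (ignore_case) toupper(gene_universe) else gene_universe
    key <- function(g) if (ignore_case) toupper(g) else g
    lig_in <- key(ligands(x)) %in% uni
    rec_in <- key(receptors(x)) %in% uni
    keep <- lig_in & rec_in
    reason <- character(sum(!keep))
    if (any(!keep)) {
        miss_l <- !lig_in[!keep]; miss_r <- !rec_in[!keep]
        reason <- ifelse(miss_l & miss_r, "ligand and receptor absent",
                         ifelse(miss_l, "ligand absent", "receptor absent"))
    }
    dropped <- data.frame(pair_id = pairIds(x)[!keep], reason = reason,
                          stringsAsFactors = FALSE)
    kept <- x[which(keep)]
    if (length(kept) == 0L)
        warning("no ligand-receptor pair has both genes in the universe")
    list(kept = kept, dropped = dropped)
}
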