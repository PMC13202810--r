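#' @rdname CommNetwork-class
#' @export
setMethod("networkEdges", "CommNetwork", function(x) x@edges)
#' @rdname CommNetwork-class
#' @export
setMethod("networkNodes", "CommNetwork", function(x) x@nodes)

setMethod("show", "CommNetwork", function(object) {
    cat("CommNetwork for condition", object@condition, "with",
        length(object@nodes), "node(s) and", nrow(object@edges), "edge(s)\n")
    if (nrow(object@edges)) print(object@edges)
    invisible(NULL)
})

#' Build the communication network for one condition
#'
#' Cell types become nodes and each configured sender-receiver direction
#' with at least one valid crosstalk record becomes a directed edge whose
#' weight is the mean Crosstalk Potential over that direction's valid
#' ligand-receptor records. Directions with no valid record are omitted.
#'
#' @param x a [CrosstalkResults-class] (or its records data.frame).
#' @param condition condition label to build the network for.
#' @param directions configured directions (defaults to those stored in
#'   \code{x}; required when \code{x} is a plain data.frame).
#' @return a [CommNetwork-class].
#' @export
buildCommNetwork <- function(x, condition, directions = NULL) {
    rec <- .recordsOf(x)
    if (is.null(directions)) {
        directions <- if (is(x, "CrosstalkResults")) x@directions
                      else unique(rec[, c("sender", "receiver")])
    }
    if (!condition %in% rec$condition)
        stop("condition '", condition, "' absent from records")
    rc <- rec[rec$condition == condition & rec$valid, ]
    edges <- do.call(rbind, lapply(seq_len(nrow(directions)), function(d) {
        e <- rc[rc$sender == directions$sender[d] &
                rc$receiver == directions$receiver[d], ]
        if (nrow(e) == 0L) return(NULL)
        data.frame(sender = directions$sender[d],
                   receiver = directions$receiver[d],
                   weight = mean(e$potential), stringsAsFactors = FALSE)
    }))
    if (is.null(edges))
        edges <- data.frame(sender = character(), receiver = character(),
                            weight = numeric())
    nodes <- sort(unique(c(directions$sender, directions$receiver)))
    new("CommNetwork", condition = condition, nodes = nodes, edges = edges,
        directions = directions)
}

#' Topology metrics of a communication network
#'
#' Per node, the out-strength (sum of outgoing edge weights) and in-strength
#' (sum of incoming edge weights). Per network, two scalar indices
#' operationalizing qualitative topology descriptions: the centralization
#' index \code{(max weight - mean weight) / total weight} (0 when all edge
#' weights are equal) and the fragmentation, the fraction of configured
#' directions lacking a valid edge.
#'
#' @param net a [CommNetwork-class] with at least one edge.
#' @return list with \code{nodes} (data.frame: \code{node},
#'   \code{out_strength}, \code{in_strength}), \code{centralization} and
#'   \code{fragmentation}.
#' @export
networkMetrics <- function(net) {
    stopifnot(is(net, "CommNetwork"))
    e <- net@edges
    if (nrow(e) == 0L) stop("network has no edges")
    nodes <- data.frame(
        node = net@nodes,
        out_strength = vapply(net@nodes, function(v)
            sum(e$weight[e$sender == v]), numeric(1)),
        in_strength = vapply(net@nodes, function(v)
            sum(e$weight[e$receiver == v]), numeric(1)),
        stringsAsFactors = FALSE)
    rownames(nodes) <- NULL
    list(nodes = nodes,
         centralization = (max(e$weight) - mean(e$weight)) / sum(e$weight),
         fragmentation = 1 - nrow(e) / nrow(net@directions))
}

#' Export a communication network to JSON or GraphML
#'
#' JSON output is \code{{condition, nodes: [...], edges: [{source, target,
#' weight}]}} with nodes and edges deterministically sorted, so repeated
#' exports are byte-identical. GraphML goes through \pkg{igraph} with the
#' condition stored as a graph attribute. [importNetwork()] round-trips
#' nodes, edges and weights exactly.
#'
#' @param net a [CommNetwork-class].
#' @param path output file path.
#' @param format \code{"json"} or \code{"graphml"}.
#' @return \code{path}, invisibly.
#' @export
exportNetwork <- function(net, path, format = c("json", "graphml")) {
    format <- match.arg(format)
    e <- net@edges[order(net@edges$sender, net@edges$receiver), , drop = FALSE]
    if (format == "json") {
        obj <- list(condition = net@condition, nodes = sort(net@nodes),
                    edges = lapply(seq_len(nrow(e)), function(i)
                        list(source = e$sender[i], target = e$receiver[i],
                             weight = e$weight[i])))
        jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    } else {
        g <- igraph::graph_from_data_frame(
            d = stats::setNames(e, c("from", "to", "weight")),
            directed = TRUE,
            vertices = data.frame(name = sort(net@nodes)))
        g <- igraph::set_graph_attr(g, "condition", net@condition)
        igraph::write_graph(g, path, format = "graphml")
    }
    invisible(path)
}

#' Import a communication network written by [exportNetwork()]
#'
#' @param path file path.
#' @param format \code{"json"} or \code{"graphml"}.
#' @param directions optional configured-directions data.frame to restore
#'   (defaults to the imported edge list, which affects only the
#'   fragmentation metric).
#' @return a [CommNetwork-class].
#' @export
importNetwork <- function(path, format = c("json", "graphml"),
                          directions = NULL) {
    format <- match.arg(format)
    if (format == "json") {
        obj <- jsonlite::read_json(path, simplifyVector = FALSE)
        edges <- do.call(rbind, lapply(obj$edges, function(x)
            data.frame(sender = x$source, target = x$target,
                       weight = as.numeric(x$weight),
                       stringsAsFactors = FALSE)))
        if (is.null(edges))
            edges <- data.frame(sender = character(), receiver = character(),
                                weight = numeric())
        else names(edges) <- c("sender", "receiver", "weight")
        nodes <- as.character(unlist(obj$nodes))
        condition <- obj$condition
    } else {
        g <- igraph::read_graph(path, format = "graphml")
        ed <- igraph::as_data_frame(g, what = "edges")
        edges <- data.frame(sender = ed$from, receiver = ed$to,
                            weight = as.numeric(ed$weight),
                            stringsAsFactors = FALSE)
        nodes <- igraph::V(g)$name
        condition <- igraph::graph_attr(g, "condition")
    }
    if (is.null(directions))
        directions <- edges[, c("sender", "receiver"), drop = FALSE]
    new("CommNetwork", condition = as.character(condition),
        nodes = sort(nodes), edges = edges, directions = directions)
}
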