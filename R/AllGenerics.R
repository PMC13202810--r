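#' @rdname LRTable-class
#' @param x an object.
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))

#' @rdname LRTable-class
#' @export
setGeneric("ligands", function(x) standardGeneric("ligands"))

#' @rdname LRTable-class
#' @export
setGeneric("receptors", function(x) standardGeneric("receptors"))

#' @rdname LRTable-class
#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' @rdname LRTable-class
#' @export
setGeneric("isHomophilic", function(x) standardGeneric("isHomophilic"))

#' @rdname CrosstalkResults-class
#' @param x an object.
#' @export
setGeneric("crosstalkRecords", function(x) standardGeneric("crosstalkRecords"))

#' @rdname CrosstalkResults-class
#' @export
setGeneric("lrPairs", function(x) standardGeneric("lrPairs"))

#' @rdname CommNetwork-class
#' @param x an object.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname CommNetwork-class
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
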