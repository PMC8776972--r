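#' @title Accessors for SimilarityGraph objects
#' @name SimilarityGraph-accessors
#' @param x a \linkS4class{SimilarityGraph}.
#' @param includeBridges logical; keep artificial bridge edges.
#' @return \code{graphNodes}: the node table; \code{graphEdges}: the canonical
#'   edge table; \code{graphBridges}: only the bridge edges;
#'   \code{nodeKinds}: named character vector node_id -> kind;
#'   \code{nComponents}: number of connected components (isolated nodes count
#'   as singleton components); \code{asIgraph}: the corresponding
#'   \pkg{igraph} object with a \code{weight} edge attribute.
NULL

#' @rdname SimilarityGraph-accessors
#' @export
setGeneric("graphNodes", function(x) standardGeneric("graphNodes"))

#' @rdname SimilarityGraph-accessors
#' @export
setGeneric("graphEdges",
           function(x, includeBridges = TRUE) standardGeneric("graphEdges"))

#' @rdname SimilarityGraph-accessors
#' @export
setGeneric("graphBridges", function(x) standardGeneric("graphBridges"))

#' @rdname SimilarityGraph-accessors
#' @export
setGeneric("nodeKinds", function(x) standardGeneric("nodeKinds"))

#' @rdname SimilarityGraph-accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' @rdname SimilarityGraph-accessors
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname SimilarityGraph-accessors
setMethod("graphNodes", "SimilarityGraph", function(x) x@nodes)

#' @rdname SimilarityGraph-accessors
setMethod("graphEdges", "SimilarityGraph",
  function(x, includeBridges = TRUE) {
    e <- x@edges
    if (!includeBridges) e <- e[!e$is_bridge, , drop = FALSE]
    e
  })

#' @rdname SimilarityGraph-accessors
setMethod("graphBridges", "SimilarityGraph",
  function(x) x@edges[x@edges$is_bridge, , drop = FALSE])

#' @rdname SimilarityGraph-accessors
setMethod("nodeKinds", "SimilarityGraph",
  function(x) setNames(x@nodes$kind, x@nodes$node_id))

#' @rdname SimilarityGraph-accessors
setMethod("asIgraph", "SimilarityGraph", function(x) {
  igraph::graph_from_data_frame(
    d = x@edges[, c("node_a", "node_b", "weight", "subnetwork",
                    "is_bridge"), drop = FALSE],
    directed = FALSE,
    vertices = x@nodes)
})

#' @rdname SimilarityGraph-accessors
setMethod("nComponents", "SimilarityGraph", function(x) {
  if (!nrow(x@nodes)) return(0L)
  igraph::count_components(asIgraph(x))
})

setMethod("show", "SimilarityGraph", function(object) {
  e <- object@edges
  kinds <- table(factor(object@nodes$kind,
                        levels = c("drug", "food_compound")))
  cat(sprintf("SimilarityGraph: %d nodes (%d drugs, %d food compounds), %d edges\n",
              nrow(object@nodes), kinds[["drug"]], kinds[["food_compound"]],
              nrow(e)))
  if (nrow(e)) {
    sn <- table(factor(e$subnetwork, levels = c("DD", "FF", "FD")))
    cat(sprintf("  subnetworks: DD=%d FF=%d FD=%d; bridges=%d; components=%d\n",
                sn[["DD"]], sn[["FF"]], sn[["FD"]], sum(e$is_bridge),
                nComponents(object)))
  }
  invisible(NULL)
})

#' @rdname EvalReport-class
#' @param object an \linkS4class{EvalReport}.
#' @export
setGeneric("evalSummary", function(object) standardGeneric("evalSummary"))

#' @rdname EvalReport-class
setMethod("evalSummary", "EvalReport", function(object) object@summary)

#' @rdname EvalReport-class
#' @export
setGeneric("evalPerRepeat", function(object) standardGeneric("evalPerRepeat"))

#' @rdname EvalReport-class
setMethod("evalPerRepeat", "EvalReport", function(object) object@perRepeat)

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (evaluation %d): %d repeats x %d methods\n",
              object@evaluation,
              length(unique(object@perRepeat$repeat_index)),
              length(unique(object@perRepeat$method))))
  print(object@summary, row.names = FALSE)
  invisible(NULL)
})
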