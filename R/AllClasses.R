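#' SimilarityGraph: a homogeneous chemical similarity graph
#'
#' An undirected weighted graph whose nodes are all chemical entities (drugs
#' and food compounds) so that any subnetwork (drug-drug, food-food,
#' food-drug) can serve as evaluation ground truth.  Edges are stored in
#' canonical form (\code{node_a < node_b}, no self-loops).  Artificial bridge
#' edges added to connect components are tagged with \code{is_bridge} and are
#' excluded from evaluation eligibility.
#'
#' @slot nodes data.frame with columns \code{node_id} and \code{kind}
#'   (\code{"drug"} or \code{"food_compound"}); extra columns (smiles,
#'   food_id, compound_id) are preserved.
#' @slot edges data.frame with columns \code{node_a}, \code{node_b},
#'   \code{weight}, \code{subnetwork} (DD/FF/FD), \code{is_bridge}.
#'
#' @aliases SimilarityGraph-class
#' @exportClass SimilarityGraph
setClass("SimilarityGraph",
  representation(nodes = "data.frame", edges = "data.frame"))

setValidity("SimilarityGraph", function(object) {
  n <- object@nodes
  e <- object@edges
  msgs <- character(0)
  if (!all(c("node_id", "kind") %in% names(n)))
    msgs <- c(msgs, "nodes must have columns node_id, kind")
  else {
    if (anyDuplicated(n$node_id))
      msgs <- c(msgs, "duplicated node_id")
    if (!all(n$kind %in% c("drug", "food_compound")))
      msgs <- c(msgs, "kind must be 'drug' or 'food_compound'")
  }
  if (!all(EDGE_COLS %in% names(e)))
    msgs <- c(msgs, sprintf("edges must have columns %s",
                            paste(EDGE_COLS, collapse = ", ")))
  else if (nrow(e)) {
    if (any(e$node_a == e$node_b)) msgs <- c(msgs, "self-loop edge")
    if (any(e$node_a > e$node_b))
      msgs <- c(msgs, "edges not in canonical order (node_a < node_b)")
    if (anyDuplicated(pairKey(e$node_a, e$node_b)))
      msgs <- c(msgs, "duplicated edge")
    if (any(!c(e$node_a, e$node_b) %in% n$node_id))
      msgs <- c(msgs, "edge endpoint not among nodes")
    if (any(e$weight <= 0 & !e$is_bridge))
      msgs <- c(msgs, "non-bridge edge with non-positive weight")
    if (any(e$weight > 1))
      msgs <- c(msgs, "edge weight above 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SimilarityGraph
#'
#' @param nodes data.frame with \code{node_id} and \code{kind} columns, or a
#'   character vector of node ids (then kinds are inferred from edge
#'   subnetwork labels where possible, defaulting to \code{"drug"}).
#' @param edges data.frame with columns \code{node_a}, \code{node_b},
#'   \code{weight}; \code{subnetwork} and \code{is_bridge} are filled in when
#'   absent.  Pairs are canonicalized to \code{node_a < node_b}.
#' @return a \linkS4class{SimilarityGraph}.
#' @export
#' @examples
#' g <- SimilarityGraph(
#'   nodes = data.frame(node_id = c("D1", "D2", "F1"),
#'                      kind = c("drug", "drug", "food_compound")),
#'   edges = data.frame(node_a = "D1", node_b = "D2", weight = 0.9))
#' graphEdges(g)
SimilarityGraph <- function(nodes, edges = emptyEdges()) {
  if (is.character(nodes))
    nodes <- data.frame(node_id = nodes, kind = "drug",
                        stringsAsFactors = FALSE)
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges)) {
    cp <- canonicalPair(as.character(edges$node_a), as.character(edges$node_b))
    edges$node_a <- cp$a
    edges$node_b <- cp$b
    if (is.null(edges$is_bridge)) edges$is_bridge <- FALSE
    if (is.null(edges$subnetwork)) {
      kind <- setNames(nodes$kind, nodes$node_id)
      edges$subnetwork <- subnetworkLabel(kind[edges$node_a],
                                          kind[edges$node_b])
    }
    edges <- edges[order(edges$node_a, edges$node_b), EDGE_COLS,
                   drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- emptyEdges()
  }
  rownames(nodes) <- NULL
  new("SimilarityGraph", nodes = nodes, edges = edges)
}

#' EvalReport: link-prediction evaluation results
#'
#' Per-repeat metrics and a mean/sd summary produced by
#' \code{\link{runEvaluation}}.
#'
#' @slot evaluation integer evaluation protocol id (1-4).
#' @slot perRepeat data.frame with one row per (repeat, method).
#' @slot summary data.frame of mean and sd per method and metric.
#'
#' @aliases EvalReport-class
#' @exportClass EvalReport
setClass("EvalReport",
  representation(evaluation = "integer", perRepeat = "data.frame",
                 summary = "data.frame"))

setValidity("EvalReport", function(object) {
  if (!object@evaluation %in% 1:4) return("evaluation must be 1..4")
  pr <- object@perRepeat
  pcols <- grep("^precision_at_", names(pr), value = TRUE)
  for (cl in pcols) {
    v <- pr[[cl]]
    if (any(!is.na(v) & (v < 0 | v > 1)))
      return(sprintf("%s outside [0,1]", cl))
  }
  TRUE
})
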