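## Thresholding of the structure similarity profile into a sparse graph,
## contribution-based re-weighting, and disjoint / joint graph variants.

#' Tanimoto threshold on similarity edges
#'
#' Keeps edges whose similarity score is at least \code{tc} (inclusive, as in
#' the ">= 0.6" convention); zero-score pairs are always dropped, which is
#' what makes the representation sparse.
#'
#' @param edges similarity edge data.frame with a \code{score} column (as
#'   from \code{\link{buildSSP}}).
#' @param tc threshold in \code{[0, 1]}; 0.6 is the default working point.
#' @return the filtered edge data.frame.
#' @export
applyThreshold <- function(edges, tc = 0.6) {
  stopifnot(tc >= 0, tc <= 1, "score" %in% names(edges))
  out <- edges[edges$score > 0 & edges$score >= tc, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Contribution re-weighting of similarity edges
#'
#' Multiplies each similarity score by the pair-level contribution factor
#' (see \code{\link{pairContribution}}): drug-drug scores are preserved,
#' drug-food scores are scaled by the food compound's contribution, and
#' food-food scores by the larger of the two contributions.  Since
#' contributions are at most 1, updating never increases a weight.
#'
#' @param edges similarity edge data.frame with \code{node_a}, \code{node_b},
#'   \code{score}, \code{subnetwork}.
#' @param entries composition data.frame with \code{node_id} and
#'   \code{contribution}.
#' @return the edge data.frame with a \code{weight} column added
#'   (\code{score * factor}).
#' @export
updateScores <- function(edges, entries) {
  stopifnot(all(c("node_a", "node_b", "score", "subnetwork") %in%
                  names(edges)))
  if (!nrow(edges)) {
    edges$weight <- numeric(0)
    return(edges)
  }
  lookup <- setNames(entries$contribution, entries$node_id)
  ca <- unname(lookup[edges$node_a])
  cb <- unname(lookup[edges$node_b])
  factor <- rep(1.0, nrow(edges))
  fd <- edges$subnetwork == "FD"
  ff <- edges$subnetwork == "FF"
  factor[fd] <- ifelse(is.na(ca[fd]), cb[fd], ca[fd])
  factor[ff] <- pmax(ca[ff], cb[ff])
  if (anyNA(factor)) {
    bad <- unique(c(edges$node_a, edges$node_b)[
      c(is.na(factor), is.na(factor))])
    stop("food-compound node(s) without a contribution, e.g.: ",
         paste(utils::head(setdiff(bad, entries$node_id), 3),
               collapse = ", "))
  }
  edges$weight <- edges$score * factor
  edges
}

#' Second-stage threshold on updated weights
#'
#' After contribution re-weighting a more relaxed threshold is applied
#' (typical working points 0.3-0.6; 0.5 for primary results, 0.3 for the
#' "relaxed" batch).  By default it filters on the updated \code{weight};
#' set \code{on = "score"} to threshold the raw Tanimoto score instead (the
#' alternative reading of the procedure).
#'
#' @param edges edge data.frame carrying \code{weight} (and \code{score}).
#' @param t2 threshold in \code{[0, 1]}.
#' @param on which column the threshold applies to.
#' @return the filtered edge data.frame.
#' @export
applyContributionThreshold <- function(edges, t2 = 0.5,
                                       on = c("weight", "score")) {
  on <- match.arg(on)
  stopifnot(t2 >= 0, t2 <= 1, on %in% names(edges))
  out <- edges[edges[[on]] >= t2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble a (disjoint) homogeneous graph from weighted edges
#'
#' @param edges edge data.frame with \code{node_a}, \code{node_b} and either
#'   \code{weight} or \code{score} (used as weight when \code{weight} is
#'   absent).
#' @param nodes node data.frame (\code{node_id}, \code{kind}); nodes with no
#'   surviving edge stay in the graph as singleton components.  When absent,
#'   nodes are inferred from the edge endpoints and \code{subnetwork} labels.
#' @return a \linkS4class{SimilarityGraph}; its connected components are the
#'   "disjoint" structure that \code{\link{joinify}} can connect.
#' @export
buildGraph <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!nrow(edges)) edges <- emptyEdges()
  if (is.null(edges$weight)) edges$weight <- edges$score
  if (is.null(edges$is_bridge)) edges$is_bridge <- FALSE
  if (is.null(nodes)) {
    ids <- unique(c(edges$node_a, edges$node_b))
    kind <- rep("drug", length(ids))
    names(kind) <- ids
    if (nrow(edges) && !is.null(edges$subnetwork)) {
      ff <- edges$subnetwork == "FF"
      kind[c(edges$node_a[ff], edges$node_b[ff])] <- "food_compound"
      ## FD: the endpoint not already known to be a drug via a DD edge is
      ## ambiguous from labels alone; prefer explicit `nodes` in that case
      dd <- edges$subnetwork == "DD"
      drugIds <- unique(c(edges$node_a[dd], edges$node_b[dd]))
      fd <- edges$subnetwork == "FD"
      for (i in which(fd)) {
        a <- edges$node_a[i]; b <- edges$node_b[i]
        if (a %in% drugIds && !(b %in% drugIds)) kind[b] <- "food_compound"
        if (b %in% drugIds && !(a %in% drugIds)) kind[a] <- "food_compound"
      }
    }
    nodes <- data.frame(node_id = ids, kind = unname(kind),
                        stringsAsFactors = FALSE)
  }
  SimilarityGraph(nodes = nodes,
                  edges = edges[, intersect(c(EDGE_COLS, "score"),
                                            names(edges)), drop = FALSE])
}

#' Component membership of a SimilarityGraph
#'
#' @param graph a \linkS4class{SimilarityGraph}.
#' @return named integer vector node_id -> component index.
#' @export
componentMembership <- function(graph) {
  igraph::components(asIgraph(graph))$membership
}

#' Connect a disjoint graph with low-weight bridge edges
#'
#' Some neighborhood link-prediction scorers cannot operate across
#' disconnected components, so a "joint" graph variant is built by linking
#' all components: one randomly chosen node per component, components
#' chained in seeded random order, each added edge carrying a very small
#' weight (default 1e-5) so the bridges stay near-inert for scoring.
#' Exactly \code{components - 1} bridges are added; bridge edges are tagged
#' and never count as recoverable links during evaluation.
#'
#' @param graph a \linkS4class{SimilarityGraph}.
#' @param bridgeWeight weight assigned to each added edge.
#' @param seed integer seed controlling component order and node choice.
#' @return a connected \linkS4class{SimilarityGraph} with the added bridges
#'   flagged \code{is_bridge = TRUE}.
#' @export
joinify <- function(graph, bridgeWeight = 1e-5, seed = 1L) {
  stopifnot(is(graph, "SimilarityGraph"))
  if (!nrow(graphNodes(graph))) return(graph)
  memb <- componentMembership(graph)
  k <- max(memb)
  if (k <= 1L) return(graph)
  kind <- nodeKinds(graph)
  set.seed(as.integer(seed))
  order_ <- sample.int(k)
  anchors <- vapply(order_, function(cmp) {
    members <- names(memb)[memb == cmp]
    members[sample.int(length(members), 1L)]
  }, character(1))
  a <- anchors[-k]
  b <- anchors[-1L]
  cp <- canonicalPair(a, b)
  bridges <- data.frame(node_a = cp$a, node_b = cp$b,
                        weight = bridgeWeight,
                        subnetwork = subnetworkLabel(kind[cp$a], kind[cp$b]),
                        is_bridge = TRUE, stringsAsFactors = FALSE)
  SimilarityGraph(nodes = graphNodes(graph),
                  edges = rbind(graphEdges(graph)[, EDGE_COLS], bridges))
}
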