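## Link-prediction scoring on the homogeneous graph: shortest-path scores
## (minimum weight-sum paths of exactly 2 or 3 edges, Dijkstra) and the six
## neighborhood scorers (Adamic-Adar, common neighbors, Jaccard, resource
## allocation, degree-normalized 3-path L3, Dice).

PREDICTION_METHODS <- c("sp2", "sp3", "aa", "cn", "jac", "ra", "l3", "dice")

## ---- internal adjacency helpers ----

adjacencyMatrices <- function(graph) {
  nodes <- graphNodes(graph)$node_id
  n <- length(nodes)
  e <- graphEdges(graph)
  idx <- function(x) match(x, nodes)
  if (nrow(e)) {
    i <- idx(e$node_a); j <- idx(e$node_b)
    Aw <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                               x = rep(e$weight, 2L), dims = c(n, n))
    A0 <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                               x = 1, dims = c(n, n))
  } else {
    Aw <- A0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                     x = numeric(0), dims = c(n, n))
  }
  list(nodes = nodes, A0 = A0, Aw = Aw, k = Matrix::rowSums(A0 > 0))
}

neighborSets <- function(graph) {
  e <- graphEdges(graph)
  ids <- graphNodes(graph)$node_id
  out <- setNames(vector("list", length(ids)), ids)
  for (id in ids) out[[id]] <- character(0)
  if (nrow(e)) {
    sp <- split(c(e$node_b, e$node_a), c(e$node_a, e$node_b))
    out[names(sp)] <- lapply(sp, unique)
  }
  out
}

checkPairInGraph <- function(graph, nodeA, nodeB) {
  ids <- graphNodes(graph)$node_id
  missing <- setdiff(c(nodeA, nodeB), ids)
  if (length(missing))
    stop("node(s) not in graph: ", paste(missing, collapse = ", "))
}

## ---- per-pair neighborhood scorers ----

#' Neighborhood link-prediction scores for a node pair
#'
#' Single-pair scoring functions on the unweighted neighbor structure of the
#' graph (L3 excepted, which uses edge weights).  \code{\link{predictLinks}}
#' computes the same scores for every candidate pair at once.
#'
#' \describe{
#'   \item{\code{cnScore}}{number of common neighbors
#'     \eqn{|\Gamma(a) \cap \Gamma(b)|}.}
#'   \item{\code{aaScore}}{Adamic-Adar, \eqn{\sum_z 1/\log k_z} over common
#'     neighbors \eqn{z}; 0 with no common neighbor.  A common neighbor with
#'     degree \eqn{\le} 1 cannot occur in a well-formed graph; such a node
#'     contributes 0 with a warning.}
#'   \item{\code{raScore}}{resource allocation, \eqn{\sum_z 1/k_z}.}
#'   \item{\code{jaccardScore}}{\eqn{|\Gamma(a) \cap \Gamma(b)| /
#'     |\Gamma(a) \cup \Gamma(b)|}, 0 when the union is empty.}
#'   \item{\code{diceScore}}{\eqn{2|\Gamma(a) \cap \Gamma(b)| /
#'     (|\Gamma(a)| + |\Gamma(b)|)}; equals \eqn{2J/(1+J)}.}
#'   \item{\code{l3Score}}{degree-normalized 3-path score
#'     \eqn{\sum_{a-u-v-b} A_{au} A_{uv} A_{vb} / \sqrt{k_u k_v}} over simple
#'     3-edge paths, with \eqn{A} the weighted adjacency and \eqn{k} the
#'     (unweighted) degree.}
#' }
#'
#' @param graph a \linkS4class{SimilarityGraph}.
#' @param nodeA,nodeB node ids.
#' @param logBase logarithm base for Adamic-Adar (default natural log).
#' @return a single non-negative numeric score.
#' @name neighborhood-scores
NULL

#' @rdname neighborhood-scores
#' @export
cnScore <- function(graph, nodeA, nodeB) {
  checkPairInGraph(graph, nodeA, nodeB)
  nb <- neighborSets(graph)
  length(intersect(nb[[nodeA]], nb[[nodeB]]))
}

#' @rdname neighborhood-scores
#' @export
aaScore <- function(graph, nodeA, nodeB, logBase = exp(1)) {
  checkPairInGraph(graph, nodeA, nodeB)
  nb <- neighborSets(graph)
  z <- intersect(nb[[nodeA]], nb[[nodeB]])
  if (!length(z)) return(0)
  kz <- lengths(nb[z])
  if (any(kz <= 1L)) {
    warning("common neighbor with degree <= 1; contributes 0")
    kz <- kz[kz > 1L]
    if (!length(kz)) return(0)
  }
  sum(1 / (log(kz) / log(logBase)))
}

#' @rdname neighborhood-scores
#' @export
raScore <- function(graph, nodeA, nodeB) {
  checkPairInGraph(graph, nodeA, nodeB)
  nb <- neighborSets(graph)
  z <- intersect(nb[[nodeA]], nb[[nodeB]])
  if (!length(z)) return(0)
  sum(1 / lengths(nb[z]))
}

#' @rdname neighborhood-scores
#' @export
jaccardScore <- function(graph, nodeA, nodeB) {
  checkPairInGraph(graph, nodeA, nodeB)
  nb <- neighborSets(graph)
  u <- length(union(nb[[nodeA]], nb[[nodeB]]))
  if (u == 0L) return(0)
  length(intersect(nb[[nodeA]], nb[[nodeB]])) / u
}

#' @rdname neighborhood-scores
#' @export
diceScore <- function(graph, nodeA, nodeB) {
  checkPairInGraph(graph, nodeA, nodeB)
  nb <- neighborSets(graph)
  denom <- length(nb[[nodeA]]) + length(nb[[nodeB]])
  if (denom == 0L) return(0)
  2 * length(intersect(nb[[nodeA]], nb[[nodeB]])) / denom
}

#' @rdname neighborhood-scores
#' @export
l3Score <- function(graph, nodeA, nodeB) {
  checkPairInGraph(graph, nodeA, nodeB)
  nb <- neighborSets(graph)
  e <- graphEdges(graph)
  w <- setNames(e$weight, pairKey(e$node_a, e$node_b))
  deg <- lengths(nb)
  total <- 0
  for (u in setdiff(nb[[nodeA]], nodeB)) {
    for (v in setdiff(intersect(nb[[u]], nb[[nodeB]]), c(nodeA, u))) {
      total <- total +
        w[[pairKey(nodeA, u)]] * w[[pairKey(u, v)]] *
        w[[pairKey(v, nodeB)]] / sqrt(deg[[u]] * deg[[v]])
    }
  }
  total
}

## ---- full candidate scoring ----

candidateMask <- function(adj, fdiOnly, kinds) {
  n <- length(adj$nodes)
  mask <- upper.tri(matrix(TRUE, n, n))
  mask[as.matrix(adj$A0 > 0)] <- FALSE
  if (fdiOnly) {
    isDrug <- kinds[adj$nodes] == "drug"
    mask <- mask & outer(isDrug, isDrug, "!=")
  }
  mask
}

neighborhoodScoreMatrix <- function(adj, method, logBase = exp(1)) {
  A0 <- adj$A0
  k <- adj$k
  CN <- as.matrix(A0 %*% A0)
  switch(method,
    cn = CN,
    aa = {
      invlog <- ifelse(k > 1, 1 / (log(k) / log(logBase)), 0)
      as.matrix(A0 %*% Matrix::Diagonal(x = invlog) %*% A0)
    },
    ra = {
      invk <- ifelse(k > 0, 1 / k, 0)
      as.matrix(A0 %*% Matrix::Diagonal(x = invk) %*% A0)
    },
    jac = {
      denom <- outer(k, k, "+") - CN
      ifelse(denom > 0, CN / denom, 0)
    },
    dice = {
      denom <- outer(k, k, "+")
      ifelse(denom > 0, 2 * CN / denom, 0)
    },
    l3 = {
      D <- Matrix::Diagonal(x = ifelse(k > 0, 1 / sqrt(k), 0))
      as.matrix(adj$Aw %*% (D %*% adj$Aw %*% D) %*% adj$Aw)
    },
    stop("unknown neighborhood method: ", method))
}

#' Shortest-path link scores (SP_2 / SP_3)
#'
#' For every non-adjacent node pair, Dijkstra's algorithm finds the
#' minimum weight-sum path (edge weights summed).  Pairs whose minimal path
#' has exactly \code{length} edges are emitted with that minimal sum as the
#' score; all other pairs are excluded.  Because Dijkstra minimizes the sum
#' of similarity weights, the final ranking is taken in \emph{descending}
#' score order by default, preferring interactions supported by higher
#' similarity (see \code{\link{rankPredictions}}).
#'
#' @param graph a \linkS4class{SimilarityGraph} with edge weights.
#' @param length path length in edges, 2 or 3.
#' @param fdiOnly restrict output to drug/food-compound pairs.
#' @param excludeBridgePaths drop pairs whose minimal path traverses an
#'   artificial bridge edge (they are flagged in \code{uses_bridge} either
#'   way).
#' @return unranked prediction data.frame: \code{node_a}, \code{node_b},
#'   \code{method}, \code{score}, \code{rank} (NA until
#'   \code{\link{rankPredictions}}), \code{uses_bridge}.
#' @export
shortestPathScores <- function(graph, length = 2L, fdiOnly = FALSE,
                               excludeBridgePaths = FALSE) {
  stopifnot(length %in% c(2L, 3L))
  nodes <- graphNodes(graph)$node_id
  n <- base::length(nodes)
  if (n < 2L || !nrow(graphEdges(graph))) return(emptyPredictions())
  g <- asIgraph(graph)
  wts <- igraph::E(g)$weight
  bridgeE <- igraph::E(g)$is_bridge
  kinds <- nodeKinds(graph)
  adj <- adjacencyMatrices(graph)
  adjMat <- as.matrix(adj$A0 > 0)
  res <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    targets <- seq.int(i + 1L, n)
    sp <- suppressWarnings(igraph::shortest_paths(
      g, from = nodes[i], to = nodes[targets], weights = wts,
      output = "epath"))
    nEdges <- lengths(sp$epath)
    keep <- which(nEdges == length & !adjMat[i, targets])
    if (!base::length(keep)) next
    rows <- lapply(keep, function(kk) {
      ep <- sp$epath[[kk]]
      data.frame(node_a = nodes[i], node_b = nodes[targets[kk]],
                 score = sum(wts[as.integer(ep)]),
                 uses_bridge = any(bridgeE[as.integer(ep)]),
                 stringsAsFactors = FALSE)
    })
    res[[i]] <- do.call(rbind, rows)
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) return(emptyPredictions())
  if (fdiOnly)
    out <- out[kinds[out$node_a] != kinds[out$node_b], , drop = FALSE]
  if (excludeBridgePaths)
    out <- out[!out$uses_bridge, , drop = FALSE]
  if (!nrow(out)) return(emptyPredictions())
  cp <- canonicalPair(out$node_a, out$node_b)
  out$node_a <- cp$a
  out$node_b <- cp$b
  out$method <- paste0("sp", length)
  out$rank <- NA_integer_
  rownames(out) <- NULL
  out[, names(emptyPredictions())]
}

#' Score and rank candidate links
#'
#' Computes one method's scores for every candidate pair (all unordered,
#' non-adjacent pairs of graph nodes; existing edges are never re-predicted)
#' and returns the ranked prediction list.  Neighborhood methods emit only
#' pairs with a positive score (a pair with no common neighbor, or no
#' 3-path, carries no evidence); shortest-path methods emit pairs whose
#' minimal path has exactly the requested edge count.
#'
#' @param graph a \linkS4class{SimilarityGraph}.
#' @param method one of \code{"sp2"}, \code{"sp3"}, \code{"aa"},
#'   \code{"cn"}, \code{"jac"}, \code{"ra"}, \code{"l3"}, \code{"dice"}.
#' @param fdiOnly restrict to pairs of one drug and one food compound.
#' @param excludeBridgePaths see \code{\link{shortestPathScores}}.
#' @param invertRank rank ascending instead of descending (the alternative
#'   reading of shortest-path scores as dissimilarities).
#' @param logBase Adamic-Adar logarithm base.
#' @return ranked prediction data.frame (\code{node_a}, \code{node_b},
#'   \code{method}, \code{score}, \code{rank}, \code{uses_bridge}).
#' @export
predictLinks <- function(graph, method = PREDICTION_METHODS,
                         fdiOnly = FALSE, excludeBridgePaths = FALSE,
                         invertRank = FALSE, logBase = exp(1)) {
  method <- match.arg(method)
  if (method %in% c("sp2", "sp3")) {
    preds <- shortestPathScores(graph,
                                length = if (method == "sp2") 2L else 3L,
                                fdiOnly = fdiOnly,
                                excludeBridgePaths = excludeBridgePaths)
    return(rankPredictions(preds, descending = !invertRank))
  }
  adj <- adjacencyMatrices(graph)
  if (base::length(adj$nodes) < 2L) return(emptyPredictions())
  kinds <- nodeKinds(graph)
  S <- neighborhoodScoreMatrix(adj, method, logBase = logBase)
  mask <- candidateMask(adj, fdiOnly, kinds)
  idx <- which(mask & S > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(emptyPredictions())
  cp <- canonicalPair(adj$nodes[idx[, 1L]], adj$nodes[idx[, 2L]])
  preds <- data.frame(node_a = cp$a, node_b = cp$b, method = method,
                      score = S[idx], rank = NA_integer_,
                      uses_bridge = FALSE, stringsAsFactors = FALSE)
  rankPredictions(preds, descending = !invertRank)
}

#' Rank a prediction list
#'
#' Orders predictions by score (descending by default, preferring higher
#' similarity support), breaking ties lexicographically on
#' \code{(node_a, node_b)} so the ranking is deterministic, and assigns
#' 1-based ranks.
#'
#' @param predictions prediction data.frame with \code{score},
#'   \code{node_a}, \code{node_b}.
#' @param descending logical; rank high scores first.
#' @return the data.frame reordered with \code{rank} filled (1..n).
#' @export
rankPredictions <- function(predictions, descending = TRUE) {
  if (!nrow(predictions)) return(predictions)
  ord <- if (descending)
    order(-predictions$score, predictions$node_a, predictions$node_b)
  else order(predictions$score, predictions$node_a, predictions$node_b)
  out <- predictions[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
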