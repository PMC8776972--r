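# Independent brute-force oracles. These deliberately avoid the package's
# adjacency/scoring code paths: neighbor sets are rebuilt by scanning the
# edge table, path scores come from naive enumeration or a Bellman-Ford
# style DP, so agreement with the package is a genuine cross-check.

pairKeyTest <- function(a, b) paste(pmin(a, b), pmax(a, b))

oracleNeighbors <- function(graph, id) {
  e <- graphEdges(graph)
  unique(c(e$node_b[e$node_a == id], e$node_a[e$node_b == id]))
}

oracleDegree <- function(graph, id) length(oracleNeighbors(graph, id))

oracleWeight <- function(graph, a, b) {
  e <- graphEdges(graph)
  hit <- (e$node_a == a & e$node_b == b) | (e$node_a == b & e$node_b == a)
  if (!any(hit)) 0 else e$weight[hit][1L]
}

oracleNeighborScore <- function(graph, a, b, method) {
  na <- oracleNeighbors(graph, a)
  nb <- oracleNeighbors(graph, b)
  z <- intersect(na, nb)
  switch(method,
    cn = length(z),
    aa = if (!length(z)) 0 else {
      s <- 0
      for (zz in z) s <- s + 1 / log(oracleDegree(graph, zz))
      s
    },
    ra = if (!length(z)) 0 else {
      s <- 0
      for (zz in z) s <- s + 1 / oracleDegree(graph, zz)
      s
    },
    jac = if (!length(union(na, nb))) 0 else
      length(z) / length(union(na, nb)),
    dice = if (!(length(na) + length(nb))) 0 else
      2 * length(z) / (length(na) + length(nb)),
    l3 = {
      s <- 0
      for (u in setdiff(na, b)) {
        for (v in setdiff(nb, c(a, u))) {
          wuv <- oracleWeight(graph, u, v)
          if (wuv > 0)
            s <- s + oracleWeight(graph, a, u) * wuv *
              oracleWeight(graph, v, b) /
              sqrt(oracleDegree(graph, u) * oracleDegree(graph, v))
        }
      }
      s
    },
    stop("unknown method ", method))
}

# min weight-sum over walks with exactly k edges, k = 1..n-1 (positive
# weights make min-sum walks coincide with min-sum paths); returns the
# global minimum sum and the edge count attaining it
oracleShortestPath <- function(graph, a, b) {
  ids <- graphNodes(graph)$node_id
  n <- length(ids)
  W <- matrix(Inf, n, n, dimnames = list(ids, ids))
  e <- graphEdges(graph)
  for (i in seq_len(nrow(e))) {
    W[e$node_a[i], e$node_b[i]] <- e$weight[i]
    W[e$node_b[i], e$node_a[i]] <- e$weight[i]
  }
  dp <- rep(Inf, n)
  names(dp) <- ids
  dp[a] <- 0
  best <- rep(Inf, n - 1L)
  for (k in seq_len(n - 1L)) {
    nxt <- rep(Inf, n)
    names(nxt) <- ids
    for (v in ids) {
      cand <- dp + W[, v]
      nxt[v] <- min(cand)
    }
    dp <- nxt
    best[k] <- dp[b]
  }
  if (all(!is.finite(best))) return(list(dist = Inf, nEdges = NA_integer_))
  list(dist = min(best), nEdges = which.min(best))
}

# per-source variant: min sums and attaining edge counts for every target
oracleShortestPathAll <- function(graph, a) {
  ids <- graphNodes(graph)$node_id
  n <- length(ids)
  W <- matrix(Inf, n, n, dimnames = list(ids, ids))
  e <- graphEdges(graph)
  for (i in seq_len(nrow(e))) {
    W[e$node_a[i], e$node_b[i]] <- e$weight[i]
    W[e$node_b[i], e$node_a[i]] <- e$weight[i]
  }
  dp <- rep(Inf, n)
  names(dp) <- ids
  dp[a] <- 0
  best <- matrix(Inf, n - 1L, n, dimnames = list(NULL, ids))
  for (k in seq_len(n - 1L)) {
    dp <- apply(W + dp, 2L, min)   # relax one more edge
    best[k, ] <- dp
  }
  dist <- apply(best, 2L, min)
  nEdges <- apply(best, 2L, which.min)
  nEdges[!is.finite(dist)] <- NA_integer_
  list(dist = dist, nEdges = nEdges)
}

# seeded random weighted graph, built without igraph
randomTestGraph <- function(n, p, seed, wMin = 0.1, wMax = 1) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  kind <- rep(c("drug", "food_compound"), length.out = n)
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      if (runif(1) < p)
        rows[[length(rows) + 1L]] <- data.frame(
          node_a = ids[i], node_b = ids[j],
          weight = runif(1, wMin, wMax), stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(node_a = character(0), node_b = character(0),
               weight = numeric(0))
  SimilarityGraph(data.frame(node_id = ids, kind = kind,
                             stringsAsFactors = FALSE), edges)
}

# quick graph constructor for hand-built examples (all drug nodes unless
# kinds given)
quickGraph <- function(a, b, w = 1, kinds = NULL, extraNodes = character(0)) {
  ids <- unique(c(a, b, extraNodes))
  kind <- if (is.null(kinds)) rep("drug", length(ids)) else kinds[ids]
  SimilarityGraph(
    data.frame(node_id = ids, kind = kind, stringsAsFactors = FALSE),
    data.frame(node_a = a, node_b = b, weight = w,
               stringsAsFactors = FALSE))
}

# independent union-find for component counting
unionFindComponents <- function(graph) {
  ids <- graphNodes(graph)$node_id
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  e <- graphEdges(graph)
  for (i in seq_len(nrow(e))) {
    ra <- find(e$node_a[i])
    rb <- find(e$node_b[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  length(unique(vapply(ids, find, character(1))))
}
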