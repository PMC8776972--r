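test_that("neighborhood scorers reproduce hand-computed values", {
  # square q1-q2-q3-q4-q1: opposite corners share two degree-2 neighbors
  sq <- toyGraph("square")
  expect_equal(cnScore(sq, "q1", "q3"), 2)
  expect_equal(aaScore(sq, "q1", "q3"), 2 / log(2))
  expect_equal(raScore(sq, "q1", "q3"), 1)
  expect_equal(jaccardScore(sq, "q1", "q3"), 1)  # identical neighborhoods
  expect_equal(diceScore(sq, "q1", "q3"), 1)

  # one common neighbor of degree 2 (path a-z-b)
  pz <- quickGraph(c("a", "z"), c("z", "b"))
  expect_equal(aaScore(pz, "a", "b"), 1 / log(2))
  expect_equal(raScore(pz, "a", "b"), 0.5)
  expect_equal(cnScore(pz, "a", "b"), 1)

  # common neighbors of degrees 2 and 4 -> AA = 1/ln2 + 1/ln4
  g24 <- quickGraph(c("a", "z1", "a", "z2", "z2", "z2"),
                    c("z1", "b", "z2", "b", "x1", "x2"))
  expect_equal(oracleDegree(g24, "z1"), 2)
  expect_equal(oracleDegree(g24, "z2"), 4)
  expect_equal(aaScore(g24, "a", "b"), 1 / log(2) + 1 / log(4))

  # common neighbors of degrees 2 and 5 -> RA = 0.7
  g25 <- quickGraph(c("a", "z1", "a", "z2", "z2", "z2", "z2"),
                    c("z1", "b", "z2", "b", "x1", "x2", "x3"))
  expect_equal(raScore(g25, "a", "b"), 0.7)
  # single common neighbor of degree 4 -> RA = 0.25
  expect_equal(raScore(quickGraph(c("a", "z", "z", "z"),
                                  c("z", "b", "x1", "x2")), "a", "b"), 0.25)

  # Jaccard / Dice worked example: G(a)={z,c}, G(b)={z,d}
  gj <- quickGraph(c("a", "a", "b", "b"), c("z", "c", "z", "d"))
  expect_equal(jaccardScore(gj, "a", "b"), 1 / 3)
  expect_equal(diceScore(gj, "a", "b"), 0.5)

  # no common neighbors / disconnected
  tc <- toyGraph("two_components")
  expect_equal(aaScore(tc, "a", "c"), 0)
  expect_equal(cnScore(tc, "a", "c"), 0)
  expect_equal(jaccardScore(tc, "a", "c"), 0)

  # triangle minus one edge; complete K4
  expect_equal(cnScore(quickGraph(c("a", "b"), c("z", "z")), "a", "b"), 1)
  k4 <- quickGraph(c("a", "a", "a", "b", "b", "c"),
                   c("b", "c", "d", "c", "d", "d"))
  for (p in list(c("a", "b"), c("a", "c"), c("c", "d")))
    expect_equal(cnScore(k4, p[1], p[2]), 2)
  expect_error(cnScore(k4, "a", "nope"), "not in graph")
})

test_that("L3 matches its degree-normalized path formula", {
  l3p <- toyGraph("l3_path")          # a-u-v-b, unit weights, K_u=K_v=2
  expect_equal(l3Score(l3p, "a", "b"), 0.5)
  expect_equal(l3Score(l3p, "a", "b"), 1 / sqrt(2 * 2))  # degree-2 identity
  half <- toyGraph("l3_path", weight = 0.5)
  expect_equal(l3Score(half, "a", "b"), 0.125 / 2)       # 0.0625
  expect_equal(l3Score(toyGraph("two_components"), "a", "c"), 0)
})

test_that("shortest-path scoring emits exact-length minimal weight sums", {
  kinds <- c(D1 = "drug", F1 = "food_compound", F2 = "food_compound")
  chain <- quickGraph(c("D1", "F1"), c("F1", "F2"), w = c(0.9, 0.8),
                      kinds = kinds)
  sp2 <- shortestPathScores(chain, 2)
  expect_equal(nrow(sp2), 1)
  expect_equal(sp2$score, 1.7)
  expect_setequal(c(sp2$node_a, sp2$node_b), c("D1", "F2"))

  # two 2-edge routes between a and b: Dijkstra returns the lower sum
  twoRoutes <- quickGraph(c("a", "x", "a", "y"), c("x", "b", "y", "b"),
                          w = c(0.9, 0.8, 0.4, 0.5))
  spTwo <- shortestPathScores(twoRoutes, 2)
  expect_equal(spTwo$score[spTwo$node_a == "a" & spTwo$node_b == "b"], 0.9)

  # descending rank prefers the higher similarity sum
  preds <- rankPredictions(data.frame(
    node_a = c("DrugA", "DrugB"), node_b = c("FoodX", "FoodY"),
    method = "sp2", score = c(1.12, 2), rank = NA, uses_bridge = FALSE))
  expect_equal(preds$node_a[preds$rank == 1], "DrugB")

  # adjacent pairs are never emitted
  tri <- toyGraph("triangle")
  expect_equal(nrow(shortestPathScores(tri, 2)), 0)
  expect_equal(nrow(shortestPathScores(
    SimilarityGraph(data.frame(node_id = "solo", kind = "drug")), 2)), 0)
})

test_that("bridge-traversing shortest paths are flagged and excludable", {
  joined <- joinify(toyGraph("two_components"), seed = 3)
  sp <- shortestPathScores(joined, 2)
  expect_true(any(sp$uses_bridge))
  spNoBridge <- shortestPathScores(joined, 2, excludeBridgePaths = TRUE)
  expect_true(all(!spNoBridge$uses_bridge))
  expect_lt(nrow(spNoBridge), nrow(sp))
})

test_that("ranking is descending, tie-broken lexicographically, order-invariant", {
  df <- data.frame(node_a = c("x", "y", "z"), node_b = "t",
                   method = "cn", score = c(3, 1, 2), rank = NA,
                   uses_bridge = FALSE, stringsAsFactors = FALSE)
  r <- rankPredictions(df)
  expect_equal(r$node_a, c("x", "z", "y"))
  expect_equal(r$rank, 1:3)
  ties <- data.frame(node_a = "A", node_b = c("C", "B"), method = "cn",
                     score = 1, rank = NA, uses_bridge = FALSE,
                     stringsAsFactors = FALSE)
  expect_equal(rankPredictions(ties)$node_b, c("B", "C"))
  shuffled <- df[c(2, 3, 1), ]
  expect_identical(rankPredictions(shuffled), r)
  # ascending option (inverted-similarity reading)
  expect_equal(rankPredictions(df, descending = FALSE)$node_a[1], "y")
})

test_that("vectorized candidate scoring agrees with per-pair functions and oracles", {
  scorers <- list(cn = cnScore, aa = aaScore, jac = jaccardScore,
                  ra = raScore, dice = diceScore, l3 = l3Score)
  for (s in 1:25) {
    g <- randomTestGraph(n = 5 + (s %% 8), p = 0.35, seed = 1000 + s)
    for (m in names(scorers)) {
      preds <- predictLinks(g, method = m)
      if (!nrow(preds)) next
      for (r in sample(seq_len(nrow(preds)), min(4, nrow(preds)))) {
        a <- preds$node_a[r]; b <- preds$node_b[r]
        expect_equal(preds$score[r], scorers[[m]](g, a, b),
                     tolerance = 1e-12, label = paste(m, "per-pair", s))
        expect_equal(preds$score[r], oracleNeighborScore(g, a, b, m),
                     tolerance = 1e-12, label = paste(m, "oracle", s))
      }
    }
  }
})

test_that("SP predictions match the exhaustive min weight-sum DP oracle", {
  for (s in 1:12) {
    g <- randomTestGraph(n = 7, p = 0.3, seed = 2000 + s)
    for (L in c(2L, 3L)) {
      preds <- shortestPathScores(g, L)
      ids <- graphNodes(g)$node_id
      adjKeys <- with(graphEdges(g), paste(node_a, node_b))
      for (i in seq_along(ids)) for (j in seq_along(ids)) {
        if (j <= i) next
        a <- ids[i]; b <- ids[j]
        if (paste(a, b) %in% adjKeys) next
        o <- oracleShortestPath(g, a, b)
        hit <- preds$node_a == a & preds$node_b == b
        if (is.finite(o$dist) && o$nEdges == L) {
          expect_true(any(hit), label = sprintf("s=%d L=%d %s-%s", s, L, a, b))
          expect_equal(preds$score[hit], o$dist, tolerance = 1e-12)
        } else {
          expect_false(any(hit), label = sprintf("s=%d L=%d %s-%s", s, L, a, b))
        }
      }
    }
  }
})

test_that("scores are symmetric, non-negative; Jaccard and Dice stay in [0,1]", {
  for (s in 1:8) {
    g <- randomTestGraph(n = 9, p = 0.3, seed = 3000 + s)
    ids <- graphNodes(g)$node_id
    pairs <- utils::combn(ids, 2)
    for (cid in sample(ncol(pairs), 5)) {
      a <- pairs[1, cid]; b <- pairs[2, cid]
      expect_equal(cnScore(g, a, b), cnScore(g, b, a))
      expect_equal(l3Score(g, a, b), l3Score(g, b, a), tolerance = 1e-12)
      j <- jaccardScore(g, a, b)
      d <- diceScore(g, a, b)
      expect_gte(j, 0); expect_lte(j, 1)
      expect_gte(d, 0); expect_lte(d, 1)
      expect_gte(aaScore(g, a, b), 0)
    }
  }
})

test_that("fdiOnly restricts candidates to drug/food-compound pairs", {
  kinds <- c(D1 = "drug", D2 = "drug", F1 = "food_compound")
  g <- quickGraph(c("D1", "D2"), c("F1", "F1"), w = 0.9, kinds = kinds)
  all <- predictLinks(g, "cn")
  fdi <- predictLinks(g, "cn", fdiOnly = TRUE)
  expect_equal(nrow(all), 1)  # D1-D2 via F1
  expect_equal(nrow(fdi), 0)  # D1-D2 is not a food-drug pair
  sp <- predictLinks(quickGraph(c("D1", "F1"), c("F1", "D2"), w = 0.9,
                                kinds = kinds), "sp2", fdiOnly = TRUE)
  expect_equal(nrow(sp), 0)   # only candidate is drug-drug
})
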