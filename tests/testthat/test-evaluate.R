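# a ring of 100 drug-drug links plus a small food appendix, for split tests
ringGraph <- function(nDD = 100) {
  ids <- sprintf("d%03d", seq_len(nDD))
  e <- data.frame(node_a = ids, node_b = ids[c(2:nDD, 1)], weight = 0.9,
                  stringsAsFactors = FALSE)
  nodes <- data.frame(node_id = c(ids, "f1", "f2"),
                      kind = c(rep("drug", nDD),
                               "food_compound", "food_compound"),
                      stringsAsFactors = FALSE)
  e <- rbind(e,
             data.frame(node_a = "f1", node_b = "f2", weight = 0.8),
             data.frame(node_a = ids[1], node_b = "f1", weight = 0.7))
  SimilarityGraph(nodes, e)
}

test_that("link splitting removes the requested fraction, deterministically", {
  g <- ringGraph(100)
  spec <- splitSpec(fractionRemoved = 0.3, scope = "DD_only", seed = 7)
  sp <- splitLinks(g, spec, repeatIndex = 1)
  expect_equal(nrow(sp$test), 30)
  expect_equal(sum(graphEdges(sp$train)$subnetwork == "DD"), 70)
  # FF and FD links all stay in training under DD_only scope
  expect_equal(sum(graphEdges(sp$train)$subnetwork != "DD"), 2)
  expect_true(all(sp$test$subnetwork == "DD"))
  # train and test partition the eligible links
  allKeys <- with(graphEdges(g), paste(node_a, node_b))
  expect_setequal(c(with(graphEdges(sp$train), paste(node_a, node_b)),
                    with(sp$test, paste(node_a, node_b))), allKeys)
  # determinism per (seed, repeat)
  sp2 <- splitLinks(g, spec, repeatIndex = 1)
  expect_identical(sp2$test, sp$test)
  expect_false(identical(splitLinks(g, spec, repeatIndex = 2)$test, sp$test))
  # bridges are never eligible
  j <- joinify(toyGraph("two_components"), seed = 1)
  spJ <- splitLinks(j, splitSpec(0.5, "all_links", seed = 1), 1)
  expect_true(all(!spJ$test$is_bridge))
  expect_error(splitLinks(toyGraph("two_components"),
                          splitSpec(0.99, "all_links"), 1), "all eligible")
})

test_that("precision@top-k counts held-out links in the ceiling-k window", {
  preds <- rankPredictions(data.frame(
    node_a = sprintf("a%03d", 1:100), node_b = sprintf("b%03d", 1:100),
    method = "cn", score = 100:1, rank = NA, uses_bridge = FALSE,
    stringsAsFactors = FALSE))
  top5 <- preds[preds$rank <= 5, c("node_a", "node_b")]
  expect_equal(precisionAtTop(preds, top5, 5), 1.0)
  none <- data.frame(node_a = "zz", node_b = "zz2")
  expect_equal(precisionAtTop(preds, none, 5), 0.0)
  three <- preds[c(1, 3, 5), c("node_a", "node_b")]
  expect_equal(precisionAtTop(preds, three, 5), 0.6)
  # k = ceiling(percent * n): 1% of 100 -> 1
  expect_equal(precisionAtTop(preds, preds[1, ], 1), 1.0)
  expect_error(precisionAtTop(preds[0, ], three, 5), "empty")
})

test_that("threshold sweep produces consistent confusion counts and areas", {
  mk <- function(scores) rankPredictions(data.frame(
    node_a = sprintf("p%04d", seq_along(scores)),
    node_b = sprintf("q%04d", seq_along(scores)),
    method = "cn", score = scores, rank = NA, uses_bridge = FALSE,
    stringsAsFactors = FALSE))
  # separable: all held-out links score far above all others
  preds <- mk(c(runif(50, 0.9, 1.0), runif(150, 0.0, 0.3)))
  test <- preds[preds$score >= 0.9, c("node_a", "node_b")]
  sw <- confusionSweep(preds, test)
  expect_equal(sw$auc, 1.0)
  with(sw$counts, {
    expect_true(all(tp + fn == nrow(test)))
    expect_true(all(tn + fp == nrow(preds) - nrow(test)))
  })
  prec <- with(sw$counts, ifelse(tp + fp > 0, tp / (tp + fp), NA))
  # all-test predictions: precision 1 wherever tp > 0
  swAll <- confusionSweep(preds, preds[, c("node_a", "node_b")])
  precAll <- with(swAll$counts, ifelse(tp + fp > 0, tp / (tp + fp), NA))
  expect_true(all(precAll[!is.na(precAll)] == 1))
  # anti-separated: held-out links score lowest -> AUC 0
  anti <- confusionSweep(preds, preds[preds$score <= 0.3,
                                      c("node_a", "node_b")])
  expect_equal(anti$auc, 0)
  # never-predicted test links count as FN at every threshold
  extra <- rbind(test, data.frame(node_a = "ghost", node_b = "ghost2"))
  swG <- confusionSweep(preds, extra)
  expect_true(all(swG$counts$tp + swG$counts$fn == nrow(extra)))
  # degenerate single-threshold case: counts but no areas
  one <- confusionSweep(mk(c(0.5, 0.5)), test)
  expect_true(is.na(one$auc))
})

test_that("evaluation 3 on a dense clique recovers the removed links", {
  n <- 12
  ids <- sprintf("k%02d", seq_len(n))
  pairs <- utils::combn(ids, 2)
  g <- SimilarityGraph(
    data.frame(node_id = ids, kind = "drug"),
    data.frame(node_a = pairs[1, ], node_b = pairs[2, ], weight = 0.95))
  rep <- runEvaluation(g, 3, methods = "cn",
                       spec = splitSpec(0.05, repeats = 3, seed = 2))
  pr <- evalPerRepeat(rep)
  # every removed clique link is re-proposed (all survivors are common
  # neighbors of the removed endpoints)
  expect_true(all(pr$n_matched == round(0.05 * ncol(pairs))))
  expect_s4_class(rep, "EvalReport")
  expect_true(all(c("precision_at_1_mean", "auc_mean") %in%
                    names(evalSummary(rep))))
})

test_that("evaluation 1 scope removes only DD links and reports per method", {
  g <- toyGraph("planted_partition", nNodes = 60, seed = 3)
  rep <- runEvaluation(g, 1, methods = c("cn", "ra"),
                       spec = splitSpec(0.3, repeats = 2, seed = 9))
  pr <- evalPerRepeat(rep)
  expect_setequal(unique(pr$method), c("cn", "ra"))
  expect_equal(nrow(pr), 4)
  pcols <- grep("precision_at", names(pr), value = TRUE)
  expect_true(all(pr[pcols] >= 0 & pr[pcols] <= 1, na.rm = TRUE))
})

test_that("evaluation 2 matches removals against the known-DDI list only", {
  g <- ringGraph(40)
  e <- graphEdges(g)
  dd <- e[e$subnetwork == "DD", ]
  known <- dd[seq_len(20), c("node_a", "node_b")]
  rep <- runEvaluation(g, 2, methods = "cn", knownDdi = known,
                       spec = splitSpec(0.3, repeats = 2, seed = 4))
  pr <- evalPerRepeat(rep)
  expect_equal(nrow(pr), 2)
  expect_error(runEvaluation(g, 2, methods = "cn"), "knownDdi")
})

test_that("evaluation 4 recovers planted gold pairs via 3-path scorers", {
  # food compound F (of FOOD1) and drug D joined by a 3-edge path F-x-y-D;
  # the gold pair (FOOD1, D) is absent from the graph as required
  kinds <- c(FOOD1_FDB1_C = "food_compound", x = "drug", y = "drug",
             D = "drug")
  g <- quickGraph(c("FOOD1_FDB1_C", "x", "y"), c("x", "y", "D"),
                  w = c(0.9, 0.8, 0.85), kinds = kinds)
  comp <- data.frame(food_id = "FOOD1", compound_id = "FDB1",
                     node_id = "FOOD1_FDB1_C", orig_content = 10,
                     contribution = 1, stringsAsFactors = FALSE)
  gold <- data.frame(food_id = "FOOD1", drug_id = "D",
                     stringsAsFactors = FALSE)
  rep <- runEvaluation(g, 4, methods = c("l3", "sp3"), goldStandard = gold,
                       composition = comp)
  pr <- evalPerRepeat(rep)
  expect_equal(pr$recovery_rate[pr$method == "l3"], 1.0)
  expect_equal(pr$recovery_rate[pr$method == "sp3"], 1.0)
  expect_error(runEvaluation(g, 4, methods = "l3"), "goldStandard")
})

test_that("food-level aggregation takes the per-(food,drug) maximum", {
  comp <- data.frame(food_id = c("FOOD1", "FOOD1", "FOOD2"),
                     compound_id = c("FDB1", "FDB2", "FDB1"),
                     node_id = c("FOOD1_FDB1_A", "FOOD1_FDB2_B",
                                 "FOOD2_FDB1_A"),
                     orig_content = 1, contribution = 0.5,
                     stringsAsFactors = FALSE)
  preds <- data.frame(
    node_a = c("FOOD1_FDB1_A", "DB9", "FOOD2_FDB1_A"),
    node_b = c("DB9", "FOOD1_FDB2_B", "DB9"),
    method = "l3", score = c(0.4, 0.7, 0.2), rank = 1:3,
    uses_bridge = FALSE, stringsAsFactors = FALSE)
  tab <- aggregateFoodLevel(preds, comp)
  expect_equal(tab$score[tab$food_id == "FOOD1"], 0.7)
  expect_equal(tab$n_compounds[tab$food_id == "FOOD1"], 2)
  expect_equal(nrow(tab), 2)
  # brute-force group-by maximum oracle
  foodOf <- setNames(comp$food_id, comp$node_id)
  for (r in seq_len(nrow(tab))) {
    rows <- apply(preds, 1, function(p) {
      f <- foodOf[c(p[["node_a"]], p[["node_b"]])]
      f <- f[!is.na(f)]
      length(f) == 1 && f == tab$food_id[r]
    })
    expect_equal(tab$score[r], max(as.numeric(preds$score[rows])))
  }
  expect_equal(nrow(aggregateFoodLevel(preds[0, ], comp)), 0)
})
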