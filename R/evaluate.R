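## Evaluation protocols: link-removal splits, precision@top-k, the
## threshold-sweep confusion procedure with AUC and precision-recall area,
## the four evaluation harnesses, and food-level aggregation of predictions.

#' Split specification for link-removal evaluation
#'
#' @param fractionRemoved fraction of eligible links held out as the test
#'   set (default 0.3).
#' @param scope \code{"DD_only"} removes only drug-drug similarity links
#'   (all food-food and food-drug links stay in training);
#'   \code{"all_links"} draws from every non-bridge link.
#' @param repeats number of random repeats (default 10).
#' @param seed integer base seed; repeat \code{r} uses
#'   \code{stageSeed(seed + r, "split")}.
#' @return a list of class \code{"SplitSpec"}.
#' @export
splitSpec <- function(fractionRemoved = 0.3,
                      scope = c("DD_only", "all_links"),
                      repeats = 10L, seed = 1L) {
  scope <- match.arg(scope)
  stopifnot(fractionRemoved > 0, fractionRemoved < 1, repeats >= 1)
  structure(list(fractionRemoved = fractionRemoved, scope = scope,
                 repeats = as.integer(repeats), seed = as.integer(seed)),
            class = "SplitSpec")
}

#' Remove a random fraction of links for testing
#'
#' Bridges are never eligible.  The split is deterministic given
#' \code{(spec$seed, repeatIndex)}.
#'
#' @param graph a \linkS4class{SimilarityGraph}.
#' @param spec a \code{\link{splitSpec}}.
#' @param repeatIndex 1-based repeat number.
#' @return list with \code{train} (a \linkS4class{SimilarityGraph} on the
#'   same node set, minus the test links) and \code{test} (data.frame of
#'   removed edges).
#' @export
splitLinks <- function(graph, spec = splitSpec(), repeatIndex = 1L) {
  stopifnot(is(graph, "SimilarityGraph"), inherits(spec, "SplitSpec"))
  e <- graphEdges(graph)
  eligible <- which(!e$is_bridge &
                      (spec$scope == "all_links" | e$subnetwork == "DD"))
  if (length(eligible) < 2L)
    stop("fewer than 2 eligible links to split (scope ", spec$scope, ")")
  nTest <- max(1L, round(spec$fractionRemoved * length(eligible)))
  if (nTest >= length(eligible))
    stop("fractionRemoved would remove all eligible links")
  set.seed(stageSeed(spec$seed + repeatIndex, "split"))
  testIdx <- eligible[sample.int(length(eligible), nTest)]
  test <- e[sort(testIdx), , drop = FALSE]
  rownames(test) <- NULL
  train <- SimilarityGraph(nodes = graphNodes(graph),
                           edges = e[-testIdx, , drop = FALSE])
  list(train = train, test = test)
}

#' Precision among the top-ranked predictions
#'
#' \code{k = ceiling(percent/100 * n)} over a ranked prediction list of
#' length \code{n}; returns the fraction of the top \code{k} predictions
#' that are held-out (test) links.
#'
#' @param predictions ranked prediction data.frame (see
#'   \code{\link{rankPredictions}}).
#' @param testLinks data.frame with \code{node_a}, \code{node_b} of held-out
#'   links.
#' @param percent top window as a percentage (1, 2 or 5 are the usual
#'   choices; any value in (0, 100] works).
#' @return precision in \code{[0, 1]}.
#' @export
precisionAtTop <- function(predictions, testLinks, percent = 1) {
  stopifnot(percent > 0, percent <= 100)
  n <- nrow(predictions)
  if (!n) stop("empty prediction list")
  k <- ceiling(percent / 100 * n)
  ord <- predictions[order(predictions$rank), , drop = FALSE]
  top <- ord[seq_len(k), , drop = FALSE]
  testKeys <- pairKey(testLinks$node_a, testLinks$node_b)
  mean(pairKey(top$node_a, top$node_b) %in% testKeys)
}

#' Threshold-sweep confusion counts, AUC and PRC area
#'
#' Sweeps a score threshold from the minimum to the maximum predicted score
#' in steps of \code{step} (the maximum is always included).  At each
#' threshold: a held-out link predicted with score strictly greater than the
#' threshold is a TP; a non-held-out prediction above the threshold is an
#' FP; held-out links at or below the threshold -- plus held-out links the
#' method never proposed -- are FN; remaining predictions are TN.  AUC is
#' the trapezoid over (FPR, TPR) with (0,0)/(1,1) anchors; the PRC area is
#' the trapezoid over (recall, precision) after dropping points with
#' undefined precision.
#'
#' @param predictions ranked prediction data.frame.
#' @param testLinks held-out link data.frame (\code{node_a}, \code{node_b}).
#' @param step threshold increment (default 0.1).
#' @return list with \code{counts} (data.frame: threshold, tp, fp, tn, fn),
#'   \code{auc} and \code{prc} (NA in the degenerate single-threshold case).
#' @export
confusionSweep <- function(predictions, testLinks, step = 0.1) {
  stopifnot(nrow(predictions) >= 1, all(is.finite(predictions$score)))
  testKeys <- unique(pairKey(testLinks$node_a, testLinks$node_b))
  predKeys <- pairKey(predictions$node_a, predictions$node_b)
  isTest <- predKeys %in% testKeys
  missedTests <- sum(!testKeys %in% predKeys)  # FN at every threshold
  lo <- min(predictions$score)
  hi <- max(predictions$score)
  thr <- seq(lo, hi, by = step)
  if (thr[length(thr)] < hi) thr <- c(thr, hi)
  counts <- do.call(rbind, lapply(thr, function(t) {
    above <- predictions$score > t
    data.frame(threshold = t,
               tp = sum(above & isTest),
               fp = sum(above & !isTest),
               tn = sum(!above & !isTest),
               fn = sum(!above & isTest) + missedTests)
  }))
  if (length(thr) < 2L)
    return(list(counts = counts, auc = NA_real_, prc = NA_real_))
  tpr <- with(counts, ifelse(tp + fn > 0, tp / (tp + fn), 0))
  fpr <- with(counts, ifelse(fp + tn > 0, fp / (fp + tn), 0))
  ## anchor the curve at both extremes and integrate by trapezoid
  roc <- unique(data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
  roc <- roc[order(roc$fpr, roc$tpr), , drop = FALSE]
  auc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  prec <- with(counts, ifelse(tp + fp > 0, tp / (tp + fp), NA_real_))
  rec <- tpr
  keep <- !is.na(prec)
  prc <- NA_real_
  if (sum(keep) >= 2L) {
    pr <- data.frame(rec = rec[keep], prec = prec[keep])
    pr <- pr[order(pr$rec, pr$prec), , drop = FALSE]
    prc <- sum(diff(pr$rec) * (head(pr$prec, -1) + pr$prec[-1]) / 2)
  }
  list(counts = counts, auc = auc, prc = prc)
}

evalMetrics <- function(predictions, testLinks, topPercents = c(1, 2, 5),
                        sweepStep = 0.1) {
  out <- list()
  if (!nrow(predictions)) {
    for (p in topPercents) out[[sprintf("precision_at_%g", p)]] <- NA_real_
    out$auc <- NA_real_
    out$prc <- NA_real_
    out$n_predictions <- 0L
    out$n_matched <- 0L
    return(out)
  }
  for (p in topPercents)
    out[[sprintf("precision_at_%g", p)]] <-
      precisionAtTop(predictions, testLinks, p)
  sw <- confusionSweep(predictions, testLinks, step = sweepStep)
  out$auc <- sw$auc
  out$prc <- sw$prc
  out$n_predictions <- nrow(predictions)
  out$n_matched <- sum(pairKey(predictions$node_a, predictions$node_b) %in%
                         pairKey(testLinks$node_a, testLinks$node_b))
  out
}

summarizeRepeats <- function(perRepeat) {
  metricCols <- setdiff(names(perRepeat), c("repeat_index", "method"))
  parts <- lapply(split(perRepeat, perRepeat$method), function(df) {
    row <- data.frame(method = df$method[1L], stringsAsFactors = FALSE)
    for (cl in metricCols) {
      row[[paste0(cl, "_mean")]] <- mean(df[[cl]], na.rm = TRUE)
      row[[paste0(cl, "_sd")]] <- if (nrow(df) > 1L)
        stats::sd(df[[cl]], na.rm = TRUE) else 0
    }
    row
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Run a link-removal evaluation protocol
#'
#' Four harnesses over a built graph:
#' \describe{
#'   \item{1}{remove 30\% of the drug-drug similarity links (all food links
#'     stay in training), predict with every requested method, and match
#'     predictions against the removed links.}
#'   \item{2}{ground truth from an external known-DDI list: the eligible
#'     links are the graph's DD edges that appear in \code{knownDdi}; a
#'     fraction of those is removed and predictions are matched against the
#'     removed known interactions (matching is undirected).}
#'   \item{3}{remove a fraction of \emph{all} links (DD, FF and FD) and
#'     match against the removed set.}
#'   \item{4}{gold-standard recovery: food-drug pairs held out from all
#'     training are matched against food-level aggregated predictions; the
#'     recovery rate is the fraction of gold pairs proposed at any rank.}
#' }
#' Each split-based protocol repeats \code{spec$repeats} times and reports
#' mean and sd.
#'
#' @param graph a \linkS4class{SimilarityGraph}.
#' @param evaluationId 1, 2, 3 or 4.
#' @param methods prediction methods to run (defaults: all eight for
#'   evaluation 1; \code{c("sp2", "ra")} for 2 and 3 -- the best disjoint
#'   and joint performers; \code{c("sp2", "sp3", "ra", "aa", "cn", "l3")}
#'   for 4).
#' @param spec a \code{\link{splitSpec}} (scope is forced by the protocol).
#' @param knownDdi data.frame of known drug-drug interaction pairs
#'   (\code{node_a}, \code{node_b}); required for evaluation 2.
#' @param goldStandard data.frame of gold-standard food-drug pairs
#'   (\code{food_id}, \code{drug_id}); required for evaluation 4.
#' @param composition composition entries (for food-level aggregation in
#'   evaluation 4).
#' @param topPercents precision@top windows.
#' @param sweepStep threshold-sweep step.
#' @param ... passed to \code{\link{predictLinks}} (e.g. \code{fdiOnly},
#'   \code{excludeBridgePaths}).
#' @return an \linkS4class{EvalReport}.
#' @export
runEvaluation <- function(graph, evaluationId,
                          methods = NULL,
                          spec = splitSpec(),
                          knownDdi = NULL, goldStandard = NULL,
                          composition = NULL,
                          topPercents = c(1, 2, 5), sweepStep = 0.1, ...) {
  stopifnot(is(graph, "SimilarityGraph"), evaluationId %in% 1:4)
  evaluationId <- as.integer(evaluationId)
  methods <- methods %||% switch(evaluationId,
    PREDICTION_METHODS,
    c("sp2", "ra"),
    c("sp2", "ra"),
    c("sp2", "sp3", "ra", "aa", "cn", "l3"))
  stopifnot(all(methods %in% PREDICTION_METHODS))

  if (evaluationId == 4L) {
    if (is.null(goldStandard) || is.null(composition))
      stop("evaluation 4 requires goldStandard and composition")
    dots <- list(...)
    dots$fdiOnly <- TRUE   # gold pairs are food-drug by definition
    rows <- lapply(methods, function(m) {
      preds <- do.call(predictLinks,
                       c(list(graph = graph, method = m), dots))
      foodTab <- aggregateFoodLevel(preds, composition)
      goldKeys <- pairKey(goldStandard$food_id, goldStandard$drug_id)
      hit <- if (nrow(foodTab))
        pairKey(foodTab$food_id, foodTab$drug_id) else character(0)
      data.frame(repeat_index = 1L, method = m,
                 recovery_rate = mean(goldKeys %in% hit),
                 n_predictions = nrow(foodTab),
                 n_matched = sum(goldKeys %in% hit),
                 stringsAsFactors = FALSE)
    })
    perRepeat <- do.call(rbind, rows)
    return(new("EvalReport", evaluation = 4L, perRepeat = perRepeat,
               summary = summarizeRepeats(perRepeat)))
  }

  spec$scope <- if (evaluationId == 3L) "all_links" else "DD_only"

  eligibleGraph <- graph
  if (evaluationId == 2L) {
    if (is.null(knownDdi)) stop("evaluation 2 requires a knownDdi list")
    ## restrict the removable set to DD edges reported as known interactions
    e <- graphEdges(graph)
    knownKeys <- pairKey(knownDdi$node_a, knownDdi$node_b)
    isKnown <- pairKey(e$node_a, e$node_b) %in% knownKeys &
      e$subnetwork == "DD"
    if (sum(isKnown) < 2L)
      stop("fewer than 2 known-DDI links present in the graph")
  }

  rows <- list()
  for (r in seq_len(spec$repeats)) {
    if (evaluationId == 2L) {
      ## split only the known-DDI links
      e <- graphEdges(graph)
      knownKeys <- pairKey(knownDdi$node_a, knownDdi$node_b)
      idx <- which(pairKey(e$node_a, e$node_b) %in% knownKeys &
                     e$subnetwork == "DD" & !e$is_bridge)
      nTest <- max(1L, round(spec$fractionRemoved * length(idx)))
      if (nTest >= length(idx))
        stop("fractionRemoved would remove all known-DDI links")
      set.seed(stageSeed(spec$seed + r, "split"))
      testIdx <- idx[sample.int(length(idx), nTest)]
      split <- list(
        train = SimilarityGraph(nodes = graphNodes(graph),
                                edges = e[-testIdx, , drop = FALSE]),
        test = e[sort(testIdx), , drop = FALSE])
    } else {
      split <- splitLinks(graph, spec, repeatIndex = r)
    }
    for (m in methods) {
      preds <- predictLinks(split$train, method = m, ...)
      met <- evalMetrics(preds, split$test, topPercents, sweepStep)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(repeat_index = r, method = m, stringsAsFactors = FALSE),
        as.data.frame(met))
    }
  }
  perRepeat <- do.call(rbind, rows)
  rownames(perRepeat) <- NULL
  new("EvalReport", evaluation = evaluationId, perRepeat = perRepeat,
      summary = summarizeRepeats(perRepeat))
}

#' Aggregate compound-level predictions to food level
#'
#' A predicted food-compound/drug pair is attributed to its food; per
#' (food, drug) the maximum compound-level score is reported along with the
#' contributing compounds.
#'
#' @param predictions prediction data.frame whose food-compound nodes follow
#'   the \code{FOODxxxx_FDBxxxxx_Name} convention (or appear in
#'   \code{composition}).
#' @param composition composition entries (\code{node_id}, \code{food_id}).
#' @return data.frame: \code{food_id}, \code{drug_id}, \code{score} (max
#'   over compounds), \code{n_compounds}, \code{compounds}
#'   (comma-separated node ids), sorted by decreasing score.
#' @export
aggregateFoodLevel <- function(predictions, composition) {
  if (!nrow(predictions))
    return(data.frame(food_id = character(0), drug_id = character(0),
                      score = numeric(0), n_compounds = integer(0),
                      compounds = character(0), stringsAsFactors = FALSE))
  foodOf <- setNames(composition$food_id, composition$node_id)
  aFood <- predictions$node_a %in% names(foodOf)
  bFood <- predictions$node_b %in% names(foodOf)
  fd <- xor(aFood, bFood)
  predictions <- predictions[fd, , drop = FALSE]
  if (!nrow(predictions))
    return(aggregateFoodLevel(emptyPredictions(), composition))
  aFood <- aFood[fd]
  foodNode <- ifelse(aFood, predictions$node_a, predictions$node_b)
  drug <- ifelse(aFood, predictions$node_b, predictions$node_a)
  tab <- data.frame(food_id = unname(foodOf[foodNode]), drug_id = drug,
                    node = foodNode, score = predictions$score,
                    stringsAsFactors = FALSE)
  parts <- lapply(split(tab, paste(tab$food_id, tab$drug_id, sep = "\r")),
    function(df) {
      data.frame(food_id = df$food_id[1L], drug_id = df$drug_id[1L],
                 score = max(df$score), n_compounds = nrow(df),
                 compounds = paste(sort(unique(df$node)), collapse = ","),
                 stringsAsFactors = FALSE)
    })
  out <- do.call(rbind, parts)
  out <- out[order(-out$score, out$food_id, out$drug_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
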