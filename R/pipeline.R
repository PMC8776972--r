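## End-to-end orchestration: fixtures -> ingest -> SSP -> graph -> predict
## (-> evaluate), seeded and logged, with every stage's output written as
## plain text beside a resolved configuration file.

#' Write / read a weighted edge-list graph TSV
#'
#' The interchange format is a TSV with columns \code{node_a}, \code{node_b},
#' \code{weight}, \code{subnetwork}, \code{is_bridge}, preceded by \code{#}
#' comment lines listing nodes as \code{node_id<TAB>kind} so isolated nodes
#' survive the round trip.
#'
#' @param graph a \linkS4class{SimilarityGraph}.
#' @param path file path.
#' @return \code{writeGraphTsv}: the path, invisibly; \code{readGraphTsv}:
#'   a \linkS4class{SimilarityGraph}.
#' @export
writeGraphTsv <- function(graph, path) {
  nodes <- graphNodes(graph)
  hdr <- sprintf("#node\t%s\t%s", nodes$node_id, nodes$kind)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(EDGE_COLS, collapse = "\t"), con)
  e <- graphEdges(graph)
  if (nrow(e))
    writeLines(paste(e$node_a, e$node_b,
                     format(e$weight, digits = 15, scientific = FALSE,
                            trim = TRUE),
                     e$subnetwork, e$is_bridge, sep = "\t"), con)
  invisible(path)
}

#' @rdname writeGraphTsv
#' @export
readGraphTsv <- function(path) {
  lines <- readLines(path)
  nodeLines <- grep("^#node\t", lines, value = TRUE)
  body <- lines[!startsWith(lines, "#")]
  nodes <- if (length(nodeLines)) {
    parts <- strsplit(sub("^#node\t", "", nodeLines), "\t", fixed = TRUE)
    data.frame(node_id = vapply(parts, `[`, "", 1L),
               kind = vapply(parts, `[`, "", 2L), stringsAsFactors = FALSE)
  } else NULL
  edges <- if (length(body) > 1L) {
    df <- read.table(text = body, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    df$is_bridge <- as.logical(df$is_bridge)
    df
  } else emptyEdges()
  if (is.null(nodes)) return(buildGraph(edges))
  SimilarityGraph(nodes = nodes, edges = edges)
}

#' Pipeline run configuration
#'
#' Default thresholds follow the framework's working points: Tanimoto
#' threshold 0.6, contribution-stage threshold 0.5 (0.3 for the "relaxed"
#' batch), bridge weight 1e-5.
#'
#' @param outDir run output directory.
#' @param drugbankXml,foodbDir input corpus paths; when \code{NULL} and
#'   \code{fixtures} is given, synthetic fixtures are generated under
#'   \code{outDir/fixtures}.
#' @param fixtures a \code{\link{fixtureSpec}} or \code{NULL}.
#' @param tanimotoThreshold,contributionThreshold,thresholdOn,bridgeWeight
#'   graph-construction parameters (see \code{\link{applyThreshold}},
#'   \code{\link{applyContributionThreshold}}, \code{\link{joinify}}).
#' @param graphVariant \code{"disjoint"} or \code{"joint"}.
#' @param methods link-prediction methods to run.
#' @param evaluation evaluation protocol id (1-4) or \code{NULL} to skip;
#'   protocols 2 and 4 additionally need \code{knownDdi} /
#'   \code{goldStandard} side inputs.
#' @param split a \code{\link{splitSpec}}.
#' @param fdiOnly restrict predictions to food-drug pairs.
#' @param contentRangeMode,healthEffectFilter FooDB parsing options.
#' @param radius,nBits fingerprint parameters.
#' @param seed run seed; per-stage seeds derive via \code{\link{stageSeed}}.
#' @return a list of class \code{"RunConfig"}.
#' @export
runConfig <- function(outDir,
                      drugbankXml = NULL, foodbDir = NULL, fixtures = NULL,
                      tanimotoThreshold = 0.6,
                      contributionThreshold = 0.5,
                      thresholdOn = "weight",
                      bridgeWeight = 1e-5,
                      graphVariant = c("disjoint", "joint"),
                      methods = c("sp2", "ra"),
                      evaluation = NULL,
                      split = splitSpec(),
                      fdiOnly = FALSE,
                      contentRangeMode = "max",
                      healthEffectFilter = TRUE,
                      radius = 2L, nBits = 2048L,
                      seed = 1L) {
  graphVariant <- match.arg(graphVariant)
  stopifnot(tanimotoThreshold >= 0, tanimotoThreshold <= 1,
            contributionThreshold >= 0, contributionThreshold <= 1,
            all(methods %in% PREDICTION_METHODS))
  structure(list(outDir = outDir, drugbankXml = drugbankXml,
                 foodbDir = foodbDir, fixtures = fixtures,
                 tanimotoThreshold = tanimotoThreshold,
                 contributionThreshold = contributionThreshold,
                 thresholdOn = thresholdOn,
                 bridgeWeight = bridgeWeight,
                 graphVariant = graphVariant, methods = methods,
                 evaluation = evaluation, split = split,
                 fdiOnly = fdiOnly,
                 contentRangeMode = contentRangeMode,
                 healthEffectFilter = healthEffectFilter,
                 radius = as.integer(radius), nBits = as.integer(nBits),
                 seed = as.integer(seed)),
            class = "RunConfig")
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Executes fixtures (optional) -> parsing and filtering -> structure
#' similarity profile -> thresholding, contribution re-weighting and graph
#' assembly (disjoint or joint) -> link prediction -> (optional) evaluation,
#' writing each stage's output under \code{config$outDir} plus a
#' machine-readable \code{summary.json}.  Deterministic given the config
#' (including its seed).
#'
#' @param config a \code{\link{runConfig}}.
#' @param knownDdi,goldStandard optional side inputs for evaluations 2 / 4.
#' @param quiet suppress stage log messages.
#' @return (invisibly) list with the built \code{graph}, the
#'   \code{predictions} per method, the \code{report} (or NULL) and the
#'   \code{summary} list.
#' @export
runPipeline <- function(config, knownDdi = NULL, goldStandard = NULL,
                        quiet = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  cfgOut <- config
  cfgOut$split <- unclass(config$split)
  if (!is.null(cfgOut$fixtures)) cfgOut$fixtures <- unclass(cfgOut$fixtures)
  jsonlite::write_json(unclass(cfgOut),
                       file.path(config$outDir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)

  dbXml <- config$drugbankXml
  fbDir <- config$foodbDir
  if (!is.null(config$fixtures)) {
    fixDir <- file.path(config$outDir, "fixtures")
    say("stage fixtures: generating synthetic corpora in %s", fixDir)
    db <- generateDrugbankFixture(config$fixtures, fixDir)
    fb <- generateFoodbFixture(config$fixtures, fixDir)
    dbXml <- dbXml %||% db$xml
    fbDir <- fbDir %||% fb$dir
  }
  if (is.null(dbXml) || is.null(fbDir))
    stop("stage ingest: no inputs (provide drugbankXml/foodbDir or fixtures)")

  say("stage ingest: parsing %s and %s", dbXml, fbDir)
  drugs <- parseDrugBank(dbXml)
  fdb <- parseFooDB(fbDir, contentRangeMode = config$contentRangeMode,
                    healthEffectFilter = config$healthEffectFilter)
  nodes <- rbind(drugs, fdb$nodes)
  if (nrow(nodes) < 2L) stop("stage ingest: fewer than 2 nodes survived")
  entries <- fdb$entries
  writeTsv(nodes, file.path(config$outDir, "nodes.tsv"))
  writeTsv(entries, file.path(config$outDir, "contributions.tsv"))
  say("stage ingest: %d drugs, %d food-compound nodes",
      nrow(drugs), nrow(fdb$nodes))

  say("stage ssp: fingerprinting %d nodes (radius %d, %d bits)",
      nrow(nodes), config$radius, config$nBits)
  ssp <- buildSSP(nodes, radius = config$radius, nBits = config$nBits)
  writeTsv(ssp, file.path(config$outDir, "ssp.tsv"))

  kept <- applyThreshold(ssp, config$tanimotoThreshold)
  say("stage graph: %d/%d pairs pass Tanimoto >= %g",
      nrow(kept), nrow(ssp), config$tanimotoThreshold)
  kept <- updateScores(kept, entries)
  kept <- applyContributionThreshold(kept, config$contributionThreshold,
                                     on = config$thresholdOn)
  say("stage graph: %d edges pass contribution-stage threshold >= %g",
      nrow(kept), config$contributionThreshold)
  graph <- buildGraph(kept, nodes = nodes[c("node_id", "kind")])
  if (config$graphVariant == "joint")
    graph <- joinify(graph, bridgeWeight = config$bridgeWeight,
                     seed = stageSeed(config$seed, "joinify"))
  writeGraphTsv(graph, file.path(config$outDir, "graph.tsv"))
  graphSummary <- list(
    nodes = nrow(graphNodes(graph)),
    edges = nrow(graphEdges(graph)),
    bridges = sum(graphEdges(graph)$is_bridge),
    components = nComponents(graph),
    subnetworks = as.list(table(graphEdges(graph)$subnetwork)))
  jsonlite::write_json(graphSummary,
                       file.path(config$outDir, "graph_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  predictions <- list()
  for (m in config$methods) {
    say("stage predict: method %s", m)
    p <- predictLinks(graph, method = m, fdiOnly = config$fdiOnly)
    predictions[[m]] <- p
    writeTsv(p, file.path(config$outDir,
                          sprintf("predictions_%s.tsv", m)))
  }

  report <- NULL
  if (!is.null(config$evaluation)) {
    say("stage evaluate: protocol %d", config$evaluation)
    spec <- config$split
    spec$seed <- stageSeed(config$seed, "evaluate")
    report <- runEvaluation(graph, config$evaluation,
                            methods = config$methods, spec = spec,
                            knownDdi = knownDdi,
                            goldStandard = goldStandard,
                            composition = entries,
                            fdiOnly = config$fdiOnly)
    writeTsv(evalPerRepeat(report),
             file.path(config$outDir, "eval_report.tsv"))
    jsonlite::write_json(evalSummary(report),
                         file.path(config$outDir, "eval_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  }

  summary <- list(
    seed = config$seed,
    n_drugs = nrow(drugs),
    n_food_compounds = nrow(fdb$nodes),
    n_ssp_pairs = nrow(ssp),
    graph = graphSummary,
    predictions = lapply(predictions, function(p)
      list(n = nrow(p),
           top = if (nrow(p)) paste(p$node_a[1L], p$node_b[1L], sep = "--")
                 else NA,
           top_score = if (nrow(p)) p$score[1L] else NA)),
    evaluation = if (!is.null(report)) list(
      protocol = report@evaluation,
      summary = evalSummary(report)) else NULL)
  jsonlite::write_json(summary, file.path(config$outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       null = "null", pretty = TRUE)
  say("run complete: %s", file.path(config$outDir, "summary.json"))
  invisible(list(graph = graph, predictions = predictions,
                 report = report, summary = summary))
}
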