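## Seeded synthetic fixtures: DrugBank-dialect XML, FooDB-dialect JSON,
## SMILES pools and small oracle graphs, so every downstream stage is
## testable without external downloads.  The XML/JSON dialects cover only
## the fields the dataset filters read.

#' Specification for synthetic database fixtures
#'
#' @param nDrugs,nFoods counts (>= 1).
#' @param compoundsPerFood integer range \code{c(min, max)} of compounds
#'   drawn per food.
#' @param fractionMetabolismDdi fraction of approved small-molecule drugs
#'   that carry a metabolism-related interaction description (these are the
#'   drugs that survive the dataset filter).
#' @param fractionBiotech,fractionExperimental fractions of drugs emitted as
#'   biotech type / experimental group (both fail the filter).
#' @param seed integer seed; the same spec produces byte-identical files.
#' @return a list of class \code{"FixtureSpec"}.
#' @export
fixtureSpec <- function(nDrugs = 20L, nFoods = 5L,
                        compoundsPerFood = c(2L, 5L),
                        fractionMetabolismDdi = 0.5,
                        fractionBiotech = 0.1,
                        fractionExperimental = 0.1,
                        seed = 1L) {
  stopifnot(nDrugs >= 1, nFoods >= 1, length(compoundsPerFood) == 2L,
            all(compoundsPerFood >= 1),
            compoundsPerFood[1] <= compoundsPerFood[2],
            fractionMetabolismDdi >= 0, fractionMetabolismDdi <= 1,
            fractionBiotech + fractionExperimental <= 1)
  structure(list(nDrugs = as.integer(nDrugs), nFoods = as.integer(nFoods),
                 compoundsPerFood = as.integer(compoundsPerFood),
                 fractionMetabolismDdi = fractionMetabolismDdi,
                 fractionBiotech = fractionBiotech,
                 fractionExperimental = fractionExperimental,
                 seed = as.integer(seed)),
            class = "FixtureSpec")
}

## vetted parseable SMILES; ethanol deliberately first
VETTED_SMILES <- c(
  "CCO",                                  # ethanol
  "CC(=O)Oc1ccccc1C(=O)O",                # aspirin
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",           # caffeine
  "CC(=O)Nc1ccc(O)cc1",                   # paracetamol
  "CC(C)Cc1ccc(cc1)C(C)C(=O)O",           # ibuprofen
  "C1CCCCC1", "c1ccccc1", "Cc1ccccc1",
  "OC(=O)CCCCC(=O)O",                     # adipic acid
  "NCC(=O)O", "CC(N)C(=O)O",              # glycine, alanine
  "NCCCCC(N)C(=O)O",                      # lysine
  "OCC(O)C(O)C(O)C(O)CO",                 # sorbitol
  "OC(=O)c1ccccc1",                       # benzoic acid
  "Oc1ccc(cc1)C=CC(=O)O",                 # coumaric acid
  "CCCCCCCCC=CCCCCCCCC(=O)O",             # oleic-like fatty acid
  "CCCCCCCCCCCCCCCC(=O)O",                # palmitic acid
  "COc1cc(C=CC)ccc1O",                    # eugenol-like
  "CC(C)c1ccc(C)cc1",                     # p-cymene
  "CC(C)c1ccc(C)cc1O",                    # carvacrol
  "OCC1OC(O)C(O)C(O)C1O",                 # sugar
  "C(C1C(C(C(C(O1)O)O)O)O)O",             # glucose spelling
  "CN1CCC[C@H]1c1cccnc1",                 # nicotine
  "OC(=O)C=Cc1ccccc1",                    # cinnamic acid
  "CSCCC(N)C(=O)O",                       # methionine
  "NC(Cc1ccccc1)C(=O)O",                  # phenylalanine
  "OC(=O)CC(O)(CC(=O)O)C(=O)O",           # citric acid
  "CC(O)C(=O)O",                          # lactic acid
  "OCC(O)CO",                             # glycerol
  "CCCCCO", "CCCCO", "CCCO",
  "CCOC(=O)C", "CCOCC", "CC=O", "CC#N",
  "c1ccc2ccccc2c1",                       # naphthalene
  "c1ccncc1", "c1ccoc1", "c1cc[nH]c1",
  "CC(C)=CCCC(C)=CCO"                     # geraniol
)

decoratedSmiles <- function(k) {
  chain <- strrep("C", ((k - 1L) %% 30L) + 2L)
  switch((k - 1L) %/% 30L + 1L,
         paste0(chain, "O"),
         paste0(chain, "C(=O)O"),
         paste0(chain, "N"),
         paste0(chain, "OC"))
}

#' Deterministic pool of valid SMILES strings
#'
#' Returns the built-in vetted list (ethanol first) followed, when more are
#' needed, by combinatorially decorated alkyl chains (alcohols, acids,
#' amines, ethers).  Every returned string parses in the chemistry toolkit.
#' Duplicates occur only when \code{n} exceeds the pool capacity, in which
#' case the result carries a warning and a \code{recycled} attribute.
#'
#' @param n number of SMILES requested.
#' @param seed integer seed (shuffles only the decorated tail, so small
#'   requests are stable across seeds).
#' @return character vector of length \code{n}.
#' @export
generateSmilesPool <- function(n, seed = 1L) {
  stopifnot(n >= 1)
  base <- VETTED_SMILES
  if (n <= length(base)) return(base[seq_len(n)])
  extraNeeded <- n - length(base)
  capacity <- 120L
  deco <- vapply(seq_len(capacity), decoratedSmiles, character(1))
  set.seed(as.integer(seed))
  deco <- sample(deco)
  pool <- c(base, deco)
  if (n > length(pool)) {
    warning("requested ", n, " SMILES but pool capacity is ",
            length(pool), "; recycling")
    out <- rep_len(pool, n)
    attr(out, "recycled") <- TRUE
    return(out)
  }
  c(base, deco[seq_len(extraNeeded)])
}

#' Generate a DrugBank-dialect XML fixture
#'
#' Emits a small XML corpus mixing approved/experimental groups and
#' small-molecule/biotech types.  Exactly
#' \code{round(fractionMetabolismDdi * n)} of the approved small molecules
#' carry an interaction description containing "metabolism"; those are the
#' drugs the dataset filter keeps, and the manifest lists them.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir output directory (created if needed).
#' @return (invisibly) list with \code{xml} and \code{manifest} file paths
#'   and the \code{manifest} data.frame of surviving drug ids.
#' @export
generateDrugbankFixture <- function(spec, dir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- spec$nDrugs
  set.seed(stageSeed(spec$seed, "drugbank"))
  ids <- sprintf("DB%05d", seq_len(n))
  smiles <- generateSmilesPool(n, seed = spec$seed)
  nBio <- round(spec$fractionBiotech * n)
  nExp <- round(spec$fractionExperimental * n)
  type <- rep("small molecule", n)
  group <- rep("approved", n)
  if (nBio > 0) type[sample.int(n, nBio)] <- "biotech"
  expCandidates <- which(type == "small molecule")
  nExp <- min(nExp, length(expCandidates))
  if (nExp > 0)
    group[sample(expCandidates, nExp)] <- "experimental"
  qualified <- which(type == "small molecule" & group == "approved")
  nMet <- round(spec$fractionMetabolismDdi * length(qualified))
  metIdx <- if (nMet > 0) sort(sample(qualified, nMet)) else integer(0)

  doc <- xml2::xml_new_root("drugbank")
  for (i in seq_len(n)) {
    d <- xml2::xml_add_child(doc, "drug", type = type[i])
    xml2::xml_add_child(d, "drugbank-id", ids[i], primary = "true")
    xml2::xml_add_child(d, "name", sprintf("Drug_%03d", i))
    g <- xml2::xml_add_child(d, "groups")
    xml2::xml_add_child(g, "group", group[i])
    cp <- xml2::xml_add_child(d, "calculated-properties")
    pr <- xml2::xml_add_child(cp, "property")
    xml2::xml_add_child(pr, "kind", "SMILES")
    xml2::xml_add_child(pr, "value", smiles[i])
    di <- xml2::xml_add_child(d, "drug-interactions")
    partner <- ids[if (i == n) 1L else i + 1L]
    it <- xml2::xml_add_child(di, "drug-interaction")
    xml2::xml_add_child(it, "drugbank-id", partner)
    xml2::xml_add_child(it, "description",
      if (i %in% metIdx)
        sprintf("The metabolism of %s can be decreased when combined with %s.",
                sprintf("Drug_%03d", i), partner)
      else
        sprintf("The risk or severity of hypotension can be increased when %s is combined with %s.",
                sprintf("Drug_%03d", i), partner))
  }
  xmlPath <- file.path(dir, "drugbank.xml")
  xml2::write_xml(doc, xmlPath)
  manifest <- data.frame(node_id = ids[metIdx], stringsAsFactors = FALSE)
  manPath <- file.path(dir, "drugbank_manifest.tsv")
  write.table(manifest, manPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(xml = xmlPath, manifest_path = manPath,
                 manifest = manifest))
}

#' Generate a FooDB-dialect JSON fixture
#'
#' Writes \code{Content.json}, \code{Compound.json} and
#' \code{HealthEffect.json}.  Survivor rows have citation type
#' \code{DATABASE}, source type \code{COMPOUND}, a mapped compound with a
#' SMILES, an original content amount (uniform on [1, 1000] mg/100 g) and a
#' health-effect link.  Distractor rows violate one rule each (ARTICLE
#' citation, NUTRIENT source, missing content, compound without SMILES,
#' compound without health effect) so the parser's filters are exercised.
#'
#' @param spec a \code{\link{fixtureSpec}}.
#' @param dir output directory.
#' @return (invisibly) list with the \code{dir}, the \code{manifest}
#'   data.frame of surviving (food, compound) rows (with their expected
#'   node ids and contents) and its path.
#' @export
generateFoodbFixture <- function(spec, dir) {
  stopifnot(inherits(spec, "FixtureSpec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(stageSeed(spec$seed, "foodb"))
  nFoods <- spec$nFoods
  poolSize <- max(spec$compoundsPerFood[2L] * 2L, 6L)
  cmpIds <- sprintf("FDB%06d", seq_len(poolSize))
  cmpNames <- sprintf("Compound %03d", seq_len(poolSize))  # space tests sanitization
  smiles <- generateSmilesPool(poolSize, seed = spec$seed + 1L)
  foods <- sprintf("FOOD%05d", seq_len(nFoods))

  rows <- list()
  for (f in foods) {
    k <- sample(seq(spec$compoundsPerFood[1L], spec$compoundsPerFood[2L]),
                1L)
    k <- min(k, poolSize)
    chosen <- sample.int(poolSize, k)
    for (ci in chosen) {
      rows[[length(rows) + 1L]] <- data.frame(
        id = length(rows) + 1L, food_id = f, source_id = cmpIds[ci],
        source_type = "COMPOUND", citation_type = "DATABASE",
        orig_content = round(runif(1, 1, 1000), 3),
        orig_min = NA_real_, orig_max = NA_real_,
        orig_unit = "mg/100 g", survivor = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  ## distractors, one per violated rule, attached to the first food
  bad <- function(...) {
    df <- data.frame(..., stringsAsFactors = FALSE)
    df$id <- length(rows) + 1L
    df$survivor <- FALSE
    df
  }
  rows[[length(rows) + 1L]] <- bad(
    food_id = foods[1L], source_id = "FDBEXTRA1", source_type = "COMPOUND",
    citation_type = "ARTICLE", orig_content = 12.0,
    orig_min = NA_real_, orig_max = NA_real_, orig_unit = "mg/100 g")
  rows[[length(rows) + 1L]] <- bad(
    food_id = foods[1L], source_id = "FDBNUTR01", source_type = "NUTRIENT",
    citation_type = "DATABASE", orig_content = 40.0,
    orig_min = NA_real_, orig_max = NA_real_, orig_unit = "mg/100 g")
  rows[[length(rows) + 1L]] <- bad(
    food_id = foods[1L], source_id = "FDBNOCON1", source_type = "COMPOUND",
    citation_type = "DATABASE", orig_content = NA_real_,
    orig_min = NA_real_, orig_max = NA_real_, orig_unit = "mg/100 g")
  rows[[length(rows) + 1L]] <- bad(
    food_id = foods[1L], source_id = "FDBNOSMI1", source_type = "COMPOUND",
    citation_type = "DATABASE", orig_content = 7.5,
    orig_min = NA_real_, orig_max = NA_real_, orig_unit = "mg/100 g")
  rows[[length(rows) + 1L]] <- bad(
    food_id = foods[1L], source_id = "FDBNOHE01", source_type = "COMPOUND",
    citation_type = "DATABASE", orig_content = 3.1,
    orig_min = NA_real_, orig_max = NA_real_, orig_unit = "mg/100 g")
  content <- do.call(rbind, lapply(rows, function(r)
    r[c("id", "food_id", "source_id", "source_type", "citation_type",
        "orig_content", "orig_min", "orig_max", "orig_unit", "survivor")]))
  ## drop duplicate (food, compound) pairs among survivors
  dup <- duplicated(content[c("food_id", "source_id")])
  content <- content[!dup, , drop = FALSE]

  compound <- data.frame(
    id = c(cmpIds, "FDBNOSMI1", "FDBNOHE01", "FDBEXTRA1", "FDBNOCON1"),
    name = c(cmpNames, "No Smiles", "No HealthEffect", "Extra Article",
             "No Content"),
    moldb_smiles = c(smiles, NA_character_, smiles[1L], smiles[2L],
                     smiles[3L]),
    stringsAsFactors = FALSE)
  healthEffect <- data.frame(
    compound_id = c(cmpIds, "FDBEXTRA1", "FDBNOCON1"),
    health_effect = rep(c("anti-inflammatory", "antioxidant", "allergenic"),
                        length.out = length(cmpIds) + 2L),
    stringsAsFactors = FALSE)

  writeJson <- function(x, name) {
    p <- file.path(dir, name)
    jsonlite::write_json(x, p, dataframe = "rows", na = "null",
                         auto_unbox = FALSE, digits = NA, pretty = TRUE)
    p
  }
  writeJson(content[names(content) != "survivor"], "Content.json")
  writeJson(compound, "Compound.json")
  writeJson(healthEffect, "HealthEffect.json")

  surv <- content[content$survivor, , drop = FALSE]
  nm <- setNames(compound$name, compound$id)
  manifest <- data.frame(
    food_id = surv$food_id, compound_id = surv$source_id,
    node_id = foodCompoundNodeId(surv$food_id, surv$source_id,
                                 nm[surv$source_id]),
    orig_content = surv$orig_content, stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$node_id), , drop = FALSE]
  rownames(manifest) <- NULL
  manPath <- file.path(dir, "foodb_manifest.tsv")
  write.table(manifest, manPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(dir = dir, manifest_path = manPath, manifest = manifest))
}

#' Catalogued toy graphs with hand-computable scorer values
#'
#' Small named graphs used as oracles:
#' \describe{
#'   \item{triangle}{3 drug nodes, 3 edges of weight 1.}
#'   \item{square}{4-cycle (opposite pairs share 2 common neighbors).}
#'   \item{two_components}{two disjoint weighted edges.}
#'   \item{l3_path}{path a-u-v-b with uniform edge \code{weight}; the only
#'     3-edge path, so L3(a,b) = weight^3 / sqrt(k_u k_v).}
#'   \item{star}{hub with 4 leaves.}
#'   \item{planted_partition}{seeded two-cluster graph (default 150 nodes,
#'     within-cluster edge probability \code{pIn} = 0.6, across
#'     \code{pOut} = 0.05, weights uniform on [0.6, 1], alternating
#'     drug/food-compound labels).  The defaults emulate the dense blocks a
#'     Tanimoto threshold of 0.6 carves out of a chemical similarity matrix,
#'     with sparse incidental cross-cluster similarity.}
#' }
#'
#' @param name catalogue entry name.
#' @param weight uniform edge weight for the fixed-topology entries.
#' @param nNodes,pIn,pOut,seed planted-partition parameters.
#' @return a \linkS4class{SimilarityGraph}.
#' @export
toyGraph <- function(name = c("triangle", "square", "two_components",
                              "l3_path", "star", "planted_partition"),
                     weight = 1.0, nNodes = 150L, pIn = 0.6, pOut = 0.05,
                     seed = 1L) {
  name <- match.arg(name)
  drugNodes <- function(ids)
    data.frame(node_id = ids, kind = "drug", stringsAsFactors = FALSE)
  ed <- function(a, b, w = weight)
    data.frame(node_a = a, node_b = b, weight = w,
               stringsAsFactors = FALSE)
  switch(name,
    triangle = SimilarityGraph(drugNodes(c("t1", "t2", "t3")),
      ed(c("t1", "t1", "t2"), c("t2", "t3", "t3"))),
    square = SimilarityGraph(drugNodes(c("q1", "q2", "q3", "q4")),
      ed(c("q1", "q2", "q3", "q1"), c("q2", "q3", "q4", "q4"))),
    two_components = SimilarityGraph(drugNodes(c("a", "b", "c", "d")),
      ed(c("a", "c"), c("b", "d"), c(0.9, 0.8))),
    l3_path = SimilarityGraph(drugNodes(c("a", "u", "v", "b")),
      ed(c("a", "u", "v"), c("u", "v", "b"))),
    star = SimilarityGraph(drugNodes(c("hub", paste0("leaf", 1:4))),
      ed(rep("hub", 4), paste0("leaf", 1:4))),
    planted_partition = {
      set.seed(as.integer(seed))
      ids <- sprintf("n%03d", seq_len(nNodes))
      kind <- rep(c("drug", "food_compound"), length.out = nNodes)
      cluster <- rep(1:2, each = ceiling(nNodes / 2))[seq_len(nNodes)]
      pairs <- utils::combn(nNodes, 2L)
      same <- cluster[pairs[1L, ]] == cluster[pairs[2L, ]]
      p <- ifelse(same, pIn, pOut)
      keep <- runif(ncol(pairs)) < p
      edges <- data.frame(
        node_a = ids[pairs[1L, keep]], node_b = ids[pairs[2L, keep]],
        weight = round(runif(sum(keep), 0.6, 1), 6),
        stringsAsFactors = FALSE)
      SimilarityGraph(
        data.frame(node_id = ids, kind = kind, stringsAsFactors = FALSE),
        edges)
    })
}
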