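## Parsing of DrugBank-style XML and FooDB-style JSON corpora, the filtering
## rules that define the modelled dataset, the food-compound naming
## convention, and normalized composition contribution scores.

sanitizeName <- function(x) gsub("\\s+", "_", trimws(x))

#' Node identifier for a food-compound instance
#'
#' The same compound occurring in two foods yields two distinct graph nodes,
#' named \code{FOODxxxx_FDBxxxxx_CompoundName} (whitespace in the compound
#' name becomes underscores).
#'
#' @param foodId,compoundId,name character vectors.
#' @return character vector of node ids.
#' @export
#' @examples
#' foodCompoundNodeId("FOOD00005", "FDB000633", "Kaempferol")
foodCompoundNodeId <- function(foodId, compoundId, name) {
  paste(foodId, compoundId, sanitizeName(name), sep = "_")
}

#' Parse a DrugBank-dialect XML file
#'
#' Keeps only drugs that are (i) in the \code{approved} group, (ii) of type
#' \code{small molecule}, and (iii) carry at least one metabolism-related
#' drug-interaction description (case-insensitive keyword match on the
#' description text).  Drugs without a SMILES are excluded with a warning;
#' duplicate drug ids are collapsed to one node.
#'
#' @param xmlPath path to the XML file (documented minimal DrugBank dialect:
#'   \code{drug} elements with a \code{type} attribute, \code{drugbank-id},
#'   \code{name}, \code{groups/group}, a SMILES calculated property and
#'   \code{drug-interactions/drug-interaction/description}).
#' @param metabolismPattern regular expression a drug-interaction description
#'   must match (case-insensitively) for the drug to qualify.
#' @return data.frame of drug nodes: \code{node_id}, \code{kind} (always
#'   \code{"drug"}), \code{name}, \code{smiles}, \code{food_id},
#'   \code{compound_id} (both \code{NA} for drugs).
#' @export
parseDrugBank <- function(xmlPath, metabolismPattern = "metabolism") {
  doc <- xml2::read_xml(xmlPath)
  drugs <- xml2::xml_find_all(doc, ".//drug[not(ancestor::drug)]")
  pick <- function(d, xp) xml2::xml_text(xml2::xml_find_first(d, xp))
  rows <- lapply(drugs, function(d) {
    id <- pick(d, "./drugbank-id[@primary='true']")
    if (is.na(id)) id <- pick(d, "./drugbank-id")
    groups <- xml2::xml_text(xml2::xml_find_all(d, "./groups/group"))
    descr <- xml2::xml_text(xml2::xml_find_all(
      d, "./drug-interactions/drug-interaction/description"))
    data.frame(
      node_id = id,
      name = pick(d, "./name"),
      type = xml2::xml_attr(d, "type"),
      approved = "approved" %in% tolower(groups),
      has_metab = any(grepl(metabolismPattern, descr, ignore.case = TRUE)),
      smiles = pick(d,
        "./calculated-properties/property[kind='SMILES']/value"),
      stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(node_id = character(0))
  keep <- tab$approved & tolower(tab$type) %in% "small molecule" &
    tab$has_metab
  tab <- tab[keep, , drop = FALSE]
  noSmiles <- is.na(tab$smiles) | !nzchar(tab$smiles)
  if (any(noSmiles)) {
    warning("excluding ", sum(noSmiles), " drug(s) without SMILES: ",
            paste(utils::head(tab$node_id[noSmiles], 5), collapse = ", "))
    tab <- tab[!noSmiles, , drop = FALSE]
  }
  tab <- tab[!duplicated(tab$node_id), , drop = FALSE]
  if (!nrow(tab))
    return(data.frame(node_id = character(0), kind = character(0),
                      name = character(0), smiles = character(0),
                      food_id = character(0), compound_id = character(0),
                      stringsAsFactors = FALSE))
  out <- data.frame(node_id = tab$node_id, kind = "drug",
                    name = tab$name, smiles = tab$smiles,
                    food_id = NA_character_, compound_id = NA_character_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Parse a FooDB-dialect JSON directory
#'
#' Reads \code{Content.json}, \code{Compound.json} and (optionally)
#' \code{HealthEffect.json} and applies the dataset filters: a content row
#' survives only when its \code{citation_type} is \code{DATABASE}, its
#' \code{source_type} is \code{COMPOUND}, it maps to a compound with a
#' SMILES, it carries a usable original content amount, and (when
#' health-effect filtering is on) its compound is linked to at least one
#' health effect.  Each surviving (food, compound) instance becomes one node
#' under the \code{FOODxxxx_FDBxxxxx_Name} convention.
#'
#' @param jsonDir directory containing the three JSON tables.
#' @param contentRangeMode how a reported content range
#'   (\code{orig_min}/\code{orig_max}) collapses to the scalar used by the
#'   contribution score when no scalar \code{orig_content} is given:
#'   \code{"max"} (default; the conservative interaction-risk choice),
#'   \code{"min"} or \code{"mean"}.
#' @param healthEffectFilter logical; require a health-effect link (default
#'   \code{TRUE}, matching the modelled dataset construction).  Set to
#'   \code{FALSE} when no health-effect table exists.
#' @return list with \code{nodes} (food-compound node data.frame:
#'   \code{node_id}, \code{kind}, \code{name}, \code{smiles},
#'   \code{food_id}, \code{compound_id}) and \code{entries} (composition
#'   data.frame: \code{food_id}, \code{compound_id}, \code{node_id},
#'   \code{orig_content}, \code{contribution} filled by
#'   \code{\link{computeContributions}}).
#' @export
parseFooDB <- function(jsonDir, contentRangeMode = c("max", "min", "mean"),
                       healthEffectFilter = TRUE) {
  contentRangeMode <- match.arg(contentRangeMode)
  need <- c("Content.json", "Compound.json")
  if (healthEffectFilter) need <- c(need, "HealthEffect.json")
  paths <- file.path(jsonDir, need)
  if (any(!file.exists(paths)))
    stop("missing FooDB table(s): ",
         paste(need[!file.exists(paths)], collapse = ", "))
  content <- jsonlite::fromJSON(file.path(jsonDir, "Content.json"),
                                simplifyDataFrame = TRUE)
  compound <- jsonlite::fromJSON(file.path(jsonDir, "Compound.json"),
                                 simplifyDataFrame = TRUE)
  keep <- toupper(content$citation_type %||% "") == "DATABASE" &
    toupper(content$source_type %||% "") == "COMPOUND"
  content <- content[keep, , drop = FALSE]
  ## scalar content: prefer the reported scalar, else collapse the range
  rangeCollapse <- switch(contentRangeMode,
    max = function(lo, hi) hi,
    min = function(lo, hi) lo,
    mean = function(lo, hi) (lo + hi) / 2)
  oc <- content$orig_content %||% rep(NA_real_, nrow(content))
  lo <- content$orig_min %||% rep(NA_real_, nrow(content))
  hi <- content$orig_max %||% rep(NA_real_, nrow(content))
  useRange <- is.na(oc) & !is.na(lo) & !is.na(hi)
  oc[useRange] <- rangeCollapse(lo[useRange], hi[useRange])
  content$scalar_content <- as.numeric(oc)
  dropped <- is.na(content$scalar_content)
  if (any(dropped)) {
    warning("excluding ", sum(dropped),
            " content row(s) without a usable orig_content")
    content <- content[!dropped, , drop = FALSE]
  }
  ## map to compounds: need a SMILES
  m <- match(content$source_id, compound$id)
  content$compound_name <- compound$name[m]
  content$smiles <- compound$moldb_smiles[m]
  content <- content[!is.na(m) & !is.na(content$smiles) &
                       nzchar(content$smiles), , drop = FALSE]
  if (healthEffectFilter) {
    he <- jsonlite::fromJSON(file.path(jsonDir, "HealthEffect.json"),
                             simplifyDataFrame = TRUE)
    withEffect <- unique(he$compound_id)
    content <- content[content$source_id %in% withEffect, , drop = FALSE]
  }
  content <- content[!duplicated(content[c("food_id", "source_id")]), ,
                     drop = FALSE]
  nodeId <- foodCompoundNodeId(content$food_id, content$source_id,
                               content$compound_name)
  nodes <- data.frame(node_id = nodeId, kind = "food_compound",
                      name = content$compound_name,
                      smiles = content$smiles,
                      food_id = content$food_id,
                      compound_id = content$source_id,
                      stringsAsFactors = FALSE)
  entries <- data.frame(food_id = content$food_id,
                        compound_id = content$source_id,
                        node_id = nodeId,
                        orig_content = content$scalar_content,
                        contribution = NA_real_,
                        stringsAsFactors = FALSE)
  ord <- order(nodes$node_id)
  nodes <- nodes[ord, , drop = FALSE]
  entries <- entries[ord, , drop = FALSE]
  rownames(nodes) <- rownames(entries) <- NULL
  list(nodes = nodes, entries = computeContributions(entries))
}

#' Normalized composition contribution scores
#'
#' Within each food, a compound's contribution is its original content
#' divided by the total original content of all included compounds of that
#' food.  Contributions lie in \code{[0, 1]} and sum to 1 per food.  The
#' denominator is the sum over compounds that survived all filters, which is
#' why normalization is applied after filtering.
#'
#' @param entries composition data.frame with columns \code{food_id},
#'   \code{node_id}, \code{orig_content}.
#' @return the same data.frame with \code{contribution} filled.
#' @export
#' @examples
#' computeContributions(data.frame(
#'   food_id = "FOOD00001", compound_id = c("FDB1", "FDB2"),
#'   node_id = c("a", "b"), orig_content = c(30, 10)))
computeContributions <- function(entries) {
  stopifnot(all(c("food_id", "node_id", "orig_content") %in% names(entries)))
  if (!nrow(entries)) {
    entries$contribution <- numeric(0)
    return(entries)
  }
  if (any(entries$orig_content < 0))
    stop("negative orig_content for food(s): ",
         paste(unique(entries$food_id[entries$orig_content < 0]),
               collapse = ", "))
  totals <- tapply(entries$orig_content, entries$food_id, sum)
  bad <- names(totals)[totals <= 0]
  if (length(bad))
    stop("total content is zero for food(s): ",
         paste(bad, collapse = ", "))
  entries$contribution <-
    entries$orig_content / as.numeric(totals[entries$food_id])
  entries
}

#' Pair-level contribution scaling factor
#'
#' The factor by which a similarity score is rescaled when composition is
#' taken into account: drug-drug pairs keep their score (factor 1);
#' drug-food pairs use the food compound's contribution; food-food pairs use
#' the larger of the two contributions.
#'
#' @param nodeA,nodeB node ids (single strings).
#' @param entries composition data.frame with \code{node_id} and
#'   \code{contribution} columns (as returned by
#'   \code{\link{computeContributions}} or \code{\link{parseFooDB}}).
#' @param kinds optional named character vector node_id -> kind; when absent,
#'   a node is treated as a food compound iff it appears in \code{entries}.
#' @return scaling factor in \code{[0, 1]}.
#' @export
#' @examples
#' entries <- data.frame(
#'   food_id = "FOOD00006",
#'   compound_id = c("FDB000474", "FDB000556"),
#'   node_id = c("FOOD00006_FDB000474_L-Lysine",
#'               "FOOD00006_FDB000556_L-Alanine"),
#'   orig_content = c(1, 1),
#'   contribution = c(0.007301117, 0.009780473))
#' pairContribution("FOOD00006_FDB000474_L-Lysine",
#'                  "FOOD00006_FDB000556_L-Alanine", entries)
pairContribution <- function(nodeA, nodeB, entries, kinds = NULL) {
  stopifnot(is.character(nodeA), is.character(nodeB),
            length(nodeA) == 1L, length(nodeB) == 1L)
  lookup <- setNames(entries$contribution, entries$node_id)
  isFood <- function(id) {
    if (!is.null(kinds)) {
      if (!id %in% names(kinds)) stop("unknown node: ", id)
      kinds[[id]] == "food_compound"
    } else id %in% names(lookup)
  }
  contrib <- function(id) {
    c0 <- if (id %in% names(lookup)) lookup[[id]] else NA_real_
    if (is.na(c0))
      stop("food-compound node without a contribution: ", id)
    c0
  }
  fa <- isFood(nodeA)
  fb <- isFood(nodeB)
  if (!fa && !fb) return(1.0)
  if (fa && fb) return(max(contrib(nodeA), contrib(nodeB)))
  if (fa) contrib(nodeA) else contrib(nodeB)
}
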