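#' @importFrom methods new validObject is slot
#' @importFrom stats runif setNames sd
#' @importFrom utils head write.table read.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Canonical key for an unordered node pair
#'
#' Unordered pairs are stored with \code{node_a < node_b} under the default
#' string collation; the key is used for set membership tests (e.g. matching
#' predicted links against held-out links).
#'
#' @param a,b character vectors of node identifiers (recycled together).
#' @return character vector of canonical pair keys.
#' @keywords internal
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

canonicalPair <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  list(a = a, b = b)
}

#' Derive a per-stage random seed from a run seed
#'
#' One user-facing seed fans out to per-stage sub-seeds so that a stage can be
#' re-run in isolation and still reproduce its in-pipeline behaviour.  The rule
#' is a small deterministic hash of the stage name folded into the seed, kept
#' below 2^31 so it is always a valid R integer.
#'
#' @param seed integer run seed.
#' @param stage character stage name.
#' @return a single integer seed.
#' @export
#' @examples
#' stageSeed(1L, "split")
stageSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

# columns every edge table carries, in canonical order
EDGE_COLS <- c("node_a", "node_b", "weight", "subnetwork", "is_bridge")

emptyEdges <- function() {
  data.frame(node_a = character(0), node_b = character(0),
             weight = numeric(0), subnetwork = character(0),
             is_bridge = logical(0), stringsAsFactors = FALSE)
}

emptyPredictions <- function() {
  data.frame(node_a = character(0), node_b = character(0),
             method = character(0), score = numeric(0),
             rank = integer(0), uses_bridge = logical(0),
             stringsAsFactors = FALSE)
}

subnetworkLabel <- function(kind_a, kind_b) {
  ifelse(kind_a == "drug" & kind_b == "drug", "DD",
         ifelse(kind_a == "food_compound" & kind_b == "food_compound",
                "FF", "FD"))
}
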