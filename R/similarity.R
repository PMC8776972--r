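## Structure similarity profile (SSP): Morgan/ECFP4 fingerprints from SMILES
## and pairwise Tanimoto coefficients over drug-drug, food-food and food-drug
## pairs.  Fingerprinting is delegated to RDKit through a single batched
## python subprocess; everything downstream is computed here.

pythonBinary <- function() {
  py <- Sys.getenv("FDINET_PYTHON", unset = Sys.which("python"))
  if (!nzchar(py))
    stop("no 'python' found on PATH; Morgan fingerprinting requires ",
         "Python with RDKit (see SystemRequirements)")
  py
}

fingerprintScript <- function() {
  p <- system.file("python", "fingerprints.py", package = "fdinet")
  if (!nzchar(p)) stop("fingerprints.py not found in installed package")
  p
}

#' Morgan/circular fingerprints from SMILES
#'
#' Computes hashed circular (Morgan) fingerprints; the default radius 2 at
#' 2048 bits is the standard ECFP4 configuration.  The computation is
#' delegated to RDKit in one batched subprocess, so fingerprinting a vector
#' of SMILES costs a single process launch.
#'
#' @param smiles character vector of SMILES strings; names, when present, are
#'   used as fingerprint ids.
#' @param radius circular neighborhood radius (ECFP4 = radius 2).
#' @param nBits fingerprint length in bits.
#' @return a list of class \code{"FingerprintSet"}: for each input, an
#'   integer vector of set-bit indices in \code{[0, nBits)}, with attributes
#'   \code{nBits} and \code{radius}.
#' @details Two SMILES spellings of the same molecule (e.g. \code{"CCO"} and
#'   \code{"OCC"}) yield identical bit sets because the fingerprint is
#'   computed on the parsed molecular graph, not the string.
#' @export
#' @examples
#' \dontrun{
#' fps <- fingerprintSmiles(c(ethanol = "CCO", aspirin = "CC(=O)Oc1ccccc1C(=O)O"))
#' tanimoto(fps[[1]], fps[[2]])
#' }
fingerprintSmiles <- function(smiles, radius = 2L, nBits = 2048L) {
  stopifnot(is.character(smiles), length(smiles) >= 1L,
            radius >= 0, nBits >= 1)
  ids <- names(smiles) %||% paste0("s", seq_along(smiles))
  if (any(!nzchar(smiles)))
    stop("empty SMILES string at position ",
         which(!nzchar(smiles))[1L])
  fin <- tempfile(fileext = ".tsv")
  fout <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste(seq_along(smiles), smiles, sep = "\t"), fin)
  status <- system2(pythonBinary(),
                    c(fingerprintScript(), "--radius", radius,
                      "--nbits", nBits, "--infile", shQuote(fin),
                      "--outfile", shQuote(fout)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")))
    stop("fingerprint subprocess failed: ",
         paste(status, collapse = "\n"))
  rows <- strsplit(readLines(fout), "\t", fixed = TRUE)
  if (length(rows) != length(smiles))
    stop("fingerprint subprocess returned ", length(rows),
         " rows for ", length(smiles), " inputs")
  bad <- vapply(rows, function(r) r[2] == "ERROR", logical(1))
  if (any(bad)) {
    offending <- vapply(rows[bad], function(r)
      if (length(r) >= 3) r[3] else "", character(1))
    stop("unparseable SMILES: ",
         paste(utils::head(offending, 5), collapse = ", "))
  }
  fps <- lapply(rows, function(r) {
    if (length(r) < 3 || !nzchar(r[3])) integer(0)
    else as.integer(strsplit(r[3], ",", fixed = TRUE)[[1]])
  })
  names(fps) <- ids
  structure(fps, nBits = as.integer(nBits), radius = as.integer(radius),
            class = "FingerprintSet")
}

#' @export
print.FingerprintSet <- function(x, ...) {
  cat(sprintf("FingerprintSet: %d fingerprints, %d bits, radius %d\n",
              length(x), attr(x, "nBits"), attr(x, "radius")))
  invisible(x)
}

#' Tanimoto coefficient of two fingerprints
#'
#' \eqn{|A \cap B| / |A \cup B|} over two set-bit index vectors; defined as 0
#' when both are empty.
#'
#' @param fpA,fpB integer vectors of set-bit indices (elements of a
#'   \code{FingerprintSet}, or any integer vectors on the same bit space).
#' @param nBitsA,nBitsB optional bit-space sizes; when both are supplied they
#'   must agree.
#' @return similarity score in \code{[0, 1]}.
#' @export
tanimoto <- function(fpA, fpB, nBitsA = attr(fpA, "nBits"),
                     nBitsB = attr(fpB, "nBits")) {
  if (!is.null(nBitsA) && !is.null(nBitsB) && nBitsA != nBitsB)
    stop("fingerprints live on different bit spaces (",
         nBitsA, " vs ", nBitsB, " bits)")
  u <- length(union(fpA, fpB))
  if (u == 0L) return(0)
  length(intersect(fpA, fpB)) / u
}

#' Build the structure similarity profile (SSP)
#'
#' Computes the Tanimoto coefficient for every unordered pair of nodes (no
#' self-pairs), labelled by subnetwork: DD (drug-drug), FF (food-food), FD
#' (food-drug).  Nodes with the same underlying compound in different foods
#' are deliberately distinct (the naming convention keeps one node per
#' food-compound instance).  Pairs where either fingerprint is empty score 0
#' rather than erroring.
#'
#' @param nodes data.frame with columns \code{node_id}, \code{kind},
#'   \code{smiles}.
#' @param radius,nBits fingerprint parameters (see
#'   \code{\link{fingerprintSmiles}}).
#' @param fingerprints optional precomputed \code{FingerprintSet} named by
#'   \code{node_id} (skips the RDKit call).
#' @return data.frame of similarity edges: \code{node_a}, \code{node_b},
#'   \code{score}, \code{subnetwork}, one row per unordered pair
#'   (\code{n(n-1)/2} rows before any thresholding).
#' @export
buildSSP <- function(nodes, radius = 2L, nBits = 2048L,
                     fingerprints = NULL) {
  stopifnot(all(c("node_id", "kind") %in% names(nodes)))
  n <- nrow(nodes)
  if (n < 2L)
    return(data.frame(node_a = character(0), node_b = character(0),
                      score = numeric(0), subnetwork = character(0),
                      stringsAsFactors = FALSE))
  if (is.null(fingerprints)) {
    stopifnot("smiles" %in% names(nodes))
    fingerprints <- fingerprintSmiles(
      setNames(nodes$smiles, nodes$node_id), radius = radius, nBits = nBits)
  }
  fps <- fingerprints[nodes$node_id]
  if (anyNA(names(fps)) || any(vapply(fps, is.null, logical(1))))
    stop("missing fingerprint for some node_id")
  ## sparse node x bit incidence matrix; |A.B| via one cross-product
  lens <- lengths(fps)
  X <- Matrix::sparseMatrix(
    i = rep.int(seq_len(n), lens),
    j = unlist(fps, use.names = FALSE) + 1L,
    x = 1, dims = c(n, max(c(unlist(fps, use.names = FALSE) + 1L, 1L))))
  inter <- as.matrix(Matrix::tcrossprod(X))
  uni <- outer(lens, lens, "+") - inter
  score <- ifelse(uni > 0, inter / uni, 0)
  idx <- which(upper.tri(score), arr.ind = TRUE)
  ids <- nodes$node_id
  cp <- canonicalPair(ids[idx[, 1L]], ids[idx[, 2L]])
  kind <- setNames(nodes$kind, nodes$node_id)
  out <- data.frame(node_a = cp$a, node_b = cp$b,
                    score = score[idx],
                    subnetwork = subnetworkLabel(kind[cp$a], kind[cp$b]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$node_a, out$node_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
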