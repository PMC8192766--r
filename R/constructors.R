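#' @include AllClasses.R
NULL

#' Construct a ChainRecord
#'
#' @param chainId single-character chain identifier.
#' @param sequence one-letter amino-acid string.
#' @param atoms data.frame with columns `resno`, `elety`, `elesy`,
#'   `x`, `y`, `z`; residue numbers must cover `1..nchar(sequence)`.
#' @return a validated [ChainRecord-class].
#' @export
chainRecord <- function(chainId, sequence, atoms) {
  atoms$resno <- as.integer(atoms$resno)
  new("ChainRecord", chainId = as.character(chainId),
      sequence = as.character(sequence),
      atoms = as.data.frame(atoms, stringsAsFactors = FALSE))
}

#' Construct a ContactMap
#'
#' Intrachain pairs are canonicalized to `i < j` and deduplicated; interchain
#' pairs are kept asymmetric as given (deduplicated only on exact rows).
#'
#' @param kind `"intra"` or `"inter"`.
#' @param L chain length.
#' @param pairs two-column matrix or data.frame of (i, j) pairs; may be empty.
#' @return a validated [ContactMap-class].
#' @export
contactMap <- function(kind, L, pairs) {
  p <- if (is.null(pairs)) matrix(integer(), 0, 2) else as.matrix(pairs)
  if (length(p) == 0) p <- matrix(integer(), 0, 2)
  storage.mode(p) <- "integer"
  dimnames(p) <- NULL
  if (nrow(p) > 0) {
    if (kind == "intra") {
      swap <- p[, 1] > p[, 2]
      p[swap, ] <- p[swap, 2:1]
      p <- p[p[, 1] != p[, 2], , drop = FALSE]
    }
    p <- unique(p)
    p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  }
  new("ContactMap", kind = kind, L = as.integer(L), pairs = p)
}

#' Construct a PredictionSet
#'
#' @param L monomer length.
#' @param i,j integer vectors of residue indices with `i < j`.
#' @param score numeric vector of confidences in `[0, 1]`.
#' @return a validated [PredictionSet-class], sorted by (i, j).
#' @export
predictionSet <- function(L, i = integer(), j = integer(), score = numeric()) {
  it <- data.frame(i = as.integer(i), j = as.integer(j),
                   score = as.numeric(score))
  it <- it[order(it$i, it$j), , drop = FALSE]
  rownames(it) <- NULL
  new("PredictionSet", L = as.integer(L), items = it)
}

#' Construct a RigidTransform
#'
#' @param rotation 3x3 proper rotation matrix (default: identity).
#' @param translation length-3 translation vector in Angstrom (default: zero).
#' @return a validated [RigidTransform-class].
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' @rdname ContactThresholds-class
#' @param intraCb,interHeavy,minSeqSep see the class slots.
#' @return a validated [ContactThresholds-class].
#' @export
contactThresholds <- function(intraCb = 8.0, interHeavy = 6.0, minSeqSep = 6L) {
  new("ContactThresholds", intraCb = intraCb, interHeavy = interHeavy,
      minSeqSep = as.integer(minSeqSep))
}

#' @rdname PrepConfig-class
#' @param minChainSimilarity,dedupIdentity,interchainThreshold see the class
#'   slots.
#' @return a validated [PrepConfig-class].
#' @export
prepConfig <- function(minChainSimilarity = 0.95, dedupIdentity = 0.30,
                       interchainThreshold = 6.0) {
  new("PrepConfig", minChainSimilarity = minChainSimilarity,
      dedupIdentity = dedupIdentity,
      interchainThreshold = interchainThreshold)
}

#' @rdname AnnealConfig-class
#' @param tInitial,tFinal,cooling,stepsPerTemp,rotScale,transScale,clashDist,clashWeight,restarts
#'   see the class slots.
#' @return a validated [AnnealConfig-class].
#' @export
annealConfig <- function(tInitial = 10, tFinal = 0.02, cooling = 0.85,
                         stepsPerTemp = 60L, rotScale = 0.6, transScale = 4.0,
                         clashDist = 2.5, clashWeight = 1.0, restarts = 5L) {
  new("AnnealConfig", tInitial = tInitial, tFinal = tFinal, cooling = cooling,
      stepsPerTemp = as.integer(stepsPerTemp), rotScale = rotScale,
      transScale = transScale, clashDist = clashDist,
      clashWeight = clashWeight, restarts = as.integer(restarts))
}
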