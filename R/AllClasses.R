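#' @import methods
NULL

## Central containers. All residue indices are 1-based and contiguous
## (1..L) after preparation; classes enforce this in their validity methods.

#' ChainRecord: one cleaned protein chain
#'
#' Holds a single protein chain after splitting and reindexing: its one-letter
#' sequence and a per-atom coordinate table. Residue numbers are always the
#' contiguous range `1..L`.
#'
#' @slot chainId single chain identifier (e.g. `"A"`).
#' @slot sequence one-letter amino-acid string of length L; non-standard
#'   residues appear as `"X"`.
#' @slot atoms data.frame with columns `resno` (integer, in `1..L`),
#'   `elety` (atom name, e.g. `"CA"`), `elesy` (element symbol), and
#'   `x`, `y`, `z` coordinates in Angstrom. Hydrogens are excluded on read.
#'
#' @seealso [splitAndReindex()], [makeMonomer()]
#' @export
setClass("ChainRecord",
  representation(chainId = "character", sequence = "character",
                 atoms = "data.frame"))

setValidity("ChainRecord", function(object) {
  msg <- character()
  L <- nchar(object@sequence)
  a <- object@atoms
  need <- c("resno", "elety", "elesy", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms must have columns:", paste(need, collapse = ", ")))
  if (length(object@chainId) != 1L || !nzchar(object@chainId))
    msg <- c(msg, "chainId must be a single non-empty string")
  if (L < 1L) msg <- c(msg, "empty chain: sequence has zero residues")
  if (nrow(a) > 0) {
    if (!all(is.finite(as.matrix(a[, c("x", "y", "z")]))))
      msg <- c(msg, "non-finite atom coordinates")
    if (!setequal(unique(a$resno), seq_len(L)))
      msg <- c(msg, sprintf(
        "residue numbers must be exactly 1..%d with every residue present", L))
  } else msg <- c(msg, "chain has no atoms")
  if (length(msg)) msg else TRUE
})

#' ContactMap: binary residue-pair contact set
#'
#' A set of contacting residue pairs over a chain of length L. Intrachain
#' maps are stored canonically with `i < j`; interchain maps are asymmetric
#' and store `(i, j)` ("residue i of the first chain contacts residue j of
#' the partner") independently of `(j, i)`.
#'
#' @slot kind `"intra"` or `"inter"`.
#' @slot L chain length the indices refer to.
#' @slot pairs two-column integer matrix of (i, j) pairs, one row per contact.
#'
#' @seealso [intrachainMap()], [interchainMap()], [contactDensity()]
#' @export
setClass("ContactMap",
  representation(kind = "character", L = "integer", pairs = "matrix"))

setValidity("ContactMap", function(object) {
  msg <- character()
  if (!object@kind %in% c("intra", "inter"))
    msg <- c(msg, "kind must be 'intra' or 'inter'")
  if (length(object@L) != 1L || object@L < 1L)
    msg <- c(msg, "L must be a positive integer")
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must be a two-column matrix")
  if (nrow(p) > 0) {
    if (any(p < 1L) || any(p > object@L))
      msg <- c(msg, "pair indices out of range 1..L")
    if (object@kind == "intra") {
      if (any(p[, 1] >= p[, 2]))
        msg <- c(msg, "intra pairs must satisfy i < j (and no (i,i))")
    }
    if (anyDuplicated(paste(p[, 1], p[, 2])))
      msg <- c(msg, "duplicate contact pairs")
  }
  if (length(msg)) msg else TRUE
})

#' PredictionSet: scored residue-pair predictions for one monomer
#'
#' The upper triangle of a predicted monomeric contact matrix: unique pairs
#' `i < j` with a confidence score in `[0, 1]`, rankable by score.
#'
#' @slot L monomer length.
#' @slot items data.frame with integer columns `i`, `j` (`1 <= i < j <= L`)
#'   and numeric `score` in `[0, 1]`.
#'
#' @seealso [readRR()], [filterShortRange()], [relaxRemove()], [rankTopK()]
#' @export
setClass("PredictionSet",
  representation(L = "integer", items = "data.frame"))

setValidity("PredictionSet", function(object) {
  msg <- character()
  it <- object@items
  if (!all(c("i", "j", "score") %in% names(it)))
    return("items must have columns i, j, score")
  if (object@L < 1L) msg <- c(msg, "L must be positive")
  if (nrow(it) > 0) {
    if (any(it$i < 1L) || any(it$j > object@L) || any(it$i >= it$j))
      msg <- c(msg, "items must satisfy 1 <= i < j <= L")
    if (any(it$score < 0) || any(it$score > 1))
      msg <- c(msg, "scores must lie in [0, 1]")
    if (anyDuplicated(paste(it$i, it$j)))
      msg <- c(msg, "duplicate (i, j) prediction")
  }
  if (length(msg)) msg else TRUE
})

#' RigidTransform: rotation + translation in 3D
#'
#' A proper rigid motion `x -> R x + t` used to place the second copy of a
#' monomer relative to the first.
#'
#' @slot rotation 3x3 orthonormal matrix with determinant +1.
#' @slot translation length-3 numeric vector (Angstrom).
#'
#' @seealso [rigidTransform()], [applyTransform()], [annealDimer()]
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric"))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3x3")
  if (length(object@translation) != 3L) return("translation must have length 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-8) return("rotation not orthonormal")
  if (abs(det(R) - 1) > 1e-8) return("rotation must have determinant +1")
  TRUE
})

#' Contact-definition thresholds
#'
#' Distance cutoffs and the short-range sequence-separation filter used
#' throughout the pipeline. Intrachain contacts use the Cbeta-Cbeta distance
#' (Calpha when Cbeta is absent, e.g. glycine) at 8.0 A; interchain contacts
#' use the minimum heavy-atom distance at 6.0 A; predictions at sequence
#' separation below 6 are discarded as short-range. All boundaries are
#' inclusive.
#'
#' @slot intraCb intrachain Cbeta cutoff in Angstrom (default 8.0).
#' @slot interHeavy interchain heavy-atom cutoff in Angstrom (default 6.0).
#' @slot minSeqSep minimum sequence separation kept by the short-range
#'   filter (default 6).
#' @export
setClass("ContactThresholds",
  representation(intraCb = "numeric", interHeavy = "numeric",
                 minSeqSep = "integer"),
  prototype(intraCb = 8.0, interHeavy = 6.0, minSeqSep = 6L))

setValidity("ContactThresholds", function(object) {
  if (object@intraCb <= 0 || object@interHeavy <= 0 || object@minSeqSep <= 0)
    "all thresholds must be positive" else TRUE
})

#' Preparation configuration
#'
#' Settings for the cleaning cascade: the minimum chain similarity for a
#' homomultimer to be kept (chain pairs below it are rejected), the identity
#' ceiling for greedy redundancy removal, and the interchain heavy-atom
#' distance defining "has an interface at all".
#'
#' @slot minChainSimilarity fraction in (0, 1], default 0.95.
#' @slot dedupIdentity fraction in (0, 1], default 0.30.
#' @slot interchainThreshold Angstrom, default 6.0.
#' @export
setClass("PrepConfig",
  representation(minChainSimilarity = "numeric", dedupIdentity = "numeric",
                 interchainThreshold = "numeric"),
  prototype(minChainSimilarity = 0.95, dedupIdentity = 0.30,
            interchainThreshold = 6.0))

setValidity("PrepConfig", function(object) {
  ok <- function(x) length(x) == 1 && x > 0 && x <= 1
  if (!ok(object@minChainSimilarity) || !ok(object@dedupIdentity))
    return("similarity fractions must lie in (0, 1]")
  if (object@interchainThreshold <= 0) return("threshold must be positive")
  TRUE
})

#' Simulated-annealing configuration for rigid-body reconstruction
#'
#' Controls the Metropolis annealing search over the 6 rigid degrees of
#' freedom of the second monomer copy. Move sizes shrink with temperature;
#' the schedule is geometric.
#'
#' @slot tInitial initial temperature (energy units).
#' @slot tFinal final temperature.
#' @slot cooling geometric cooling factor in (0, 1).
#' @slot stepsPerTemp Metropolis proposals per temperature level.
#' @slot rotScale rotation move scale in radians (at the initial temperature).
#' @slot transScale translation move scale in Angstrom (at the initial
#'   temperature).
#' @slot clashDist heavy-atom clash distance in Angstrom (default 2.5).
#' @slot clashWeight weight of the clash penalty relative to restraint
#'   violations.
#' @slot restarts number of independent randomized starts.
#' @export
setClass("AnnealConfig",
  representation(tInitial = "numeric", tFinal = "numeric", cooling = "numeric",
                 stepsPerTemp = "integer", rotScale = "numeric",
                 transScale = "numeric", clashDist = "numeric",
                 clashWeight = "numeric", restarts = "integer"),
  prototype(tInitial = 10, tFinal = 0.02, cooling = 0.85, stepsPerTemp = 60L,
            rotScale = 0.6, transScale = 4.0, clashDist = 2.5,
            clashWeight = 1.0, restarts = 5L))

setValidity("AnnealConfig", function(object) {
  msg <- character()
  if (object@tInitial <= 0 || object@tFinal <= 0)
    msg <- c(msg, "temperatures must be positive")
  if (object@cooling <= 0 || object@cooling >= 1)
    msg <- c(msg, "cooling must lie in (0, 1)")
  if (object@stepsPerTemp < 1L || object@restarts < 1L)
    msg <- c(msg, "stepsPerTemp and restarts must be >= 1")
  if (length(msg)) msg else TRUE
})
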