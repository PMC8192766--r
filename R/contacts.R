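#' @include AllClasses.R geometry.R
NULL

#' True intrachain contact map of a monomer
#'
#' Two residues i and j (i < j) of one chain are in intrachain contact when
#' the Euclidean distance between their Cbeta atoms (Calpha when the Cbeta is
#' unavailable, notably glycine) is less than or equal to the `intraCb`
#' cutoff, 8.0 A by default. The boundary is inclusive. No sequence-separation
#' filter is applied here: short-range filtering belongs to the prediction
#' side (see [filterShortRange()]).
#'
#' @param chain a [ChainRecord-class] with coordinates.
#' @param th a [ContactThresholds-class].
#' @return an intrachain [ContactMap-class]. Residues lacking both Cbeta and
#'   Calpha are excluded from all pairs with a warning.
#' @export
intrachainMap <- function(chain, th = contactThresholds()) {
  xyz <- cbCoords(chain)
  L <- chainLength(chain)
  bad <- which(!is.finite(xyz[, 1]))
  if (length(bad))
    warning(sprintf("%d residue(s) lack both CB and CA; excluded: %s",
                    length(bad), paste(bad, collapse = ",")))
  ok <- setdiff(seq_len(L), bad)
  d2 <- .crossDist2(xyz[ok, , drop = FALSE], xyz[ok, , drop = FALSE])
  hit <- which(d2 <= th@intraCb^2, arr.ind = TRUE)
  hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
  contactMap("intra", L, cbind(ok[hit[, 1]], ok[hit[, 2]]))
}

#' True interchain contact map between two chains
#'
#' Residue i of chain `a` and residue j of chain `b` are in interchain
#' contact when the minimum distance over all heavy-atom pairs of the two
#' residues is less than or equal to the `interHeavy` cutoff, 6.0 A by
#' default (inclusive). The map is stored asymmetrically: `(i, j)` means
#' "residue i of `a` against residue j of `b`", and `(j, i)` is an
#' independent entry — homodimer interfaces are often symmetric but need not
#' be, so the full matrix is kept.
#'
#' @param a,b homogenized [ChainRecord-class] objects of equal length.
#' @param th a [ContactThresholds-class].
#' @return an interchain [ContactMap-class] over `L = chainLength(a)`.
#' @export
interchainMap <- function(a, b, th = contactThresholds()) {
  stopifnot(chainLength(a) == chainLength(b))
  ha <- .heavyAtoms(a); hb <- .heavyAtoms(b)
  L <- chainLength(a)
  dmin <- .minResidueDist(ha, hb, L, L)
  hit <- which(dmin <= th@interHeavy, arr.ind = TRUE)
  contactMap("inter", L, hit)
}

#' Select the partner chain with the most interchain contacts
#'
#' For a multimer with chains A, B, C, ... the pipeline analyses one chain
#' pair: the first chain against each other chain in turn (AB, AC, AD, ...),
#' keeping the pair with the highest interchain contact count. Ties go to
#' the earliest chain in input order.
#'
#' @param chains list of homogenized [ChainRecord-class] objects (>= 2).
#' @param th a [ContactThresholds-class].
#' @return a list with `partnerId`, `contactCount`, `allCounts` (named
#'   integer vector over candidate partners) and `interMap` (the winning
#'   interchain [ContactMap-class]).
#' @export
selectMaxPair <- function(chains, th = contactThresholds()) {
  if (length(chains) < 2L)
    stop("need at least two chains to select an interchain pair")
  first <- chains[[1]]
  others <- chains[-1]
  maps <- lapply(others, function(ch) interchainMap(first, ch, th))
  counts <- vapply(maps, nContacts, integer(1))
  names(counts) <- vapply(others, chainId, character(1))
  best <- which.max(counts)  # first maximum wins ties
  list(partnerId = names(counts)[best],
       contactCount = as.integer(counts[best]),
       allCounts = counts,
       interMap = maps[[best]])
}

#' Interchain contact density
#'
#' Number of true interchain contacts per residue of monomer length,
#' `|contacts| / L`. High-density interfaces are the regime where interchain
#' prediction from monomeric maps works best.
#'
#' @param inter an interchain [ContactMap-class].
#' @return a single number >= 0.
#' @export
contactDensity <- function(inter) {
  nContacts(inter) / mapLength(inter)
}
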