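#' @include AllClasses.R geometry.R io.R
NULL

## ---- pairwise global alignment ------------------------------------------
## Scheme: match = 1, mismatch = 0, linear gap = -1. 'X' (non-standard
## residue) scores 0 against everything, itself included, so it always counts
## as a mismatch. Identity = matching columns / total alignment columns.

.alnSubMatrix <- function(letters) {
  letters <- sort(unique(c(letters, strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1]])))
  m <- matrix(0, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- 1
  m["X", "X"] <- 0
  m
}

.alignPair <- function(sa, sb) {
  sub <- .alnSubMatrix(c(strsplit(sa, "")[[1]], strsplit(sb, "")[[1]]))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(sa), Biostrings::AAString(sb),
    type = "global", substitutionMatrix = sub,
    gapOpening = 0, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  match <- pa == pb & pa != "-" & pa != "X"
  list(pa = pa, pb = pb, match = match,
       identity = sum(match) / length(pa))
}

#' Global pairwise sequence identity
#'
#' Identity under a simple reproducible global alignment (match 1,
#' mismatch 0, linear gap -1): matching columns divided by total alignment
#' columns (gaps included in the denominator). Non-standard residues (`X`)
#' always count as mismatches.
#'
#' @param a,b one-letter amino-acid strings.
#' @return identity fraction in `[0, 1]`.
#' @export
sequenceIdentity <- function(a, b) .alignPair(a, b)$identity

## ---- Fig.-style cleaning cascade ----------------------------------------

#' Split a raw complex into reindexed per-chain records
#'
#' Separates a parsed multi-chain structure into one [ChainRecord-class] per
#' chain, keeping ATOM content only, and renumbers the residues of each chain
#' to the contiguous range `1..L` in file order (author numbering gaps and
#' insertion codes collapse away). Non-standard residues are kept with
#' sequence letter `X`.
#'
#' @param raw a `RawComplex` from [readComplexPDB()], or any list with the
#'   same `atoms` layout.
#' @return named list of [ChainRecord-class] objects in order of first
#'   appearance.
#' @export
splitAndReindex <- function(raw) {
  a <- raw$atoms
  chainIds <- unique(a$chain)
  out <- lapply(chainIds, function(cid) {
    ca <- a[a$chain == cid, , drop = FALSE]
    if (nrow(ca) == 0L) stop("empty chain: ", cid)
    key <- paste(ca$resno, ca$insert, sep = "|")
    newResno <- match(key, unique(key))
    firsts <- !duplicated(key)
    seqLetters <- bio3d::aa321(ca$resid[firsts])
    seqLetters[is.na(seqLetters) | !seqLetters %in%
                 strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
    chainRecord(cid, paste(seqLetters, collapse = ""),
                data.frame(resno = newResno, elety = ca$elety, elesy = ca$elesy,
                           x = ca$x, y = ca$y, z = ca$z,
                           stringsAsFactors = FALSE))
  })
  names(out) <- chainIds
  out
}

## subset a chain to a set of (old) residue indices, reindexing to 1..L'
.subsetResidues <- function(chain, keep) {
  a <- atomTable(chain)
  a <- a[a$resno %in% keep, , drop = FALSE]
  a$resno <- match(a$resno, keep)
  letters1 <- strsplit(chainSeq(chain), "")[[1]]
  chainRecord(chainId(chain), paste(letters1[keep], collapse = ""), a)
}

#' Homogenize a chain pair for homomultimer analysis
#'
#' Aligns the two sequences globally; if their identity (matching columns
#' over alignment columns) is below `minChainSimilarity` — 95% by default —
#' the pair is rejected. Otherwise every mismatched or gapped alignment
#' column is deleted from BOTH chains and both are reindexed `1..L'`, so the
#' returned chains carry identical sequences.
#'
#' @param a,b [ChainRecord-class] objects.
#' @param cfg a [PrepConfig-class].
#' @return list with `accepted` (logical), `identity` (fraction), and when
#'   accepted `chains` (list of the two homogenized records, same order as
#'   the arguments).
#' @export
homogenizePair <- function(a, b, cfg = prepConfig()) {
  aln <- .alignPair(chainSeq(a), chainSeq(b))
  if (aln$identity < cfg@minChainSimilarity)
    return(list(accepted = FALSE, identity = aln$identity,
                reason = sprintf("chain similarity %.3f below %.2f",
                                 aln$identity, cfg@minChainSimilarity)))
  posA <- cumsum(aln$pa != "-")
  posB <- cumsum(aln$pb != "-")
  keepA <- posA[aln$match]
  keepB <- posB[aln$match]
  if (length(keepA) == 0L)
    return(list(accepted = FALSE, identity = aln$identity,
                reason = "no residues left after removing mismatches"))
  list(accepted = TRUE, identity = aln$identity,
       chains = list(.subsetResidues(a, keepA), .subsetResidues(b, keepB)))
}

#' Does the complex have any interchain contact at all?
#'
#' `TRUE` when some heavy-atom pair between the first chain and any other
#' chain is within `interchainThreshold` (6.0 A, inclusive). Complexes
#' failing this have no interface to predict and are discarded upstream.
#'
#' @param chains list of [ChainRecord-class] objects (>= 2).
#' @param cfg a [PrepConfig-class].
#' @return logical scalar.
#' @export
requireInterchainContact <- function(chains, cfg = prepConfig()) {
  stopifnot(length(chains) >= 2L)
  ha <- .heavyAtoms(chains[[1]])
  for (other in chains[-1]) {
    hb <- .heavyAtoms(other)
    if (min(.crossDist2(ha$xyz, hb$xyz)) <= cfg@interchainThreshold^2)
      return(TRUE)
  }
  FALSE
}

#' Greedy sequence-redundancy removal
#'
#' Scans records in input order and drops any whose pairwise identity to an
#' already-kept record exceeds `dedupIdentity` (30% by default) — an internal
#' greedy stand-in for dataset-scale sequence clustering.
#'
#' @param records list of [ChainRecord-class] objects.
#' @param cfg a [PrepConfig-class].
#' @return the kept subset, in input order.
#' @export
greedyDedup <- function(records, cfg = prepConfig()) {
  kept <- list()
  for (rec in records) {
    dup <- any(vapply(kept, function(k)
      sequenceIdentity(chainSeq(rec), chainSeq(k)) > cfg@dedupIdentity,
      logical(1)))
    if (!dup) kept[[length(kept) + 1L]] <- rec
  }
  kept
}

#' Full preparation cascade for one complex
#'
#' Convenience wrapper: split and reindex, homogenize every other chain
#' against the first (rejecting the complex if any pair falls below the
#' similarity floor), restrict all chains to the common homogenized residue
#' set, and check that an interface exists.
#'
#' @param raw a `RawComplex` from [readComplexPDB()].
#' @param cfg a [PrepConfig-class].
#' @return list with `accepted`, `reason` (when rejected) and `chains`.
#' @export
prepareComplex <- function(raw, cfg = prepConfig()) {
  chains <- splitAndReindex(raw)
  if (length(chains) >= 2L) {
    first <- chains[[1]]
    for (k in seq_along(chains)[-1]) {
      h <- homogenizePair(first, chains[[k]], cfg)
      if (!h$accepted)
        return(list(accepted = FALSE, reason = h$reason))
      first <- h$chains[[1]]
      chains[[k]] <- h$chains[[2]]
    }
    ## re-homogenize so every chain matches the final common core of chain 1
    for (k in seq_along(chains)[-1]) {
      h <- homogenizePair(first, chains[[k]], cfg)
      if (!h$accepted) return(list(accepted = FALSE, reason = h$reason))
      chains[[k]] <- h$chains[[2]]
    }
    chains[[1]] <- first
    if (!requireInterchainContact(chains, cfg))
      return(list(accepted = FALSE, reason = "no interchain contact"))
  }
  list(accepted = TRUE, chains = chains)
}
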