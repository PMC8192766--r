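#' @include AllClasses.R evaluate.R
NULL

#' Eligible prediction pairs
#'
#' The support on which both the method and the random baseline operate: all
#' upper-triangle pairs `i < j`, optionally restricted to sequence separation
#' `j - i >= minSeqSep` (the short-range filter applied to real predictions).
#'
#' @param L monomer length.
#' @param minSeqSep minimum separation (default 6).
#' @param respectShortRangeFilter apply the separation restriction
#'   (default `TRUE`).
#' @return two-column integer matrix of (i, j) pairs.
#' @export
eligiblePairs <- function(L, minSeqSep = 6L, respectShortRangeFilter = TRUE) {
  idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  if (respectShortRangeFilter)
    idx <- idx[idx[, 2] - idx[, 1] >= minSeqSep, , drop = FALSE]
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  dimnames(idx) <- NULL
  storage.mode(idx) <- "integer"
  idx
}

#' Random prediction baseline
#'
#' Draws `nPairs` residue pairs uniformly without replacement from the
#' eligible support and assigns uniform random scores, inducing a random
#' ranking. Fully reproducible from the seed; the caller's RNG state is left
#' untouched.
#'
#' @param L monomer length.
#' @param nPairs number of pairs to draw.
#' @param seed integer RNG seed.
#' @param minSeqSep,respectShortRangeFilter see [eligiblePairs()].
#' @return a [PredictionSet-class].
#' @export
randomPrediction <- function(L, nPairs, seed, minSeqSep = 6L,
                             respectShortRangeFilter = TRUE) {
  elig <- eligiblePairs(L, minSeqSep, respectShortRangeFilter)
  if (nPairs > nrow(elig))
    stop(sprintf("requested %d pairs but only %d eligible at L = %d",
                 nPairs, nrow(elig), L))
  .withSeed(seed, {
    take <- sample.int(nrow(elig), nPairs)
    sc <- stats::runif(nPairs)
    predictionSet(L, elig[take, 1], elig[take, 2], sc)
  })
}

#' Expected single-draw precision of the random baseline
#'
#' The probability that a uniformly drawn eligible pair is a relaxed hit
#' against the truth map: (number of eligible pairs matching at relaxation
#' `n`) / (number of eligible pairs). By exchangeability this is also the
#' expected precision of a random Top-k list for any k.
#'
#' @param truth interchain [ContactMap-class].
#' @param n relaxation half-width.
#' @param minSeqSep,respectShortRangeFilter see [eligiblePairs()].
#' @return a number in `[0, 1]`.
#' @export
expectedRandomPrecision <- function(truth, n = 0L, minSeqSep = 6L,
                                    respectShortRangeFilter = TRUE) {
  elig <- eligiblePairs(mapLength(truth), minSeqSep, respectShortRangeFilter)
  if (nrow(elig) == 0L) stop("no eligible pairs")
  M <- as.matrix(truth)
  mean(.relaxedMatchDense(elig[, 1], elig[, 2], M, as.integer(n)))
}
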