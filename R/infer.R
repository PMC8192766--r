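#' @include AllClasses.R
NULL

#' Remove short-range predictions
#'
#' Discards predicted pairs whose sequence separation `j - i` is below the
#' minimum (default 6): short-range contacts are dominated by local backbone
#' geometry and carry no interface signal.
#'
#' @param pred a [PredictionSet-class].
#' @param th a [ContactThresholds-class] (uses `minSeqSep`).
#' @return the filtered [PredictionSet-class].
#' @export
filterShortRange <- function(pred, th = contactThresholds()) {
  it <- predItems(pred)
  keep <- (it$j - it$i) >= th@minSeqSep
  predictionSet(predLength(pred), it$i[keep], it$j[keep], it$score[keep])
}

#' Relax removal: subtract true intrachain contacts from a predicted map
#'
#' The core of deriving interchain predictions from a monomeric contact map:
#' every predicted pair that can be explained by a true intrachain contact is
#' deleted, and what survives is assumed to be interchain signal. For each
#' true intrachain contact (i, j) — and its mirror (j, i), so the upper
#' triangle is never spared by orientation — all predicted pairs (p, q) with
#' `p` in `[i - n, i + n]` and `q` in `[j - n, j + n]` are removed (window
#' clipped to `[1, L]`). With `n = 0` only exact matches are removed; `n`
#' ranges over 0..2 ("within two residue shifts").
#'
#' @param pred a [PredictionSet-class].
#' @param trueIntra the intrachain [ContactMap-class] of the monomer.
#' @param n relax-removal window half-width, integer in 0..2.
#' @return the surviving [PredictionSet-class].
#' @export
relaxRemove <- function(pred, trueIntra, n = 0L) {
  stopifnot(contactKind(trueIntra) == "intra",
            predLength(pred) == mapLength(trueIntra))
  n <- as.integer(n)
  if (n < 0L) stop("relax-removal window half-width must be >= 0")
  L <- predLength(pred)
  it <- predItems(pred)
  if (nrow(it) == 0L || nContacts(trueIntra) == 0L)
    return(pred)
  removed <- matrix(FALSE, L, L)
  p <- contactPairs(trueIntra)
  centers <- rbind(p, p[, 2:1, drop = FALSE])  # mirror windows too
  for (r in seq_len(nrow(centers))) {
    xs <- max(1L, centers[r, 1] - n):min(L, centers[r, 1] + n)
    ys <- max(1L, centers[r, 2] - n):min(L, centers[r, 2] + n)
    removed[xs, ys] <- TRUE
  }
  keep <- !removed[cbind(it$i, it$j)]
  predictionSet(L, it$i[keep], it$j[keep], it$score[keep])
}

#' The standard Top-k evaluation grid
#'
#' @return character vector of the seven k labels used throughout:
#'   Top-5, Top-10, Top-L/10, Top-L/5, Top-L/2, Top-L, Top-2L.
#' @export
topKLabels <- function() {
  c("Top-5", "Top-10", "Top-L/10", "Top-L/5", "Top-L/2", "Top-L", "Top-2L")
}

#' Resolve a Top-k label to an integer k
#'
#' Fractional cutoffs use the floor; the result is clamped to at least 1
#' (with a warning) so tiny chains still yield a defined evaluation.
#'
#' @param label one of [topKLabels()].
#' @param L monomer length.
#' @return integer `k >= 1`.
#' @export
resolveTopK <- function(label, L) {
  k <- switch(label,
    "Top-5"    = 5,
    "Top-10"   = 10,
    "Top-L/10" = floor(L / 10),
    "Top-L/5"  = floor(L / 5),
    "Top-L/2"  = floor(L / 2),
    "Top-L"    = L,
    "Top-2L"   = 2 * L,
    stop("unknown Top-k label: ", label))
  k <- as.integer(k)
  if (k < 1L) {
    warning(sprintf("resolved k < 1 for %s at L = %d; clamped to 1", label, L))
    k <- 1L
  }
  k
}

#' Rank predictions and take the top k
#'
#' Sorts by score descending, breaking ties by (i, j) ascending so the
#' ranking is fully deterministic, and returns the first `k` rows. When fewer
#' than `k` predictions remain the shortfall is attached as an attribute
#' (missing slots later count as misses in fixed-k precision).
#'
#' @param pred a [PredictionSet-class].
#' @param k integer number of predictions to keep.
#' @return data.frame with columns `i`, `j`, `score` (at most `k` rows) and
#'   attribute `shortfall` = `max(0, k - rows)`.
#' @export
rankTopK <- function(pred, k) {
  k <- as.integer(k)
  if (k < 1L) {
    warning("k < 1; clamped to 1")
    k <- 1L
  }
  it <- predItems(pred)
  ord <- order(-it$score, it$i, it$j)
  out <- it[ord, , drop = FALSE][seq_len(min(k, nrow(it))), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "shortfall") <- max(0L, k - nrow(out))
  out
}

#' Monomer prediction to ranked interchain candidates
#'
#' Convenience wrapper chaining the two inference steps in pipeline order:
#' short-range filtering first, then relax removal against the true
#' intrachain map.
#'
#' @inheritParams relaxRemove
#' @param th a [ContactThresholds-class] for the short-range filter.
#' @return the surviving [PredictionSet-class] of putative interchain pairs.
#' @export
inferInterchain <- function(pred, trueIntra, n = 0L, th = contactThresholds()) {
  relaxRemove(filterShortRange(pred, th), trueIntra, n)
}
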