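#' @include AllClasses.R infer.R
NULL

#' Relaxed match of one prediction against the true interchain map
#'
#' A predicted interchain pair (i, j) counts as correct at relaxation `n`
#' when any true interchain contact lies inside the window
#' `[i - n, i + n] x [j - n, j + n]`, or inside the mirror window centered at
#' (j, i) — the truth map is asymmetric and a monomeric prediction carries no
#' chain orientation, so both (x, y) and (y, x) are looked up. Windows are
#' clipped to `[1, L]`.
#'
#' @param i,j predicted residue pair (scalars or equal-length vectors).
#' @param truth an interchain [ContactMap-class].
#' @param n relaxation half-width, integer in 0..2.
#' @return logical vector, `TRUE` where the prediction is a relaxed hit.
#' @export
relaxedMatch <- function(i, j, truth, n = 0L) {
  stopifnot(contactKind(truth) == "inter")
  M <- as.matrix(truth)
  .relaxedMatchDense(i, j, M, as.integer(n))
}

## dense-matrix workhorse so grid evaluation builds the truth matrix once
.relaxedMatchDense <- function(i, j, M, n) {
  L <- nrow(M)
  vapply(seq_along(i), function(r) {
    xs <- max(1L, i[r] - n):min(L, i[r] + n)
    ys <- max(1L, j[r] - n):min(L, j[r] + n)
    any(M[xs, ys]) || any(M[ys, xs])
  }, logical(1))
}

#' Top-k precision grid under relaxation
#'
#' Evaluates a ranked prediction list against the true interchain map over
#' the full Top-k grid and the requested relaxation values. Precision is
#' fixed-k: (number of relaxed hits among the top k) / k, so when fewer than
#' k predictions survive, the missing slots count as misses. A single true
#' contact may validate several predictions (truth entries are not consumed).
#'
#' @param ranked data.frame with columns `i`, `j` sorted best-first (e.g.
#'   from [rankTopK()] with large k, or a full sorted list).
#' @param truth interchain [ContactMap-class].
#' @param L monomer length used to resolve the fractional k labels.
#' @param nRemoval the relax-removal setting that produced `ranked`
#'   (annotation only, copied into the report).
#' @param nRelax integer vector of relaxation values to evaluate (default 0:2).
#' @param kLabels subset of [topKLabels()] to evaluate.
#' @return data.frame with columns `n_r`, `n_e`, `k_label`, `k`, `tp`,
#'   `precision`, `density` — one row per (relaxation, k label).
#' @export
precisionGrid <- function(ranked, truth, L, nRemoval = NA_integer_,
                          nRelax = 0:2, kLabels = topKLabels()) {
  stopifnot(contactKind(truth) == "inter")
  if (nrow(ranked) == 0L)
    warning("empty prediction list; all precisions are 0")
  M <- as.matrix(truth)
  dens <- contactDensity(truth)
  ks <- vapply(kLabels, resolveTopK, integer(1), L = L)
  kmax <- min(max(ks), nrow(ranked))
  out <- do.call(rbind, lapply(as.integer(nRelax), function(ne) {
    hits <- if (kmax > 0)
      .relaxedMatchDense(ranked$i[seq_len(kmax)], ranked$j[seq_len(kmax)],
                         M, ne)
    else logical(0)
    cum <- cumsum(hits)
    tp <- vapply(ks, function(k) {
      if (kmax == 0L) 0L else as.integer(cum[min(k, kmax)])
    }, integer(1))
    data.frame(n_r = nRemoval, n_e = ne, k_label = kLabels, k = ks,
               tp = tp, precision = tp / ks, density = dens,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Evaluate a monomeric prediction over the full (relax removal, relaxation) grid
#'
#' Runs the whole inference-plus-evaluation pipeline for every relax-removal
#' setting: short-range filter, relax removal at each `n_r`, ranking, then
#' [precisionGrid()] at each relaxation `n_e`.
#'
#' @param pred monomeric [PredictionSet-class].
#' @param trueIntra intrachain [ContactMap-class] of the monomer.
#' @param truth interchain [ContactMap-class].
#' @param nRemoval,nRelax integer vectors of settings (default 0:2 each).
#' @param th a [ContactThresholds-class].
#' @return data.frame as in [precisionGrid()], stacked over `n_r`.
#' @export
evaluatePrediction <- function(pred, trueIntra, truth, nRemoval = 0:2,
                               nRelax = 0:2, th = contactThresholds()) {
  filtered <- filterShortRange(pred, th)
  L <- predLength(pred)
  out <- do.call(rbind, lapply(as.integer(nRemoval), function(nr) {
    surv <- relaxRemove(filtered, trueIntra, nr)
    ranked <- rankTopK(surv, max(1L, nrow(predItems(surv))))
    precisionGrid(ranked, truth, L, nRemoval = nr, nRelax = nRelax)
  }))
  rownames(out) <- NULL
  out
}

#' Stratify precision reports by interchain contact density
#'
#' Groups evaluation rows into half-open density bins of fixed width
#' (`[0, 0.25)`, `[0.25, 0.5)`, ... by default) and averages precision per
#' bin and per (n_r, n_e, k label) — the summary behind "high contact density
#' leads to high precision".
#'
#' @param reports data.frame from [precisionGrid()] /
#'   [evaluatePrediction()], possibly row-bound over many targets; must carry
#'   a `density` column.
#' @param binWidth bin width in contacts per residue (default 0.25).
#' @return data.frame with columns `bin_low`, `bin_high`, `n_r`, `n_e`,
#'   `k_label`, `mean_precision`, `n_targets`.
#' @export
densityReport <- function(reports, binWidth = 0.25) {
  stopifnot("density" %in% names(reports))
  lo <- floor(reports$density / binWidth) * binWidth
  key <- data.frame(bin_low = lo, bin_high = lo + binWidth,
                    n_r = reports$n_r, n_e = reports$n_e,
                    k_label = reports$k_label, stringsAsFactors = FALSE)
  agg <- stats::aggregate(reports$precision, by = key, FUN = mean)
  cnt <- stats::aggregate(reports$precision, by = key, FUN = length)
  agg$n_targets <- cnt$x
  names(agg)[names(agg) == "x"] <- "mean_precision"
  agg <- agg[order(agg$bin_low, agg$n_r, agg$n_e, agg$k_label), ]
  rownames(agg) <- NULL
  agg
}
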