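#' @include AllClasses.R contacts.R geometry.R
NULL

## Toy homomultimer generator. Geometry is deliberately simple: what matters
## for the pipeline is relative distances, not stereochemistry. Side chains
## are pseudo-atoms placed along the local outward direction so residues have
## 1-3 heavy atoms beyond the backbone and interfaces get realistic
## residue-to-residue distance variation.

#' Specification for a synthetic homomultimer fixture
#'
#' Bundles every knob of the generator: fold geometry, copy placement and the
#' fabricated-predictor error model (the stand-in for a deep-learning
#' monomeric contact predictor, whose output superimposes intrachain and
#' interchain co-evolutionary signal in one upper triangle).
#'
#' @param L monomer length (>= 12 so separation-6 filtering leaves pairs).
#' @param fold `"helix"` (ideal alpha-helix trace) or `"walk"`
#'   (self-avoiding fixed-step walk).
#' @param nCopies number of chains (>= 2); copies are placed by successive
#'   powers of `transform`.
#' @param transform a [RigidTransform-class] placing copy k+1 relative to
#'   copy k. The default, a 10.2 A lateral offset combined with a rise of
#'   0.42 x L residues along the helix axis, packs two parallel helices into
#'   a staggered interface with an asymmetric contact map.
#' @param intraKeep,interKeep fraction of true intrachain / interchain
#'   contacts the fabricated predictor recovers (defaults 0.85 / 0.70).
#' @param fpRate probability that a non-contact upper-triangle pair enters
#'   the prediction as a false positive (default 0.02).
#' @param noiseSd standard deviation of Gaussian score noise (default 0.10).
#' @param seed integer seed; every stochastic step is reproducible from it.
#' @return a list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(L = 40L, fold = c("helix", "walk"), nCopies = 2L,
                          transform = NULL, intraKeep = 0.85,
                          interKeep = 0.70, fpRate = 0.02, noiseSd = 0.10,
                          seed = 1L) {
  fold <- match.arg(fold)
  if (L < 12L) stop("L must be >= 12 (separation-6 filtering needs pairs)")
  if (nCopies < 2L) stop("nCopies must be >= 2")
  rates <- c(intraKeep, interKeep, fpRate)
  if (any(rates < 0) || any(rates > 1)) stop("rates must lie in [0, 1]")
  if (is.null(transform))
    transform <- rigidTransform(diag(3),
                                c(10.2, 0, round(0.42 * L) * 1.5))
  structure(list(L = as.integer(L), fold = fold, nCopies = as.integer(nCopies),
                 transform = transform, intraKeep = intraKeep,
                 interKeep = interKeep, fpRate = fpRate, noiseSd = noiseSd,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

## local outward direction per residue: away from the midpoint of the
## neighbouring Calphas (radial for a helix); ends copy their neighbour
.outwardDirs <- function(ca) {
  L <- nrow(ca)
  dir <- matrix(0, L, 3)
  for (i in 2:(L - 1)) {
    v <- ca[i, ] - (ca[i - 1, ] + ca[i + 1, ]) / 2
    n <- sqrt(sum(v^2))
    dir[i, ] <- if (n > 1e-8) v / n else c(1, 0, 0)
  }
  dir[1, ] <- dir[2, ]
  dir[L, ] <- dir[L - 1, ]
  dir
}

.helixTrace <- function(L, radius = 2.3, rise = 1.5, turn = 100 * pi / 180) {
  th <- (seq_len(L) - 1) * turn
  cbind(radius * cos(th), radius * sin(th), rise * (seq_len(L) - 1))
}

.walkTrace <- function(L, step = 3.8, minSep = 3.5, maxRestarts = 50L) {
  for (attempt in seq_len(maxRestarts)) {
    ca <- matrix(NA_real_, L, 3)
    ca[1, ] <- c(0, 0, 0)
    ok <- TRUE
    for (i in 2:L) {
      placed <- FALSE
      for (try in 1:200) {
        d <- stats::rnorm(3)
        cand <- ca[i - 1, ] + step * d / sqrt(sum(d^2))
        prev <- ca[seq_len(max(0, i - 2)), , drop = FALSE]
        if (nrow(prev) == 0 ||
            min(sqrt(rowSums(sweep(prev, 2, cand)^2))) >= minSep) {
          ca[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(ca)
  }
  stop("self-avoiding walk failed after ", maxRestarts, " restarts")
}

#' Generate a toy monomer
#'
#' Builds a Calpha trace for the requested fold, adds a pseudo-Cbeta 1.5 A
#' from each Calpha along the local outward direction, and 0-2 further
#' pseudo side-chain heavy atoms (CG at 2.4 A, CD at 3.2 A). Glycines get no
#' side-chain atoms at all, so the Calpha fallback of the intrachain contact
#' definition is exercised naturally. Deterministic under the spec seed.
#'
#' @param spec a [syntheticSpec()].
#' @return a [ChainRecord-class] with chain id `"A"`.
#' @export
makeMonomer <- function(spec = syntheticSpec()) {
  .withSeed(spec$seed, {
    L <- spec$L
    ca <- switch(spec$fold, helix = .helixTrace(L), walk = .walkTrace(L))
    dirs <- .outwardDirs(ca)
    letters1 <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], L,
                       replace = TRUE)
    nExtra <- sample(0:2, L, replace = TRUE)
    rows <- list()
    for (i in seq_len(L)) {
      rows[[length(rows) + 1L]] <-
        data.frame(resno = i, elety = "CA", elesy = "C",
                   x = ca[i, 1], y = ca[i, 2], z = ca[i, 3])
      if (letters1[i] != "G") {
        offs <- c(1.5, 2.4, 3.2)[seq_len(1 + nExtra[i])]
        name <- c("CB", "CG", "CD")[seq_len(1 + nExtra[i])]
        for (k in seq_along(offs)) {
          p <- ca[i, ] + offs[k] * dirs[i, ]
          rows[[length(rows) + 1L]] <-
            data.frame(resno = i, elety = name[k], elesy = "C",
                       x = p[1], y = p[2], z = p[3])
        }
      }
    }
    chainRecord("A", paste(letters1, collapse = ""), do.call(rbind, rows))
  })
}

#' Generate a toy homomultimer with its truth maps
#'
#' Places `nCopies` rigid copies of the monomer by successive powers of the
#' interface transform, verifies the placement is neither collapsed (minimum
#' interchain heavy-atom distance must exceed 1.5 A) nor contact-free, and
#' computes the true intrachain map (of the first chain) and the true
#' interchain map of the max-contact chain pair via the contact module.
#'
#' @param spec a [syntheticSpec()].
#' @param th a [ContactThresholds-class].
#' @return list with `chains` (named A, B, ...), `intra`, `inter`
#'   ([ContactMap-class] objects), `partnerId` and `monomer`.
#' @export
makeComplex <- function(spec = syntheticSpec(), th = contactThresholds()) {
  mono <- makeMonomer(spec)
  tf <- rigidTransform()
  chains <- vector("list", spec$nCopies)
  for (k in seq_len(spec$nCopies)) {
    chains[[k]] <- applyTransform(mono, tf, LETTERS[k])
    tf <- composeTransforms(spec$transform, tf)
  }
  names(chains) <- LETTERS[seq_len(spec$nCopies)]
  ha <- .heavyAtoms(chains[[1]])
  minD <- min(vapply(chains[-1], function(ch)
    sqrt(min(.crossDist2(ha$xyz, .heavyAtoms(ch)$xyz))), numeric(1)))
  if (minD <= 1.5)
    stop(sprintf("steric collapse: min interchain heavy-atom distance %.2f A",
                 minD))
  sel <- selectMaxPair(chains, th)
  if (sel$contactCount == 0L)
    stop(sprintf("no interchain contact: min heavy-atom distance %.2f A",
                 minD))
  list(chains = chains, intra = intrachainMap(chains[[1]], th),
       inter = sel$interMap, partnerId = sel$partnerId, monomer = mono)
}

#' Fabricate a monomeric contact-map prediction from the truth maps
#'
#' Emulates what a monomer-trained contact predictor sees for a
#' homomultimer: intrachain and interchain signal superimposed in a single
#' upper triangle. True intrachain pairs are kept with probability
#' `intraKeep`; true interchain pairs are folded to `i < j` (a monomeric map
#' has no chain orientation) and kept with probability `interKeep`; every
#' remaining upper-triangle pair may enter as a false positive with
#' probability `fpRate`. Scores are 0.8 for true and 0.3 for false entries
#' plus Gaussian noise, clipped to `[0, 1]`.
#'
#' @param intra,inter truth [ContactMap-class] objects sharing `L`.
#' @param spec a [syntheticSpec()] carrying the error model and seed.
#' @return a [PredictionSet-class].
#' @export
fabricatePrediction <- function(intra, inter, spec = syntheticSpec()) {
  stopifnot(mapLength(intra) == mapLength(inter))
  L <- mapLength(intra)
  .withSeed(spec$seed + 1L, {
    pi_ <- contactPairs(intra)
    keepIntra <- pi_[stats::runif(nrow(pi_)) <= spec$intraKeep, ,
                     drop = FALSE]
    pe <- contactPairs(inter)
    folded <- unique(cbind(pmin(pe[, 1], pe[, 2]), pmax(pe[, 1], pe[, 2])))
    folded <- folded[folded[, 1] != folded[, 2], , drop = FALSE]
    keepInter <- folded[stats::runif(nrow(folded)) <= spec$interKeep, ,
                        drop = FALSE]
    true <- unique(rbind(keepIntra, keepInter))
    allTrue <- unique(rbind(pi_, folded))
    inTruth <- matrix(FALSE, L, L)
    if (nrow(allTrue) > 0) inTruth[allTrue] <- TRUE
    ut <- which(upper.tri(inTruth), arr.ind = TRUE)
    free <- ut[!inTruth[ut], , drop = FALSE]
    fp <- free[stats::runif(nrow(free)) <= spec$fpRate, , drop = FALSE]
    i <- c(true[, 1], fp[, 1])
    j <- c(true[, 2], fp[, 2])
    base <- c(rep(0.8, nrow(true)), rep(0.3, nrow(fp)))
    sc <- pmin(1, pmax(0, base + stats::rnorm(length(base), 0, spec$noiseSd)))
    predictionSet(L, i, j, sc)
  })
}
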