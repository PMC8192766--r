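#' @include AllClasses.R geometry.R
NULL

## Rigid-body homodimer reconstruction: the monomer structure is taken as
## fixed and a second copy is placed by a 6-degree-of-freedom rigid motion
## optimized by Metropolis simulated annealing against flat-bottom distance
## restraints derived from predicted interchain contacts.

## precompute everything the energy needs from the fixed monomer + restraints
.energyContext <- function(monomer, pairs, dc, cfg) {
  h <- .heavyAtoms(monomer)
  resAtoms <- split(seq_len(nrow(h$xyz)), h$resno)
  pairs <- as.matrix(pairs)
  storage.mode(pairs) <- "integer"
  if (nrow(pairs) == 0L) stop("nothing to satisfy: zero restraints")
  L <- chainLength(monomer)
  if (any(pairs < 1L) || any(pairs > L))
    stop("restraint indices out of range")
  restrained <- matrix(FALSE, L, L)  # unordered membership of the restraints
  restrained[cbind(pmin(pairs[, 1], pairs[, 2]),
                   pmax(pairs[, 1], pairs[, 2]))] <- TRUE
  resCen <- do.call(rbind, lapply(resAtoms, function(idx)
    colMeans(h$xyz[idx, , drop = FALSE])))
  resRad <- vapply(seq_along(resAtoms), function(i)
    sqrt(max(.crossDist2(h$xyz[resAtoms[[i]], , drop = FALSE],
                         resCen[i, , drop = FALSE]))), numeric(1))
  list(X = h$xyz, resno = h$resno, resAtoms = resAtoms, pairs = pairs,
       dc = dc, L = L, restrained = restrained,
       resCen = resCen, resRad = resRad,
       clashDist = cfg@clashDist, clashWeight = cfg@clashWeight,
       centroid = colMeans(h$xyz))
}

## number of induced interchain contacts (unordered) absent from the
## restraint list -- the map-consistency tie-break among zero-energy poses.
## Residue-centroid bounding spheres prune the atom-level distance checks.
.extraContacts <- function(ctx, moved, movedCen) {
  reach <- outer(ctx$resRad, ctx$resRad, "+") + ctx$dc
  cand <- which(sqrt(.crossDist2(ctx$resCen, movedCen)) <= reach,
                arr.ind = TRUE)
  M <- matrix(FALSE, ctx$L, ctx$L)
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    M[i, j] <- min(.crossDist2(ctx$X[ctx$resAtoms[[i]], , drop = FALSE],
                               moved[ctx$resAtoms[[j]], , drop = FALSE])) <=
      ctx$dc^2
  }
  M <- M | t(M)
  induced <- M & upper.tri(M, diag = TRUE)
  sum(induced & !ctx$restrained)
}

.pairMinDist <- function(ctx, moved, i, j) {
  sqrt(min(.crossDist2(ctx$X[ctx$resAtoms[[i]], , drop = FALSE],
                       moved[ctx$resAtoms[[j]], , drop = FALSE])))
}

.energy <- function(ctx, R, t) {
  moved <- ctx$X %*% t(R) + matrix(t, nrow(ctx$X), 3, byrow = TRUE)
  d2 <- .crossDist2(ctx$X, moved)  # fixed atoms x moved atoms, once per pose
  e <- 0
  for (r in seq_len(nrow(ctx$pairs))) {
    i <- ctx$pairs[r, 1]; j <- ctx$pairs[r, 2]
    ai <- ctx$resAtoms[[i]]; aj <- ctx$resAtoms[[j]]
    v1 <- max(0, sqrt(min(d2[ai, aj])) - ctx$dc)^2
    ## the mirror orientation may be the real interaction; charge the lighter
    v2 <- if (i == j) v1 else max(0, sqrt(min(d2[aj, ai])) - ctx$dc)^2
    e <- e + min(v1, v2)
  }
  close <- d2 < ctx$clashDist^2
  if (any(close))
    e <- e + ctx$clashWeight * sum((ctx$clashDist - sqrt(d2[close]))^2)
  e
}

#' Restraint + clash energy of a candidate placement
#'
#' Flat-bottom quadratic restraint energy: for each restrained pair (i, j),
#' `max(0, d - dc)^2` where `d` is the minimum heavy-atom distance between
#' residue i of the fixed copy and residue j of the transformed copy; because
#' a monomeric prediction carries no chain orientation, the mirror pair
#' (j, i) is also evaluated and the lighter of the two penalties is charged.
#' A soft-sphere clash term `clashWeight * sum (clashDist - d)^2` over
#' heavy-atom pairs closer than `clashDist` keeps the copies from collapsing.
#' Zero if and only if every restraint is satisfied and no clash exists.
#'
#' @param transform a [RigidTransform-class] placing the second copy.
#' @param monomer the fixed [ChainRecord-class].
#' @param pairs two-column matrix/data.frame of restrained (i, j) pairs.
#' @param dc satisfaction distance in Angstrom (default 6.0, the interchain
#'   contact definition).
#' @param cfg an [AnnealConfig-class] (clash settings).
#' @return non-negative energy.
#' @export
restraintEnergy <- function(transform, monomer, pairs, dc = 6.0,
                            cfg = annealConfig()) {
  ctx <- .energyContext(monomer, pairs, dc, cfg)
  .energy(ctx, transform@rotation, transform@translation)
}

#' Fraction of restraints satisfied by a placement
#'
#' @inheritParams restraintEnergy
#' @return fraction in `[0, 1]` of pairs whose (orientation-lenient) minimum
#'   heavy-atom distance is `<= dc`.
#' @export
satisfiedFraction <- function(transform, monomer, pairs, dc = 6.0,
                              cfg = annealConfig()) {
  ctx <- .energyContext(monomer, pairs, dc, cfg)
  moved <- ctx$X %*% t(transform@rotation) +
    matrix(transform@translation, nrow(ctx$X), 3, byrow = TRUE)
  ok <- vapply(seq_len(nrow(ctx$pairs)), function(r) {
    i <- ctx$pairs[r, 1]; j <- ctx$pairs[r, 2]
    .pairMinDist(ctx, moved, i, j) <= dc ||
      .pairMinDist(ctx, moved, j, i) <= dc
  }, logical(1))
  mean(ok)
}

#' Reconstruct a homodimer by contact-restrained simulated annealing
#'
#' Searches the 6 rigid degrees of freedom of the second monomer copy by
#' Metropolis annealing with a geometric cooling schedule; move sizes scale
#' with temperature, rotations are applied about the moving copy's centroid,
#' and each restart begins from a uniformly random orientation placed a few
#' gyration radii away. The best-energy placement over all restarts wins.
#' Flat-bottom restraints leave an extended zero-energy region, so ties at
#' zero energy are broken by map consistency: among placements satisfying
#' every restraint, the one inducing the fewest interchain contacts absent
#' from the restraint list is preferred (the restraint map is treated as the
#' interface's contact inventory, so unlisted induced contacts signal an
#' over-tight or shifted pose). Deterministic under the seed.
#'
#' @param monomer the fixed [ChainRecord-class].
#' @param pairs two-column matrix/data.frame of predicted interchain (i, j)
#'   restraints.
#' @param cfg an [AnnealConfig-class].
#' @param dc restraint satisfaction distance in Angstrom (default 6.0).
#' @param seed integer RNG seed.
#' @return list with `transform` (best [RigidTransform-class]), `model`
#'   (list of two [ChainRecord-class], ids A and B), and `report` (list:
#'   `bestEnergy`, `satisfiedFraction`, `trace` data.frame with one row per
#'   restart).
#' @export
annealDimer <- function(monomer, pairs, cfg = annealConfig(), dc = 6.0,
                        seed = 1L) {
  ctx <- .energyContext(monomer, pairs, dc, cfg)
  rg <- sqrt(mean(rowSums(sweep(ctx$X, 2, ctx$centroid)^2)))
  .withSeed(seed, {
    best <- NULL
    trace <- data.frame(restart = integer(), energy = numeric(),
                        extra = numeric())
    ## lexicographic objective: energy first, extras only compared at E = 0
    xOf <- function(e, R, t) {
      if (e > 0) return(Inf)
      moved <- ctx$X %*% t(R) + matrix(t, nrow(ctx$X), 3, byrow = TRUE)
      movedCen <- ctx$resCen %*% t(R) + matrix(t, ctx$L, 3, byrow = TRUE)
      .extraContacts(ctx, moved, movedCen)
    }
    better <- function(e1, x1, e2, x2) e1 < e2 || (e1 == e2 && x1 < x2)
    for (rs in seq_len(cfg@restarts)) {
      R <- .uniformRotation()
      dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
      tVec <- ctx$centroid + (2.5 * rg + 6) * dir - as.numeric(R %*% ctx$centroid)
      e <- .energy(ctx, R, tVec)
      x <- xOf(e, R, tVec)
      temp <- cfg@tInitial
      bR <- R; bT <- tVec; bE <- e; bX <- x
      while (temp > cfg@tFinal) {
        frac <- max(sqrt(temp / cfg@tInitial), 0.05)
        for (s in seq_len(cfg@stepsPerTemp)) {
          dR <- .randomRotation(cfg@rotScale * frac)
          cM <- as.numeric(R %*% ctx$centroid) + tVec  # moving-copy centroid
          Rn <- dR %*% R
          tn <- as.numeric(dR %*% (tVec - cM)) + cM +
            stats::rnorm(3, 0, cfg@transScale * frac)
          en <- .energy(ctx, Rn, tn)
          xn <- xOf(en, Rn, tn)
          ## Metropolis on the active objective level
          dObj <- if (en == 0 && e == 0) xn - x else en - e
          if (dObj < 0 || stats::runif(1) < exp(-dObj / temp)) {
            R <- Rn; tVec <- tn; e <- en; x <- xn
            if (better(e, x, bE, bX)) { bR <- R; bT <- tVec; bE <- e; bX <- x }
          }
          if (bE == 0 && bX == 0) break
        }
        if (bE == 0 && bX == 0) break
        temp <- temp * cfg@cooling
      }
      trace <- rbind(trace, data.frame(restart = rs, energy = bE,
                                       extra = bX))
      if (is.null(best) || better(bE, bX, best$e, best$x))
        best <- list(R = bR, t = bT, e = bE, x = bX)
      if (best$e == 0 && best$x == 0) break
    }
    tf <- rigidTransform(best$R, best$t)
    model <- list(A = applyTransform(monomer, rigidTransform(), "A"),
                  B = applyTransform(monomer, tf, "B"))
    list(transform = tf, model = model,
         report = list(bestEnergy = best$e,
                       extraContacts = if (is.finite(best$x)) best$x else NA,
                       satisfiedFraction = satisfiedFraction(
                         tf, monomer, ctx$pairs, dc, cfg),
                       trace = trace))
  })
}

#' Calpha RMSD of a complex model against the native after optimal superposition
#'
#' Concatenates the Calpha traces of all chains and computes the
#' least-squares optimally superposed RMSD (via `bio3d::rmsd(fit = TRUE)`).
#' Because homodimer chain labels are arbitrary, both chain pairings of the
#' model onto the native are tried and the smaller RMSD returned.
#'
#' @param model,native lists of [ChainRecord-class] objects with equal chain
#'   counts and equal per-chain lengths.
#' @return RMSD in Angstrom.
#' @export
superposeRmsd <- function(model, native) {
  if (length(model) != length(native))
    stop("chain count mismatch between model and native")
  caOf <- function(chs) do.call(rbind, lapply(chs, caCoords))
  lenM <- vapply(model, chainLength, integer(1))
  lenN <- vapply(native, chainLength, integer(1))
  if (!all(lenM == lenN))
    stop("chain length mismatch between model and native")
  m1 <- caOf(model)
  orders <- list(seq_along(native), rev(seq_along(native)))
  vals <- vapply(orders, function(ord) {
    n1 <- caOf(native[ord])
    if (!all(vapply(native[ord], chainLength, integer(1)) == lenM))
      return(Inf)
    bio3d::rmsd(as.numeric(t(m1)), as.numeric(t(n1)), fit = TRUE)
  }, numeric(1))
  min(vals)
}
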