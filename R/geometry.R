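## Internal coordinate helpers shared by the contact, prep and
## reconstruction code. Hydrogens (and deuterium) never reach these
## functions: they are filtered on read and never generated synthetically.

#' Calpha coordinates of a chain
#'
#' @param chain a [ChainRecord-class].
#' @return `L x 3` matrix of Calpha coordinates; `NA` rows where a residue
#'   has no CA atom.
#' @export
caCoords <- function(chain) {
  a <- atomTable(chain)
  L <- chainLength(chain)
  out <- matrix(NA_real_, L, 3)
  ca <- a[a$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  out[ca$resno, ] <- as.matrix(ca[, c("x", "y", "z")])
  out
}

#' Contact-reference coordinates: Cbeta, falling back to Calpha
#'
#' Returns, per residue, the Cbeta position, or the Calpha position when no
#' Cbeta exists (glycine, or a residue with the atom missing). Residues with
#' neither atom get an `NA` row.
#'
#' @param chain a [ChainRecord-class].
#' @return `L x 3` coordinate matrix.
#' @export
cbCoords <- function(chain) {
  a <- atomTable(chain)
  L <- chainLength(chain)
  out <- caCoords(chain)
  cb <- a[a$elety == "CB", , drop = FALSE]
  cb <- cb[!duplicated(cb$resno), , drop = FALSE]
  out[cb$resno, ] <- as.matrix(cb[, c("x", "y", "z")])
  out
}

## atom coordinate matrix + residue index vector, heavy atoms only
.heavyAtoms <- function(chain) {
  a <- atomTable(chain)
  keep <- !(toupper(a$elesy) %in% c("H", "D"))
  a <- a[keep, , drop = FALSE]
  list(xyz = as.matrix(a[, c("x", "y", "z")]), resno = a$resno)
}

## squared Euclidean cross-distances between two coordinate matrices
.crossDist2 <- function(A, B) {
  an <- rowSums(A * A); bn <- rowSums(B * B)
  d2 <- -2 * tcrossprod(A, B)
  d2 <- d2 + an  # recycles down columns
  d2 <- sweep(d2, 2, bn, "+")
  d2[d2 < 0] <- 0
  d2
}

## minimum heavy-atom distance per residue pair: La x Lb matrix.
## Chunks over the first chain's atoms to bound memory on large chains.
.minResidueDist <- function(a, b, La, Lb, chunk = 4000L) {
  out <- matrix(Inf, La, Lb)
  bGroups <- split(seq_len(nrow(b$xyz)), b$resno)
  bIdx <- as.integer(names(bGroups))
  starts <- seq(1L, nrow(a$xyz), by = chunk)
  for (s in starts) {
    rows <- s:min(s + chunk - 1L, nrow(a$xyz))
    d2 <- .crossDist2(a$xyz[rows, , drop = FALSE], b$xyz)
    ## reduce columns to per-residue minima of chain b
    cmin <- vapply(bGroups, function(cols)
      do.call(pmin, lapply(cols, function(cc) d2[, cc])), numeric(length(rows)))
    cmin <- matrix(cmin, nrow = length(rows))
    ## then reduce rows to per-residue minima of chain a
    for (g in split(seq_along(rows), a$resno[rows])) {
      ri <- a$resno[rows[g[1]]]
      m <- if (length(g) == 1L) cmin[g, ] else do.call(pmin, lapply(g, function(r) cmin[r, ]))
      out[ri, bIdx] <- pmin(out[ri, bIdx], m)
    }
  }
  sqrt(out)
}

#' Apply a rigid transform to a chain
#'
#' @param chain a [ChainRecord-class].
#' @param transform a [RigidTransform-class].
#' @param chainId identifier for the transformed copy (default: keep).
#' @return a new [ChainRecord-class] with coordinates `R x + t`.
#' @export
applyTransform <- function(chain, transform, chainId = chain@chainId) {
  a <- atomTable(chain)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  moved <- xyz %*% t(transform@rotation) +
    matrix(transform@translation, nrow(xyz), 3, byrow = TRUE)
  a$x <- moved[, 1]; a$y <- moved[, 2]; a$z <- moved[, 3]
  chainRecord(chainId, chainSeq(chain), a)
}

#' Compose two rigid transforms
#'
#' `composeTransforms(s, t)` returns the transform applying `t` first and
#' then `s` (matrix convention), so powers of a transform place successive
#' copies of a cyclic assembly.
#'
#' @param s,t [RigidTransform-class] objects.
#' @return their composition as a [RigidTransform-class].
#' @export
composeTransforms <- function(s, t) {
  rigidTransform(s@rotation %*% t@rotation,
                 as.numeric(s@rotation %*% t@translation) + s@translation)
}

## run expr with a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## small rotation about a uniformly random axis (Rodrigues), angle ~ N(0, sd)
.randomRotation <- function(sd) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::rnorm(1, 0, sd)
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## uniform random rotation (QR of a Gaussian matrix, sign-fixed)
.uniformRotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
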