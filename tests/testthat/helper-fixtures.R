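# Tiny in-code fixtures and independent brute-force oracles used across the
# suite. The oracles deliberately use naive per-pair loops so they share no
# code path with the package implementations they check.

# build a small chain from a list of residues; each residue is a named list
# of atom name -> c(x, y, z)
mkChain <- function(id, seq1, residues) {
  rows <- do.call(rbind, lapply(seq_along(residues), function(i) {
    at <- residues[[i]]
    do.call(rbind, lapply(names(at), function(nm)
      data.frame(resno = i, elety = nm,
                 elesy = substr(nm, 1, 1),
                 x = at[[nm]][1], y = at[[nm]][2], z = at[[nm]][3])))
  }))
  chainRecord(id, seq1, rows)
}

# chain of CA-only residues along the x axis, step `gap` Angstrom
lineChain <- function(id, L, gap = 4, offset = c(0, 0, 0), letter = "A") {
  mkChain(id, paste(rep(letter, L), collapse = ""),
          lapply(seq_len(L), function(i)
            list(CA = c((i - 1) * gap + offset[1], offset[2], offset[3]))))
}

# ---- brute-force oracles --------------------------------------------------

bruteIntraMap <- function(chain, cutoff = 8) {
  a <- atomTable(chain)
  L <- chainLength(chain)
  ref <- lapply(seq_len(L), function(i) {
    r <- a[a$resno == i, ]
    cb <- r[r$elety == "CB", c("x", "y", "z")]
    if (nrow(cb) == 0) cb <- r[r$elety == "CA", c("x", "y", "z")]
    if (nrow(cb) == 0) NULL else as.numeric(cb[1, ])
  })
  out <- NULL
  for (i in seq_len(L - 1)) for (j in (i + 1):L) {
    if (is.null(ref[[i]]) || is.null(ref[[j]])) next
    if (sqrt(sum((ref[[i]] - ref[[j]])^2)) <= cutoff) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

bruteInterMap <- function(a, b, cutoff = 6) {
  ta <- atomTable(a); tb <- atomTable(b)
  ta <- ta[!toupper(ta$elesy) %in% c("H", "D"), ]
  tb <- tb[!toupper(tb$elesy) %in% c("H", "D"), ]
  L <- chainLength(a)
  out <- NULL
  for (i in seq_len(L)) for (j in seq_len(L)) {
    ai <- as.matrix(ta[ta$resno == i, c("x", "y", "z")])
    bj <- as.matrix(tb[tb$resno == j, c("x", "y", "z")])
    dmin <- Inf
    for (p in seq_len(nrow(ai))) for (q in seq_len(nrow(bj)))
      dmin <- min(dmin, sqrt(sum((ai[p, ] - bj[q, ])^2)))
    if (dmin <= cutoff) out <- rbind(out, c(i, j))
  }
  if (is.null(out)) matrix(integer(), 0, 2) else out
}

# per-pair window check, one prediction at a time
bruteRelaxRemove <- function(items, intraPairs, n) {
  if (nrow(items) == 0 || nrow(intraPairs) == 0) return(items)
  centers <- rbind(intraPairs, intraPairs[, 2:1, drop = FALSE])
  keep <- vapply(seq_len(nrow(items)), function(r) {
    !any(abs(items$i[r] - centers[, 1]) <= n &
           abs(items$j[r] - centers[, 2]) <= n)
  }, logical(1))
  items[keep, , drop = FALSE]
}

bruteRelaxedMatch <- function(i, j, truthPairs, n) {
  if (nrow(truthPairs) == 0) return(FALSE)
  any((abs(truthPairs[, 1] - i) <= n & abs(truthPairs[, 2] - j) <= n) |
        (abs(truthPairs[, 1] - j) <= n & abs(truthPairs[, 2] - i) <= n))
}

brutePrecision <- function(ranked, truthPairs, n, k) {
  if (k < 1) stop("k must be >= 1")
  kk <- min(k, nrow(ranked))
  tp <- 0
  for (r in seq_len(kk))
    if (bruteRelaxedMatch(ranked$i[r], ranked$j[r], truthPairs, n))
      tp <- tp + 1
  tp / k
}

# ---- random instances -----------------------------------------------------

randomInstance <- function(seed, L = NULL) {
  set.seed(seed)
  if (is.null(L)) L <- sample(12:40, 1)
  ut <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  nIntra <- sample(0:min(30, nrow(ut)), 1)
  intra <- ut[sample(nrow(ut), nIntra), , drop = FALSE]
  all_ <- which(matrix(TRUE, L, L), arr.ind = TRUE)
  all_ <- all_[all_[, 1] != all_[, 2], , drop = FALSE]
  nInter <- sample(1:min(40, nrow(all_)), 1)
  inter <- all_[sample(nrow(all_), nInter), , drop = FALSE]
  nPred <- sample(5:min(120, nrow(ut)), 1)
  pi_ <- ut[sample(nrow(ut), nPred), , drop = FALSE]
  pred <- predictionSet(L, pi_[, 1], pi_[, 2], runif(nPred))
  list(L = L,
       intra = contactMap("intra", L, intra),
       inter = contactMap("inter", L, inter),
       pred = pred)
}
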