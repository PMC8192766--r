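# a minimal RawComplex-shaped object without touching the PDB reader
rawFrom <- function(chains) {
  atoms <- do.call(rbind, lapply(names(chains), function(cid) {
    df <- chains[[cid]]
    df$chain <- cid
    df$insert <- ""
    df
  }))
  structure(list(atoms = atoms, sourceId = "in-memory"), class = "RawComplex")
}

test_that("splitting renumbers author residue ids to a contiguous 1..L", {
  chA <- data.frame(resno = c(5, 6, 8), resid = c("ALA", "GLY", "XYZ"),
                    elety = "CA", elesy = "C",
                    x = c(0, 4, 8), y = 0, z = 0)
  chB <- data.frame(resno = c(-2, 0), resid = c("LYS", "TRP"),
                    elety = "CA", elesy = "C", x = c(0, 4), y = 5, z = 0)
  recs <- suppressWarnings(splitAndReindex(rawFrom(list(A = chA, B = chB))))
  expect_named(recs, c("A", "B"))
  expect_equal(atomTable(recs$A)$resno, c(1L, 2L, 3L))
  expect_equal(chainSeq(recs$A), "AGX")   # non-standard residue kept as X
  expect_equal(chainSeq(recs$B), "KW")
})

test_that("homogenization removes mismatched columns and enforces the 95% rule", {
  L <- 100
  a <- lineChain("A", L)
  lettersB <- strsplit(chainSeq(a), "")[[1]]
  lettersB[50] <- "W"   # one mismatch -> 99% identity
  b <- mkChain("B", paste(lettersB, collapse = ""),
               lapply(seq_len(L), function(i) list(CA = c((i - 1) * 4, 9, 0))))
  h <- homogenizePair(a, b)
  expect_true(h$accepted)
  expect_equal(h$identity, 0.99)
  expect_equal(chainLength(h$chains[[1]]), 99L)
  expect_identical(chainSeq(h$chains[[1]]), chainSeq(h$chains[[2]]))
  expect_equal(atomTable(h$chains[[1]])$resno, 1:99)
  # position 50 is gone: atom x-coordinates skip the removed residue
  expect_equal(atomTable(h$chains[[1]])$x[50], 50 * 4)

  # identical chains: identity 1, nothing removed
  h2 <- homogenizePair(a, a)
  expect_equal(h2$identity, 1.0)
  expect_equal(chainLength(h2$chains[[1]]), L)

  # 90% identity: rejected by the 95% floor
  lettersC <- strsplit(chainSeq(a), "")[[1]]
  swap <- c("W", "Y")[1 + (lettersC[1:10] == "W")]
  lettersC[1:10] <- swap
  cc <- mkChain("C", paste(lettersC, collapse = ""),
                lapply(seq_len(L), function(i) list(CA = c((i - 1) * 4, 9, 0))))
  h3 <- homogenizePair(a, cc)
  expect_false(h3$accepted)
  expect_equal(h3$identity, 0.90)
})

test_that("homogenization is symmetric in its arguments", {
  set.seed(42)
  lettersA <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 60, TRUE)
  lettersB <- lettersA
  lettersB[10] <- if (lettersA[10] == "W") "Y" else "W"
  lettersB[30] <- if (lettersA[30] == "W") "Y" else "W"
  a <- mkChain("A", paste(lettersA, collapse = ""),
               lapply(1:60, function(i) list(CA = c(i * 4, 0, 0))))
  b <- mkChain("B", paste(lettersB, collapse = ""),
               lapply(1:60, function(i) list(CA = c(i * 4, 9, 0))))
  h1 <- homogenizePair(a, b)
  h2 <- homogenizePair(b, a)
  expect_equal(h1$identity, h2$identity)
  expect_identical(chainSeq(h1$chains[[1]]), chainSeq(h2$chains[[2]]))
  expect_identical(atomTable(h1$chains[[1]]), atomTable(h2$chains[[2]]))
})

test_that("interface detection uses an inclusive 6 A heavy-atom cutoff", {
  one <- function(id, x) mkChain(id, "A", list(list(CA = c(x, 0, 0))))
  expect_true(requireInterchainContact(list(one("A", 0), one("B", 5.9))))
  expect_true(requireInterchainContact(list(one("A", 0), one("B", 6.0))))
  expect_false(requireInterchainContact(list(one("A", 0), one("B", 6.5))))
  # any other chain can supply the interface
  expect_true(requireInterchainContact(list(one("A", 0), one("B", 50),
                                            one("C", 4))))
})

test_that("greedy dedup drops records above the identity ceiling", {
  m1 <- makeMonomer(syntheticSpec(L = 40, seed = 1))
  m2 <- makeMonomer(syntheticSpec(L = 40, seed = 2))
  m3 <- makeMonomer(syntheticSpec(L = 40, seed = 3))
  kept <- greedyDedup(list(m1, m1, m2, m3))
  # the duplicate goes; random 40-mers may or may not clear 30% pairwise
  expect_lt(length(kept), 4L)
  ids <- vapply(kept, chainSeq, character(1))
  if (length(kept) > 1) {
    combs <- utils::combn(length(kept), 2)
    for (k in seq_len(ncol(combs)))
      expect_lte(sequenceIdentity(ids[combs[1, k]], ids[combs[2, k]]), 0.30)
  }
  expect_identical(greedyDedup(list()), list())
})

test_that("the full preparation cascade accepts a synthetic dimer", {
  cx <- makeComplex(syntheticSpec(L = 30, seed = 8))
  raw <- rawFrom(lapply(cx$chains, function(ch) {
    a <- atomTable(ch)
    l1 <- strsplit(chainSeq(ch), "")[[1]]
    r3 <- bio3d::aa123(l1)
    a$resid <- r3[a$resno]
    a
  }))
  prep <- prepareComplex(raw)
  expect_true(prep$accepted)
  expect_equal(length(prep$chains), 2L)
  expect_identical(chainSeq(prep$chains[[1]]), chainSeq(prep$chains[[2]]))
})
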