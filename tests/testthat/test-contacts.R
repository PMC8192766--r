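test_that("intrachain contacts use Cbeta with inclusive 8 A boundary and Calpha fallback", {
  at <- function(d) mkChain("A", "AA", list(
    list(CA = c(0, 0, 0), CB = c(0, 1.5, 0)),
    list(CA = c(d, 0, 0), CB = c(d, 1.5, 0))))
  expect_equal(nContacts(intrachainMap(at(8.0))), 1L)   # boundary included
  expect_equal(nContacts(intrachainMap(at(8.01))), 0L)
  # glycines: no CB, Calpha distance decides
  gly <- mkChain("A", "GG", list(list(CA = c(0, 0, 0)),
                                 list(CA = c(7, 0, 0))))
  expect_equal(contactPairs(intrachainMap(gly)), cbind(1L, 2L))
  # a residue missing both CB and CA is excluded with a warning
  odd <- mkChain("A", "AAA", list(list(CA = c(0, 0, 0)),
                                  list(N = c(4, 0, 0)),
                                  list(CA = c(6, 0, 0))))
  expect_warning(m <- intrachainMap(odd), "lack both")
  expect_equal(contactPairs(m), cbind(1L, 3L))
})

test_that("intrachain map equals a brute-force double loop on random folds", {
  for (seed in 1:5) {
    mono <- makeMonomer(syntheticSpec(L = 30, fold = "walk", seed = seed))
    got <- contactPairs(intrachainMap(mono))
    want <- bruteIntraMap(mono)
    expect_equal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
  }
})

test_that("interchain contacts use minimum heavy-atom distance, stored asymmetrically", {
  a <- mkChain("A", "AK", list(list(CA = c(0, 0, 0), CB = c(0, 2, 0)),
                               list(CA = c(4, 0, 0))))
  b <- applyTransform(a, rigidTransform(diag(3), c(0, 7.5, 0)), "B")
  m <- interchainMap(a, b)
  # CB of res 1 (y=2) to CA of B res 1 (y=7.5): 5.5 A -> contact
  expect_true(any(contactPairs(m)[, 1] == 1 & contactPairs(m)[, 2] == 1))
  # far apart -> empty
  far <- applyTransform(a, rigidTransform(diag(3), c(0, 100, 0)), "B")
  expect_equal(nContacts(interchainMap(a, far)), 0L)
})

test_that("interchain map agrees with brute force and translation dimers are symmetric", {
  sp <- syntheticSpec(L = 20, seed = 3)
  mono <- makeMonomer(sp)
  b <- applyTransform(mono, rigidTransform(diag(3), c(8.5, 0, 0)), "B")
  m <- interchainMap(mono, b)
  want <- bruteInterMap(mono, b)
  got <- contactPairs(m)
  expect_setequal(paste(got[, 1], got[, 2]), paste(want[, 1], want[, 2]))
  # swapping the chain arguments mirrors the asymmetric pairs exactly
  rev_ <- contactPairs(interchainMap(b, mono))
  expect_setequal(paste(got[, 1], got[, 2]), paste(rev_[, 2], rev_[, 1]))
  # the default staggered placement is genuinely asymmetric
  cx <- makeComplex(syntheticSpec(L = 40, seed = 1))
  p <- contactPairs(cx$inter)
  expect_false(any(paste(p[, 1], p[, 2]) %in% paste(p[, 2], p[, 1]) &
                     p[, 1] != p[, 2]))
})

test_that("max-contact pair selection ties break to the earliest chain", {
  sp <- syntheticSpec(L = 20, seed = 2)
  mono <- makeMonomer(sp)
  near <- rigidTransform(diag(3), c(8.5, 0, 0))
  farT <- rigidTransform(diag(3), c(200, 0, 0))
  chains <- list(mono,
                 applyTransform(mono, near, "B"),
                 applyTransform(mono, farT, "C"),
                 applyTransform(mono, near, "D"))  # D duplicates B's placement
  sel <- selectMaxPair(chains)
  expect_equal(sel$allCounts[["B"]], sel$allCounts[["D"]])
  expect_identical(sel$partnerId, "B")
  expect_equal(sel$contactCount, max(sel$allCounts))
  expect_equal(sel$allCounts[["C"]], 0L)
  expect_error(selectMaxPair(list(mono)), "two chains")
})

test_that("contact density is contacts per residue and rigid-motion invariant", {
  m <- contactMap("inter", 60, cbind(rep(1:5, each = 6), rep(6:11, 5)))
  expect_equal(contactDensity(m), 30 / 60)
  expect_equal(contactDensity(contactMap("inter", 10, NULL)), 0)
  cx <- makeComplex(syntheticSpec(L = 24, seed = 5))
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  tf <- rigidTransform(rot, c(11, -3, 7))
  moved <- lapply(cx$chains, applyTransform, transform = tf)
  m2 <- interchainMap(moved[[1]], moved[[cx$partnerId]])
  expect_equal(contactDensity(m2), contactDensity(cx$inter))
})
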