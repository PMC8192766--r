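test_that("restraint energy is a flat-bottom quadratic plus clash penalty", {
  # two CA-only residues 4 A apart; second copy translated along y
  mono <- mkChain("A", "AK", list(list(CA = c(0, 0, 0)),
                                  list(CA = c(4, 0, 0))))
  place <- function(dy) rigidTransform(diag(3), c(0, dy, 0))
  pairs <- cbind(1, 1)
  cfg <- annealConfig()
  expect_equal(restraintEnergy(place(5), mono, pairs), 0)        # satisfied
  expect_equal(restraintEnergy(place(8), mono, pairs), 4)        # (8 - 6)^2
  expect_equal(restraintEnergy(place(6), mono, pairs), 0)        # boundary
  # superposed copies: restraints trivially satisfied but clash dominates
  e0 <- restraintEnergy(place(0), mono, pairs)
  expect_gt(e0, cfg@clashWeight * cfg@clashDist^2)
  # the mirror orientation is charged at the lighter penalty:
  # (1,2) spans 9.4 A but its mirror (2,1) spans 5 A -> no penalty
  shift <- rigidTransform(diag(3), c(4, 5, 0))
  expect_equal(restraintEnergy(shift, mono, cbind(1, 2)), 0)
  expect_error(restraintEnergy(place(5), mono, matrix(integer(), 0, 2)),
               "zero restraints")
})

test_that("satisfied fraction counts orientation-lenient restraints", {
  mono <- mkChain("A", "AK", list(list(CA = c(0, 0, 0)),
                                  list(CA = c(40, 0, 0))))
  tf <- rigidTransform(diag(3), c(0, 5, 0))
  pairs <- rbind(c(1, 1), c(1, 2))   # (1,2) spans 40 A -> unsatisfied
  expect_equal(satisfiedFraction(tf, mono, pairs), 0.5)
})

test_that("annealing is deterministic under the seed and solves a single restraint", {
  mono <- makeMonomer(syntheticSpec(L = 14, seed = 3))
  pairs <- cbind(1L, 14L)
  cfg <- annealConfig(restarts = 2L, stepsPerTemp = 30L)
  r1 <- annealDimer(mono, pairs, cfg, seed = 5)
  r2 <- annealDimer(mono, pairs, cfg, seed = 5)
  expect_identical(r1$transform@rotation, r2$transform@rotation)
  expect_identical(r1$transform@translation, r2$transform@translation)
  expect_identical(r1$report, r2$report)
  expect_equal(r1$report$bestEnergy, 0)
  expect_equal(r1$report$satisfiedFraction, 1)
})

test_that("superposed RMSD is rigid-invariant, symmetric and matches a hand Kabsch", {
  cx <- makeComplex(syntheticSpec(L = 18, seed = 2))
  native <- cx$chains
  expect_equal(superposeRmsd(native, native), 0, tolerance = 1e-8)
  th <- 1.1
  rot <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  moved <- lapply(native, applyTransform,
                  transform = rigidTransform(rot, c(3, -8, 12)))
  expect_equal(superposeRmsd(moved, native), 0, tolerance = 1e-6)
  expect_equal(superposeRmsd(native, moved), superposeRmsd(moved, native),
               tolerance = 1e-6)
  # independent Kabsch on a tiny displaced set
  kabschRmsd <- function(P, Q) {
    Pc <- scale(P, scale = FALSE); Qc <- scale(Q, scale = FALSE)
    s <- svd(crossprod(Pc, Qc))
    d <- sign(det(tcrossprod(s$v, s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    sqrt(mean(rowSums((Qc - Pc %*% t(R))^2)))
  }
  tri <- function(p3) mkChain("A", "AAA",
    list(list(CA = c(0, 0, 0)), list(CA = c(3.8, 0, 0)), list(CA = p3)))
  m1 <- list(tri(c(1.9, 3.3, 0)))
  m2 <- list(tri(c(1.9, 6.3, 0)))   # third point displaced 3 A
  # bio3d::rmsd reports three decimals, hence the coarse tolerance
  expect_equal(superposeRmsd(m1, m2),
               kabschRmsd(caCoords(m1[[1]]), caCoords(m2[[1]])),
               tolerance = 1e-3)
  expect_error(superposeRmsd(m1, list(lineChain("A", 4))), "length mismatch")
})

test_that("extra restraints beyond the true map degrade recovered accuracy", {
  sp <- syntheticSpec(L = 30, seed = 4)
  cx <- makeComplex(sp)
  native <- cx$chains[c("A", cx$partnerId)]
  truePairs <- contactPairs(cx$inter)
  set.seed(99)
  junk <- cbind(sample(1:10, 8, TRUE), sample(1:10, 8, TRUE))
  cfg <- annealConfig(restarts = 3L)
  rmsOf <- function(pairs, seeds) vapply(seeds, function(s)
    superposeRmsd(annealDimer(cx$monomer, pairs, cfg, seed = s)$model,
                  native), numeric(1))
  clean <- rmsOf(truePairs, 1:3)
  noisy <- rmsOf(rbind(truePairs, junk), 1:3)
  expect_lt(median(clean), median(noisy))
})
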