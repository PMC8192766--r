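test_that("monomer generation is deterministic and geometrically sane", {
  sp <- syntheticSpec(L = 30, seed = 4)
  m1 <- makeMonomer(sp)
  m2 <- makeMonomer(sp)
  expect_identical(atomTable(m1), atomTable(m2))
  expect_identical(chainSeq(m1), chainSeq(m2))
  ca <- caCoords(m1)
  steps <- sqrt(rowSums(diff(ca)^2))
  expect_true(all(abs(steps - 3.8) < 0.1))   # ideal helix rise/turn
  w <- makeMonomer(syntheticSpec(L = 25, fold = "walk", seed = 9))
  caw <- caCoords(w)
  expect_true(all(abs(sqrt(rowSums(diff(caw)^2)) - 3.8) < 1e-6))
  # self-avoidance between non-neighbours
  d2 <- as.matrix(dist(caw))
  far <- abs(row(d2) - col(d2)) > 1
  expect_true(min(d2[far]) >= 3.5)
  expect_error(syntheticSpec(L = 5), ">= 12")
})

test_that("complex generation validates placement and returns truth maps", {
  cx <- makeComplex(syntheticSpec(L = 40, nCopies = 4, seed = 2))
  expect_named(cx$chains, c("A", "B", "C", "D"))
  expect_true(cx$partnerId %in% c("B", "C", "D"))
  expect_gt(nContacts(cx$inter), 0)
  expect_s4_class(cx$intra, "ContactMap")
  # contact-free placement is rejected with a diagnostic
  farSpec <- syntheticSpec(L = 20, seed = 1,
                           transform = rigidTransform(diag(3), c(50, 0, 0)))
  expect_error(makeComplex(farSpec), "no interchain contact")
  # collapsed placement is rejected
  tight <- syntheticSpec(L = 20, seed = 1,
                         transform = rigidTransform(diag(3), c(0.5, 0, 0)))
  expect_error(makeComplex(tight), "steric collapse")
})

test_that("fabricated predictions mix intrachain and folded interchain truth", {
  spTrue <- syntheticSpec(L = 40, seed = 1, intraKeep = 1, interKeep = 1,
                          fpRate = 0, noiseSd = 0)
  cx <- makeComplex(spTrue)
  pred <- fabricatePrediction(cx$intra, cx$inter, spTrue)
  pi_ <- contactPairs(cx$intra)
  pe <- contactPairs(cx$inter)
  folded <- unique(cbind(pmin(pe[, 1], pe[, 2]), pmax(pe[, 1], pe[, 2])))
  folded <- folded[folded[, 1] != folded[, 2], , drop = FALSE]
  want <- unique(rbind(pi_, folded))
  it <- predItems(pred)
  expect_setequal(paste(it$i, it$j), paste(want[, 1], want[, 2]))
  expect_true(all(it$score == 0.8))
  # keep rates 0: only false positives, none of them true
  spFP <- syntheticSpec(L = 40, seed = 1, intraKeep = 0, interKeep = 0,
                        fpRate = 0.05, noiseSd = 0)
  fp <- predItems(fabricatePrediction(cx$intra, cx$inter, spFP))
  expect_false(any(paste(fp$i, fp$j) %in% paste(want[, 1], want[, 2])))
  expect_true(all(fp$score == 0.3))
})

test_that("noiseless fixtures reduce to the folded interchain truth after relax removal", {
  sp <- syntheticSpec(L = 36, seed = 6, intraKeep = 1, interKeep = 1,
                      fpRate = 0, noiseSd = 0)
  cx <- makeComplex(sp)
  pred <- fabricatePrediction(cx$intra, cx$inter, sp)
  pe <- contactPairs(cx$inter)
  folded <- unique(cbind(pmin(pe[, 1], pe[, 2]), pmax(pe[, 1], pe[, 2])))
  surv <- predItems(inferInterchain(pred, cx$intra, n = 0))
  expect_setequal(paste(surv$i, surv$j), paste(folded[, 1], folded[, 2]))
})

test_that("more false positives means a lower hit fraction among survivors", {
  hitFrac <- function(fpRate) {
    vals <- vapply(1:6, function(seed) {
      sp <- syntheticSpec(L = 36, seed = seed, fpRate = fpRate)
      cx <- makeComplex(sp)
      pred <- fabricatePrediction(cx$intra, cx$inter, sp)
      surv <- predItems(inferInterchain(pred, cx$intra, n = 2))
      mean(relaxedMatch(surv$i, surv$j, cx$inter, n = 0))
    }, numeric(1))
    mean(vals)
  }
  expect_gt(hitFrac(0.01), hitFrac(0.30))
})
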