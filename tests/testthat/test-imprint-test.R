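test_that("Fisher's exact test matches its closed-form extremes", {
  expect_equal(fisherExact2x2(47, 0, 0, 47)$p, 2 / choose(94, 47))
  expect_equal(fisherExact2x2(5, 5, 5, 5)$p, 1)
  r <- fisherExact2x2(19, 0, 2, 9)
  expect_lt(r$p, 0.05)
  expect_lte(r$p, 0.045042863)  # raw p cannot exceed its adjusted value
  expect_error(fisherExact2x2(0, 0, 0, 0), "zero")
})

test_that("odds ratios follow the zero-cell convention", {
  expect_equal(fisherExact2x2(6, 3, 2, 4)$oddsRatio, 24 / 6)
  expect_identical(fisherExact2x2(5, 0, 0, 5)$oddsRatio, Inf)
  expect_identical(fisherExact2x2(0, 5, 5, 0)$oddsRatio, 0)
  expect_equal(fisherExact2x2(5, 0, 0, 5)$oddsRatioHA,
               (5.5 * 5.5) / (0.5 * 0.5))
})

test_that("Fisher p agrees with enumeration and stats::fisher.test on random tables", {
  set.seed(11)
  for (i in 1:150) {
    t <- rmultinom(1, sample(1:40, 1), prob = runif(4))[, 1]
    if (sum(t) == 0) next
    p <- fisherExact2x2(t[1], t[2], t[3], t[4])$p
    expect_equal(p, bruteFisherP(t[1], t[2], t[3], t[4]), tolerance = 1e-12)
    ft <- stats::fisher.test(matrix(t, 2, byrow = TRUE))
    expect_equal(p, ft$p.value, tolerance = 1e-9)
  }
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bhAdjust(0.02), 0.02)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(c(0.5, 1.0)), c(1.0, 1.0))
  expect_error(bhAdjust(c(0.5, 1.2)), "0, 1")
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(1:400, 1))^sample(1:3, 1)
    expect_equal(bhAdjust(p), naiveBH(p))
  }
})

test_that("the TRUE-SNP rule combines FDR, reciprocal AF and confirming coverage", {
  des <- jxoDesign()
  # clean reciprocal site: TRUE and maternal (discovered in JXO)
  cand <- mkCandidate(47, 0, 0, 47)
  r <- callTrueSnps(cand, des)
  expect_equal(r$status, "TRUE")
  expect_equal(r$origin, "MATERNAL")
  expect_equal(r$failReasons, "")
  expect_gte(r$fdr, r$p)

  # confirming AF above 0.20: reciprocal_af_fail
  r <- callTrueSnps(mkCandidate(85, 15, 22, 78), des)
  expect_equal(r$status, "FALSE")
  expect_match(r$failReasons, "reciprocal_af_fail")
  expect_equal(r$origin, "UNASSIGNED")

  # near-identical allele fractions: Fisher p ~ 1, fails the FDR gate
  r <- callTrueSnps(mkCandidate(9, 1, 8, 2), des)
  expect_equal(r$status, "FALSE")
  expect_match(r$failReasons, "low_fdr_fail")

  # zero confirming coverage can never be TRUE
  r <- callTrueSnps(mkCandidate(40, 0, 0, 0), des)
  expect_equal(r$status, "FALSE")
  expect_match(r$failReasons, "unconfirmed_low_coverage")

  # candidates that still qualify in both crosses must be excluded first
  both <- mkCandidate(40, 0, 38, 0, discovering = "both")
  expect_error(callTrueSnps(both, des), "excludeStrainVariants")
})

test_that("BH family can be pooled or per discovering cross", {
  cand <- rbind(mkCandidate(12, 0, 0, 12, pos = 1L),
                mkCandidate(11, 1, 1, 11, pos = 2L),
                mkCandidate(0, 12, 12, 0, "B", pos = 3L))
  pooled <- callTrueSnps(cand, jxoDesign(), fdrFamily = "pooled")
  expect_equal(pooled$fdr, bhAdjust(pooled$p))
  per <- callTrueSnps(cand, jxoDesign(), fdrFamily = "per_cross")
  iA <- per$discoveringCross == "A"
  expect_equal(per$fdr[iA], bhAdjust(per$p[iA]))
  expect_equal(per$fdr[!iA], bhAdjust(per$p[!iA]))
})

test_that("parental origin follows the alternative strain's role in the discovering cross", {
  des <- jxoDesign()
  expect_equal(assignOrigin("JXO", des), "MATERNAL")
  expect_equal(assignOrigin("OXJ", des), "PATERNAL")
  expect_error(assignOrigin("AXB", des), "absent")
  # swapping the cross labels flips the roles
  des2 <- swapCrosses(des)
  expect_equal(assignOrigin("JXO", des2), "PATERNAL")
  expect_equal(assignOrigin("OXJ", des2), "MATERNAL")
})

test_that("relabelling the crosses flips every origin and nothing else", {
  cfg <- syntheticConfig(nGenes = 40, fractionMaternal = 0.2,
                         fractionPaternal = 0.2, fractionLeaky = 0.05,
                         nStrainVariantSites = 10)
  sim <- simulateReciprocalCross(cfg, 99)
  des <- sim$design
  r1 <- callTrueSnps(excludeStrainVariants(
    findCandidates(sim$countsA, sim$countsB))$kept, des)
  cA <- sim$countsA; cB <- sim$countsB
  crossId(cA) <- "OXJ"; crossId(cB) <- "JXO"
  r2 <- callTrueSnps(excludeStrainVariants(
    findCandidates(cB, cA))$kept, des)
  r2 <- r2[match(r1$snpId, r2$snpId), ]
  expect_equal(r1$status, r2$status)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$fdr, r2$fdr)
  isT <- r1$status == "TRUE"
  expect_true(all(isT == (r2$status == "TRUE")))
  flip <- c(MATERNAL = "PATERNAL", PATERNAL = "MATERNAL")
  expect_equal(unname(flip[r1$origin[isT]]), r2$origin[isT])
})

test_that("under an all-biallelic null the realized FDP stays within the BH guarantee", {
  nTrueCalls <- 0; nSites <- 0
  for (seed in 1:20) {
    cfg <- syntheticConfig(nGenes = 30, fractionMaternal = 0,
                           fractionPaternal = 0, fractionLeaky = 0,
                           nStrainVariantSites = 0)
    sim <- simulateReciprocalCross(cfg, seed)
    r <- callTrueSnps(excludeStrainVariants(
      findCandidates(sim$countsA, sim$countsB))$kept, sim$design)
    nTrueCalls <- nTrueCalls + sum(r$status == "TRUE")
    nSites <- nSites + nrow(sim$truth$snps)
  }
  expect_gt(nSites, 5000)
  # every TRUE call here is a miscall; realized FDP pooled over replicates
  fdp <- nTrueCalls / max(1L, nTrueCalls)
  expect_lte(fdp, 0.10)
  expect_lte(nTrueCalls / nSites, 0.001)
})

test_that("alternative-strain concordance reports integer percentages", {
  expect_equal(altStrainConcordance(502, 527)$percent, 95)
  expect_equal(altStrainConcordance(330, 334)$percent, 99)
  expect_equal(altStrainConcordance(0, 10)$percent, 0)
  expect_error(altStrainConcordance(1, 0), "empty")
})
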