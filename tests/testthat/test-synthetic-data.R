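test_that("configuration is validated", {
  expect_error(syntheticConfig(fractionMaternal = 0.7,
                               fractionPaternal = 0.4), "fractions")
  expect_error(syntheticConfig(seqError = 0.5), "seqError")
  expect_error(syntheticConfig(coverageMean = 0), "coverageMean")
  expect_error(syntheticConfig(leakRange = c(0.3, 0.2)), "leakRange")
})

test_that("a noise-free maternal gene gives fully reciprocal counts", {
  cfg <- syntheticConfig(nGenes = 1, fractionMaternal = 1,
                         fractionPaternal = 0, fractionLeaky = 0,
                         snpRatePerKb = 0.01, minSnpsImprinted = 1,
                         coverageMean = 40, seqError = 0,
                         nStrainVariantSites = 0, sampling = "expected")
  sim <- simulateReciprocalCross(cfg, 5)
  expect_equal(length(sim$countsA), 1L)
  expect_equal(altCount(sim$countsA), 40L)
  expect_equal(refCount(sim$countsA), 0L)
  expect_equal(altCount(sim$countsB), 0L)
  expect_equal(refCount(sim$countsB), 40L)
})

test_that("biallelic sites fluctuate around one half", {
  cfg <- syntheticConfig(nGenes = 1, fractionMaternal = 0,
                         fractionPaternal = 0, fractionLeaky = 0,
                         geneLengthBp = 50000, snpRatePerKb = 20,
                         coverageMean = 40, coverageDispersion = Inf,
                         seqError = 0, nStrainVariantSites = 0)
  sim <- simulateReciprocalCross(cfg, 8)
  n <- length(sim$countsA)
  expect_gt(n, 500)
  af <- altCount(sim$countsA) / siteCoverage(sim$countsA)
  se <- sqrt(0.25 / mean(siteCoverage(sim$countsA))) / sqrt(n)
  expect_lt(abs(mean(af) - 0.5), 3 * se)
})

test_that("identical config and seed give byte-identical outputs", {
  cfg <- syntheticConfig(nGenes = 15, fractionMaternal = 0.2,
                         fractionPaternal = 0.2, nPseudogeneDecoys = 1,
                         extensionSpec = list(list()))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeSimulation(simulateReciprocalCross(cfg, 123), d1)
  writeSimulation(simulateReciprocalCross(cfg, 123), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # and a different seed changes the data
  s3 <- simulateReciprocalCross(cfg, 124)
  s1 <- simulateReciprocalCross(cfg, 123)
  expect_false(identical(as.data.frame(s1$countsA),
                         as.data.frame(s3$countsA)))
})

test_that("appending loci does not perturb earlier genes' draws", {
  base <- syntheticConfig(nGenes = 30, fractionMaternal = 3 / 30,
                          fractionPaternal = 3 / 30, fractionLeaky = 0,
                          nStrainVariantSites = 0)
  more <- syntheticConfig(nGenes = 40, fractionMaternal = 3 / 40,
                          fractionPaternal = 3 / 40, fractionLeaky = 0,
                          nStrainVariantSites = 5, nPseudogeneDecoys = 1)
  s1 <- simulateReciprocalCross(base, 77)
  s2 <- simulateReciprocalCross(more, 77)
  g30 <- sprintf("gene%04d", 1:30)
  a <- s1$truth$snps[s1$truth$snps$gene %in% g30, ]
  b <- s2$truth$snps[s2$truth$snps$gene %in% g30, ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("the global RNG stream is left untouched by simulation", {
  set.seed(1); before <- runif(1)
  set.seed(1)
  invisible(simulateReciprocalCross(syntheticConfig(nGenes = 3), 9))
  expect_equal(runif(1), before)
})

test_that("call scoring counts confusion cells exactly", {
  cfg <- syntheticConfig(nGenes = 10, fractionMaternal = 0.2,
                         fractionPaternal = 0.1, fractionLeaky = 0.1,
                         nStrainVariantSites = 0, sampling = "expected",
                         seqError = 0)
  sim <- simulateReciprocalCross(cfg, 31)
  run <- runPipeline(sim$countsA, sim$countsB, sim$design, sim$models)
  ev <- evaluateCalls(run$snps, run$transcripts, sim$truth)
  # noise-free: every imprinted SNP recovered, nothing else called
  expect_equal(ev$snpSensitivity, 1)
  expect_equal(ev$snpFdp, 0)
  expect_equal(ev$geneSensitivity, 1)
  expect_equal(ev$originAccuracy, 1)
  # a leaky gene called nothing is a correct rejection
  leaky <- sim$truth$genes$gene[sim$truth$genes$status == "LEAKY"]
  expect_gte(length(leaky), 1)
  expect_false(any(run$transcripts$geneName %in% leaky))
  expect_equal(ev$geneSpecificity, 1)

  # all-biallelic calls: sensitivity zero
  ev0 <- evaluateCalls(run$snps[0, ], run$transcripts[0, ], sim$truth)
  expect_equal(ev0$snpSensitivity, 0)
  # foreign site keys are a validation error
  bad <- run$snps
  bad$snpId[1] <- "chrZ_1"
  expect_error(evaluateCalls(bad, run$transcripts, sim$truth),
               "key mismatch")
})

test_that("simulated strand counts agree with the transcript strand", {
  cfg <- syntheticConfig(nGenes = 6, fractionMaternal = 0.5,
                         fractionPaternal = 0.5, fractionLeaky = 0,
                         nStrainVariantSites = 0,
                         sampling = "expected", seqError = 0)
  sim <- simulateReciprocalCross(cfg, 12)
  snps <- sim$truth$snps
  plusGenes <- snps$strand == "+"
  expect_true(all(snps$minusA[plusGenes] == 0))
  expect_true(all(snps$plusA[!plusGenes] == 0))
})
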