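mkModels <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    transcriptId = df$id, geneName = df$id,
    exons = methods::as(IRanges::ranges(gr), "IRangesList"))
  gr
}

annotatedFixture <- function() {
  models <- mkModels(data.frame(
    chrom = "chr12", start = c(110779000, 110830000, 110830000),
    end = c(110798000, 110840000, 110840000),
    strand = c("+", "+", "-"),
    id = c("Meg3", "Rtl1", "Rtl1as")))
  cand <- rbind(
    mkCandidate(139, 0, 0, 118, pos = 110783337L, chrom = "chr12"),
    mkCandidate(20, 0, 0, 22, pos = 110831619L, chrom = "chr12"),
    mkCandidate(30, 0, 0, 25, pos = 110900000L, chrom = "chr12"))
  tested <- callTrueSnps(cand, jxoDesign())
  list(models = models, tested = tested)
}

test_that("SNPs map to spanning transcripts; outside SNPs are intergenic", {
  fx <- annotatedFixture()
  ann <- annotateSnps(fx$tested, fx$models)
  meg <- ann[ann$pos == 110783337, ]
  expect_equal(meg$transcriptId, "Meg3")
  expect_equal(meg$txStrand, "+")
  # a SNP inside two overlapping opposite-strand models maps to both
  rtl <- ann[ann$pos == 110831619, ]
  expect_setequal(rtl$transcriptId, c("Rtl1", "Rtl1as"))
  # and the downstream SNP is intergenic
  expect_true(ann$intergenic[ann$pos == 110900000])
})

test_that("exonic-only annotation drops intronic SNPs", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 1000),
                               strand = "+")
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    transcriptId = "tx", geneName = "tx",
    exons = IRanges::IRangesList(IRanges::IRanges(c(100, 900),
                                                  c(200, 1000))))
  tested <- callTrueSnps(rbind(mkCandidate(20, 0, 0, 20, pos = 150L),
                               mkCandidate(20, 0, 0, 20, pos = 500L)),
                         jxoDesign())
  annSpan <- annotateSnps(tested, gr)
  expect_equal(sum(!annSpan$intergenic), 2L)
  annEx <- annotateSnps(tested, gr, exonicOnly = TRUE)
  expect_true(annEx$intergenic[annEx$pos == 500])
  expect_false(annEx$intergenic[annEx$pos == 150])
})

test_that("transcript aggregation computes counts, means, consensus and representative", {
  des <- jxoDesign()
  cand <- rbind(mkCandidate(8, 2, 0, 10, pos = 110783100L, chrom = "chr12"),
                mkCandidate(18, 2, 0, 20, pos = 110783200L, chrom = "chr12"),
                mkCandidate(28, 2, 0, 30, pos = 110783300L, chrom = "chr12"))
  tested <- callTrueSnps(cand, des)
  expect_true(all(tested$status == "TRUE"))
  models <- mkModels(data.frame(chrom = "chr12", start = 110783000,
                                end = 110784000, strand = "+", id = "Meg3"))
  ann <- annotateSnps(tested, models)
  call <- aggregateTranscripts(ann)
  expect_equal(call$nTrueSnps, 3L)
  expect_equal(call$meanReadsPerSnp, 20)  # combined means 10, 20, 30
  expect_equal(call$consensusOrigin, "MATERNAL")
  expect_equal(call$representativeSnp, "chr12_110783300")
  # permutation invariance
  ann2 <- ann[sample(nrow(ann)), ]
  expect_equal(aggregateTranscripts(ann2), call)
})

test_that("opposite-origin SNPs on one transcript give CONFLICT; single SNP is its own representative", {
  models <- mkModels(data.frame(chrom = "chr1", start = 100, end = 1000,
                                strand = "+", id = "tx"))
  cand <- rbind(mkCandidate(20, 0, 0, 20, pos = 200L),
                mkCandidate(0, 20, 20, 0, "B", pos = 300L))
  tested <- callTrueSnps(cand, jxoDesign())
  call <- aggregateTranscripts(annotateSnps(tested, models))
  expect_equal(call$consensusOrigin, "CONFLICT")

  one <- callTrueSnps(mkCandidate(20, 0, 0, 20, pos = 200L), jxoDesign())
  call1 <- aggregateTranscripts(annotateSnps(one, models))
  expect_equal(call1$representativeSnp, "chr1_200")
  # transcripts without TRUE SNPs emit no call
  none <- callTrueSnps(mkCandidate(9, 1, 8, 2, pos = 200L), jxoDesign())
  expect_equal(nrow(aggregateTranscripts(annotateSnps(none, models))), 0L)
})

test_that("catalogue bookkeeping identities hold and reproduce the published tallies", {
  t1 <- exampleKnownGenes()
  tested <- callTrueSnps(candidatesFromExample(t1), jxoDesign())
  calls <- aggregateTranscripts(annotateSnps(tested, exampleGeneModels(t1)))
  cs <- summarizeCatalogue(calls, exampleCatalogue())
  expect_equal(cs$nEvaluable, 117)
  expect_equal(cs$nNoCall, 66)
  expect_equal(cs$nNoCallLowExpression, 61)
  expect_equal(cs$nNoCallNoSnp, 5)
  expect_equal(cs$nFound, 32)
  expect_equal(cs$nNotConfirmed, 19)
  expect_equal(cs$nCatalogue - cs$nExcludedSmallRna - cs$nExcludedNotGenuine -
                 cs$nExcludedDuplicate, cs$nEvaluable)
  # identities hold on arbitrary subsets too
  set.seed(3)
  for (i in 1:5) {
    sub <- exampleCatalogue()[sample(152, sample(10:152, 1)), ]
    s <- summarizeCatalogue(calls, sub)
    expect_equal(s$nFound + s$nNoCall + s$nNotConfirmed, s$nEvaluable)
  }
  # empty catalogue -> all zero
  s0 <- summarizeCatalogue(calls, exampleCatalogue()[0, ])
  expect_equal(s0$nEvaluable, 0)
  # unknown category labels are rejected
  badCat <- exampleCatalogue()
  badCat$category[1] <- "mystery"
  expect_error(summarizeCatalogue(calls, badCat), "category")
})
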