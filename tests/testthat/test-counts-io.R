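test_that("counts-TSV round-trips and is returned sorted", {
  ac <- mkCounts(c(500L, 100L, 300L), ref = c(1L, 2L, 3L),
                 alt = c(10L, 20L, 30L), crossId = "JXO")
  expect_equal(sitePositions(ac), c(100L, 300L, 500L))  # sorting contract
  f <- withr::local_tempfile(fileext = ".tsv")
  writeAlleleCounts(ac, f)
  back <- readAlleleCounts(f, "JXO")
  expect_equal(as.data.frame(back), as.data.frame(ac))
  expect_equal(crossId(back), "JXO")
})

test_that("counts reader rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  header <- "chrom\tpos\tref\talt\tref_count\talt_count\tplus_count\tminus_count"
  # empty file with valid header -> empty collection
  writeLines(header, f)
  expect_length(readAlleleCounts(f, "JXO"), 0)
  # negative count -> validation error
  writeLines(c(header, "chr1\t10\tA\tG\t5\t-1\tNA\tNA"), f)
  expect_error(readAlleleCounts(f, "JXO"), "negative")
  # duplicate site -> validation error
  writeLines(c(header, "chr1\t10\tA\tG\t5\t5\tNA\tNA",
               "chr1\t10\tA\tC\t2\t2\tNA\tNA"), f)
  expect_error(readAlleleCounts(f, "JXO"), "duplicate")
  # wrong header -> error naming the dialect
  writeLines("a\tb\tc", f)
  expect_error(readAlleleCounts(f, "JXO"), "header")
})

test_that("AlleleCounts enforces its invariants", {
  expect_error(mkCounts(0L, 1L, 1L, "JXO"), "1")        # pos >= 1
  expect_error(AlleleCounts("chr1", 5L, "A", "A", 1L, 1L, crossId = "x"),
               "differ")
  expect_error(AlleleCounts("chr1", 5L, "A", "G", 4L, 4L,
                            plusCount = 3L, minusCount = 3L, crossId = "x"),
               "plusCount")
  ok <- AlleleCounts("chr1", 5L, "A", "G", 4L, 4L,
                     plusCount = 6L, minusCount = 2L, crossId = "x")
  expect_equal(siteCoverage(ok), 8L)
  expect_equal(siteKey(ok), "chr1_5")
})

test_that("base-quality filtering keeps only reads at or above threshold", {
  # no filtering: 12 reads all at q40, 8 alt / 4 ref
  r <- filterBaseQuality(rep(c("G", "A"), c(8, 4)), rep(40, 12), "A", "G")
  expect_equal(r$altCount, 8)
  expect_equal(r$refCount, 4)
  # 5 of 12 reads at q12 are dropped; the 7 at q>=13 are counted
  quals <- c(rep(12, 5), rep(30, 7))
  bases <- c(rep("G", 6), rep("A", 6))
  r <- filterBaseQuality(bases, quals, "A", "G")
  expect_equal(r$refCount + r$altCount, 7)
  expect_equal(r$altCount, 1)   # hand count: one alt read passes
  # all reads below threshold -> (0, 0)
  r <- filterBaseQuality(rep("G", 6), rep(5, 6), "A", "G")
  expect_equal(c(r$refCount, r$altCount), c(0, 0))
  # third bases are excluded from counts but tallied
  r <- filterBaseQuality(c("G", "C", "A"), rep(40, 3), "A", "G")
  expect_equal(r$otherCount, 1)
  expect_equal(r$refCount + r$altCount, 2)
})

test_that("raising the quality threshold never increases any count", {
  set.seed(42)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    bases <- sample(c("A", "G", "C", "a", "g"), n, replace = TRUE)
    quals <- sample(0:45, n, replace = TRUE)
    prev <- filterBaseQuality(bases, quals, "A", "G", minQuality = 0)
    for (q in c(5, 13, 20, 35, 50)) {
      cur <- filterBaseQuality(bases, quals, "A", "G", minQuality = q)
      expect_lte(cur$refCount, prev$refCount)
      expect_lte(cur$altCount, prev$altCount)
      prev <- cur
    }
  }
})

test_that("mpileup text is parsed with qualities, strand and indels", {
  f <- withr::local_tempfile(fileext = ".pileup")
  # 8 plus-strand alt (G, q40 'I'), 4 minus-strand ref (',' q40)
  # plus one read-start marker, one read-end and one insertion to skip
  l1 <- paste("chr1", 100, "A", 12,
              "^IGGGGGGGG+2AC,,,$,", paste(rep("I", 12), collapse = ""),
              sep = "\t")
  # 5 low-quality reads (q12 = '-') among 12: only 7 counted
  l2 <- paste("chr1", 200, "A", 12,
              "GGGGGGaaaaaa",
              paste(c(rep("-", 5), rep("I", 7)), collapse = ""), sep = "\t")
  # all reads reference -> no alternative allele, site dropped
  l3 <- paste("chr1", 300, "A", 4, "....", "IIII", sep = "\t")
  writeLines(c(l1, l2, l3), f)
  ac <- readMpileup(f, "JXO")
  expect_equal(length(ac), 2L)
  df <- as.data.frame(ac)
  expect_equal(df$alt_count[df$pos == 100], 8)
  expect_equal(df$ref_count[df$pos == 100], 4)
  expect_equal(df$plus_count[df$pos == 100], 8)
  expect_equal(df$minus_count[df$pos == 100], 4)
  expect_equal(df$ref_count[df$pos == 200] + df$alt_count[df$pos == 200], 7)
})

test_that("library stats reproduce the printed alignment percentages", {
  expect_equal(libraryStats(95517702, 76712608)$alignedPct, 80.3)
  expect_equal(libraryStats(117618284, 86369632)$alignedPct, 73.4)
  s <- libraryStats(100, 100, 100)
  expect_equal(c(s$alignedPct, s$sensePct), c(100, 100))
  expect_error(libraryStats(0, 0), "zero")
  expect_error(libraryStats(10, 20), "exceeds")
})

test_that("read-pair orientation codes map to transcript strands", {
  expect_equal(strandFromOrientation(c("F2R1", "R1F2")),
               c("antisense", "antisense"))
  expect_equal(strandFromOrientation(c("F1R2", "R2F1")), c("sense", "sense"))
  expect_error(strandFromOrientation("XYZ"), "unknown")
})

test_that("annotation readers build stranded gene models", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr12\t110779000\t110798000\tMeg3\t0\t+", bed)
  gm <- readAnnotation(bed)
  expect_equal(length(gm), 1L)
  expect_equal(as.character(GenomicRanges::strand(gm)), "+")
  expect_equal(S4Vectors::mcols(gm)$transcriptId, "Meg3")
  expect_equal(GenomicRanges::start(gm), 110779001L)  # BED is 0-based

  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste0("chr1\tsrc\texon\t100\t200\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1"; gene_name "G1";'),
    paste0("chr1\tsrc\texon\t400\t500\t.\t+\t.\t",
           'gene_id "g1"; transcript_id "t1"; gene_name "G1";')), gtf)
  gm <- readAnnotation(gtf)
  expect_equal(length(gm), 1L)
  expect_equal(lengths(S4Vectors::mcols(gm)$exons), 2L,
               ignore_attr = TRUE)
  expect_equal(GenomicRanges::start(gm), 100L)
  expect_equal(GenomicRanges::end(gm), 500L)

  bed3 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", bed3)
  expect_error(readAnnotation(bed3), "strand")
})
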