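#' Configuration for the synthetic reciprocal-cross generator
#'
#' Defines the simulated study conditions: how many genes, which fractions
#' are maternally/paternally expressed or leaky, SNP density, the
#' negative-binomial coverage model, the sequencing/cross-mapping error rate,
#' and the decoy structures (strain-homozygous variant sites, pseudogene
#' read-misassignment mixtures, biallelic genes with one aberrant SNP,
#' imprinted transcript extensions).
#'
#' Defaults model a deeply sequenced fibroblast transcriptome of a
#' JF1-by-reference-strain reciprocal cross: 500 expressed genes of which 20
#' are maternal, 20 paternal and 5 leaky (21-25% expression from the
#' nominally silenced maternal allele), ~2 informative SNPs per kb along 5 kb
#' transcripts with at least 3 SNPs per imprinted gene, mean per-site
#' coverage 30 with negative-binomial overdispersion (size 5), and a 1%
#' combined sequencing/cross-mapping error.
#'
#' @param nGenes Number of annotated genes.
#' @param fractionMaternal,fractionPaternal,fractionLeaky Fractions of genes
#'   with maternal, paternal, or leaky (paternally biased) expression; the
#'   remainder is biallelic. Counts are fixed at construction
#'   (`round(fraction * nGenes)`).
#' @param leakRange Range of the maternal leak fraction for leaky genes.
#' @param geneLengthBp,interGeneGapBp Gene length and intergenic spacing.
#' @param snpRatePerKb Poisson rate of informative SNP placement.
#' @param minSnpsImprinted Minimum SNPs guaranteed on imprinted/leaky genes.
#' @param coverageMean,coverageDispersion Negative-binomial mean and size of
#'   per-site coverage (size = Inf gives Poisson-like, effectively fixed at
#'   the mean in `"expected"` sampling).
#' @param seqError Sequencing + cross-mapping error epsilon in \[0, 0.1\]: the
#'   probability that a read reports the silenced allele.
#' @param senseFraction Fraction of reads assigned to the transcript's sense
#'   strand (strand-specific protocol fidelity), default 0.9.
#' @param nStrainVariantSites Standalone sites homozygous-alternative in both
#'   crosses (strain variants, not imprinting).
#' @param nPseudogeneDecoys Pseudogene read-misassignment loci: ~30 SNPs over
#'   1.1 kb, most shared by both crosses, two uniparental.
#' @param nAberrantDecoys Biallelic genes carrying one aberrant uniparental
#'   SNP.
#' @param extensionSpec Optional list of extension descriptors, each a list
#'   with `parent` (gene name, or `NA` to auto-pick imprinted genes in
#'   order), `lengthBp`, `coverageScale`, `gapBp`.
#' @param sampling `"binomial"` (default) draws coverages and allele counts
#'   stochastically; `"expected"` is the noise-free limit: coverage fixed at
#'   `coverageMean` and alternative counts `floor(f * coverage)`, truncating
#'   toward the silenced allele so a leaky gene's AF never exceeds `1 -
#'   theta`.
#' @param chrom Name of the synthetic chromosome.
#' @return A validated list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(nGenes = 500,
                            fractionMaternal = 0.04,
                            fractionPaternal = 0.04,
                            fractionLeaky = 0.01,
                            leakRange = c(0.21, 0.25),
                            geneLengthBp = 5000,
                            interGeneGapBp = 50000,
                            snpRatePerKb = 2,
                            minSnpsImprinted = 3,
                            coverageMean = 30,
                            coverageDispersion = 5,
                            seqError = 0.01,
                            senseFraction = 0.9,
                            nStrainVariantSites = 50,
                            nPseudogeneDecoys = 0,
                            nAberrantDecoys = 0,
                            extensionSpec = NULL,
                            sampling = c("binomial", "expected"),
                            chrom = "simChr1") {
  sampling <- match.arg(sampling)
  fr <- fractionMaternal + fractionPaternal + fractionLeaky
  if (fr > 1) .valErr("state fractions sum above 1: infeasible config")
  if (seqError < 0 || seqError > 0.1) .valErr("seqError must be in [0, 0.1]")
  if (coverageMean <= 0) .valErr("coverageMean must be positive")
  if (length(leakRange) != 2L || leakRange[1] > leakRange[2] ||
      leakRange[1] <= 0 || leakRange[2] >= 0.5) {
    .valErr("leakRange must be an increasing pair inside (0, 0.5)")
  }
  cfg <- list(
    nGenes = nGenes,
    nMaternal = round(fractionMaternal * nGenes),
    nPaternal = round(fractionPaternal * nGenes),
    nLeaky = round(fractionLeaky * nGenes),
    leakRange = leakRange,
    geneLengthBp = geneLengthBp, interGeneGapBp = interGeneGapBp,
    snpRatePerKb = snpRatePerKb, minSnpsImprinted = minSnpsImprinted,
    coverageMean = coverageMean, coverageDispersion = coverageDispersion,
    seqError = seqError, senseFraction = senseFraction,
    nStrainVariantSites = nStrainVariantSites,
    nPseudogeneDecoys = nPseudogeneDecoys,
    nAberrantDecoys = nAberrantDecoys,
    extensionSpec = extensionSpec,
    sampling = sampling, chrom = chrom)
  class(cfg) <- "syntheticConfig"
  cfg
}

## internal: per-locus substream seed, deterministic in (rootSeed, index) so
## appending loci never perturbs earlier loci's draws; kept below 2^31
.geneSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 69069 + as.numeric(i) * 104729) %%
               2147483629) + 1L
}

## internal: draw coverage vector under the config's model
.drawCoverage <- function(n, cfg, scale = 1) {
  mu <- cfg$coverageMean * scale
  if (cfg$sampling == "expected") return(rep(round(mu), n))
  if (is.infinite(cfg$coverageDispersion)) {
    stats::rpois(n, mu)
  } else {
    stats::rnbinom(n, mu = mu, size = cfg$coverageDispersion)
  }
}

## internal: alternative-allele counts given coverage and alt fraction f
.drawAlt <- function(cov, f, cfg) {
  if (cfg$sampling == "expected") return(as.integer(floor(f * cov)))
  stats::rbinom(length(cov), cov, f)
}

## internal: strand breakdown for reads of a transcript on `strand`
.drawStrand <- function(cov, strand, cfg) {
  if (cfg$sampling == "expected") {
    sense <- cov
  } else {
    sense <- stats::rbinom(length(cov), cov, cfg$senseFraction)
  }
  if (strand == "+") list(plus = sense, minus = cov - sense)
  else list(plus = cov - sense, minus = sense)
}

## internal: alt fraction in both crosses given the maternal expression
## fraction mu (cross A: mother carries alt; cross B: father carries alt)
.altFractions <- function(mu, eps) {
  list(A = mu * (1 - eps) + (1 - mu) * eps,
       B = (1 - mu) * (1 - eps) + mu * eps)
}

#' Simulate reciprocal-cross allele counts with known truth
#'
#' Generates two [AlleleCounts-class] objects (one per reciprocal cross),
#' gene models, and per-gene/per-SNP ground truth under the conditions of a
#' [syntheticConfig()]. Gene states are assigned in blocks (maternal,
#' paternal, leaky, biallelic); at each SNP the alternative-read count is
#' binomial in the cross's expected alternative fraction: `1 - eps` for the
#' expressed-alternative state, `eps` for the silenced-alternative state, 0.5
#' for biallelic, the maternal leak `theta` for leaky genes, and `1 - eps` in
#' both crosses for strain-variant sites. In cross A the maternal strain
#' carries the alternative allele; in cross B the paternal strain does
#' (reciprocal flip). Sites with zero coverage in a cross are absent from
#' that cross's counts, as in a real pileup. Identical `(config, seed)` give
#' byte-identical outputs; each locus has its own deterministic RNG
#' substream, so appending loci leaves earlier loci unchanged.
#'
#' @param config A [syntheticConfig()].
#' @param seed Integer root seed.
#' @return A list with `countsA`, `countsB` ([AlleleCounts-class]),
#'   `models` (`GRanges` gene models, decoys included),
#'   `truth` (list of `genes`, `snps`, `extensions` data frames),
#'   `design` (the [CrossDesign-class] used: JXO/OXJ with JF1 alternative),
#'   and `config`.
#' @export
simulateReciprocalCross <- function(config, seed) {
  stopifnot(inherits(config, "syntheticConfig"))
  cfg <- config
  design <- jxoDesign()
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(oldSeed)) assign(".Random.seed", oldSeed,
                                  envir = globalenv())
  })

  states <- c(rep("MAT", cfg$nMaternal), rep("PAT", cfg$nPaternal),
              rep("LEAKY", cfg$nLeaky),
              rep("BIALLELIC",
                  cfg$nGenes - cfg$nMaternal - cfg$nPaternal - cfg$nLeaky))
  span <- cfg$geneLengthBp + cfg$interGeneGapBp
  eps <- cfg$seqError

  geneRows <- list(); snpRows <- list(); extRows <- list()
  modelRows <- list()
  extQueue <- cfg$extensionSpec

  emitLocus <- function(name, state, start, end, strand, theta, covScale,
                        locusSeed, annotate, snpOverride = NULL) {
    set.seed(locusSeed)
    len <- end - start + 1
    n <- stats::rpois(1, cfg$snpRatePerKb * len / 1000)
    if (state %in% c("MAT", "PAT", "LEAKY")) {
      n <- max(n, cfg$minSnpsImprinted)
    }
    if (!is.null(snpOverride)) n <- snpOverride
    if (n == 0) {
      return(list(snps = NULL))
    }
    pos <- sort(sample(start:end, min(n, len)))
    n <- length(pos)
    mu <- switch(state, MAT = 1, PAT = 0, BIALLELIC = 0.5, LEAKY = theta)
    f <- .altFractions(mu, eps)
    covA <- .drawCoverage(n, cfg, covScale)
    covB <- .drawCoverage(n, cfg, covScale)
    altA <- .drawAlt(covA, f$A, cfg)
    altB <- .drawAlt(covB, f$B, cfg)
    strA <- .drawStrand(covA, strand, cfg)
    strB <- .drawStrand(covB, strand, cfg)
    list(snps = data.frame(
      gene = name, state = state, chrom = cfg$chrom, pos = pos,
      strand = strand, covA = covA, altA = altA,
      plusA = strA$plus, minusA = strA$minus,
      covB = covB, altB = altB, plusB = strB$plus, minusB = strB$minus,
      fA = f$A, fB = f$B, theta = mu, stringsAsFactors = FALSE))
  }

  nextImprinted <- which(states %in% c("MAT", "PAT"))
  autoExtPtr <- 1L

  for (i in seq_len(cfg$nGenes)) {
    start <- as.integer((i - 1) * span + cfg$interGeneGapBp + 1)
    end <- as.integer(start + cfg$geneLengthBp - 1)
    gseed <- .geneSeed(seed, i)
    set.seed(gseed)
    strand <- sample(c("+", "-"), 1)
    theta <- if (states[i] == "LEAKY") {
      stats::runif(1, cfg$leakRange[1], cfg$leakRange[2])
    } else NA_real_
    name <- sprintf("gene%04d", i)
    loc <- emitLocus(name, states[i], start, end, strand, theta, 1,
                     .geneSeed(seed, i * 13 + 1), TRUE)
    geneRows[[i]] <- data.frame(
      gene = name, status = states[i], chrom = cfg$chrom,
      start = start, end = end, strand = strand, theta = theta,
      stringsAsFactors = FALSE)
    modelRows[[length(modelRows) + 1L]] <- geneRows[[i]]
    if (!is.null(loc$snps)) snpRows[[length(snpRows) + 1L]] <- loc$snps
  }

  ## imprinted transcript extensions reuse the parent gene's state at scaled
  ## coverage, downstream of its 3' end
  if (!is.null(extQueue)) {
    for (k in seq_along(extQueue)) {
      ex <- extQueue[[k]]
      lengthBp <- if (!is.null(ex$lengthBp)) ex$lengthBp else 20000
      covScale <- if (!is.null(ex$coverageScale)) ex$coverageScale else 0.3
      gapBp <- if (!is.null(ex$gapBp)) ex$gapBp else 2000
      parentName <- ex$parent
      if (is.null(parentName) || is.na(parentName)) {
        if (autoExtPtr > length(nextImprinted)) {
          .valErr("extensionSpec asks for more parents than imprinted genes")
        }
        parentName <- sprintf("gene%04d", nextImprinted[autoExtPtr])
        autoExtPtr <- autoExtPtr + 1L
      }
      pg <- do.call(rbind, geneRows)
      p <- pg[pg$gene == parentName, , drop = FALSE]
      if (nrow(p) != 1L) .valErr("unknown extension parent: ", parentName)
      if (!p$status %in% c("MAT", "PAT")) {
        .valErr("extension parent must be imprinted: ", parentName)
      }
      if (p$strand == "+") {
        s <- as.integer(p$end + gapBp); e <- as.integer(s + lengthBp - 1)
      } else {
        e <- as.integer(p$start - gapBp); s <- as.integer(e - lengthBp + 1)
      }
      exName <- paste0(parentName, "_ext")
      loc <- emitLocus(exName, p$status, s, e, p$strand, NA_real_, covScale,
                       .geneSeed(seed, 2000000L + k), FALSE,
                       snpOverride = max(
                         2L, stats::rpois(1, cfg$snpRatePerKb *
                                            lengthBp / 1000)))
      if (!is.null(loc$snps)) {
        snpRows[[length(snpRows) + 1L]] <- loc$snps
        extRows[[length(extRows) + 1L]] <- data.frame(
          parent = parentName, chrom = cfg$chrom,
          start = min(loc$snps$pos), end = max(loc$snps$pos),
          strand = p$strand, origin = if (p$status == "MAT") "MATERNAL"
                                      else "PATERNAL",
          nSnps = nrow(loc$snps), stringsAsFactors = FALSE)
      }
    }
  }

  base <- as.integer(cfg$nGenes * span + cfg$interGeneGapBp)

  ## strain-homozygous variant sites: alternative allele in both crosses
  if (cfg$nStrainVariantSites > 0) {
    set.seed(.geneSeed(seed, 3000017L))
    n <- cfg$nStrainVariantSites
    pos <- base + seq_len(n) * 1000L
    covA <- .drawCoverage(n, cfg); covB <- .drawCoverage(n, cfg)
    snpRows[[length(snpRows) + 1L]] <- data.frame(
      gene = "strain_variant", state = "STRAIN_VARIANT", chrom = cfg$chrom,
      pos = pos, strand = "+",
      covA = covA, altA = .drawAlt(covA, 1 - eps, cfg),
      plusA = covA, minusA = 0L,
      covB = covB, altB = .drawAlt(covB, 1 - eps, cfg),
      plusB = covB, minusB = 0L,
      fA = 1 - eps, fB = 1 - eps, theta = NA_real_,
      stringsAsFactors = FALSE)
  }

  base <- as.integer(base + (cfg$nStrainVariantSites + 2L) * 1000L)

  ## pseudogene decoys: 50:50 mixture of a biallelic locus and a uniparental
  ## contaminant at high SNP density (1.1 kb, ~30 sites, 2 uniparental)
  if (cfg$nPseudogeneDecoys > 0) {
    for (k in seq_len(cfg$nPseudogeneDecoys)) {
      set.seed(.geneSeed(seed, 4000000L + k))
      s <- as.integer(base + (k - 1) * (1100 + cfg$interGeneGapBp) +
        cfg$interGeneGapBp)
      e <- as.integer(s + 1100 - 1)
      name <- sprintf("decoyP%02d", k)
      nS <- 30L
      pos <- sort(sample(s:e, nS))
      type <- c(rep("uniparental", 2L),
                rep("shared", 22L), rep("biallelic", nS - 24L))
      fA <- ifelse(type == "uniparental", 1 - eps,
                   ifelse(type == "shared", 1 - eps, 0.5))
      fB <- ifelse(type == "uniparental", eps,
                   ifelse(type == "shared", 1 - eps, 0.5))
      covA <- .drawCoverage(nS, cfg); covB <- .drawCoverage(nS, cfg)
      snpRows[[length(snpRows) + 1L]] <- data.frame(
        gene = name, state = "PSEUDOGENE_DECOY", chrom = cfg$chrom,
        pos = pos, strand = "+",
        covA = covA, altA = .drawAlt(covA, fA, cfg),
        plusA = covA, minusA = 0L,
        covB = covB, altB = .drawAlt(covB, fB, cfg),
        plusB = covB, minusB = 0L,
        fA = fA, fB = fB, theta = NA_real_, stringsAsFactors = FALSE)
      modelRows[[length(modelRows) + 1L]] <- data.frame(
        gene = name, status = "PSEUDOGENE_DECOY", chrom = cfg$chrom,
        start = s, end = e, strand = "+", theta = NA_real_,
        stringsAsFactors = FALSE)
      geneRows[[length(geneRows) + 1L]] <- modelRows[[length(modelRows)]]
    }
    base <- as.integer(base + cfg$nPseudogeneDecoys *
                         (1100 + cfg$interGeneGapBp))
  }

  ## biallelic genes carrying one aberrant uniparental SNP
  if (cfg$nAberrantDecoys > 0) {
    for (k in seq_len(cfg$nAberrantDecoys)) {
      set.seed(.geneSeed(seed, 5000000L + k))
      s <- as.integer(base + (k - 1) * span + cfg$interGeneGapBp)
      e <- as.integer(s + cfg$geneLengthBp - 1)
      name <- sprintf("decoyA%02d", k)
      n <- max(4L, stats::rpois(1, cfg$snpRatePerKb * cfg$geneLengthBp /
                                  1000))
      pos <- sort(sample(s:e, n))
      fA <- c(1 - eps, rep(0.5, n - 1L))
      fB <- c(eps, rep(0.5, n - 1L))
      covA <- .drawCoverage(n, cfg); covB <- .drawCoverage(n, cfg)
      snpRows[[length(snpRows) + 1L]] <- data.frame(
        gene = name, state = "ABERRANT_BIALLELIC", chrom = cfg$chrom,
        pos = pos, strand = "+",
        covA = covA, altA = .drawAlt(covA, fA, cfg),
        plusA = covA, minusA = 0L,
        covB = covB, altB = .drawAlt(covB, fB, cfg),
        plusB = covB, minusB = 0L,
        fA = fA, fB = fB, theta = NA_real_, stringsAsFactors = FALSE)
      modelRows[[length(modelRows) + 1L]] <- data.frame(
        gene = name, status = "ABERRANT_BIALLELIC", chrom = cfg$chrom,
        start = s, end = e, strand = "+", theta = NA_real_,
        stringsAsFactors = FALSE)
      geneRows[[length(geneRows) + 1L]] <- modelRows[[length(modelRows)]]
    }
  }

  snps <- if (length(snpRows)) do.call(rbind, snpRows) else
    data.frame(gene = character(0), state = character(0),
               chrom = character(0), pos = integer(0), strand = character(0),
               covA = integer(0), altA = integer(0), plusA = integer(0),
               minusA = integer(0), covB = integer(0), altB = integer(0),
               plusB = integer(0), minusB = integer(0), fA = numeric(0),
               fB = numeric(0), theta = numeric(0))
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  rownames(snps) <- NULL
  snps$snpId <- paste0(snps$chrom, "_", snps$pos)

  mkCounts <- function(cov, alt, plus, minus, id) {
    keep <- cov > 0
    AlleleCounts(snps$chrom[keep], snps$pos[keep], "A", "G",
                 refCount = cov[keep] - alt[keep], altCount = alt[keep],
                 plusCount = plus[keep], minusCount = minus[keep],
                 crossId = id)
  }
  ids <- crossIds(design)
  countsA <- mkCounts(snps$covA, snps$altA, snps$plusA, snps$minusA, ids[1])
  countsB <- mkCounts(snps$covB, snps$altB, snps$plusB, snps$minusB, ids[2])

  genes <- do.call(rbind, geneRows)
  models <- GRanges(genes$chrom, IRanges(genes$start, genes$end),
                    strand = genes$strand)
  mcols(models) <- DataFrame(
    transcriptId = genes$gene, geneName = genes$gene,
    exons = methods::as(IRanges::ranges(models), "IRangesList"))

  extensions <- if (length(extRows)) do.call(rbind, extRows) else
    data.frame(parent = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               origin = character(0), nSnps = integer(0))

  list(countsA = countsA, countsB = countsB, models = models,
       truth = list(genes = genes, snps = snps, extensions = extensions),
       design = design, config = cfg)
}

#' Write a simulated dataset to disk
#'
#' Writes the two counts-TSV files (named by cross id), a BED6 annotation of
#' the gene models, the per-gene and per-SNP truth tables, and the exact
#' configuration used (YAML) into `dir`.
#'
#' @param sim Output of [simulateReciprocalCross()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeSimulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeAlleleCounts(sim$countsA,
                    file.path(dir, paste0("counts_", crossId(sim$countsA),
                                          ".tsv")))
  writeAlleleCounts(sim$countsB,
                    file.path(dir, paste0("counts_", crossId(sim$countsB),
                                          ".tsv")))
  g <- sim$truth$genes
  bed <- data.frame(chrom = g$chrom, start = g$start - 1L, end = g$end,
                    name = g$gene, score = 0L, strand = g$strand)
  utils::write.table(bed, file.path(dir, "annotation.bed"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(g, file.path(dir, "truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$snps, file.path(dir, "truth_snps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$extensions,
                     file.path(dir, "truth_extensions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  cfg$extensionSpec <- NULL
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Score pipeline calls against simulation truth
#'
#' Exact confusion-matrix counting of per-SNP and per-gene performance.
#' Truth positives are SNPs of maternally or paternally expressed loci
#' (extensions included); leaky genes, strain variants and decoys count as
#' negatives, so a leaky gene correctly rejected is a correct rejection.
#'
#' @param snpTests SNP table from [callTrueSnps()].
#' @param transcriptCalls Calls from [aggregateTranscripts()] (may be the
#'   empty frame when only SNP-level metrics are wanted).
#' @param truth The `truth` element of [simulateReciprocalCross()] output.
#' @return A list: `snpSensitivity`, `snpFdp`, `snpTP`, `snpFP`, `snpFN`,
#'   `geneSensitivity`, `geneSpecificity`, `originAccuracy`, `nDetected`,
#'   `nImprintedTrue`.
#' @export
evaluateCalls <- function(snpTests, transcriptCalls, truth) {
  stopifnot(is.data.frame(snpTests))
  tsnp <- truth$snps
  if (nrow(snpTests) && any(!snpTests$snpId %in% tsnp$snpId)) {
    .valErr("tested SNPs absent from truth: key mismatch")
  }
  posStates <- c("MAT", "PAT")
  truthPos <- tsnp$snpId[tsnp$state %in% posStates]
  called <- snpTests$snpId[snpTests$status == "TRUE"]
  tp <- sum(called %in% truthPos)
  fp <- length(called) - tp
  fn <- length(truthPos) - tp
  snpSens <- if (length(truthPos)) tp / length(truthPos) else NA_real_
  snpFdp <- if (length(called)) fp / length(called) else 0

  tg <- truth$genes
  impr <- tg[tg$status %in% posStates, , drop = FALSE]
  nonImpr <- tg[!tg$status %in% posStates, , drop = FALSE]
  calls <- transcriptCalls[transcriptCalls$consensusOrigin %in%
                             c("MATERNAL", "PATERNAL"), , drop = FALSE]
  callOrigin <- stats::setNames(calls$consensusOrigin, calls$geneName)
  detected <- impr$gene[impr$gene %in% names(callOrigin)]
  geneSens <- if (nrow(impr)) length(detected) / nrow(impr) else NA_real_
  geneSpec <- if (nrow(nonImpr)) {
    sum(!nonImpr$gene %in% names(callOrigin)) / nrow(nonImpr)
  } else NA_real_
  originAcc <- if (length(detected)) {
    want <- ifelse(impr$status[match(detected, impr$gene)] == "MAT",
                   "MATERNAL", "PATERNAL")
    mean(callOrigin[detected] == want)
  } else NA_real_
  list(snpSensitivity = snpSens, snpFdp = snpFdp,
       snpTP = tp, snpFP = fp, snpFN = fn,
       geneSensitivity = geneSens, geneSpecificity = geneSpec,
       originAccuracy = originAcc,
       nDetected = length(detected), nImprintedTrue = nrow(impr))
}
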