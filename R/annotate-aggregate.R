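#' @importFrom GenomicRanges findOverlaps
#' @importFrom S4Vectors queryHits subjectHits
NULL

## internal: majority read strand of a SNP from plus/minus counts over both
## crosses; NA when strand information is absent or tied
.majorityStrand <- function(snps) {
  plus <- rowSums(cbind(snps$plusA, snps$plusB), na.rm = TRUE)
  minus <- rowSums(cbind(snps$minusA, snps$minusB), na.rm = TRUE)
  noInfo <- (is.na(snps$plusA) & is.na(snps$plusB)) | (plus + minus == 0)
  ifelse(noInfo | plus == minus, NA_character_,
         ifelse(plus > minus, "+", "-"))
}

#' Annotate SNPs against gene models
#'
#' Maps every SNP to all transcripts whose span (or exons, with
#' `exonicOnly = TRUE`) contains its position; SNPs overlapping no transcript
#' are labelled intergenic. The transcript strand is compared with the SNP's
#' majority read strand and mismatches are flagged.
#'
#' @param snpTests SNP table from [callTrueSnps()] (or any table with
#'   `chrom`, `pos`, `snpId`, plus/minus count columns).
#' @param geneModels `GRanges` of transcript models from [readAnnotation()].
#' @param exonicOnly If `TRUE`, restrict overlap to exon blocks rather than
#'   the transcript span (intronic SNPs in primary transcripts are then
#'   intergenic). Default `FALSE`.
#' @return The input with list-free annotation columns: one row per
#'   (SNP, transcript) pair plus one row per intergenic SNP, with
#'   `transcriptId`, `geneName`, `txStrand`, `readStrand`,
#'   `strandConcordant` and `intergenic`.
#' @export
annotateSnps <- function(snpTests, geneModels, exonicOnly = FALSE) {
  stopifnot(is.data.frame(snpTests))
  snpTests$readStrand <- .majorityStrand(snpTests)
  if (nrow(snpTests) == 0L || is.null(geneModels) ||
      length(geneModels) == 0L) {
    out <- snpTests
    out$transcriptId <- character(nrow(out))
    out$geneName <- character(nrow(out))
    out$txStrand <- character(nrow(out))
    out$strandConcordant <- logical(nrow(out))
    out$intergenic <- rep(TRUE, nrow(out))
    return(out)
  }
  snpGr <- GRanges(snpTests$chrom, IRanges(snpTests$pos, width = 1L))
  hits <- if (exonicOnly) {
    exons <- mcols(geneModels)$exons
    exGr <- GRanges(rep(as.character(seqnames(geneModels)),
                        lengths(exons)),
                    unlist(exons))
    exTx <- rep(seq_along(geneModels), lengths(exons))
    h <- findOverlaps(snpGr, exGr, ignore.strand = TRUE)
    unique(data.frame(q = queryHits(h), s = exTx[subjectHits(h)]))
  } else {
    h <- findOverlaps(snpGr, geneModels, ignore.strand = TRUE)
    data.frame(q = queryHits(h), s = subjectHits(h))
  }
  annRows <- if (nrow(hits)) {
    cbind(snpTests[hits$q, , drop = FALSE],
          data.frame(
            transcriptId = mcols(geneModels)$transcriptId[hits$s],
            geneName = mcols(geneModels)$geneName[hits$s],
            txStrand = as.character(strand(geneModels))[hits$s],
            stringsAsFactors = FALSE))
  } else NULL
  interIdx <- setdiff(seq_len(nrow(snpTests)), hits$q)
  interRows <- if (length(interIdx)) {
    cbind(snpTests[interIdx, , drop = FALSE],
          data.frame(transcriptId = NA_character_, geneName = NA_character_,
                     txStrand = NA_character_, stringsAsFactors = FALSE))
  } else NULL
  out <- rbind(annRows, interRows)
  out$intergenic <- is.na(out$transcriptId)
  out$strandConcordant <- !is.na(out$txStrand) & !is.na(out$readStrand) &
    out$txStrand == out$readStrand
  out <- out[order(out$chrom, out$pos, out$transcriptId,
                   na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate TRUE SNPs to transcript-level imprinting calls
#'
#' One call per transcript carrying at least one TRUE SNP: the number of TRUE
#' SNPs, the mean combined per-SNP read count (mean over TRUE SNPs of
#' (coverage in cross A + coverage in cross B)/2, half-up rounded to integer;
#' per-cross means are also emitted), the consensus parental origin (by
#' unanimity, otherwise `CONFLICT`) and the representative SNP (the TRUE SNP
#' with maximum combined coverage; ties broken by position).
#'
#' @param annotated Output of [annotateSnps()].
#' @return A `data.frame` with one row per transcript with >= 1 TRUE SNP:
#'   `transcriptId`, `geneName`, `strand`, `nTrueSnps`, `meanReadsPerSnp`,
#'   `meanReadsA`, `meanReadsB`, `consensusOrigin`, `representativeSnp`.
#' @export
aggregateTranscripts <- function(annotated) {
  stopifnot(is.data.frame(annotated))
  tr <- annotated[!annotated$intergenic & annotated$status == "TRUE", ,
                  drop = FALSE]
  empty <- data.frame(transcriptId = character(0), geneName = character(0),
                      strand = character(0), nTrueSnps = integer(0),
                      meanReadsPerSnp = numeric(0), meanReadsA = numeric(0),
                      meanReadsB = numeric(0), consensusOrigin = character(0),
                      representativeSnp = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(tr) == 0L) return(empty)
  parts <- split(tr, tr$transcriptId)
  rows <- lapply(parts, function(g) {
    comb <- (g$covA + g$covB) / 2
    org <- unique(g$origin)
    rep <- order(-(g$covA + g$covB), g$pos)[1]
    data.frame(
      transcriptId = g$transcriptId[1], geneName = g$geneName[1],
      strand = g$txStrand[1], nTrueSnps = nrow(g),
      meanReadsPerSnp = roundHalfUp(mean(comb), 0),
      meanReadsA = roundHalfUp(mean(g$covA), 0),
      meanReadsB = roundHalfUp(mean(g$covB), 0),
      consensusOrigin = if (length(org) == 1L) org else "CONFLICT",
      representativeSnp = g$snpId[rep],
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$transcriptId), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize pipeline calls against a catalogue of known imprinted genes
#'
#' Applies the bookkeeping used when comparing calls with a published
#' catalogue: catalogue entries are first excluded as small RNAs (the method
#' cannot detect them), as not genuinely imprinted, or as duplicate entries;
#' the remainder are evaluable. Evaluable genes with a transcript call of the
#' catalogued origin are found; those not expressed in the cell type or
#' without informative SNPs are no-calls (with sub-reason); the rest are not
#' confirmed (biallelic in this data).
#'
#' @param transcriptCalls Calls from [aggregateTranscripts()].
#' @param catalogue A `data.frame` with columns `gene`, `known_origin`
#'   (`MATERNAL`/`PATERNAL`), `category` (`ok`, `small_rna`, `not_genuine`,
#'   `duplicate`), `expressed` (logical), `has_snps` (logical).
#' @return A list of counts: `nCatalogue`, `nExcludedSmallRna`,
#'   `nExcludedNotGenuine`, `nExcludedDuplicate`, `nEvaluable`, `nFound`,
#'   `nNoCallLowExpression`, `nNoCallNoSnp`, `nNoCall`, `nNotConfirmed`.
#'   The bookkeeping identities are asserted before returning.
#' @export
summarizeCatalogue <- function(transcriptCalls, catalogue) {
  need <- c("gene", "known_origin", "category", "expressed", "has_snps")
  miss <- setdiff(need, names(catalogue))
  if (length(miss)) {
    .valErr("catalogue lacks columns: ", paste(miss, collapse = ", "))
  }
  okCat <- c("ok", "small_rna", "not_genuine", "duplicate")
  if (any(!catalogue$category %in% okCat)) {
    .valErr("unknown catalogue category label")
  }
  nCat <- nrow(catalogue)
  nSmall <- sum(catalogue$category == "small_rna")
  nNotGen <- sum(catalogue$category == "not_genuine")
  nDup <- sum(catalogue$category == "duplicate")
  ev <- catalogue[catalogue$category == "ok", , drop = FALSE]
  calls <- transcriptCalls[transcriptCalls$consensusOrigin %in%
                             c("MATERNAL", "PATERNAL"), , drop = FALSE]
  callOrigin <- stats::setNames(calls$consensusOrigin, calls$geneName)
  found <- !is.na(callOrigin[ev$gene]) &
    callOrigin[ev$gene] == ev$known_origin
  found[is.na(found)] <- FALSE
  noCallLow <- !found & !ev$expressed
  noCallNoSnp <- !found & ev$expressed & !ev$has_snps
  notConfirmed <- !found & ev$expressed & ev$has_snps
  out <- list(
    nCatalogue = nCat, nExcludedSmallRna = nSmall,
    nExcludedNotGenuine = nNotGen, nExcludedDuplicate = nDup,
    nEvaluable = nrow(ev), nFound = sum(found),
    nNoCallLowExpression = sum(noCallLow), nNoCallNoSnp = sum(noCallNoSnp),
    nNoCall = sum(noCallLow) + sum(noCallNoSnp),
    nNotConfirmed = sum(notConfirmed))
  stopifnot(
    out$nEvaluable == out$nCatalogue - out$nExcludedSmallRna -
      out$nExcludedNotGenuine - out$nExcludedDuplicate,
    out$nFound + out$nNoCall + out$nNotConfirmed == out$nEvaluable)
  out
}
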