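#' Detect parental-allele-specific transcript extensions
#'
#' Searches intergenic TRUE SNPs for clusters that continue a known imprinted
#' transcript past its annotated 3' end. SNPs are grouped by (chromosome,
#' origin, majority read strand), clustered by single linkage with inter-SNP
#' gap at most `maxGap`, and a cluster becomes an extension when (i) the
#' nearest transcript with an imprinting call upstream of it in transcription
#' direction, within `maxReach` of the cluster's 5'-most SNP, has the same
#' origin and strand, and (ii) the cluster holds at least `minSnps` SNPs.
#' The cluster span is the SNP span (1-based inclusive). Clusters matching no
#' parent are returned separately as unassigned.
#'
#' @param annotated Annotated SNP table from [annotateSnps()] (intergenic
#'   TRUE SNPs are selected internally).
#' @param geneModels `GRanges` of transcript models.
#' @param transcriptCalls Calls from [aggregateTranscripts()]; defines which
#'   transcripts are eligible parents and their origins (any called
#'   transcript, not only catalogue genes, so extensions can chain).
#' @param maxGap Maximum intra-cluster inter-SNP gap in bp (default 10000).
#' @param minSnps Minimum SNPs per extension (default 2).
#' @param maxReach Maximum distance from the parent 3' end to the cluster's
#'   5'-most SNP in bp (default 100000).
#' @return A list with `extensions` (a `data.frame` shaped like a published
#'   extension table: `parentTranscriptId`, `chrom`, `start`, `end`,
#'   `strand`, `origin`, `nSnps`, `meanReadsPerSnp`, `representativeSnp`)
#'   and `unassigned` (clusters with no concordant parent).
#' @export
detectExtensions <- function(annotated, geneModels, transcriptCalls,
                             maxGap = 10000, minSnps = 2,
                             maxReach = 100000) {
  stopifnot(is.data.frame(annotated))
  emptyExt <- data.frame(
    parentTranscriptId = character(0), chrom = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    origin = character(0), nSnps = integer(0),
    meanReadsPerSnp = numeric(0), representativeSnp = character(0),
    stringsAsFactors = FALSE)
  snps <- annotated[annotated$intergenic & annotated$status == "TRUE", ,
                    drop = FALSE]
  if (nrow(snps) == 0L) {
    return(list(extensions = emptyExt, unassigned = emptyExt))
  }
  snps <- snps[order(snps$chrom, snps$pos), , drop = FALSE]
  grpKey <- paste(snps$chrom, snps$origin, snps$readStrand, sep = "\r")
  parents <- if (nrow(transcriptCalls)) {
    ok <- transcriptCalls$consensusOrigin %in% c("MATERNAL", "PATERNAL")
    idx <- match(transcriptCalls$transcriptId[ok],
                 mcols(geneModels)$transcriptId)
    data.frame(
      transcriptId = transcriptCalls$transcriptId[ok],
      origin = transcriptCalls$consensusOrigin[ok],
      chrom = as.character(seqnames(geneModels))[idx],
      start = start(geneModels)[idx], end = end(geneModels)[idx],
      strand = as.character(strand(geneModels))[idx],
      stringsAsFactors = FALSE)
  } else NULL
  extRows <- list(); orphanRows <- list()
  for (g in unique(grpKey)) {
    gs <- snps[grpKey == g, , drop = FALSE]
    pos <- gs$pos
    breaks <- c(0L, which(diff(pos) > maxGap), length(pos))
    for (ci in seq_len(length(breaks) - 1L)) {
      cl <- gs[(breaks[ci] + 1L):breaks[ci + 1L], , drop = FALSE]
      if (nrow(cl) < minSnps) next
      strandCl <- cl$readStrand[1]
      row <- data.frame(
        parentTranscriptId = NA_character_, chrom = cl$chrom[1],
        start = min(cl$pos), end = max(cl$pos),
        strand = if (is.na(strandCl)) NA_character_ else strandCl,
        origin = cl$origin[1], nSnps = nrow(cl),
        meanReadsPerSnp = roundHalfUp(mean((cl$covA + cl$covB) / 2), 0),
        representativeSnp = cl$snpId[order(-(cl$covA + cl$covB),
                                           cl$pos)[1]],
        stringsAsFactors = FALSE)
      ## find the nearest concordant parent upstream in transcription
      ## direction of the cluster's 5'-most SNP
      parent <- NULL
      if (!is.null(parents)) {
        cand <- parents[parents$chrom == row$chrom &
                        parents$origin == row$origin, , drop = FALSE]
        if (!is.na(strandCl)) {
          cand <- cand[cand$strand == strandCl, , drop = FALSE]
        }
        if (nrow(cand)) {
          if (is.na(strandCl) || strandCl == "+") {
            ## parent transcribes left to right: 3' end = end; cluster lies
            ## downstream (to the right)
            d <- row$start - cand$end
            cand <- cand[d >= 0 & d <= maxReach, , drop = FALSE]
            if (nrow(cand)) {
              parent <- cand[which.max(cand$end), , drop = FALSE]
            }
          } else {
            d <- cand$start - row$end
            cand <- cand[d >= 0 & d <= maxReach, , drop = FALSE]
            if (nrow(cand)) {
              parent <- cand[which.min(cand$start), , drop = FALSE]
            }
          }
        }
      }
      if (is.null(parent)) {
        orphanRows[[length(orphanRows) + 1L]] <- row
      } else {
        row$parentTranscriptId <- parent$transcriptId
        if (is.na(row$strand)) row$strand <- parent$strand
        extRows[[length(extRows) + 1L]] <- row
      }
    }
  }
  bindOr <- function(rows) if (length(rows)) {
    out <- do.call(rbind, rows)
    out <- out[order(out$chrom, out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
  } else emptyExt
  list(extensions = bindOr(extRows), unassigned = bindOr(orphanRows))
}

#' Summarize detected extensions
#'
#' @param extensions Extension table from [detectExtensions()].
#' @return A list with `count` and `byParent` (a table of extension counts
#'   per parent transcript).
#' @export
extensionSummary <- function(extensions) {
  list(count = nrow(extensions),
       byParent = if (nrow(extensions)) {
         table(extensions$parentTranscriptId)
       } else table(character(0)))
}

#' Export extension intervals as BED6
#'
#' Writes 0-based half-open intervals, name = parent transcript + "_ext",
#' the cluster's SNP count as score, and the strand column populated.
#'
#' @param extensions Extension table from [detectExtensions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeExtensionsBed <- function(extensions, path) {
  df <- data.frame(
    chrom = extensions$chrom,
    start = extensions$start - 1L,
    end = extensions$end,
    name = paste0(extensions$parentTranscriptId, "_ext"),
    score = extensions$nSnps,
    strand = extensions$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
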