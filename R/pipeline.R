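#' Run the reciprocal-cross imprinting pipeline end to end
#'
#' Executes the stages in order: site merge and candidate discovery,
#' strain-variant exclusion, Fisher/FDR TRUE-SNP calling with parental-origin
#' assignment, annotation and transcript aggregation, extension detection,
#' artifact vetting of novel calls, and (when a catalogue is supplied) the
#' known-gene bookkeeping summary. Every exclusion has a reason code and the
#' run manifest records the record counts surviving each filter. Identical
#' inputs and configuration give identical outputs.
#'
#' @param countsA,countsB [AlleleCounts-class] objects for the two crosses.
#' @param design A [CrossDesign-class].
#' @param geneModels Optional `GRanges` of transcript models.
#' @param catalogue Optional known-imprinted-gene catalogue
#'   (see [summarizeCatalogue()]).
#' @param minAF,minCov Candidate discovery thresholds (default 0.80, 10).
#' @param bothAF Both-cross strain-variant AF threshold (default 0.80).
#' @param fdrMax,recipAFMax,fdrFamily TRUE-SNP selection thresholds
#'   (default 0.05, 0.20, pooled).
#' @param maxGap,minSnps,maxReach Extension detection parameters.
#' @param minorityCutoff,densityCutoff,sharedCutoff Vetting thresholds.
#' @param exonicOnly Restrict SNP-to-transcript overlap to exons.
#' @param restrictTo Optional `GRanges` of known variant sites.
#' @return A list of class `imprintRun`: `snps` (all tested SNPs),
#'   `excluded` (strain variants), `transcripts`, `conflicts` (calls with
#'   conflicting origins, excluded from reporting), `extensions`,
#'   `unassignedClusters`, `vetting`, `retained`, `rejected`,
#'   `catalogueSummary` (or `NULL`), and `manifest`.
#' @export
runPipeline <- function(countsA, countsB, design,
                        geneModels = NULL, catalogue = NULL,
                        minAF = 0.80, minCov = 10, bothAF = 0.80,
                        fdrMax = 0.05, recipAFMax = 0.20,
                        fdrFamily = "pooled",
                        maxGap = 10000, minSnps = 2, maxReach = 100000,
                        minorityCutoff = 0.5, densityCutoff = 10,
                        sharedCutoff = 0.5,
                        exonicOnly = FALSE, restrictTo = NULL) {
  cand <- findCandidates(countsA, countsB, minAF = minAF, minCov = minCov,
                         restrictTo = restrictTo)
  sv <- excludeStrainVariants(cand, bothAF = bothAF)
  tested <- callTrueSnps(sv$kept, design, fdrMax = fdrMax,
                         recipAFMax = recipAFMax, fdrFamily = fdrFamily)
  ann <- annotateSnps(tested, geneModels, exonicOnly = exonicOnly)
  calls <- aggregateTranscripts(ann)
  conflicts <- calls[calls$consensusOrigin == "CONFLICT", , drop = FALSE]
  cleanCalls <- calls[calls$consensusOrigin != "CONFLICT", , drop = FALSE]
  ext <- detectExtensions(ann, geneModels, cleanCalls, maxGap = maxGap,
                          minSnps = minSnps, maxReach = maxReach)

  ## vetting sees the full pre-exclusion site table (shared-alt SNPs count)
  allSites <- .mergeCrosses(countsA, countsB)
  allSites$status <- tested$status[match(allSites$snpId, tested$snpId)]
  vetting <- NULL
  if (!is.null(geneModels) && length(geneModels) && nrow(cleanCalls)) {
    reports <- lapply(seq_len(nrow(cleanCalls)), function(i) {
      txId <- cleanCalls$transcriptId[i]
      j <- match(txId, mcols(geneModels)$transcriptId)
      gm <- geneModels[j]
      inTx <- allSites$chrom == as.character(seqnames(gm)) &
        allSites$pos >= start(gm) & allSites$pos <= end(gm)
      vetTranscript(allSites[inTx, , drop = FALSE], txId,
                    lengthBp = GenomicRanges::width(gm),
                    minorityCutoff = minorityCutoff,
                    densityCutoff = densityCutoff,
                    sharedCutoff = sharedCutoff)
    })
    vetting <- do.call(rbind, reports[!vapply(reports, is.null, logical(1))])
  }
  novel <- if (!is.null(catalogue)) {
    cleanCalls[!cleanCalls$geneName %in% catalogue$gene, , drop = FALSE]
  } else cleanCalls
  vetted <- if (!is.null(vetting) && nrow(novel)) {
    vetPredictionSet(novel, vetting)
  } else list(retained = novel,
              rejected = cbind(novel[0, , drop = FALSE],
                               data.frame(rejectReasons = character(0))))
  catSummary <- if (!is.null(catalogue)) {
    summarizeCatalogue(cleanCalls, catalogue)
  } else NULL

  manifest <- list(
    crossIdA = crossId(countsA), crossIdB = crossId(countsB),
    nSitesA = length(countsA), nSitesB = length(countsB),
    nSitesUnion = attr(cand, "nSitesUnion"),
    nCandidates = nrow(cand),
    nStrainVariantsExcluded = nrow(sv$excluded),
    nAfterExclusion = nrow(sv$kept),
    nTrue = sum(tested$status == "TRUE"),
    nFalse = sum(tested$status == "FALSE"),
    nTranscriptCalls = nrow(cleanCalls),
    nConflicts = nrow(conflicts),
    nExtensions = nrow(ext$extensions),
    thresholds = list(minAF = minAF, minCov = minCov, bothAF = bothAF,
                      fdrMax = fdrMax, recipAFMax = recipAFMax,
                      fdrFamily = fdrFamily, maxGap = maxGap,
                      minSnps = minSnps, maxReach = maxReach),
    packageVersion = as.character(utils::packageVersion("imprintASE")))
  out <- list(snps = tested, excluded = sv$excluded,
              transcripts = cleanCalls, conflicts = conflicts,
              extensions = ext$extensions,
              unassignedClusters = ext$unassigned,
              vetting = vetting, retained = vetted$retained,
              rejected = vetted$rejected,
              catalogueSummary = catSummary, manifest = manifest)
  class(out) <- "imprintRun"
  out
}

#' @export
print.imprintRun <- function(x, ...) {
  m <- x$manifest
  cat("imprintASE run (", m$crossIdA, " vs ", m$crossIdB, ")\n", sep = "")
  cat("  sites: ", m$nSitesA, " / ", m$nSitesB, " (union ", m$nSitesUnion,
      ")\n", sep = "")
  cat("  candidates: ", m$nCandidates, "; strain variants excluded: ",
      m$nStrainVariantsExcluded, "\n", sep = "")
  cat("  TRUE SNPs: ", m$nTrue, " (FALSE: ", m$nFalse, ")\n", sep = "")
  cat("  transcript calls: ", m$nTranscriptCalls, "; extensions: ",
      m$nExtensions, "\n", sep = "")
  invisible(x)
}

#' Filter funnel of a pipeline run
#'
#' Ordered record counts surviving each stated filter: observed sites,
#' candidates, candidates after strain-variant exclusion, TRUE SNPs. The
#' funnel is asserted to be monotone non-increasing; FALSE SNPs equal
#' post-exclusion candidates minus TRUE SNPs.
#'
#' @param manifest The `manifest` element of a [runPipeline()] result.
#' @return A `data.frame` with `stage` and `count`.
#' @export
filterFunnel <- function(manifest) {
  df <- data.frame(
    stage = c("sites", "candidates", "post_strain_exclusion", "true_snps"),
    count = c(manifest$nSitesUnion, manifest$nCandidates,
              manifest$nAfterExclusion, manifest$nTrue))
  if (any(diff(df$count) > 0)) {
    stop("filter funnel is not monotone non-increasing: internal error")
  }
  stopifnot(manifest$nFalse == manifest$nAfterExclusion - manifest$nTrue)
  df
}

#' Write pipeline results as TSV files
#'
#' Writes the SNP table (shaped like a published per-SNP decision table),
#' transcript and extension tables, vetting report, excluded sites, and a
#' YAML run manifest into `dir`. Output is byte-identical across runs on
#' identical inputs.
#'
#' @param run An `imprintRun` from [runPipeline()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
writePipelineResults <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  wr(run$snps, "snp_table.tsv")
  wr(run$excluded, "excluded_strain_variants.tsv")
  wr(run$transcripts, "transcript_table.tsv")
  wr(run$conflicts, "conflicting_transcripts.tsv")
  wr(run$extensions, "extension_table.tsv")
  if (nrow(run$extensions)) {
    writeExtensionsBed(run$extensions, file.path(dir, "extensions.bed"))
  }
  wr(run$vetting, "vetting_report.tsv")
  yaml::write_yaml(run$manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
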