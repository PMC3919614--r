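#' Bundled worked examples
#'
#' Small plain-text tables shipped with the package for worked examples and
#' regression tests of the decision rule:
#'
#' * `exampleKnownGenes()` - 32 known ubiquitously imprinted mouse genes
#'   confirmed in reciprocal JF1xOG2 MEF RNA-seq, one representative SNP per
#'   transcript with its reference/alternative read counts in the JXO and OXJ
#'   crosses, allele fractions, FDR and parental origin.
#' * `exampleExtensions()` - eight parental-allele-specific transcript
#'   extensions downstream of known imprinted genes, in the same shape plus
#'   the extension interval and parent transcript.
#' * `exampleCatalogue()` - a *synthetic* reconstruction of a 152-entry
#'   known-imprinted-transcript catalogue: 22 small RNAs, 12 entries not
#'   genuinely imprinted and 1 duplicate are excluded; of the 117 evaluable
#'   genes 32 are found in the MEF data, 61 lack expression, 5 lack SNPs and
#'   19 (including the leaky Dlk1) are not confirmed. Gene names outside the
#'   32 found genes and Dlk1 are synthetic placeholders.
#'
#' @return A `data.frame`.
#' @name examples
NULL

#' @rdname examples
#' @export
exampleKnownGenes <- function() {
  utils::read.delim(system.file("extdata", "known_genes_example.tsv",
                                package = "imprintASE"),
                    colClasses = c(fdr = "character"))
}

#' @rdname examples
#' @export
exampleExtensions <- function() {
  utils::read.delim(system.file("extdata", "extensions_example.tsv",
                                package = "imprintASE"),
                    colClasses = c(fdr = "character"))
}

#' @rdname examples
#' @export
exampleCatalogue <- function() {
  utils::read.delim(system.file("extdata", "catalogue_synthetic.tsv",
                                package = "imprintASE"))
}

#' Convert a worked-example table into a candidate table
#'
#' Reshapes rows of [exampleKnownGenes()] / [exampleExtensions()] (one
#' representative SNP per transcript, JXO and OXJ counts) into the candidate
#' format consumed by [callTrueSnps()]. The discovering cross is the one
#' with the higher alternative allele fraction. Duplicate sites (one SNP
#' representing two overlapping transcripts) are collapsed.
#'
#' @param df A worked-example table.
#' @return A candidate `data.frame` with `crossIdA = "JXO"`,
#'   `crossIdB = "OXJ"` attributes.
#' @export
candidatesFromExample <- function(df) {
  chrom <- sub("_[0-9]+$", "", df$snp_id)
  pos <- as.integer(sub("^.*_", "", df$snp_id))
  out <- data.frame(
    chrom = chrom, pos = pos, ref = "A", alt = "G",
    refA = df$jxo_ref, altA = df$jxo_alt,
    refB = df$oxj_ref, altB = df$oxj_alt,
    plusA = NA_integer_, minusA = NA_integer_,
    plusB = NA_integer_, minusB = NA_integer_,
    stringsAsFactors = FALSE)
  out$covA <- out$refA + out$altA
  out$covB <- out$refB + out$altB
  out$afA <- .afOrNA(out$refA, out$altA)
  out$afB <- .afOrNA(out$refB, out$altB)
  out$snpId <- df$snp_id
  out$discoveringCross <- ifelse(!is.na(out$afA) & out$afA >= 0.5, "A", "B")
  out$unconfirmedLowCoverage <- FALSE
  out <- out[!duplicated(out$snpId), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "crossIdA") <- "JXO"
  attr(out, "crossIdB") <- "OXJ"
  out
}

#' Minimal gene models for a worked-example table
#'
#' Builds point-surround transcript models (representative SNP +/- `pad` bp)
#' with the table's strand, sufficient for annotation and aggregation of the
#' representative SNPs.
#'
#' @param df A worked-example table.
#' @param pad Half-width of the model around the representative SNP.
#' @return A `GRanges` of transcript models.
#' @export
exampleGeneModels <- function(df, pad = 10L) {
  pos <- as.integer(sub("^.*_", "", df$snp_id))
  chrom <- sub("_[0-9]+$", "", df$snp_id)
  gr <- GRanges(chrom, IRanges(pmax(1L, pos - pad), pos + pad),
                strand = df$strand)
  mcols(gr) <- DataFrame(
    transcriptId = df$transcript, geneName = df$transcript,
    exons = methods::as(IRanges::ranges(gr), "IRangesList"))
  gr
}
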