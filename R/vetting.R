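#' Vet one transcript's SNP profile for artifact patterns
#'
#' Three failure modes of spurious novel-imprinting predictions are flagged
#' from all informative SNPs (coverage > 0 in both crosses) overlapping the
#' transcript, before strain-variant exclusion:
#'
#' * `minority_true` - the TRUE SNPs are a minority among the transcript's
#'   informative SNPs (`trueFraction < minorityCutoff`): the remaining SNPs
#'   behave biallelically, so the isolated allele-specific signal is suspect.
#' * `high_density` - the informative SNP density exceeds `densityCutoff`
#'   per kb, far above genuine inter-strain transcript SNP density; typical
#'   of pseudogene read misassignment.
#' * `shared_alt_paralog` - more than `sharedCutoff` of the informative SNPs
#'   have AF >= 0.8 in both crosses (before exclusion): the "variants" are
#'   paralog sequence differences present in every read, another
#'   misassignment signature.
#'
#' @param transcriptSnps `data.frame` of all SNPs overlapping one transcript
#'   (pre-exclusion), with `afA`, `afB`, `covA`, `covB` and `status`
#'   (rows never tested, e.g. excluded strain variants, may carry `NA`
#'   status, counted as not-TRUE).
#' @param transcriptId Identifier for the report.
#' @param lengthBp Transcript length in bp (used for the density).
#' @param minorityCutoff TRUE-fraction below which `minority_true` is
#'   flagged; default 0.5.
#' @param densityCutoff Informative SNPs per kb above which `high_density`
#'   is flagged; default 10.
#' @param sharedCutoff Fraction of both-cross high-AF SNPs above which
#'   `shared_alt_paralog` is flagged; default 0.5.
#' @return A one-row `data.frame`: `transcriptId`, `nInformativeSnps`,
#'   `nTrueSnps`, `trueFraction`, `snpDensityPerKb`, `nSharedAltSnps`,
#'   `flags` (comma-separated), `verdict` (`"pass"`/`"suspect"`), or `NULL`
#'   when the transcript has no informative SNP.
#' @export
vetTranscript <- function(transcriptSnps, transcriptId, lengthBp,
                          minorityCutoff = 0.5, densityCutoff = 10,
                          sharedCutoff = 0.5) {
  stopifnot(lengthBp > 0)
  inf <- transcriptSnps[transcriptSnps$covA > 0 & transcriptSnps$covB > 0, ,
                        drop = FALSE]
  if (nrow(inf) == 0L) return(NULL)
  nTrue <- sum(!is.na(inf$status) & inf$status == "TRUE")
  trueFraction <- nTrue / nrow(inf)
  density <- nrow(inf) / (lengthBp / 1000)
  nShared <- sum(inf$afA >= 0.8 & inf$afB >= 0.8)
  flags <- character(0)
  if (trueFraction < minorityCutoff) flags <- c(flags, "minority_true")
  if (density > densityCutoff) flags <- c(flags, "high_density")
  if (nShared / nrow(inf) > sharedCutoff) {
    flags <- c(flags, "shared_alt_paralog")
  }
  data.frame(
    transcriptId = transcriptId, nInformativeSnps = nrow(inf),
    nTrueSnps = nTrue, trueFraction = trueFraction,
    snpDensityPerKb = density, nSharedAltSnps = nShared,
    flags = paste(flags, collapse = ","),
    verdict = if (length(flags)) "suspect" else "pass",
    stringsAsFactors = FALSE)
}

#' Partition novel predictions by their vetting verdicts
#'
#' @param novelCalls Transcript calls (from [aggregateTranscripts()])
#'   regarded as novel predictions.
#' @param vettingReports `data.frame` of rows from [vetTranscript()] covering
#'   every novel call.
#' @return A list with `retained` (calls whose report verdict is `"pass"`)
#'   and `rejected` (calls with a `rejectReasons` column from the report
#'   flags).
#' @export
vetPredictionSet <- function(novelCalls, vettingReports) {
  stopifnot(is.data.frame(novelCalls))
  if (nrow(novelCalls) == 0L) {
    rej <- novelCalls; rej$rejectReasons <- character(0)
    return(list(retained = novelCalls, rejected = rej))
  }
  i <- match(novelCalls$transcriptId, vettingReports$transcriptId)
  if (any(is.na(i))) {
    .valErr("missing vetting report for: ",
            paste(novelCalls$transcriptId[is.na(i)], collapse = ", "))
  }
  pass <- vettingReports$verdict[i] == "pass"
  rejected <- novelCalls[!pass, , drop = FALSE]
  if (nrow(rejected)) rejected$rejectReasons <- vettingReports$flags[i][!pass]
  else rejected$rejectReasons <- character(0)
  retained <- novelCalls[pass, , drop = FALSE]
  rownames(retained) <- rownames(rejected) <- NULL
  list(retained = retained, rejected = rejected)
}
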