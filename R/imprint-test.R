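#' Two-sided Fisher's exact test for a 2x2 allele-count table
#'
#' The table rows are (altA, refA) and (altB, refB), i.e. the alternative and
#' reference read counts in the two reciprocal crosses. The two-sided p-value
#' follows the minimum-likelihood definition: the sum of hypergeometric point
#' probabilities, over all tables with the observed margins, that do not
#' exceed the observed table's point probability. Tables within relative
#' tolerance 1e-7 of the observed probability are included, matching common
#' practice at machine-epsilon ties.
#'
#' The odds ratio is the sample odds ratio (a d)/(b c) with zero-cell
#' convention `Inf` (numerator positive, denominator zero), `0` (numerator
#' zero, denominator positive) and `NaN` (both zero); a Haldane-Anscombe
#' corrected value (+0.5 in every cell) is reported alongside. The odds ratio
#' is never used as a filter.
#'
#' @param a,b Alternative and reference counts in the first cross.
#' @param c,d Alternative and reference counts in the second cross.
#' @return A list with `p` (two-sided), `oddsRatio` and `oddsRatioHA`.
#' @examples
#' fisherExact2x2(47, 0, 0, 47)$p  # 2 / choose(94, 47)
#' fisherExact2x2(5, 5, 5, 5)$p    # 1
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  .checkCount(c(a, b, c, d), "table cells")
  if (a + b + c + d == 0) .valErr("all four cells zero: test undefined")
  r1 <- a + b
  k <- a + c
  N <- a + b + c + d
  ## support of cell 'a' given margins
  lo <- max(0L, k - (N - r1))
  hi <- min(k, r1)
  x <- lo:hi
  dens <- stats::dhyper(x, k, N - k, r1)
  obs <- dens[x == a]
  p <- min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
  num <- as.numeric(a) * d
  den <- as.numeric(b) * c
  or <- if (den > 0) num / den else if (num > 0) Inf else if (num == 0 &&
    den == 0) NaN else 0
  orHA <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  list(p = p, oddsRatio = or, oddsRatioHA = orHA)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin validated wrapper around `stats::p.adjust(method = "BH")`: sort
#' ascending, adjust p_(i) to min over j >= i of p_(j) * n / j, clip at 1 and
#' map back to input order. Ties share the same adjusted value.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values aligned to the input order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))  # all 0.03
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    .valErr("p-values must be in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Assign parental origin to a TRUE SNP
#'
#' The parental origin equals the role of the alternative-allele strain in
#' the discovering cross: if that strain is the mother there, the expressed
#' allele is maternal; if the father, paternal. In the JF1xOG2 design the JXO
#' cross therefore reveals maternally expressed genes and the OXJ cross
#' paternally expressed ones.
#'
#' @param discoveringCross Cross identifier(s) in which the SNP was
#'   discovered (vectorised).
#' @param design A [CrossDesign-class].
#' @return Character vector `"MATERNAL"` / `"PATERNAL"`.
#' @examples
#' assignOrigin("JXO", jxoDesign())  # MATERNAL
#' assignOrigin("OXJ", jxoDesign())  # PATERNAL
#' @export
assignOrigin <- function(discoveringCross, design) {
  stopifnot(is(design, "CrossDesign"))
  bad <- !discoveringCross %in% crossIds(design)
  if (any(bad)) {
    .valErr("cross absent from design: ",
            paste(unique(discoveringCross[bad]), collapse = ", "))
  }
  alt <- altStrain(design)
  vapply(discoveringCross, function(cr) {
    if (motherStrain(design, cr) == alt) "MATERNAL"
    else if (fatherStrain(design, cr) == alt) "PATERNAL"
    else .valErr("altStrain not a parent of cross ", cr)
  }, character(1), USE.NAMES = FALSE)
}

#' Apply the TRUE-SNP selection rule
#'
#' For every candidate (already strain-variant-excluded) the reciprocal-cross
#' 2x2 table (alt/ref in each cross) is tested with [fisherExact2x2()], the
#' p-values are BH-adjusted across the candidate family, and a SNP is TRUE
#' iff its FDR is at most `fdrMax`, the confirming (reciprocal) cross has
#' alternative AF at most `recipAFMax`, and the confirming cross has coverage
#' greater than zero. FALSE records are retained with their failure reasons.
#'
#' @param candidates Candidate table from [findCandidates()] /
#'   [excludeStrainVariants()]; rows with `discoveringCross == "both"` are
#'   rejected (exclude strain variants first).
#' @param design A [CrossDesign-class]; cross "A" of the candidate table is
#'   `crossIds(design)[1]` unless the table's `crossIdA` attribute says
#'   otherwise.
#' @param fdrMax Maximum FDR (inclusive), default 0.05.
#' @param recipAFMax Maximum alternative AF in the confirming cross
#'   (inclusive), default 0.20.
#' @param fdrFamily `"pooled"` (one BH family for all candidates, default) or
#'   `"per_cross"` (separate families per discovering cross).
#' @return A `data.frame` with the candidate columns plus `p`, `oddsRatio`,
#'   `oddsRatioHA`, `fdr`, `status` (`"TRUE"`/`"FALSE"`), `failReasons`
#'   (comma-separated), `origin` (`MATERNAL`/`PATERNAL`/`UNASSIGNED`) and
#'   `discoveringCrossId`.
#' @export
callTrueSnps <- function(candidates, design, fdrMax = 0.05,
                         recipAFMax = 0.20,
                         fdrFamily = c("pooled", "per_cross")) {
  fdrFamily <- match.arg(fdrFamily)
  stopifnot(is.data.frame(candidates), is(design, "CrossDesign"))
  out <- candidates
  if (nrow(out) == 0L) {
    for (col in c("p", "oddsRatio", "oddsRatioHA", "fdr")) out[[col]] <- numeric(0)
    out$status <- character(0); out$failReasons <- character(0)
    out$origin <- character(0); out$discoveringCrossId <- character(0)
    return(out)
  }
  if (any(out$discoveringCross == "both")) {
    .valErr("candidates with discoveringCross 'both' present; ",
            "run excludeStrainVariants() first")
  }
  idA <- attr(candidates, "crossIdA")
  if (is.null(idA)) idA <- crossIds(design)[1]
  idB <- attr(candidates, "crossIdB")
  if (is.null(idB)) idB <- crossIds(design)[2]
  tests <- Map(fisherExact2x2, out$altA, out$refA, out$altB, out$refB)
  out$p <- vapply(tests, `[[`, numeric(1), "p")
  out$oddsRatio <- vapply(tests, `[[`, numeric(1), "oddsRatio")
  out$oddsRatioHA <- vapply(tests, `[[`, numeric(1), "oddsRatioHA")
  out$fdr <- NA_real_
  if (fdrFamily == "pooled") {
    out$fdr <- bhAdjust(out$p)
  } else {
    for (g in unique(out$discoveringCross)) {
      i <- out$discoveringCross == g
      out$fdr[i] <- bhAdjust(out$p[i])
    }
  }
  discA <- out$discoveringCross == "A"
  confAF <- ifelse(discA, out$afB, out$afA)
  confCov <- ifelse(discA, out$covB, out$covA)
  fdrOk <- out$fdr <= fdrMax
  recipOk <- !is.na(confAF) & confAF <= recipAFMax
  covOk <- confCov > 0
  out$status <- ifelse(fdrOk & recipOk & covOk, "TRUE", "FALSE")
  out$failReasons <- vapply(seq_len(nrow(out)), function(i) {
    r <- character(0)
    if (!covOk[i]) r <- c(r, "unconfirmed_low_coverage")
    if (!fdrOk[i]) r <- c(r, "low_fdr_fail")
    if (covOk[i] && !recipOk[i]) r <- c(r, "reciprocal_af_fail")
    paste(r, collapse = ",")
  }, character(1))
  out$discoveringCrossId <- ifelse(discA, idA, idB)
  out$origin <- "UNASSIGNED"
  isTrue <- out$status == "TRUE"
  if (any(isTrue)) {
    out$origin[isTrue] <- assignOrigin(out$discoveringCrossId[isTrue], design)
  }
  attr(out, "crossIdA") <- idA
  attr(out, "crossIdB") <- idB
  out
}

#' Alternative-strain concordance of TRUE SNPs
#'
#' Fraction of TRUE SNPs whose discovering cross matches the default
#' alternative-strain expectation (e.g. 502 of 527 maternal-gene SNPs
#' identifying JF1 as the alternative allele in the JXO cross), reported as an
#' integer-rounded percentage.
#'
#' @param nMatching Number of SNPs matching the expectation.
#' @param nTotal Total number of TRUE SNPs in the group.
#' @return A list with `nMatching`, `nTotal` and `percent`.
#' @examples
#' altStrainConcordance(502, 527)$percent  # 95
#' @export
altStrainConcordance <- function(nMatching, nTotal) {
  .checkCount(c(nMatching, nTotal), "counts")
  if (nTotal == 0) .valErr("empty group: concordance undefined")
  if (nMatching > nTotal) .valErr("nMatching exceeds nTotal")
  list(nMatching = nMatching, nTotal = nTotal,
       percent = roundHalfUp(100 * nMatching / nTotal, 0))
}
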