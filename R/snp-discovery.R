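#' Alternative allele fraction
#'
#' AF = alt / (ref + alt). Bases other than the reference and alternative
#' allele are excluded from the denominator upstream.
#'
#' @param refCount,altCount Non-negative read counts (vectorised).
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' alleleFraction(0, 47)   # 1
#' alleleFraction(9, 2)    # 0.1818...
#' @export
alleleFraction <- function(refCount, altCount) {
  .checkCount(refCount, "refCount"); .checkCount(altCount, "altCount")
  tot <- refCount + altCount
  if (any(tot == 0)) .valErr("zero coverage: allele fraction undefined")
  altCount / tot
}

## internal AF that returns NA at zero coverage (merged-table arithmetic)
.afOrNA <- function(ref, alt) {
  tot <- ref + alt
  ifelse(tot > 0, alt / tot, NA_real_)
}

## internal: merge two AlleleCounts objects into one site table keyed by
## (chrom, pos). Sites absent from one cross get zero counts there.
.mergeCrosses <- function(countsA, countsB) {
  stopifnot(is(countsA, "AlleleCounts"), is(countsB, "AlleleCounts"))
  if (crossId(countsA) == crossId(countsB)) {
    .valErr("the two count sets carry the same crossId")
  }
  a <- as.data.frame(countsA)
  b <- as.data.frame(countsB)
  a$key <- if (nrow(a)) paste0(a$chrom, "_", a$pos) else character(0)
  b$key <- if (nrow(b)) paste0(b$chrom, "_", b$pos) else character(0)
  shared <- intersect(a$key, b$key)
  if (length(shared)) {
    ra <- a[match(shared, a$key), ]; rb <- b[match(shared, b$key), ]
    if (any(ra$ref != rb$ref)) {
      .valErr("inconsistent reference base between crosses at ",
              shared[which(ra$ref != rb$ref)[1]])
    }
  }
  keys <- sort(union(a$key, b$key))
  ia <- match(keys, a$key); ib <- match(keys, b$key)
  pick <- function(v, i, fill) ifelse(is.na(i), fill, v[ifelse(is.na(i), 1, i)])
  chrom <- ifelse(is.na(ia), b$chrom[ib], a$chrom[ia])
  pos <- ifelse(is.na(ia), b$pos[ib], a$pos[ia])
  ref <- ifelse(is.na(ia), b$ref[ib], a$ref[ia])
  alt <- ifelse(is.na(ia), b$alt[ib], a$alt[ia])
  ## when both crosses saw the site but disagree on alt, keep the base of the
  ## cross with more alternative reads (tri-allelic sites are logged upstream)
  both <- !is.na(ia) & !is.na(ib)
  dis <- both & a$alt[ifelse(is.na(ia), 1, ia)] !=
                b$alt[ifelse(is.na(ib), 1, ib)]
  if (any(dis)) {
    useB <- dis & b$alt_count[ib] > a$alt_count[ia]
    alt[useB] <- b$alt[ib[useB]]
  }
  df <- data.frame(
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    refA = pick(a$ref_count, ia, 0L), altA = pick(a$alt_count, ia, 0L),
    refB = pick(b$ref_count, ib, 0L), altB = pick(b$alt_count, ib, 0L),
    plusA = pick(a$plus_count, ia, NA_integer_),
    minusA = pick(a$minus_count, ia, NA_integer_),
    plusB = pick(b$plus_count, ib, NA_integer_),
    minusB = pick(b$minus_count, ib, NA_integer_),
    stringsAsFactors = FALSE)
  ## alt reads counted for a different base than the retained alt do not
  ## contribute to that allele in the disagreeing cross
  if (any(dis)) {
    zeroA <- dis & alt != a$alt[ia]
    df$altA[zeroA] <- 0L
    zeroB <- dis & alt != b$alt[ib]
    df$altB[zeroB] <- 0L
  }
  df$covA <- df$refA + df$altA
  df$covB <- df$refB + df$altB
  df$afA <- .afOrNA(df$refA, df$altA)
  df$afB <- .afOrNA(df$refB, df$altB)
  df$snpId <- if (nrow(df)) paste0(df$chrom, "_", df$pos) else character(0)
  df <- df[order(df$chrom, df$pos), ]
  rownames(df) <- NULL
  attr(df, "crossIdA") <- crossId(countsA)
  attr(df, "crossIdB") <- crossId(countsB)
  df
}

#' Discover candidate allele-specific SNPs
#'
#' A site is a candidate if in at least one cross its alternative allele
#' fraction is at least `minAF` *and* its total coverage (ref + alt) is at
#' least `minCov`. The coverage gate applies to the discovering cross only;
#' the reciprocal (confirming) cross's counts are attached even when its
#' coverage is below `minCov`, and sites entirely absent from the confirming
#' cross are flagged `unconfirmedLowCoverage` (they can never become TRUE).
#'
#' @param countsA,countsB [AlleleCounts-class] objects for the two reciprocal
#'   crosses.
#' @param minAF Minimum alternative allele fraction in the discovering cross
#'   (inclusive), default 0.80.
#' @param minCov Minimum coverage in the discovering cross (inclusive),
#'   default 10.
#' @param restrictTo Optional `GRanges` of known variant sites (e.g. from
#'   [readKnownVariants()]); when given, only positions in it are considered.
#' @return A `data.frame` of candidates with per-cross counts/AFs/coverages,
#'   `discoveringCross` (`"A"`, `"B"` or `"both"`), `unconfirmedLowCoverage`,
#'   and attributes `crossIdA`/`crossIdB`.
#' @export
findCandidates <- function(countsA, countsB, minAF = 0.80, minCov = 10,
                           restrictTo = NULL) {
  stopifnot(minAF >= 0, minAF <= 1, minCov >= 0)
  m <- .mergeCrosses(countsA, countsB)
  if (!is.null(restrictTo)) {
    keys <- paste0(as.character(seqnames(restrictTo)), "_",
                   start(restrictTo))
    m <- m[m$snpId %in% keys, , drop = FALSE]
  }
  qualA <- !is.na(m$afA) & m$afA >= minAF & m$covA >= minCov
  qualB <- !is.na(m$afB) & m$afB >= minAF & m$covB >= minCov
  cand <- m[qualA | qualB, , drop = FALSE]
  qa <- qualA[qualA | qualB]; qb <- qualB[qualA | qualB]
  cand$discoveringCross <- ifelse(qa & qb, "both", ifelse(qa, "A", "B"))
  confCov <- ifelse(cand$discoveringCross == "A", cand$covB, cand$covA)
  cand$unconfirmedLowCoverage <- cand$discoveringCross != "both" & confCov == 0
  rownames(cand) <- NULL
  attr(cand, "crossIdA") <- attr(m, "crossIdA")
  attr(cand, "crossIdB") <- attr(m, "crossIdB")
  attr(cand, "nSitesUnion") <- nrow(m)
  cand
}

#' Exclude strain-homozygous variants shared by both crosses
#'
#' A site with AF at or above `bothAF` in both crosses (where both have
#' coverage > 0) reflects a strain-homozygous variant rather than imprinting
#' and is removed with reason `"strain_variant"`. After exclusion every kept
#' candidate has exactly one discovering cross.
#'
#' @param candidates Candidate table from [findCandidates()].
#' @param bothAF Both-cross AF threshold (inclusive), default 0.80.
#' @return A list with `kept` (candidates) and `excluded` (with a `reason`
#'   column).
#' @export
excludeStrainVariants <- function(candidates, bothAF = 0.80) {
  stopifnot(is.data.frame(candidates))
  if (nrow(candidates) == 0L) {
    excluded <- candidates
    excluded$reason <- character(0)
    return(list(kept = candidates, excluded = excluded))
  }
  shared <- !is.na(candidates$afA) & !is.na(candidates$afB) &
    candidates$covA > 0 & candidates$covB > 0 &
    candidates$afA >= bothAF & candidates$afB >= bothAF
  excluded <- candidates[shared, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "strain_variant"
  else excluded$reason <- character(0)
  kept <- candidates[!shared, , drop = FALSE]
  rownames(kept) <- rownames(excluded) <- NULL
  for (at in c("crossIdA", "crossIdB")) {
    attr(kept, at) <- attr(candidates, at)
  }
  list(kept = kept, excluded = excluded)
}
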