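#' Read a per-site allele-count table for one cross
#'
#' The counts-TSV dialect is tab-separated with header
#' `chrom pos ref alt ref_count alt_count plus_count minus_count`, one row per
#' site; one file per cross. Rows are returned sorted by (chrom, pos).
#' Duplicate sites, negative counts and malformed lines are rejected.
#'
#' @param path Path to the counts TSV.
#' @param crossId Identifier of the cross this file belongs to.
#' @return An [AlleleCounts-class] object.
#' @seealso [writeAlleleCounts()], [readMpileup()]
#' @export
readAlleleCounts <- function(path, crossId) {
  if (!file.exists(path)) .valErr("file not found: ", path)
  header <- c("chrom", "pos", "ref", "alt", "ref_count", "alt_count",
              "plus_count", "minus_count")
  first <- readLines(path, n = 1L)
  if (length(first) == 0L ||
      !identical(strsplit(first, "\t", fixed = TRUE)[[1]], header)) {
    .valErr("header does not match the counts-TSV dialect in ", path)
  }
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t",
                      colClasses = c("character", "integer", "character",
                                     "character", "integer", "integer",
                                     "integer", "integer"),
                      na.strings = "NA", quote = "", comment.char = ""),
    error = function(e) .valErr("parse error in ", path, ": ",
                                conditionMessage(e)))
  if (nrow(df) == 0L) {
    return(AlleleCounts(character(), integer(), character(), character(),
                        integer(), integer(), integer(), integer(),
                        crossId = crossId))
  }
  bad <- which(is.na(df$pos) | is.na(df$ref_count) | is.na(df$alt_count))
  if (length(bad)) {
    .valErr("malformed line ", bad[1] + 1L, " in ", path)  # +1 for header
  }
  if (any(df$ref_count < 0) || any(df$alt_count < 0)) {
    .valErr("negative count in ", path)
  }
  ac <- AlleleCounts(df$chrom, df$pos, df$ref, df$alt,
                     df$ref_count, df$alt_count,
                     df$plus_count, df$minus_count, crossId = crossId)
  validObject(ac)
  ac
}

#' Write an AlleleCounts object as counts-TSV
#'
#' Inverse of [readAlleleCounts()]: `readAlleleCounts(writeAlleleCounts(x, f))`
#' reproduces `x`.
#'
#' @param x An [AlleleCounts-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAlleleCounts <- function(x, path) {
  stopifnot(is(x, "AlleleCounts"))
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter a pileup site by base quality
#'
#' Keeps only read observations whose Phred-scale base quality is at least
#' `minQuality` (default 13, i.e. error probability 0.05), then tallies
#' reference and alternative reads. Bases other than `refBase`/`altBase` are
#' excluded from the counts but reported in the `otherCount` attribute.
#'
#' @param bases Character vector of observed bases (one per read), uppercase
#'   A/C/G/T; lowercase letters are accepted and mark minus-strand reads.
#' @param quals Integer vector of Phred qualities, parallel to `bases`.
#' @param refBase,altBase The site's reference and alternative base.
#' @param minQuality Minimum base quality retained (inclusive).
#' @return A list with `refCount`, `altCount`, `plusCount`, `minusCount` and
#'   attribute-like element `otherCount` (quality-passing reads showing a
#'   third base).
#' @examples
#' filterBaseQuality(rep(c("G", "A"), c(8, 4)), rep(40, 12), "A", "G")
#' @export
filterBaseQuality <- function(bases, quals, refBase, altBase,
                              minQuality = 13L) {
  if (length(bases) != length(quals)) {
    .valErr("bases and quals must have equal length")
  }
  if (any(quals < 0, na.rm = TRUE)) .valErr("qualities must be >= 0")
  keep <- !is.na(quals) & quals >= minQuality
  b <- bases[keep]
  minus <- b %in% c("a", "c", "g", "t")
  bu <- toupper(b)
  isRef <- bu == refBase
  isAlt <- bu == altBase
  list(refCount = sum(isRef), altCount = sum(isAlt),
       plusCount = sum((isRef | isAlt) & !minus),
       minusCount = sum((isRef | isAlt) & minus),
       otherCount = sum(!isRef & !isAlt))
}

## internal: expand one mpileup base string into per-read base characters.
## Handles read-start (^X), read-end ($), indels (+n.../-n...), deletions (*)
## and reference-skip (>/<). Returns characters aligned with the quality
## string: '.'/',' replaced by the reference base in upper/lower case.
.parsePileupBases <- function(baseStr, refBase) {
  chars <- strsplit(baseStr, "")[[1]]
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L            # caret + mapping quality char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "+" || ch == "-") {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len           # skip inserted/deleted sequence
    } else if (ch == ".") {
      out <- c(out, toupper(refBase)); i <- i + 1L
    } else if (ch == ",") {
      out <- c(out, tolower(refBase)); i <- i + 1L
    } else if (ch %in% c("*", ">", "<")) {
      out <- c(out, ch); i <- i + 1L   # consumes a quality, never counted
    } else {
      out <- c(out, ch); i <- i + 1L
    }
  }
  out
}

#' Read samtools-mpileup text into AlleleCounts
#'
#' Parses the 6-column mpileup text format (`chrom pos ref depth bases quals`)
#' into the counts-TSV semantics: per-read base-quality filtering at
#' `minQuality`, the most frequent quality-passing non-reference base taken as
#' the site's alternative allele, and strand counts from the read case
#' (uppercase = plus strand). Sites with no quality-passing alternative reads
#' are dropped (they carry no allele-specific information). Phred qualities
#' are decoded at ASCII offset 33.
#'
#' @param path Path to an mpileup text file.
#' @param crossId Cross identifier.
#' @param minQuality Minimum base quality retained (inclusive), default 13.
#' @return An [AlleleCounts-class] object.
#' @export
readMpileup <- function(path, crossId, minQuality = 13L) {
  if (!file.exists(path)) .valErr("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  recs <- lapply(seq_along(lines), function(k) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) .valErr("malformed mpileup line ", k, " in ", path)
    ref <- toupper(f[3])
    bases <- .parsePileupBases(f[5], ref)
    quals <- utf8ToInt(f[6]) - 33L
    if (length(bases) != length(quals)) {
      .valErr("pileup base/quality length mismatch at line ", k, " in ", path)
    }
    keep <- quals >= minQuality & toupper(bases) %in% c("A", "C", "G", "T")
    b <- bases[keep]
    bu <- toupper(b)
    altTab <- table(bu[bu != ref])
    if (length(altTab) == 0L) return(NULL)
    alt <- names(altTab)[which.max(altTab)]  # ties: first alphabetically
    isRef <- bu == ref
    isAlt <- bu == alt
    minus <- b %in% c("a", "c", "g", "t")
    data.frame(chrom = f[1], pos = as.integer(f[2]), ref = ref, alt = alt,
               ref_count = sum(isRef), alt_count = sum(isAlt),
               plus_count = sum((isRef | isAlt) & !minus),
               minus_count = sum((isRef | isAlt) & minus),
               stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) {
    return(AlleleCounts(character(), integer(), character(), character(),
                        integer(), integer(), crossId = crossId))
  }
  df <- do.call(rbind, recs)
  AlleleCounts(df$chrom, df$pos, df$ref, df$alt, df$ref_count, df$alt_count,
               df$plus_count, df$minus_count, crossId = crossId)
}

#' Library-level alignment QC arithmetic
#'
#' Computes the aligned fraction (aligned / total reads) and the sense
#' fraction (sense-orientation / aligned reads) of a sequencing library,
#' together with one-decimal percentage renderings (half-up rounding, so e.g.
#' 76712608 / 95517702 reports 80.3).
#'
#' @param totalReads,alignedReads Total and aligned read counts.
#' @param senseReads Reads in the sense orientation (optional, `NA` to skip).
#' @return A list with `totalReads`, `alignedReads`, `senseReads`,
#'   `alignedFraction`, `senseFraction`, `alignedPct`, `sensePct`.
#' @examples
#' libraryStats(95517702, 76712608)$alignedPct  # 80.3
#' @export
libraryStats <- function(totalReads, alignedReads, senseReads = NA) {
  if (totalReads == 0) .valErr("totalReads is zero: rates undefined")
  if (alignedReads > totalReads) .valErr("alignedReads exceeds totalReads")
  if (!is.na(senseReads) && senseReads > alignedReads) {
    .valErr("senseReads exceeds alignedReads")
  }
  af <- alignedReads / totalReads
  sf <- if (is.na(senseReads)) NA_real_ else senseReads / alignedReads
  list(totalReads = totalReads, alignedReads = alignedReads,
       senseReads = senseReads,
       alignedFraction = af, senseFraction = sf,
       alignedPct = roundHalfUp(100 * af, 1),
       sensePct = if (is.na(sf)) NA_real_ else roundHalfUp(100 * sf, 1))
}

#' Transcript strand from read-pair orientation code
#'
#' In the dUTP strand-specific protocol the second-strand cDNA is degraded, so
#' read 1 reports the antisense strand and read 2 the sense strand of the RNA:
#' orientation codes F2R1 and R1F2 map to antisense, F1R2 and R2F1 to sense.
#'
#' @param code Character vector of orientation codes.
#' @return Character vector of `"sense"` / `"antisense"`.
#' @examples
#' strandFromOrientation(c("F2R1", "R2F1"))
#' @export
strandFromOrientation <- function(code) {
  map <- c(F2R1 = "antisense", R1F2 = "antisense",
           F1R2 = "sense", R2F1 = "sense")
  bad <- !code %in% names(map)
  if (any(bad)) {
    .valErr("unknown orientation code: ", paste(code[bad], collapse = ", "))
  }
  unname(map[code])
}

#' Read a gene annotation (BED6/BED12 or GTF) into gene models
#'
#' Returns one model per transcript as a `GRanges` of transcript spans with
#' metadata columns `transcriptId`, `geneName` and `exons` (an `IRangesList`
#' of absolute exon intervals). Intervals are stored 0-based half-open
#' internally via GRanges 1-based closed semantics (BED input is shifted by
#' rtracklayer); SNP positions are 1-based points. A missing strand is an
#' error: the method requires stranded models.
#'
#' @param path Path to a `.bed` or `.gtf`/`.gff` file (format inferred from
#'   the extension, override with `format`).
#' @param format `"bed"` or `"gtf"`, default inferred from the file name.
#' @return A `GRanges` of transcript models.
#' @export
readAnnotation <- function(path, format = NULL) {
  if (!file.exists(path)) .valErr("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.(gtf|gff[23]?)$", path, ignore.case = TRUE))
      "gtf" else "bed"
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) && any(as.character(strand(gr)) == "*")) {
      .valErr("annotation has entries without strand; strand is required")
    }
    exons <- if ("blocks" %in% colnames(mcols(gr))) {
      IRanges::shift(mcols(gr)$blocks, start(gr) - 1L)
    } else {
      methods::as(IRanges::ranges(gr), "IRangesList")
    }
    out <- granges(gr)
    mcols(out) <- DataFrame(
      transcriptId = if (!is.null(mcols(gr)$name)) mcols(gr)$name
                     else paste0("tx", seq_along(gr)),
      geneName = if (!is.null(mcols(gr)$name)) mcols(gr)$name
                 else paste0("tx", seq_along(gr)),
      exons = exons)
    return(out)
  }
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[mcols(gr)$type == "exon"]
  if (length(ex) == 0L) ex <- gr     # transcript-only GTF
  if (is.null(mcols(ex)$transcript_id)) {
    .valErr("GTF lacks transcript_id attributes")
  }
  if (any(as.character(strand(ex)) == "*")) {
    .valErr("annotation has entries without strand; strand is required")
  }
  idx <- factor(mcols(ex)$transcript_id)
  exonsList <- methods::as(
    S4Vectors::splitAsList(IRanges::ranges(ex), idx), "IRangesList")
  txStart <- vapply(split(start(ex), idx), min, numeric(1))
  txEnd <- vapply(split(end(ex), idx), max, numeric(1))
  first <- match(levels(idx), as.character(idx))
  gn <- mcols(ex)$gene_name
  geneName <- if (is.null(gn)) levels(idx) else as.character(gn)[first]
  geneName[is.na(geneName)] <- levels(idx)[is.na(geneName)]
  out <- GRanges(as.character(seqnames(ex))[first],
                 IRanges(txStart, txEnd),
                 strand = as.character(strand(ex))[first])
  mcols(out) <- DataFrame(
    transcriptId = levels(idx),
    geneName = geneName,
    exons = exonsList)
  names(out) <- NULL
  out
}

#' Read a sites-only VCF of known strain variants
#'
#' Optionally used to pre-restrict tested positions to known variant sites.
#' Requires the `vcfR` package.
#'
#' @param path Path to an (uncompressed) VCF.
#' @return A `GRanges` of width-1 sites with `refBase`/`altBase` columns.
#' @export
readKnownVariants <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("readKnownVariants() requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(as.matrix(fix))  # single-record VCF
  gr <- GRanges(fix[, "CHROM"],
                IRanges(as.integer(fix[, "POS"]), width = 1L))
  mcols(gr) <- DataFrame(refBase = unname(fix[, "REF"]),
                         altBase = unname(fix[, "ALT"]))
  gr
}
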