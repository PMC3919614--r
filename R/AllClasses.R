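#' @import methods
#' @importFrom GenomicRanges GRanges granges start end strand seqnames mcols mcols<-
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors DataFrame metadata metadata<- Rle
NULL

#' AlleleCounts: per-site allele counts for one cross
#'
#' Holds one cross's observed base-level variant sites as width-1
#' [GenomicRanges::GRanges] (1-based point coordinates) with reference and
#' alternative read counts and an optional breakdown of total reads by
#' inferred transcript strand.
#'
#' Required metadata columns of `sites`: `refBase`, `altBase` (single bases in
#' A/C/G/T, unequal), `refCount`, `altCount` (non-negative integers), and
#' `plusCount`/`minusCount` which, when not `NA`, must partition
#' `refCount + altCount`.
#'
#' @slot sites A `GRanges` of width-1 sites with the metadata columns above.
#' @slot crossId Single string identifying the cross the sample comes from.
#'
#' @seealso [readAlleleCounts()], [AlleleCounts()]
#' @export
setClass("AlleleCounts",
  representation(sites = "GRanges", crossId = "character"))

setValidity("AlleleCounts", function(object) {
  gr <- object@sites
  msg <- character()
  if (length(object@crossId) != 1L || is.na(object@crossId) ||
      !nzchar(object@crossId)) {
    msg <- c(msg, "crossId must be a single non-empty string")
  }
  need <- c("refBase", "altBase", "refCount", "altCount",
            "plusCount", "minusCount")
  miss <- setdiff(need, colnames(mcols(gr)))
  if (length(miss)) {
    return(paste("missing metadata columns:", paste(miss, collapse = ", ")))
  }
  if (length(gr)) {
    m <- mcols(gr)
    if (any(GenomicRanges::width(gr) != 1L)) {
      msg <- c(msg, "sites must be width-1 point positions")
    }
    if (any(start(gr) < 1L)) msg <- c(msg, "positions must be >= 1")
    bases <- c("A", "C", "G", "T")
    if (!all(m$refBase %in% bases) || !all(m$altBase %in% bases)) {
      msg <- c(msg, "refBase/altBase must be one of A, C, G, T")
    }
    if (any(m$refBase == m$altBase)) {
      msg <- c(msg, "refBase and altBase must differ")
    }
    if (any(m$refCount < 0) || any(m$altCount < 0)) {
      msg <- c(msg, "counts must be non-negative")
    }
    hasStrand <- !is.na(m$plusCount) & !is.na(m$minusCount)
    if (any(hasStrand &
            m$plusCount + m$minusCount != m$refCount + m$altCount)) {
      msg <- c(msg,
        "plusCount + minusCount must equal refCount + altCount when present")
    }
    key <- paste(as.character(seqnames(gr)), start(gr))
    if (anyDuplicated(key)) {
      msg <- c(msg, "duplicate (chrom, pos) sites within one cross")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AlleleCounts object
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @param refBase,altBase Single-character reference/alternative bases.
#' @param refCount,altCount Non-negative integer read counts.
#' @param plusCount,minusCount Reads on the plus/minus transcript strand
#'   (`NA` when strand information is absent); when present they must sum to
#'   `refCount + altCount`.
#' @param crossId Identifier of the cross this sample comes from.
#' @return An [AlleleCounts-class] object, sorted by (chrom, pos).
#' @examples
#' ac <- AlleleCounts("chr1", c(200L, 100L), "A", "G", c(5L, 0L), c(5L, 12L),
#'                    crossId = "JXO")
#' sitePositions(ac)  # sorted
#' @export
AlleleCounts <- function(chrom, pos, refBase, altBase, refCount, altCount,
                         plusCount = NA_integer_, minusCount = NA_integer_,
                         crossId) {
  n <- length(pos)
  gr <- GRanges(chrom, IRanges(pos, width = 1L))
  mcols(gr) <- DataFrame(
    refBase = rep_len(as.character(refBase), n),
    altBase = rep_len(as.character(altBase), n),
    refCount = rep_len(as.integer(refCount), n),
    altCount = rep_len(as.integer(altCount), n),
    plusCount = rep_len(as.integer(plusCount), n),
    minusCount = rep_len(as.integer(minusCount), n))
  o <- order(as.character(seqnames(gr)), start(gr))
  new("AlleleCounts", sites = gr[o], crossId = as.character(crossId))
}

#' @describeIn AlleleCounts-class Number of sites.
#' @param x An `AlleleCounts` object.
#' @export
setMethod("length", "AlleleCounts", function(x) length(x@sites))

#' Accessors for AlleleCounts
#'
#' `crossId()` returns the cross identifier; `sites()` the underlying
#' `GRanges`; `refCount()`, `altCount()` the per-site read counts;
#' `siteCoverage()` their sum; `sitePositions()` the 1-based positions and
#' `siteChrom()` the chromosome names; `siteKey()` a "chrom_pos" id string.
#'
#' @param x An [AlleleCounts-class] object.
#' @return Vectors parallel to the sites.
#' @name AlleleCounts-accessors
NULL

#' @rdname AlleleCounts-accessors
#' @export
setGeneric("crossId", function(x) standardGeneric("crossId"))
#' @rdname AlleleCounts-accessors
#' @export
setMethod("crossId", "AlleleCounts", function(x) x@crossId)

#' @rdname AlleleCounts-accessors
#' @export
setGeneric("crossId<-", function(x, value) standardGeneric("crossId<-"))
#' @rdname AlleleCounts-accessors
#' @param value Replacement cross identifier.
#' @export
setMethod("crossId<-", "AlleleCounts", function(x, value) {
  x@crossId <- as.character(value)
  validObject(x)
  x
})

#' @rdname AlleleCounts-accessors
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))
#' @rdname AlleleCounts-accessors
#' @export
setMethod("sites", "AlleleCounts", function(x) x@sites)

#' @rdname AlleleCounts-accessors
#' @export
setGeneric("refCount", function(x) standardGeneric("refCount"))
#' @rdname AlleleCounts-accessors
#' @export
setMethod("refCount", "AlleleCounts", function(x) mcols(x@sites)$refCount)

#' @rdname AlleleCounts-accessors
#' @export
setGeneric("altCount", function(x) standardGeneric("altCount"))
#' @rdname AlleleCounts-accessors
#' @export
setMethod("altCount", "AlleleCounts", function(x) mcols(x@sites)$altCount)

#' @rdname AlleleCounts-accessors
#' @export
setGeneric("siteCoverage", function(x) standardGeneric("siteCoverage"))
#' @rdname AlleleCounts-accessors
#' @export
setMethod("siteCoverage", "AlleleCounts",
          function(x) mcols(x@sites)$refCount + mcols(x@sites)$altCount)

#' @rdname AlleleCounts-accessors
#' @export
setGeneric("sitePositions", function(x) standardGeneric("sitePositions"))
#' @rdname AlleleCounts-accessors
#' @export
setMethod("sitePositions", "AlleleCounts", function(x) start(x@sites))

#' @rdname AlleleCounts-accessors
#' @export
setGeneric("siteChrom", function(x) standardGeneric("siteChrom"))
#' @rdname AlleleCounts-accessors
#' @export
setMethod("siteChrom", "AlleleCounts",
          function(x) as.character(seqnames(x@sites)))

#' @rdname AlleleCounts-accessors
#' @export
setGeneric("siteKey", function(x) standardGeneric("siteKey"))
#' @rdname AlleleCounts-accessors
#' @export
setMethod("siteKey", "AlleleCounts",
          function(x) paste0(siteChrom(x), "_", sitePositions(x)))

setMethod("show", "AlleleCounts", function(object) {
  cat("AlleleCounts for cross '", object@crossId, "': ",
      length(object), " sites\n", sep = "")
  if (length(object)) {
    cv <- siteCoverage(object)
    cat("  coverage: median ", stats::median(cv), ", range ",
        min(cv), "-", max(cv), "\n", sep = "")
  }
})

#' Convert AlleleCounts to a data.frame
#'
#' Columns mirror the counts-TSV dialect: `chrom`, `pos`, `ref`, `alt`,
#' `ref_count`, `alt_count`, `plus_count`, `minus_count`.
#'
#' @param x An [AlleleCounts-class] object.
#' @param row.names,optional Ignored (S3 compatibility).
#' @param ... Ignored.
#' @return A `data.frame` with one row per site.
#' @export
as.data.frame.AlleleCounts <- function(x, row.names = NULL, optional = FALSE,
                                       ...) {
  m <- mcols(x@sites)
  data.frame(
    chrom = siteChrom(x), pos = sitePositions(x),
    ref = m$refBase, alt = m$altBase,
    ref_count = m$refCount, alt_count = m$altCount,
    plus_count = m$plusCount, minus_count = m$minusCount,
    stringsAsFactors = FALSE)
}

#' CrossDesign: reciprocal-cross mating design
#'
#' Describes the two reciprocal crosses: for each cross identifier the mother
#' and father strain, plus the strain assumed to carry the alternative
#' (non-reference) allele. The two crosses must have swapped parental roles.
#'
#' @slot crosses Character vector of the two cross identifiers.
#' @slot mother,father Named character vectors (names = cross ids) giving the
#'   maternal/paternal strain of each cross.
#' @slot altStrain The strain carrying the alternative allele (one of the two
#'   strain labels).
#' @export
setClass("CrossDesign",
  representation(crosses = "character", mother = "character",
                 father = "character", altStrain = "character"))

setValidity("CrossDesign", function(object) {
  msg <- character()
  if (length(object@crosses) != 2L || anyDuplicated(object@crosses)) {
    return("exactly two distinct crosses are required")
  }
  ids <- object@crosses
  if (!setequal(names(object@mother), ids) ||
      !setequal(names(object@father), ids)) {
    return("mother/father must be named by the two cross ids")
  }
  m1 <- object@mother[[ids[1]]]; f1 <- object@father[[ids[1]]]
  m2 <- object@mother[[ids[2]]]; f2 <- object@father[[ids[2]]]
  if (m1 == f1 || m2 == f2) msg <- c(msg, "a cross cannot be a self-cross")
  if (!(m1 == f2 && f1 == m2)) {
    msg <- c(msg, "crosses are not reciprocal (parental strains not swapped)")
  }
  if (length(object@altStrain) != 1L || !object@altStrain %in% c(m1, f1)) {
    msg <- c(msg, "altStrain must equal one of the two strain labels")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a reciprocal CrossDesign
#'
#' @param ids Character vector of the two cross identifiers, e.g.
#'   `c("JXO", "OXJ")`.
#' @param mothers,fathers Named character vectors (names = `ids`) with the
#'   maternal and paternal strain of each cross; the two crosses must be
#'   reciprocal.
#' @param altStrain Strain carrying the alternative allele (typically the
#'   strain genetically distant from the reference genome, e.g. `"JF1"`).
#' @return A [CrossDesign-class] object.
#' @examples
#' jxoDesign()
#' @export
CrossDesign <- function(ids, mothers, fathers, altStrain) {
  new("CrossDesign", crosses = as.character(ids),
      mother = mothers[ids], father = fathers[ids],
      altStrain = as.character(altStrain))
}

#' The JF1 x OG2 reciprocal MEF design
#'
#' Convenience constructor for the JXO (JF1 mother x OG2 father) and OXJ
#' (OG2 mother x JF1 father) reciprocal crosses with JF1 as the
#' alternative-allele strain.
#'
#' @return A [CrossDesign-class] object.
#' @export
jxoDesign <- function() {
  CrossDesign(c("JXO", "OXJ"),
              mothers = c(JXO = "JF1", OXJ = "OG2"),
              fathers = c(JXO = "OG2", OXJ = "JF1"),
              altStrain = "JF1")
}

#' @describeIn CrossDesign-class Mother strain of a cross.
#' @param object A `CrossDesign`.
#' @param cross Cross identifier.
#' @export
setGeneric("motherStrain", function(object, cross)
  standardGeneric("motherStrain"))
#' @rdname CrossDesign-class
#' @export
setMethod("motherStrain", "CrossDesign", function(object, cross) {
  if (!cross %in% object@crosses) .valErr("unknown cross: ", cross)
  object@mother[[cross]]
})

#' @rdname CrossDesign-class
#' @export
setGeneric("fatherStrain", function(object, cross)
  standardGeneric("fatherStrain"))
#' @rdname CrossDesign-class
#' @export
setMethod("fatherStrain", "CrossDesign", function(object, cross) {
  if (!cross %in% object@crosses) .valErr("unknown cross: ", cross)
  object@father[[cross]]
})

#' @rdname CrossDesign-class
#' @export
setGeneric("altStrain", function(object) standardGeneric("altStrain"))
#' @rdname CrossDesign-class
#' @export
setMethod("altStrain", "CrossDesign", function(object) object@altStrain)

#' @rdname CrossDesign-class
#' @export
setGeneric("crossIds", function(object) standardGeneric("crossIds"))
#' @rdname CrossDesign-class
#' @export
setMethod("crossIds", "CrossDesign", function(object) object@crosses)

#' Swap the labels of the two crosses in a design
#'
#' Returns a design in which the two cross identifiers point at the swapped
#' matings, i.e. the cross previously labelled `ids[1]` is now labelled
#' `ids[2]` and vice versa. Used by the reciprocity property: relabelling the
#' crosses must flip every maternal call to paternal and vice versa.
#'
#' @param object A [CrossDesign-class].
#' @return A [CrossDesign-class] with swapped labels.
#' @export
setGeneric("swapCrosses", function(object) standardGeneric("swapCrosses"))
#' @rdname swapCrosses
#' @export
setMethod("swapCrosses", "CrossDesign", function(object) {
  ids <- object@crosses
  CrossDesign(ids,
              mothers = stats::setNames(object@mother[rev(ids)], ids),
              fathers = stats::setNames(object@father[rev(ids)], ids),
              altStrain = object@altStrain)
})

setMethod("show", "CrossDesign", function(object) {
  ids <- object@crosses
  cat("CrossDesign (reciprocal):\n")
  for (id in ids) {
    cat("  ", id, ": mother ", object@mother[[id]],
        " x father ", object@father[[id]], "\n", sep = "")
  }
  cat("  alternative-allele strain:", object@altStrain, "\n")
})
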