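# Independent oracles and small fixture builders shared across tests.

# Brute-force two-sided Fisher p by full enumeration of all 2x2 tables with
# the observed margins, using choose() only (independent of dhyper and of the
# package implementation).
bruteFisherP <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; N <- r1 + r2
  support <- max(0, k - r2):min(k, r1)
  prob <- vapply(support, function(x) {
    choose(r1, x) * choose(r2, k - x) / choose(N, k)
  }, numeric(1))
  obs <- prob[support == a]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

# Naive O(n^2) Benjamini-Hochberg step-up straight from the definition:
# sort ascending, adj_(i) = min over j >= i of p_(j) * n / j, clip at 1,
# map back to input order.
naiveBH <- function(p) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  raw <- ps * n / seq_len(n)
  adj <- vapply(seq_len(n), function(i) min(1, min(raw[i:n])), numeric(1))
  out <- numeric(n)
  out[o] <- adj
  out
}

# Compact AlleleCounts builder for hand-written sites.
mkCounts <- function(pos, ref, alt, crossId, chrom = "chr1",
                     plus = NA_integer_, minus = NA_integer_) {
  AlleleCounts(chrom, pos, "A", "G", refCount = ref, altCount = alt,
               plusCount = plus, minusCount = minus, crossId = crossId)
}

# Candidate row(s) in the shape produced by findCandidates(), for feeding
# callTrueSnps() directly.
mkCandidate <- function(altA, refA, altB, refB, discovering = "A",
                        pos = 100L, chrom = "chr1") {
  df <- data.frame(
    chrom = chrom, pos = pos, ref = "A", alt = "G",
    refA = refA, altA = altA, refB = refB, altB = altB,
    plusA = NA_integer_, minusA = NA_integer_,
    plusB = NA_integer_, minusB = NA_integer_,
    covA = refA + altA, covB = refB + altB,
    afA = ifelse(refA + altA > 0, altA / (refA + altA), NA_real_),
    afB = ifelse(refB + altB > 0, altB / (refB + altB), NA_real_),
    stringsAsFactors = FALSE)
  df$snpId <- paste0(df$chrom, "_", df$pos)
  df$discoveringCross <- discovering
  df$unconfirmedLowCoverage <- df$covA == 0 | df$covB == 0
  attr(df, "crossIdA") <- "JXO"
  attr(df, "crossIdB") <- "OXJ"
  df
}
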