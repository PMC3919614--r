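---
title: "Detecting genomic imprinting from reciprocal-cross allele-specific RNA-seq"
author: "imprintASE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting genomic imprinting from reciprocal-cross allele-specific RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imprintASE)
```

## The problem and the design

Imprinted genes are expressed from only one parental allele. In a single
individual, allele-specific RNA-seq cannot tell parent-of-origin silencing
from ordinary strain-specific (cis-regulatory or genotype) effects. The
reciprocal-cross design resolves this: two matings with the parental strains
swapped (here JF1/Ms mother x OG2 father, "JXO", and the reciprocal "OXJ").
The JF1 genome is diverged from the reference-like OG2 background at millions
of SNPs, so reads can be assigned to a parental allele wherever a transcript
covers such a site. A maternally expressed gene shows the JF1 allele in
essentially all reads in JXO (where JF1 is the mother) and essentially none
in OXJ; a strain effect shows the same allele in *both* crosses and cancels.

`imprintASE` implements this logic as a tested pipeline operating on per-SNP
allele-count tables — one per cross — plus a stranded gene annotation:

1. **Candidate discovery** (`findCandidates`): a site is a candidate when, in
   at least one cross, the alternative allele fraction (AF = alt/(ref+alt))
   is at least 0.80 and total coverage is at least 10. The coverage gate
   binds the *discovering* cross only; the confirming cross contributes
   whatever reads it has (a confirming sample with 9 reads is still usable),
   though a site entirely absent from the confirming cross can never be
   called.
2. **Strain-variant exclusion** (`excludeStrainVariants`): sites with
   AF >= 0.80 in *both* crosses are homozygous strain variants, not
   imprinting, and are removed with a reason code.
3. **TRUE-SNP calling** (`callTrueSnps`): each candidate's 2x2 table of
   alt/ref reads in the two crosses is tested with a two-sided Fisher exact
   test; p-values are Benjamini–Hochberg adjusted over the whole candidate
   family; a SNP is TRUE iff FDR <= 0.05, the confirming cross's AF is
   <= 0.20 and its coverage is positive. All comparisons are inclusive,
   exactly as the thresholds are printed.
4. **Origin assignment** (`assignOrigin`): the origin is the parental role of
   the alternative-allele strain in the discovering cross — with JF1 as the
   alternative strain, discovery in JXO means maternal, in OXJ paternal.
5. **Annotation and aggregation** (`annotateSnps`, `aggregateTranscripts`):
   SNPs map to every transcript span containing them (an `--exonic-only`
   mode restricts to exons); transcript calls report the number of TRUE
   SNPs, the mean combined per-SNP read count, the consensus origin
   (unanimity, else CONFLICT — conflicted transcripts are diagnosed, never
   reported as imprinted) and a representative (highest-coverage) SNP.
6. **Extension detection** (`detectExtensions`): clusters of *intergenic*
   TRUE SNPs concordant in chromosome, origin and read strand that lie
   downstream of a called imprinted transcript are reported as imprinted
   transcript extensions.
7. **Vetting** (`vetTranscript`, `vetPredictionSet`): novel predictions are
   screened for three artifact signatures (below).

## Statistical model

At a heterozygous site with $r$ reference and $a$ alternative reads per
cross, the decision rule compares the two crosses' tables
$\begin{pmatrix} a_1 & r_1 \\ a_2 & r_2\end{pmatrix}$ by Fisher's exact
test. The two-sided p-value uses the minimum-likelihood definition: the sum
of hypergeometric point probabilities, over all tables with the observed
margins, not exceeding the observed table's probability (a relative
tolerance of 1e-7 guards machine-epsilon ties; this matters only at exact
probability ties and is documented because it changes p at those
boundaries). The odds ratio is reported with the zero-cell convention
(infinite or zero, never filtered on); a Haldane–Anscombe corrected value is
emitted alongside. BH adjustment is the standard step-up procedure
(`stats::p.adjust`), applied by default to all candidates pooled across both
crosses; a per-cross family is available via `fdrFamily = "per_cross"`
because the discovering cross partitions candidates naturally.

Directionality is supplied not by a one-sided test but by the reciprocal-AF
gate: the confirming cross must show the alternative allele at <= 20%. This
makes the test conservative and symmetric in the crosses: relabelling the
two crosses flips every maternal call to paternal and changes no p-value,
FDR or status — a property verified end-to-end in the test suite.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `minAF` | 0.80 | discovery AF threshold (inclusive) |
| `minCov` | 10 reads | discovery coverage threshold, discovering cross only |
| `bothAF` | 0.80 | both-cross AF above which a site is a strain variant |
| `fdrMax` | 0.05 | BH-adjusted significance threshold |
| `recipAFMax` | 0.20 | maximum confirming-cross AF |
| `minQuality` | 13 (Phred) | base quality floor in pileup parsing |
| `maxGap` | 10 kb | maximum inter-SNP gap within an extension cluster |
| `minSnps` | 2 | minimum SNPs per extension |
| `maxReach` | 100 kb | maximum parent-3'-end-to-cluster distance |
| `minorityCutoff` | 0.5 | TRUE fraction below which a call is minority-TRUE |
| `densityCutoff` | 10 /kb | SNP density above which a call is pseudogene-like |
| `sharedCutoff` | 0.5 | both-cross high-AF fraction flagging paralog mixtures |

The discovery, exclusion and selection thresholds (0.80, 10, 0.05, 0.20, 13)
are the method's published constants. The extension-clustering defaults are
this package's own choices: the original detection was visual, with no
numeric rule. `maxGap` = 10 kb reconnects extension spans whose SNPs are
locally dense but that begin ~15 kb downstream of their parent's annotated
3' end, while `maxReach` = 100 kb bounds runaway assignment across an
imprinted domain; both are exposed. The extension span is reported as the
SNP span (first to last supporting SNP, 1-based inclusive) — the only
desk-scale evidence; whether a published span marks SNP support or
continuous read coverage is unknowable from counts alone. Parent eligibility
is any transcript with an imprinting call of matching origin, not only
catalogue genes, so extensions can chain through a read-through domain.

The vetting cutoffs are declared heuristics, not published values: "in
minority" is read literally as < 0.5; 10 SNPs/kb sits far above genuine
JF1-versus-reference transcript SNP density (roughly 1 per 150 bp genome
wide) yet far below the ~27/kb observed in a pseudogene misassignment;
paralog mixtures are flagged when more than half of the informative SNPs are
high-AF in both crosses *before* strain-variant exclusion — vetting
deliberately sees the pre-exclusion site table.

## Coordinates, rounding, degenerate inputs

Interval annotations are handled 0-based half-open at the file boundary (BED
semantics via `rtracklayer`) and SNPs as 1-based points, matching
"chrom_pos" SNP identifiers. Reported percentages round half-up (80.25
prints 80.3); mean read counts round half-up to integers. Phred qualities in
mpileup text are decoded at ASCII offset 33. Sites where every read fails
the quality floor yield zero counts and drop out at the coverage gate.
Tri-allelic sites keep the most frequent non-reference base as the
alternative; reads supporting a third base are excluded from AF denominators
but tallied. An all-zero 2x2 table is a validation error; a zero-coverage AF
is undefined rather than zero. Ties for the representative SNP break by
genomic position; extension clustering is deterministic and
input-order-invariant.

## The synthetic-data generator

`simulateReciprocalCross(syntheticConfig(), seed)` emulates the data model
the decision rule assumes: SNPs placed by a Poisson process (2/kb) along
5 kb genes, per-site coverage negative-binomial (mean 30, size 5 —
RNA-seq coverage is overdispersed; `coverageDispersion = Inf` recovers
Poisson), and alternative-read counts binomial with success probability
$(1-\varepsilon)$ for the expressed-alternative state, $\varepsilon$ for
the silenced state, 0.5 for biallelic loci, the maternal leak $\theta \in
[0.21, 0.25]$ for leaky genes, and $(1-\varepsilon)$ in both crosses for
strain variants. A single global $\varepsilon = 0.01$ models sequencing
error plus cross-mapping. In cross A the maternal strain carries the
alternative allele; cross B is the reciprocal flip. Decoy structures
reproduce the known artifact modes: pseudogene mixtures (30 SNPs over
1.1 kb, most shared between crosses, two uniparental), biallelic genes with
one aberrant uniparental SNP, and extensions that reuse their parent's
state at scaled coverage downstream of its 3' end.

Each locus draws from its own deterministically derived RNG substream, so
identical `(config, seed)` give byte-identical files and appending loci
never perturbs existing ones. The `sampling = "expected"` mode is the
noise-free limit: coverage fixed at the mean and alternative counts
$\lfloor f \cdot c \rfloor$. Truncation (rather than rounding) is
deliberate: it guarantees a leaky gene's discovering-cross AF is at most
$1-\theta \le 0.79$, strictly below the 0.80 gate, *at every coverage* —
with rounding, $\theta = 0.21$ at coverage 10 would hit AF exactly 0.80 and
leak through. The leaky boundary tests therefore exercise the exact
behaviour the thresholds encode.

What the generator does **not** model: read-level errors and alignment bias
(no FASTQ, no mapping), fragment-length effects, per-site error variation,
replicate structure (the design has one library per cross), or
overdispersion beyond the negative-binomial coverage (allele counts are
binomial given coverage). Passing recovery tests therefore show the decision
rule is implemented correctly under its own assumptions, not that those
assumptions hold in any particular real library.

## Benchmarked operating characteristics

The test suite (fixed seeds, 20 replicates at the default conditions:
500 genes, 20 maternal, 20 paternal, 5 leaky, coverage 30,
$\varepsilon = 0.01$, >= 3 SNPs per imprinted gene) checks per-gene
sensitivity >= 0.90, origin accuracy = 1.0 among detections, and realized
per-SNP false-discovery proportion <= 0.10; leaky genes count as negatives.
Problem sizes throughout the suite (tables with margins <= 25 for the
Fisher enumeration oracle, p-vectors up to length 1000 for the BH oracle,
tens of genes for property tests) were chosen as the smallest scales at
which the properties are non-trivial. The leaky false positives that do
arise under binomial noise come from $\theta \approx 0.21$ sites whose
discovering-cross AF fluctuates above 0.80 — they dominate the (small)
realized FDP and are the same boundary behaviour seen at a paternally
biased, 21–25% leaky gene in real data.

## Known limitations

* No beta-binomial overdispersion in allele counts and no replicate-aware
  hierarchical testing; with one library per cross the Fisher test is the
  natural resolution.
* No genotype-likelihood model, indels or phasing; candidate discovery is
  threshold-based by design.
* Mitochondrial/NUMT-style misassignment is only handled via a user-supplied
  paralog exclusion list; inferring paralogy requires sequence, which the
  count tables do not carry.
* Extension calls describe allele-specific transcription continuing past an
  annotated 3' end; whether an extension is an independent transcription
  unit cannot be decided from counts and is out of scope.
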