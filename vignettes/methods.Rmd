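---
title: "Methods: gene-structure, splicing and functional-annotation analytics"
author: "structome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-structure, splicing and functional-annotation analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structome)
```

## The problem

Comparative questions about plant gene structure — are 5'-UTR introns
longer and more frequent in mosses than in angiosperms? how much of a
gene complement splices alternatively, and does it change the protein?
how many genes have secondarily lost introns? which families are
expanded, which loci are orphans, and what does the functional
annotation say about it — are usually answered with ad-hoc scripts bound
to one annotation release. This package turns that battery of analyses
into a tested library operating on standard inputs (GFF3, OrthoMCL-style
cluster files, GAF/OBO, simple TSV evidence tables), with synthetic
generators that plant ground truth for every stage.

## Gene models and the single region convention

`readGFF3()` builds `GenomeAnnotation` → `GeneModel` → `TranscriptModel`
objects from gene/mRNA/exon/CDS features. External files are 1-based
inclusive (the GFF3 convention); the implementation works on `IRanges`
throughout, so interval arithmetic is closed-form rather than
positional.

Two deliberate design choices remove ambiguity:

* **UTRs are always derived.** Any `five_prime_UTR`/`three_prime_UTR`
  features in the input are ignored and the UTRs recomputed from the
  exon/CDS geometry. One authority means the partition invariant
  |UTR5| + |CDS| + |UTR3| = spliced length is testable on every coding
  transcript.
* **Intron region classes are decided in spliced coordinates.** An
  intron preceded by *b* exonic nucleotides (transcript orientation) is
  `UTR5` iff *b* ≤ |UTR5|, `UTR3` iff *b* ≥ |UTR5| + |CDS|, else `CDS`.
  Introns sit strictly between exons, so no straddle case exists; the
  boundary cases are assigned so that an intron whose acceptor abuts the
  start codon is a 5'-UTR intron at ATG distance 0. Transcripts without
  CDS are retained, flagged non-coding-like, excluded from CDS/UTR
  statistics, and their introns all classed `CDS`.

CDS inputs may be given either as per-exon segments (as GFF3 emits them)
or as a genomic span crossing introns; spans are clipped to the exons. A
CDS interval with no exonic overlap is a structural error naming the
transcript.

## Structure statistics

`genomeStructureSummary()` reports means and medians for the standard
per-genome rows. Numerical conventions, fixed once:

* medians are interpolated (mean of the middle pair) everywhere;
* "introns longer than 500 bp" uses strictly greater; "ATG distance
  below 65 nt" uses strictly less;
* the multi-exon 5'-UTR fraction divides by transcripts *with* a 5'-UTR,
  not by all transcripts;
* per-gene rows (exons/introns per gene) are averaged over all
  transcripts by default. Published tables are ambiguous about whether
  such rows pool isoforms or use one representative per locus, so both
  scopes are exposed (`scope = "representative_only"` takes an explicit
  gene-to-transcript map or defaults to the longest isoform).

5'-UTR intron positions (`proximalUtr5IntronDistances()`) are measured
in **spliced** coordinates: the distance from the proximal intron's
acceptor to the ATG, and from the TSS to its donor. Genomic distances
would grow with intervening intron lengths, while the functional length
of a 5'-UTR (scanning, uORFs) is the spliced one; this was a genuinely
open choice and the spliced convention is the documented one.

## Two-sample tests

Genome-scale 2×2 comparisons produce p-values far below the
double-precision underflow limit (the multi-exon 5'-UTR comparison of
7,120/18,180 vs 7,940/31,793 transcripts has log10 p ≈ −238).
`twoProportionExactTest()` therefore computes one-sided hypergeometric
tails with `phyper(log.p = TRUE)` and reports log10 p alongside p; the
two-sided p is the doubled smaller tail, clamped at 1. The rank-sum test
uses the tie-corrected normal approximation without continuity
correction, matching the standard reference implementation, and
`adjustFdr()` is Benjamini–Hochberg.

## Alternative-splicing classification

Events are classified per isoform pair, inside the genomic overlap of
the two transcripts only — differing transcript termini outside the
partner's span are TSS/poly-A variation, not splicing. Rule precedence:

1. **Cassette exons**: an exon strictly inside a partner intron whose
   flanking introns share that intron's outer splice sites →
   `retained_exon` + `skipped_exon` (complementary pair).
2. **Retention**: an intron strictly inside a partner exon →
   `retained_intron` on the exon carrier + `spliced_intron` on the
   intron carrier.
3. **Alternative donor/acceptor**: two introns sharing exactly one
   splice site (donor = transcript-5' end, strand-aware). A pair is
   *suppressed* when either intron wholly contains a complete partner
   exon: that configuration is an exon-level difference, not a shifted
   splice site. This makes mutually-exclusive exons classify as one
   `alternate_exon` per unmatched exon rather than as spurious
   donor/acceptor shifts.
4. **Termini**: a transcript 5'/3' end strictly inside a partner intron
   → `starts_in_intron` / `ends_in_intron`.
5. **Residual**: overlap-clipped exons with no identical partner exon
   and not adjacent to any event above → `alternate_exon`.

Containment is strict throughout — single-nucleotide shared boundaries
never count as "inside". Published event tables distinguish assemblies,
subclusters and genes following the internals of transcript-assembly
pipelines; this package reports transcript-level and locus-level counts
(assembly ≈ transcript, subcluster ≈ gene), which is the mapping its
summaries document.

A locus is alternatively spliced iff it has ≥ 2 structurally distinct
isoforms. Its effect class compares CDS interval chains (any difference
→ `CDS_altering`; the distinct-chain count is the distinct protein
count) and flags UTR involvement for events whose interval overlaps the
pair's UTRs but not their CDS.

The classifier is verified two ways: every planted single-event locus
(all nine types, both strands) classifies with exactly the expected
label set, and on 1,000 random two-isoform loci the classification
matches an independent brute-force enumerator of all splice-site and
containment relations.

## Gene families and intron loss

Representative isoforms follow a three-tier rule: minimum uncorrected
distance (p-distance, gap columns excluded) to any non-focal cluster
member; else best coverage of the closest homology hit; else the longest
transcript — ties always break to the lexicographically smallest
transcript id, making selection deterministic.

Intron-loss inference compares each focal gene against the interpolated
median intron count *m* of its cluster's non-focal members:
`reduced_introns` iff strictly fewer introns than *m*, `full_loss`
additionally iff zero introns with *m* ≥ 1. "Significantly shorter"
fragmentary models are not defined quantitatively in the literature this
mirrors; the implementation uses a configurable transcript-length ratio
(default 0.5 of the median non-focal transcript length), which excludes
sub-half-length fragments before any call. A locus in several clusters
is evaluated per cluster and reported with its most severe call.
Genome-level fractions divide by all focal genes in the annotation.

Expansion calls: a family is expanded when the focal count strictly
exceeds the largest other-species count, strongly expanded when it
exceeds twice that count (strictly: 3 vs 1 qualifies, 2 vs 1 does not).

## Functional layer

`pred2goa()` pools per-protein subcellular predictions at the GO-slim
cellular-component level. A term is assigned iff its supporting weight
strictly exceeds half the total weight of the tools voting on that
protein (exact half never qualifies), so at most one term can win per
protein at the default threshold. For proteins that are N-terminally
unreliable (no annotated UTR or no start codon) the assignment also
requires a supporting tool whose prediction uses more than the
N-terminal region — N-terminal sorting signals are exactly what a
truncated model corrupts. Assignments carry the ISS evidence code and
merge into existing annotations without deletions; tool weights default
to uniform because published tool sets rarely state theirs, and the
precedence of evidence classes (experimental > ISS > IEA) is
configuration, not hard-coded policy.

`mapToSlim()` replaces each term by its minimal slim ancestors over
is_a ∪ part_of (dropping slim terms that are ancestors of other matched
slim terms), which makes the mapping idempotent. Terms without a slim
ancestor are dropped by default or mapped to the aspect root.

`termEnrichment()` frames two-species comparison as a per-term 2×2 table
over annotated-gene universes (the universe definition is configurable
to all genes, since published tables rarely print theirs), with exact
one-sided p in both directions and per-aspect BH correction.
Decorrelation heuristics over the GO graph (weight/elim-style testing)
are intentionally out of scope; classic per-term exact testing is the
documented method.

`effectiveNumberOfCodons()` implements Wright's estimator with the
homozygosity F = (nΣp̂² − 1)/(n − 1), averaged within degeneracy classes
{2, 3, 4, 6}; Met, Trp and stops are excluded, amino acids seen fewer
than twice or with non-positive F do not enter the class mean, an
unobserved threefold class is interpolated as (F̄2 + F̄4)/2, and the
result is clamped to the theoretical maximum 61. Exactly uniform usage
at finite n gives F slightly below 1/k, so the clamp is what makes the
uniform limit exact.

## The synthetic generators

`simulateGenome()` emulates a moss-like catalogue: exon counts are
1 + Poisson draws split across regions, region lengths are lognormal
(5'-UTR 307, CDS 1,062, 3'-UTR 367 nt), UTR presence probabilities are
0.47/0.50, the mean 5'-UTR intron count (0.5, given a 5'-UTR) matches a
~39% multi-exon 5'-UTR fraction, and intron lengths are lognormal with
per-region means 520/264/268 bp (sdlog 0.6, floored at 20 bp). These
defaults are the study conditions, not dials. Planted quantities that
tests assert exactly — AS locus counts and types, intron-loss calls,
fragmentary decoys, expansions, enriched terms — are constructed, not
sampled. Two-isoform AS loci come from fixed per-type templates verified
closed-loop against the classifier; mirroring a template onto the minus
strand preserves its type.

What the generators do *not* emulate: nucleotide sequence (no FASTA is
emitted; splice-site dinucleotides are never checked), transposable
elements and nested genes, partially spliced transcript evidence (which
inflates intron retention in EST-based catalogues), annotation errors
other than the explicit fragmentary decoys, and inter-gene dependence.
Passing tests therefore demonstrate correctness of the *computations*
under clean planted truth, not robustness to the noise of a real
annotation release.

## Problem sizes and determinism

Test and acceptance runs use 50–2,000-gene genomes, 200-cluster family
sets, 200-term annotation pairs and 1,000 random loci for the classifier
cross-check; the acceptance script's parameter-recovery genome uses
5,000 genes so that the rare 3'-UTR intron class (~7.6% of transcripts)
still yields a stable mean. All randomness flows from one seed;
generation is integer-driven, so equal seeds give byte-identical output
files. Parameter-recovery assertions use 3-standard-error bounds;
exactly planted counts are asserted exactly.

## Known limitations

* The AS taxonomy is pairwise; loci with many isoforms report the union
  of pairwise events, which can double-label one physical variation.
* Intron retention cannot be distinguished from partially processed
  transcript evidence — a property of the input catalogue, not of the
  classifier.
* GAF/OBO support covers the subsets the analyses need (17-column GAF
  2.x, `[Term]` stanzas with is_a/part_of); it is not a general ontology
  toolkit.
* `runPipeline()` wires file-based stages; cross-species GFF3 inputs for
  the intron-loss stage must fit in memory together.
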