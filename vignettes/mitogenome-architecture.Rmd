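---
title: "Dissecting the architecture of intron-rich organelle genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting the architecture of intron-rich organelle genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoarch)
```

# The problem

AT-rich circular mitogenomes of some red algae reach 3–6 times the size
of their relatives while encoding the same small gene set. Two
architectural features explain the expansion: group II introns — mobile,
self-splicing elements that insert into protein-coding genes, frequently
carry an ORF (the intron-encoded protein, IEP, with reverse-transcriptase
and maturase domains) and occasionally insert into *each other*
(twintrons) — and tandem repeats concentrated in one large intergenic
region (LIR), consistent with replication slippage near the replication
origin. `mitoarch` quantifies both phenomena from an annotated genome
record and provides a synthetic genome generator so that every measurement
can be validated by parameter recovery.

This vignette documents the models, the defaults and why they were
chosen, the numerical conventions, and the limitations.

# Coordinates and containers

All internal coordinates are 0-based half-open; GenBank's 1-based
inclusive convention is converted at the I/O boundary. This makes
wrapped (origin-spanning) arithmetic on circular genomes a plain modulus
and eliminates the usual off-by-one traps. A feature may be
multi-segment (spliced genes) and a segment may run past `L` to represent
an interval wrapping the sequence origin. Ambiguity codes other than `N`
are rejected; `N` is excluded from all GC computations and never matches
a repeat consensus or an alignment seed.

The region partition assigns every position exactly one label with
precedence exon > intron > rRNA > tRNA > intergenic. Two refinements
matter in practice:

* a `gene` feature acts as a *weak* exon layer (painted first, so
  introns, rRNA and tRNA overpaint it): a gene annotated only as
  gene + introns still yields its exonic remainder;
* an ORF fully contained in an intron is an IEP and stays part of the
  intron class — intron lengths in the per-gene tables therefore include
  their IEPs, matching how intron content is reported in organelle
  genomics. Free-standing ORFs count as CDS-class (exon).

The LIR is defined as the longest maximal intergenic run on the circle,
allowed to wrap the coordinate origin. Its boundaries are derived, not
asserted: annotation conventions differ in where genes "end", so
LIR-derived statistics (length, GC, repeat density) inherit that
uncertainty.

# Tandem repeats

The detector follows the ETANDEM scoring model. For a candidate period
$p$ and a run of $k \ge 2$ full copies starting at $a$, the copies are
stacked as rows of a $k \times p$ matrix; each column's consensus is its
majority base and the score is

$$S = (\#\text{matches to consensus}) - (\#\text{mismatches}) = 2\sum_c \max_b n_{cb} - kp.$$

Reported repeats are the greedy non-overlapping selection per period
(score descending, then leftmost, then fewest copies) among all runs
with $S \ge$ `threshold`; runs of different periods may overlap, and
`dedupe_repeats()` collapses them (highest score, ties to the smaller
period then leftmost start). These tie-break rules make the output a
*canonical* set, which is what allows an exact equivalence test against
a brute-force enumerator.

Defaults: unit sizes 2–500 bp (scanned in one pass; the classical
five-range protocol 2–100, …, 401–500 is reproduced by the unit-length
binning of the output), score threshold 20, and `mismatch_allowed =
FALSE`. The last default deserves a note: with mismatches allowed, a
score-20 threshold admits any adjacent pair of ≥ 52%-identical windows
once the unit is large, which floods an AT-rich 2–500 bp scan with
marginal two-copy calls; disallowing mismatches (all copies identical,
the EMBOSS default) keeps the default output interpretable, while the
mismatch-tolerant scorer remains available as a flag. Binning is by unit
length (period); an alternative by total span is available in
`bin_repeats()`, since published repeat-size ranges are sometimes read
either way.

Two engineering choices keep the scan exact where it matters and fast
where it must be. Sequences ≤ 2 kb are swept exhaustively (this is the
regime of the brute-force equivalence tests). Longer sequences use a
periodicity prefilter — a start position is only extended when the first
adjacent copy pair agrees at ≥ 50% of sites — plus an x-drop stop
(`max(2p, 2·threshold, 50)`); both are exact for the near-perfect
repeats the default scorer reports. Circular sequences are scanned with
a `2·max_period` extension and duplicates mapping to the same circular
locus are discarded. Repeat density is `1000 · count / scope_length`
with repeats assigned to a scope by their midpoint.

# GC skew and replication origin

Windowed skew is $(G-C)/(G+C)$ over windows of `w = 1000` bp every
`s = 25` bp (the resolution used for genome-scale skew plots of small
organelle genomes; at GC 25% a 1 kb window holds ~250 informative bases,
enough to make a 0.1–0.3 amplitude switch visible above counting noise).
Windows wrap on circular genomes; windows with no G or C contribute skew
0 and are flagged rather than NaN, keeping the cumulative series defined
on extremely AT-rich stretches.

The cumulative series is the prefix sum of window skews. A circular
prefix sum depends on the arbitrary starting coordinate, so extrema are
located on the *detrended* series $d_i = C_i - C_n \cdot i/n$: this
makes the predicted positions exactly invariant under genome rotation
(the detrended series only shifts and gains a constant). The global
minimum of $d$ is the predicted replication origin, the maximum the
terminus — the convention that the leading strand is G-rich. A
prominence filter (extremum depth relative to the series range, default
0.1) marks whether a peak is "distinct"; a constant-zero profile returns
a no-signal call.

One symmetry is worth recording because it is easy to get backwards:
reverse-complementing the genome negates every window skew *and* mirrors
coordinates. The two effects compose to $d_{rc}(i) = d(n-i)$, so the
minimum stays a minimum and both predictions map to the same physical
locus — as they should, since a replication origin is a property of the
molecule, not of the strand you read.

# Genome-size decomposition and correlation

`decompose_genome()` reports component totals straight from the region
partition (so they sum to `L` exactly) and a per-gene table with
`gene_span = exon_len + intron_len` and the intron fraction. Nested
(twintron) introns are handled by taking the *union* of intron positions
per gene, never double-counting the inner span. IEPs are counted as ORF
features fully contained in an intron, once each, twintron or not.

The genome-wide "genic intron share" uses exon + intron of
protein-coding genes (CDS and free-standing ORF hosts) as the
denominator, excluding structural-RNA genes; `genic_includes_rna = TRUE`
gives the alternative reading. `correlate_genome_size()` is ordinary
least squares of genome length on a component length with
$r^2 = 1 - SS_{res}/SS_{tot}$, requiring $n \ge 3$ and a non-degenerate
predictor.

# Splice-site profiles

For every intron (twintron inner introns included) four fixed-width
blocks are taken on the coding strand: 10 bp of upstream exon, the first
5 bp of intron, the last 5 bp of intron, 10 bp of downstream exon.
Blocks are ungapped, fixed-width extractions: aligning equal-length
blocks anchored at the splice junction with a general aligner reduces to
exactly this, so no realignment step is performed (a deliberate
approximation — a length-heterogeneous alignment could shift columns).
Introns shorter than 10 bp are skipped with a warning; blocks clipped at
the boundary of a linear sequence are N-padded and flagged, and pads are
excluded from the frequency matrices. Position frequency matrices
(PFMs) report per-column base frequencies and the dominant base; counts
add across context sets, which is the additivity property the tests
exercise.

# Self-similarity and twintrons

Duplicated segments are found by seed-and-extend: exact 11-mer seeds on
the forward and reverse-complement strands, clustered into diagonal
bands (bandwidth 50 bp, split at > 500 bp gaps), each cluster resolved
by a full affine-gap Smith–Waterman over a padded window (match +1,
mismatch −2, gap of length $k$ costs $5 + 2k$). Words occurring more
than 100 times are masked as low-complexity — tandem arrays would
otherwise bury the seed index, and they are the business of the repeat
module. Self-comparison excludes trivial matches structurally: the
identity diagonal is forbidden in the forward DP, and in the
reverse-complement direction mirror seeds are dropped and the
palindromic anti-diagonal (a base pairing with its own complement) is
forbidden, so an inverted duplication is reported once as a pair of
distinct loci. Hits are canonically ordered (query interval starts
first) to suppress mirror duplicates.

E-values are Karlin–Altschul, $E = K m n e^{-\lambda S}$, with the
closed-form ungapped $\lambda = \ln\!\big((3+\sqrt{21})/2\big)$ for the
+1/−2 scheme and the standard $K$ for that scheme; the gapped correction
is not re-derived (constants are configurable). These E-values rank hits
and set cutoffs; they are not calibrated against any particular BLAST
build.

Intron–intron homology calls require a hit at E ≤ 1e-10 whose two
intervals each overlap a distinct intron by ≥ 50% of the hit span (the
overlap rule is a package choice; no published convention exists).
Twintron detection is purely coordinate-based — an intron strictly
inside another intron — with partial overlaps rejected as annotation
inconsistencies. Calls are named by the nomenclature: the outer
insertion site is the count of host-gene exon bases 5′ of the intron,
the inner site the count of outer-intron bases 5′ of the inner intron,
both computed strand-aware from the annotation.

# The IEP similarity network

Nodes are protein sequences (IEPs); every pair is aligned with local
Smith–Waterman under BLOSUM62 (gap open 10, extend 1), identity is
computed over aligned columns, and an edge is kept at E ≤ 1e-5 and
identity ≥ 20% — deliberately permissive thresholds, as appropriate for
tracing deep homology of mobile-element proteins. The E-value search
space uses the query length times the total residue count of the node
set, in the spirit of an all-vs-all database search; reciprocal-best-hit
filtering is not applied. Components, degrees and hubs come from the
graph; layout is left to external viewers via GraphML export. The
pairwise aligner here is Biostrings' Smith–Waterman; the package's own
DP implementation is reserved for the nucleotide modules and is checked
against Biostrings as an independent oracle in the tests.

# The synthetic mitogenome generator

`sim_config()` defaults define the study conditions used throughout the
tests and the acceptance script: a 40 kb circular genome at GC 25%
(scaled down from the 56–132 kb genomes that motivate the package, to
keep a 20-genome recovery battery fast on one CPU); five coding genes
(cox1, cob, atp6, atp9, nad5; two RNAs rnl/rns and six tRNAs, mixed
strands) carrying eight group II introns totalling 13.5 kb — including
one twintron (an inner intron nested 1767 bp into a cox1 intron) and
one intron planted as a 95%-identity copy of another (the
self-proliferation signature); four intronic ORFs, stop-free under
translation table 4 (TGA = Trp) with AT-rich codon usage so they do not
distort genome GC; an 11 kb LIR carrying ten perfect tandem-repeat
arrays with unit sizes 6–450 bp and ≥ 3 copies (covering all five
unit-length bins); and a compositional switch of amplitude 0.3 between
a replication origin planted mid-LIR and a terminus diametrically
opposite.

Generation is deterministic given the seed, with draws in a fixed
order: intergenic spacer widths, the background sequence (per-position
G/C bias by replication arc), repeat units (drawn with the composition
of their arc, then planted verbatim), ORF codon streams, the intron
copy (mutated at 5%), then GT/AG termini. The truth table records every
planted element, and the emitted GenBank re-read through `read_genbank`
reproduces the truth coordinates exactly — that round trip is itself a
test.

What the generator does *not* emulate, and hence what passing recovery
tests cannot show: group II intron RNA secondary structure (intron
interiors are random sequence apart from termini and ORFs), realistic
codon usage and amino-acid composition, sequence decay gradients,
annotation errors, or diverged repeat arrays (planted copies are
perfect; the mismatch-tolerant scorer is exercised on constructed
examples instead). Recovery on these genomes demonstrates correctness
of the measurement machinery, not performance on hard biological
instances.

# Problem sizes and runtime conventions

The default test and acceptance runs use 40 kb genomes, 20 seeds for
recovery statistics, exhaustive oracle comparisons on strings ≤ 20 bp
(all binary strings of length 7–8, plus sampled 4-letter strings), and
Smith–Waterman oracle checks on instances ≤ 200 bp. These sizes were
chosen so the whole battery runs in minutes on a single CPU while every
detector still faces a full-architecture genome.

# Known limitations

* The GenBank parser covers the subset of the format used by organelle
  records (LOCUS/FEATURES/ORIGIN, join/complement, standard
  qualifiers); exotic location operators (`order` with gaps between
  records, remote accessions) are out of scope.
* Seed-and-extend self-alignment requires an exact 11-mer in a
  duplication; heavily diverged copies below ~80% identity may be
  missed — at the E ≤ 1e-10 working cutoff such pairs would rarely
  qualify anyway.
* Karlin–Altschul constants are scheme-level defaults, not re-estimated
  for gapped alignment; E-values should be read as ranks and cutoffs.
* The cumulative-skew origin call assumes a single origin/terminus pair;
  multi-origin or recombination-driven replication produces "no
  distinct peak" calls rather than multiple predictions.
* LIR boundaries (and everything derived from them) depend on the
  annotation's notion of where genes end.
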