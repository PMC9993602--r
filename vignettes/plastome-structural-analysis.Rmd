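---
title: "Structural analysis of plastomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural analysis of plastomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what plastomeKit computes, why the defaults are
what they are, and what the synthetic fixtures do and do not demonstrate
about real data.

# Coordinates and containers

Sequences are `Biostrings::DNAString`s restricted to A/C/G/T/N;
ambiguity codes beyond N are rejected at input, because degenerate bases
in an assembled organelle genome indicate an assembly problem rather
than information worth propagating. All coordinates are 1-based and
closed — the Bioconductor convention shared by `GRanges`, GFF3 and
GenBank — so file coordinates pass through unchanged. On a circular
genome an interval may run past the sequence end (`end > length`,
positions taken modulo the length) or be written with `end < start`;
`extractInterval()` resolves both by doubling, and a property test
checks it against an independent doubled-string slicing oracle. The
input FASTA's first base is offset 1 and all outputs report that frame
unless a function is documented to re-origin (only `stripSecondIR()`
does, to the LSC start, so that IR-reduced genomes share an origin for
synteny).

# Inverted-repeat detection and the quadripartite partition

The IR pair of an assembled plastome consists of two near-perfect
reverse-complementary copies, so detection is exact by default
(`maxMismatchRate = 0`). The algorithm seeds on k-mers shared between
the sequence and its reverse complement (k = 31, lowered to `minIrLen`
when that is smaller) and merges collinear seed runs per diagonal. An
exact match of length M contributes a seed at every one of its M−k+1
offsets, so the merged run *is* the maximal match — no extension step
and no missed bases. The reported IR length is therefore the exact
common core of the two arms. With a positive mismatch rate, runs on one
anti-diagonal are bridged when the bridged bases keep the arm-wide
mismatch fraction within the rate.

Among candidate pairs the longest wins; ties break to the smallest
start offset. The longer inter-arm arc is labelled LSC, the shorter
SSC (`len(lsc) >= len(ssc)` is an invariant), and in the canonical
reading LSC→IRb→SSC→IRa the arm whose downstream junction abuts the SSC
is IRb. Genomes with no pair ≥ `minIrLen` (default 100 bp) are
`ir_free`, with the whole circle reported as LSC; arms below the
residual threshold (default 2,000 bp, the depletion regime of heavily
contracted IRs) are `residual_ir`. Both thresholds are arguments.
Detection runs on the linear string and retries once in a rotated frame
when the best pair touches the sequence boundary *and* is circularly
extendable — the only case where the origin can truncate an arm.

Junction positions are defined as the last base of the upstream region;
a gene covering both that base and the next spans the junction, a gene
ending exactly there is "nearest at distance 0". Boundary comparison
between genomes uses set semantics: a gene counts as IR-resident when
wholly contained in an arm, gains/losses are attributed to the LSC-side
junctions (JLB/JLA) or SSC-side junctions (JSB/JSA) according to where
the gene sits in the genome in which it is single-copy; both junctions
of a side move together because the two IR copies are identical.

# Repeat cataloguing

The repeat finder reports every maximal exact repeated pair of length
≥ 30 bp (the conventional minimum for nonredundant organelle repeat
units), direct and inverted, with non-overlapping copies —
self-overlapping diagonal runs are tandem-like and excluded, as the
analysis targets dispersed repeats. The same seed-and-merge machinery
as IR detection is used with k = minimum length, which again yields
maximal extents without an extension step. Nonredundancy follows from
maximality: a short copy inside a longer repeated region is absorbed
into the longer maximal match. Units are distinct canonical sequences
(lexicographic minimum of a copy and its reverse complement);
`+`/`-` strands mark copies equal to the representative or its reverse
complement. The unit-versus-copy distinction is deliberately exposed
(`repeatUnits()` vs `repeatCopies()`), since published counts are
ambiguous between the two.

Against this contract the test suite runs a quadratic brute-force
oracle — positionwise equality run-length encoded along every diagonal
of the sequence against itself and against its reverse complement — on
dozens of planted fixtures up to 5 kb, requiring exact set equality of
the maximal pairs.

Localization is strand-aware: a copy overlapping a gene is internal
(ties to the larger overlap, then the lexicographically smaller name);
otherwise the nearest gene within the context window (default 1,000 bp,
a choice — "upstream" has no conventional cutoff — exposed as
`upstreamWindow`) gives upstream/downstream by which gene side faces
the copy; equal distances tie to the smaller gene name. Hotspot
percentages divide focal-context copies per gene by *all* copies in the
pooled input, reported to two decimals.

# Seeded local alignment and gene classification

Gene presence is decided by local alignment under the classical BLASTn
nucleotide parameterization: reward +2, mismatch −3, gap open 5, gap
extend 2 (a gap of length L costs 5 + 2L), word size 9, E-value cutoff
1e−5, no low-complexity masking. E-values use the Karlin–Altschul form
`E = K·m·n·exp(−λS)` with the published constants for (2, −3):
λ = 0.625, K = 0.41. The aligner seeds on exact 9-mers on both strands,
extends seed runs ungapped with an X-drop (default 16), discards runs
whose ungapped score stays below 28 (a noise filter that cannot drop a
genuine gene-scale homology, which always contains long exact
stretches), clusters surviving runs, and runs a full affine-gap local
dynamic program (Gotoh, implemented in C++ with origin and match-count
propagation, O(n) memory) of the query against a window padded by the
query length around each cluster. Within a window the result is the
optimal local alignment, so on pairs whose homology contains
seed-length exact stretches the top hit equals full Smith–Waterman —
asserted in the tests against `Biostrings::pairwiseAlignment()` on a
hundred randomized pairs per run. Circular targets are doubled and hits
deduplicated modulo the length.

Classification by query coverage of the best locus: ≥ 0.90 intact
(protein-coding genes additionally need an in-frame translation without
internal stop, frame taken from the hit's query offset; RNA-editing
rescue is not modelled); ≥ 0.20 pseudogene (truncated); below that,
fragment; no hit, absent. The 0.90/0.20 thresholds make "partial
sequence" and "remnant fragment" operational and are arguments. Copy
number counts disjoint loci with coverage ≥ 0.20, so IR-borne genes
count twice; a fragment's single locus still counts as one, keeping
"absent ⇔ zero copies". Intron loss is read from exon-hit spacing:
consecutive exons separated by fewer than 30 bp on the target (the
`junctionGap`) have lost the intervening intron.

# Synteny blocks and structural types

Rearrangement typing needs only block order and orientation, so blocks
are built by unique-anchor chaining rather than a full aligner: k-mers
(k = 21) occurring exactly once in each genome, with unambiguous
orientation, are sorted along the reference and chained while
consecutive anchors keep one orientation and advance consistently with
gaps ≤ 2,000 bp on both genomes; chains spanning ≥ 500 bp become
blocks. This is adequate at plastome-scale divergence; it is not a
locally-collinear-block aligner and block granularity is
breakpoint-driven, so type labels are meaningful only against a common
reference, which is also why genome ids are sorted before labelling.
Signed permutations are canonicalized by rotating block 1 to the front;
the breakpoint distance counts adjacencies (with circular closure) that
are not consecutive-and-consistently-signed in the identity, under an
orientation-symmetric convention in which whole-genome reversal has
distance 0.

# Isomer detection from long reads

Recombination between two inverted repeat copies reverses the segment
between their inner edges; the repeats themselves are regenerated
identically, which is why the construction is an involution and why the
two configurations' junction windows share the repeat core and the
outer flank and differ in exactly the inner flank. A window is the
repeat copy plus 1,000 bp flanks; a read supports a window when its
best local alignment (either strand; same 2/−3/5/2 scoring; identity
≥ 0.8 by default, tolerant of noisy long reads) covers the entire core
and at least the required flank on both sides. Reads are screened with
shared 21-mers required in *both* flanks before any alignment, so reads
that merely touch the repeat core are rejected cheaply. Each read is
assigned to at most one isomer by best supported-window score; ties
across isomers count for neither. The frequency estimate is
`100·mean2/(mean1+mean2)` over each isomer's two windows, reported with
the raw per-window counts because the averaging convention is a choice,
not a given.

A note on precision: only reads long enough to cover a full window and
positioned over a junction are informative. With 10,000 reads of
5–15 kb on a 100 kb circle roughly 1,400–1,500 reads are counted, so a
1% mixture is estimated with a binomial standard error near 0.26
percentage points; the tests therefore check recovery within three
binomial standard errors *at the counted depth*, not at the nominal
read count. The paired-short-read check is deliberately coarse — it
asks only whether at least `minPairs` (default 3) pairs straddle a
junction in a configuration-specific way, the qualitative
"both configurations are present" statement short reads can support.

# The synthetic generator: what it emulates, what it does not

`generatePlastome()` writes an i.i.d. background at GC 0.365 (the
middle of the observed plastome GC range), places the gene census
region by region with even intergenic spacing, plants genes as seeded
random ORFs (start codon, stop-free interior, terminal stop, base
composition matched to the background) or random segments for
tRNA/rRNA, applies the pseudogene plan (truncation to a fraction,
mid-gene stop codon, 10% fragment, deletion), plants repeat copies and
isomer arms, and copies IRb into IRa as its exact reverse complement,
mirroring IR genes as second copies. Because "recovered at exact
coordinates" is only well defined if the planted extent is the maximal
extent, the generator blocks single-base chance extension at the edges
of every planted repeated element by adjusting one unprotected flanking
base, iterated to a fixed point; this never touches gene interiors.
Generation is fully deterministic per seed and every planted fact is in
the manifest, which is the oracle for all downstream assertions.

The fixtures reproduce the structural phenomena — IR arms of 0/437/
1,964/10,191/33,169 bp inside genome layouts whose totals match
observed extremes (110,388 and 143,493 bp); all five gene statuses;
fourteen genomes in five rearrangement types; a 679 bp inverted pair
bracketing 60 kb with read mixtures at 0, 1% and 50% — but the
sequences themselves are random. Real plastomes have codon bias,
homopolymers, nearly identical gene families and AT-rich intergenic
spacers; real ONT reads have homopolymer-biased, non-uniform errors.
Passing the suite therefore demonstrates algorithmic correctness under
the stated contracts, not robustness to every artefact of real
libraries; the error model (uniform per-base mismatch/indel up to 20%)
bounds, but does not imitate, nanopore behaviour.

Problem sizes in the shipped tests — full-length genomes for IR
recovery (100 fixtures), 10,000 reads for the isomer frequency, 50
oracle fixtures ≤ 5 kb, 100 aligner oracle pairs ≤ 1 kb, 50 planted
inversions of 1–60 kb — were chosen so the whole suite completes in
minutes on one core while keeping every statistical check at a depth
where its tolerance is meaningful.

# Degenerate inputs and edge conventions

Zero-length intervals, non-circular genomes passed to circular-only
operations, flanks that make junction windows overlap, unpaired mate
input, direct (non-inverted) repeat pairs passed to the isomer builder,
and infeasible generator placements are all errors that name the
offending element. Empty feature lists degrade with warnings (junction
contexts without genes, hotspot summaries over zero copies). An empty
read set gives zero counts and an undefined (NA) frequency rather than
0%, since absence of evidence is not an estimate.

# Known limitations

* Mismatch-tolerant IR detection bridges only collinear exact runs; it
  will underreport arms whose copies differ by indels (not observed in
  assembled plastomes, where the arms are effectively identical).
* The premature-stop check assumes the best hit preserves the query
  frame; a pseudogene whose reading frame is destroyed by indels is
  still called (as truncated or premature-stop) but the stop position
  is not meaningful.
* Synteny blocks require unique anchors, so extremely repeat-dense
  regions contribute no anchors and can split blocks; block counts are
  granularity-dependent and only order/orientation patterns should be
  compared across runs.
* The isomer frequency is estimated from junction-spanning reads only;
  its precision is set by the counted depth, not the sequenced depth.
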