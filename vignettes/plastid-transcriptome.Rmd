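---
title: "Plastome structure and transcriptome profiling with plastex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plastome structure and transcriptome profiling with plastex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastex)
```

plastex implements the chain of computations behind a typical chloroplast
genome-and-transcriptome characterisation: quadripartite structure
detection, gene/intron/codon accounting, a maximal-repeat survey,
mismatch-bounded read mapping with pileups, FPKM expression profiling,
RNA-editing calling with per-site conversion efficiency and codon impact,
and small-RNA footprint discovery. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic-data
generator does and does not emulate.

Coordinates are 1-based inclusive throughout, matching the convention of
published plastome tables; conversion to 0-based half-open happens only at
the BED boundary, and GFF3 shares the 1-based convention natively.

## Quadripartite structure

A land-plant plastome is a circular molecule organised as
LSC + IRb + SSC + IRa, where IRa is the exact reverse complement of IRb.
`detect_quadripartite()` searches for the longest pair of disjoint,
reverse-complementary, *maximal* segments (extendable at neither end) of
length at least `min_ir_length` (default 1000 bp; real plastid IRs are
10--30 kb, so the default only guards against spurious short palindromes).
The two segments are the IR copies; the longer of the two single-copy
segments between them is the LSC. The partition is reported in canonical
orientation (LSC first); if the input coordinates place the LSC across the
origin, the genome is conceptually rotated and the offset reported as
`rotation_offset`, so callers can map positions back.

Failure modes are explicit: no qualifying pair raises
`no_inverted_repeat`; two distinct candidate pairs tying in length raise
`ambiguous_structure` rather than picking one arbitrarily.

The search itself is seed-and-extend: exact k-mer matches between the
sequence and its reverse complement seed maximal-run extensions, with one
extension per diagonal run. Every maximal pair of length ≥ k contains a
seed, so the enumeration is exact; the brute-force diagonal scan retained
in the test suite is the independent oracle.

## Gene models and codon usage

Gene models are tibble rows with an exon list-column (`start`, `end`,
`strand`, `part`), supporting multi-exon genes, IR-duplicated records
(linked by `ir_copy_of`), and trans-spliced genes whose parts may lie on
different strands. Two structural rules follow the field's table
conventions:

* an intron is a gap between consecutive exons *of the same transcript
  part*; the junction between the parts of a trans-spliced gene (rps12 in
  grasses) is never an intron;
* unique-gene accounting counts each `ir_copy_of`-linked record once, so a
  plastome with 12 IR-duplicated protein-coding genes still reports 81
  unique CDS.

Codon usage (`codon_usage()`) extracts every complete codon of every
unique, non-pseudo CDS — minus-strand genes reverse-complemented,
trans-spliced parts concatenated in part order — and aggregates amino
acids under NCBI translation table 11 (the bacterial/plastid code), the
correct code for plastid CDS. A coding length that is not a multiple of 3
is truncated with a warning rather than an error, since published
annotations contain such records; codons containing N are skipped with a
warning. Percentages in `amino_acid_totals()` are computed from the
table's own total: published codon tables sometimes print percentages
inconsistent with their own stated totals, and we make no attempt to
reproduce arithmetic that cannot be reconstructed.

## Repeat survey

`find_maximal_repeats()` enumerates maximal repeated pairs in three
orientations — forward (F), palindromic (P, second copy
reverse-complemented) and reverse (R, reversed but not complemented) —
and filters by length (default ≥ 20 bp) and by an expectation statistic

\[ E(l, n) = \frac{(n-l+1)(n-l)}{2} \cdot 4^{-l}, \]

the expected number of matching pairs of distinct length-$l$ windows in an
i.i.d. uniform length-$n$ sequence, per orientation. This is the package's
own significance measure, chosen because it is transparent and monotone in
$l$; it is *not* claimed to replicate the internal statistic of any
external repeat finder, so absolute repeat counts from different tools are
not comparable at the same nominal threshold. The default cut-off
`max_e_value = 1e-3` keeps hits that are about a thousand-fold rarer than
chance.

Because the two IR copies of a quadripartite genome are themselves one
giant palindromic repeat, hits lying inside that IR-vs-IR self-match are
suppressed by default when a partition is supplied (they describe the
genome architecture, not dispersed repeats); `include_ir_match = TRUE`
restores them. Complement-only (complemented but not reversed) repeats are
not searched. Location classes (`CDS`, `intron`, `intergenic`) are
assigned by majority overlap of the first copy, ties resolving in that
priority order.

## Read mapping and pileups

`map_reads()` is an exhaustive ungapped mapper: every placement of the
read on both strands is scored by Hamming distance, placements above
`max_mismatch` (default 2, matching common short-read practice for
organelle remapping) are discarded, and only the equally-best placements
are kept — all of them when `report_multi = TRUE` (the default), so that
downstream counting owns the multi-mapping policy. N in read or genome
counts as a mismatch. Circular genomes admit origin-wrapping placements.
Exhaustive search means no seeding heuristic can miss a placement; the
price is speed, which is acceptable because the package targets
organelle-sized references (a plastome is ~10^5 bp). Exact matching is
internally batched through an Aho–Corasick dictionary; identical read
sequences (abundant in small-RNA stacks) are scanned once.

Ungapped alignment is a deliberate scope decision: the downstream analyses
(editing, expression, small RNAs) use substitution-level evidence only,
and indel or spliced alignment would add complexity the statistics never
consume. Reads from spliced transcripts crossing an intron junction do
not map; in practice plastid RNA-seq contains abundant unspliced precursor
coverage, and the simulator places fragments within single exons.

`build_pileup()` tallies per-position, per-strand base counts with
minus-strand bases complemented into forward-strand identity, so a column
is always read in reference space; `pileup_totals()` collapses strands for
unstranded libraries.

## Expression profiling

Fragments (mate pairs collapsed by read-id stem, placements clustered
within 1 kb so IR-duplicated placements stay distinct) are assigned to a
gene when the placement midpoint lies in an exon. Midpoint assignment
avoids double-counting at gene boundaries and is cheap to reason about;
it is the default rather than any-overlap. The multi-mapping default
(`"all"`) counts a multi-placed fragment once per gene hit, which mirrors
how published plastome expression tables list both IR copies of a
duplicated gene with (near-)equal values; `"primary"` keeps only the
lowest-coordinate placement, guaranteeing the counts sum to at most the
library size.

FPKM uses the exonic (spliced) gene length and normalises against all
plastome-mapped fragments — not only in-gene fragments — so intergenic
coverage dilutes every gene equally.

## RNA editing

A site is called where the RNA pileup contradicts the DNA reference:
coverage ≥ `min_coverage` (default 5) and most-frequent non-reference
base ≥ `min_alt_fraction` (default 0.1) of all observed bases. The
defaults are deliberately permissive because published editing tables
include sites supported by as few as 2 reads and conversion rates down to
~16%; both thresholds are exposed. Ties between alternate bases break
lexicographically for determinism.

Editing efficiency is
`100 · alt_count / (sum of all base counts at the site)` — the denominator
is every observed base, not ref + alt only, so a third base at the site
lowers both shares; this matches how published per-site percentages are
computed when three bases are listed. Values are rounded to one decimal,
the precision of the tables they are compared against.

Bases, codons and conversions are reported in transcript orientation
(RNA alphabet, e.g. "C-to-U"), complementing through minus-strand genes.
Codon impact reads the reference codon through the exon structure,
substitutes the edited base at offset `((p−1) mod 3)+1` of codon
`⌈p/3⌉`, and translates both codons with table 11; stops are labelled
`stop`. Sites outside annotated genes are reported as `intergenic` with
empty codon fields (the UTR case), and `annotate_codon_change()` refuses
non-CDS sites explicitly. The reference is assumed haploid and
homogeneous (an organelle consensus); DNA-level heterogeneity is out of
scope, though `confirm_predictions()` supports intersecting called sites
with an external prediction list.

## Small-RNA footprints

Protein-protected small-RNA footprints appear as stacks of 20–24 nt reads
with a shared core sequence; RNA degradation of abundant transcripts
instead produces longer fragments. `size_stratified_coverage()` maps both
size classes with zero mismatches (published footprint catalogues use
100% identity mapping; multi-mapped reads contribute to every placement so
IR loci are visible in both copies), and `call_srna_loci()` keeps maximal
runs where

* short coverage ≥ `min_reads` (default 20 — of the order of the
  weakest loci in published catalogues), and
* `short / (long + 1) ≥ enrichment_ratio` (default 5; the +1 pseudo-count
  tolerates zero long-read background),

merging runs separated by fewer than `merge_gap` (default 10) bases. The
core sequence is the most abundant unique supporting read, ties breaking
lexicographically; locus strand is the majority read strand.

Location classes use the locus midpoint: exon → `CDS`, intron →
`intron`, otherwise intergenic, sub-classified `intergenic_5prime` when
within −150/+50 bp of a same-strand start codon (the window in which most
published plastid sRNAs cluster), `intergenic_3prime` within 100 bp of a
stop codon, else `intergenic_other`; the 5′ window takes precedence.
Ortholog matching scores unit-cost global alignment identity
(matches / alignment length, gaps included) with a 0.90 default threshold.

## Synthetic data: what it emulates and what it does not

The generator produces the study conditions every recovery test runs
under:

* `make_plastome(lsc, ssc, ir, gc = 0.38, seed)` — i.i.d. bases at the
  target GC (0.38 is typical for grass plastomes), assembled as
  LSC + IR + SSC + revcomp(IR). The generator deterministically adjusts
  one flanking base per single-copy segment when it would extend the
  planted IR match by chance, so the planted boundaries are exactly the
  maximal pair the detector must find.
* `plant_genes()` — non-overlapping CDS slots in the single-copy regions,
  optional two-exon intron genes, IR duplicates mirrored into IRa on the
  opposite strand, and one optional two-part trans-spliced gene. CDS
  lengths are multiples of 3.
* `simulate_rnaseq()` — fragments per gene proportional to
  rate × length, fixed fragment length (default 300 bp; a distribution
  would add variance the FPKM and editing statistics do not need), paired
  100 nt reads from the fragment ends, per-fragment editing decisions
  (both mates agree, as they would for one molecule), and uniform
  substitution errors (default 0.1%) with constant quality strings.
* `simulate_srna()` — per footprint, `depth` reads of 20–24 nt sharing
  the core with ±2 nt end jitter (the exact core is the most common
  form); background 31–35 nt fragments tiled over given intervals.

Deliberately not emulated: realistic Illumina error/quality profiles,
indels, spliced reads, nuclear contamination, DNA-level polymorphism, and
SRA-scale library sizes. Passing recovery tests therefore demonstrate the
*estimators* are correct under clean, known-truth conditions; they do not
certify behaviour on full-scale noisy libraries, where read-level
artefacts and reference errors dominate.

Every generator takes an explicit integer seed and is byte-deterministic
given it, restoring the caller's RNG state afterwards.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale, chosen so the
statistical checks are well-powered without being wasteful: synthetic
genomes of 4–30 kb; 20 seeded genomes for boundary recovery; repeat-finder
vs oracle cross-checks on sequences up to 3,000 nt; FPKM recovery at 50×
mean coverage over six 3 kb genes with a modest (two-fold) abundance
spread and 200 bp fragments, giving several hundred fragments per gene so
the 10% recovery tolerance sits at ≈2.5 binomial standard deviations;
editing recovery at ~300× site coverage with planted efficiencies of 0.5,
0.9 and 0.97 checked against exact 99% binomial intervals; three planted
small-RNA footprints at depths 80–120 over gene-body background.

Other numerical conventions: efficiency percentages round half-even to one
decimal (R's `round`); alternate-base and core-sequence ties break
lexicographically; equally-best placements order by start then strand;
`region_partition()` rejects empty regions and unequal IR copies;
`gc_content()` excludes N from the denominator and errors on windows with
no informative base.

## Limitations

* The E-value filter is a uniform-composition expectation; repeat counts
  at a fixed threshold are not comparable across tools with different
  statistics.
* The mapper is ungapped and quality-blind; it is not a general-purpose
  aligner and is not meant to scale past organelle-sized references.
* Editing calls assume a correct, haploid DNA reference; systematic
  reference errors masquerade as 100% "editing".
* The locus caller's thresholds describe footprint-like enrichment; they
  are heuristics to be tuned per library depth, not a statistical test
  with a controlled error rate.
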