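# plastex

Desk-scale analysis of chloroplast (plastid) genomes and their
transcriptomes in R. The package is aimed at organelle-genomics
practitioners who want the complete chain of computations behind a typical
plastome characterisation — genome structure, gene content, codon usage,
repeats, expression, RNA editing and small RNAs — as tested, scriptable
functions rather than a collection of one-off web tools, together with a
seeded simulator so every stage can be validated against known ground
truth. It ships the published reference tables for the *Deschampsia
antarctica* (Antarctic hairgrass) plastome, GenBank accession KF887484, as
worked inputs.

## What it computes

* **Quadripartite structure.** Land-plant plastomes are circular molecules
  organised as a large and a small single-copy region (LSC, SSC) separated
  by two identical inverted repeats (IRa, IRb).
  `detect_quadripartite()` finds the longest pair of disjoint, exactly
  reverse-complementary maximal segments and reports the induced partition
  in canonical orientation, so that
  `|LSC| + |SSC| + 2·|IR| = |genome|`.
* **Gene, intron and codon accounting.** Gene models are tibbles with exon
  list-columns supporting multi-exon, IR-duplicated and trans-spliced
  genes. Codon usage counts every complete codon of every unique CDS once,
  under the plastid genetic code (NCBI translation table 11).
* **Repeat survey.** All maximal repeated pairs in forward (F),
  palindromic (P = reverse complement) and reverse (R) orientations, with
  the expectation filter `E(l, n) = (n−l+1)(n−l)/2 · 4^(−l)` (expected
  count of matching window pairs in an i.i.d. uniform sequence) and
  annotation-aware location classes.
* **Read mapping and expression.** An exhaustive mismatch-bounded ungapped
  mapper (every placement on both strands scored by Hamming distance;
  circular wrap supported) feeds fragment counting by exon midpoint and
  `FPKM = count / ((L/10³)·(N/10⁶))`, with `L` the exonic gene length and
  `N` the plastome-mapped fragment total.
* **RNA editing.** Sites are called where the RNA pileup contradicts the
  DNA reference; per-site editing efficiency is the percentage of reads
  carrying the alternate base among **all** reads observed at the site,
  reported in transcript orientation (RNA alphabet) with codon and
  amino-acid impact.
* **Small-RNA footprints.** Loci where 20–24 nt reads (candidate
  protein-protected fragments, e.g. PPR footprints) stack up against a
  background of >30 nt degradation fragments:
  `short ≥ min_reads` and `short/(long+1) ≥ enrichment`, merged runs,
  most-abundant-read core sequences, 5′/3′ proximity classes, and
  ortholog matching by global-alignment identity.
* **Simulation.** `make_plastome()`, `plant_genes()`, `simulate_rnaseq()`
  (planted editing sites with chosen efficiencies) and `simulate_srna()`
  (planted footprints over a long-fragment background), all deterministic
  per seed and returning their ground truth.

## Worked example

Simulate a plastome with planted genes and one planted editing site, then
run the structure, mapping, editing and expression stages:

```r
library(plastex)

sim   <- make_plastome(lsc_len = 8000, ssc_len = 1500, ir_len = 1200, seed = 7)
genes <- plant_genes(sim$genome, sim$partition, n_genes = 6, n_intron_genes = 2,
                     n_ir_duplicates = 1, include_trans_spliced = TRUE, seed = 8)

glance(detect_quadripartite(sim$genome, min_ir_length = 500))
#>   genome_id        genome_length lsc_length ssc_length ir_length rotation_offset
#> 1 synthetic_plast…         11900       8000       1500      1200               0

pos <- genes$exons[[4]]$start[1] + 40L   # plant an edit inside gene sg04
rs  <- simulate_rnaseq(sim$genome, genes,
                       editing_sites = tibble::tibble(position = pos, alt = "C",
                                                      efficiency = 0.85),
                       n_fragments = 1000, error_rate = 0.001, seed = 9)
al    <- map_reads(rs$reads, sim$genome, max_mismatch = 2)
pile  <- build_pileup(al, rs$reads, sim$genome)
call_editing_sites(pile, sim$genome, genes)
#>   conversion efficiency n_A n_C n_G n_U codon_ref codon_alt aa_ref aa_alt
#> 1     U-to-G       83.3   0   0  75  15       CUU       CGU    Leu    Arg
```

The planted site sits in a minus-strand gene, so the genome-strand A→C
substitution is reported as U-to-G in transcript space: 75 of 90 reads
(83.3%) carry the edited base, close to the planted 85% efficiency, and the
edit changes codon CUU to CGU (Leu→Arg). Expression profiling on the same
alignments shows the IR-duplicated gene pair receiving identical FPKM, as
multi-mapped fragments count in both copies:

```r
head(tibble::as_tibble(expression_profile(al, genes)), 4)
#>   gene     start   end coding_length fragment_count    fpkm
#> 1 ir01      8061  8360           300             98 326667.
#> 2 ir01_ira 11541 11840           300             98 326667.
#> 3 sg03      1621  1920           300             98 326667.
#> 4 sg01        61   720           600            184 306667.
```

The bundled reference tables reproduce the published accounting for the
KF887484 plastome, e.g.:

```r
aa <- amino_acid_totals(codon_usage_from_counts(reference_table("codon_usage")))
aa$count[aa$amino_acid == "Leu"]   # 2466 — the most used amino acid
editing_efficiency(c(U = 11, C = 27), "C", "U")   # 28.9 (matK site 1258)
```

See the methods vignette (`vignettes/plastid-transcriptome.Rmd`) for the
models, parameter defaults and design decisions.

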