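---
title: "Organelle genome nucleotide landscapes, repeats and phylogenomic pruning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Organelle genome nucleotide landscapes, repeats and phylogenomic pruning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Most mitochondrial and plastid genomes are strongly biased towards A and T.
The rare GC-rich exceptions — notably among trebouxiophyte green algae —
are informative about the forces shaping organelle nucleotide composition:
if GC content is highest at the *least* constrained sites (intergenic
spacers, third codon positions, repeat elements), the enrichment is better
explained by nonadaptive processes (mutation pressure, biased gene
conversion) than by selection.  Making that argument quantitative requires
a consistent set of statistics over an annotated genome: GC content by
region class, GC by codon position, strand skew, the noncoding fraction,
repeat content, and — because these genomes also feed multi-gene
phylogenies — a reproducible path from per-gene alignments to a filtered
supermatrix and a rate-based taxon-pruning step.

`gclandscape` implements that pipeline end to end: GenBank in, one
landscape-report row per genome out, plus exact repeat discovery within
and between genomes, supermatrix assembly, and root-to-tip pruning.  A
seeded generator produces annotated genomes with *known* landscape
parameters so every stage can be validated against ground truth without
any downloads.

## Region classes and their precedence

Every genome position is assigned to exactly one of five classes:

* `protein_coding` — exonic CDS positions;
* `structural_rna` — rRNA and tRNA gene bodies (pooled, because
  comparative tables report one "structural RNA" number);
* `intron` — annotated introns, plus gaps between consecutive exons of a
  multi-exon gene when no explicit intron feature exists
  (`derive_introns = TRUE`);
* `unclassified_orf` — ORFs with no assigned identity: CDS features whose
  gene/product qualifiers look like `orf…`/"hypothetical", and any CDS
  nested inside an annotated intron;
* `intergenic` — the complement.

When annotations overlap, precedence is `protein_coding > structural_rna >
intron > unclassified_orf > intergenic`.  Coding assignment must win for
the coding/intergenic GC split to be well defined; the rest follows the
same "more specific first" logic.  The partition is validated to be
exhaustive: per-class lengths always sum exactly to the genome length.

Two conventions follow the comparative-table tradition: the *noncoding
fraction* is `1 − (protein_coding + structural_rna)/L`, so introns and
unclassified ORFs count as noncoding; and "coding" GC pools protein and
structural-RNA positions (a protein-only variant is available via
`coding_protein_only = TRUE`).

## GC statistics

All GC statistics use the unambiguous alphabet only: `N` and other IUPAC
ambiguity codes are excluded from numerator and denominator, and an empty
denominator yields `NA`, never zero.

* `gc_fraction`: (G+C)/(A+C+G+T).
* `gc_skew`: (G−C)/(G+C) on the deposited strand.  The sign depends on an
  arbitrary strand choice, so comparisons should use the magnitude;
  `gc_skew(revcomp(s)) == -gc_skew(s)` is asserted as a property.
* GC1/GC2/GC3: codon positions are assigned in translation order across
  exon junctions, strand-aware (minus-strand genes are phased along the
  reverse complement); all genes are pooled into one concatenate rather
  than averaged per gene, because published tables report a single value
  per genome and pooling makes the site counts well defined.  The
  terminal stop codon is excluded by default (`include_stop` flips this;
  published tables rarely say which convention they used, so the
  published-value check tries both).  CDSs whose length is not a
  multiple of 3 contribute complete codons only, with a warning.
* Amino-acid composition: standard genetic code, stops excluded,
  frequencies over the 20 amino acids summing to 1.  Internal stops
  warn (with the gene name) and are skipped.

Useful identities that double as tests: total GC is the length-weighted
mean of per-class GC, and the mean of GC1/GC2/GC3 equals GC over all
coding sites when all CDSs are complete.

## Repeat discovery

`find_maximal_repeats()` reports every *maximal* exact repeated pair —
direct (identical copies) or inverted (exact reverse complements) — of
length at least `min_len`.  Maximal means extending both copies one
position left or right breaks the match.

The implementation seeds on shared `min_len`-mers and extends. Seeds are
*left-locked*: a seed is kept only when the characters immediately left
of both copies differ, so each maximal pair is seeded exactly once (at
its leftmost shared k-mer) and recovered in full by rightward extension.
Ambiguity codes are encoded as per-position unique sentinels, so a match
can never run through an `N`.  Correctness is defined solely by a
brute-force oracle — for every diagonal offset, compare the sequence
against a shifted copy of itself (forward) or of its reverse complement
(inverted) and read maximal runs of equality — and the test suite checks
hit-for-hit equality on hundreds of random sequences at alphabet sizes 2
and 4.

Numerical/parameter choices:

* `min_len` defaults to 20 within a genome (the shortest repeats of
  interest in GC-rich organelle genomes) and 30 between genomes, where
  chance matches between ~100-kb sequences must be suppressed; values
  below 8 are refused because near-trivial matches make the pair count
  explode quadratically.
* Circular topology is honoured by analysing the sequence plus a wrap
  extension (300 nt beyond `min_len`, comfortably above the longest
  repeats these genomes carry), mapping hits back modulo the genome
  length, deduplicating, and discarding truncated origin images — a
  shorter pair aligned inside a longer one modulo L is extendable across
  the origin, hence not maximal.
* Pairs lying in low-complexity runs (period ≤ 2, length > 50) are
  flagged, not removed.

`repeat_coverage()` is the union length of all copy intervals over the
genome length (overlaps counted once); `shared_repeats()` applies the
same machinery across two genomes and summarises the merged repeat
*sites* per genome plus the total shared length.

## Supermatrix assembly and column filtering

Gene selection uses a taxon-occupancy rule: a gene enters the
concatenation iff it has sequence for at least 70% (configurable) of the
reference taxa.  Concatenation pads missing taxa with all-gap blocks and
tracks per-gene column spans and per-taxon occupancy.

`filter_columns()` implements a conserved-block filter with four
settings: no gapped columns (`allow_gaps = FALSE`), conservation and
flank thresholds defaulting to `floor(T/2) + 1` (the strict-majority
reading of "50% of the number of taxa plus one"), a maximum run of 10
contiguous non-conserved columns, and a minimum block length of 8.
Blocks are found by a single greedy left-to-right scan: gapped columns
break segments, over-long non-conserved runs are cut out, block ends are
trimmed to flank-qualified columns, and short blocks are dropped.  Gaps
never count towards conservation.  This is the simplest reading
consistent with those four settings; no attempt is made to replicate any
particular program's multi-pass heuristics, and the filter is asserted
to be idempotent and order-preserving instead.

## Root-to-tip pruning

`root_on_clade()` places the root on the edge subtending a designated
monophyletic outgroup clade — by default at the edge midpoint.  The
offset along the edge shifts all root-to-tip distances uniformly, so the
*ranking* (the procedure's actual product) is offset-invariant, and the
package asserts that property rather than pretending the split point
matters.  `root_to_tip_distances()` sums branch lengths to each leaf
(checked against a naive parent-pointer oracle to 1e-9) and ranks
descending with alphabetical tie-breaks for determinism.
`remove_fast_taxa()` drops the top-k ranked taxa (with a keep-list for
"all except the slow one" semantics) or an explicit name list, and
suppresses degree-2 nodes so survivor path lengths are unchanged.

## The synthetic-data generator

`generate_genome()` emits an annotated circular genome honouring a
`genome_spec()`.  The default spec is a 65.4-kb mitochondrial-like
genome: 59 genes (26 protein, 3 rRNA, 30 tRNA), five introns with one
intronic ORF, GC1/GC2/GC3 = 51.4/40.8/59.8%, structural-RNA GC 52.5%,
intergenic GC 55.7%, and GC-rich (65%) repeats of 20–250 nt (mean ~100)
covering 7% of the genome; `ptdna_like_spec()` is the 175.7-kb,
115-gene plastid-like counterpart with GC1/GC2/GC3 = 56.1/43.6/50.1%
and intergenic GC 51%.  `generate_genome_pair()` additionally plants
shared repeat blocks across two genomes; the default geometry is five
blocks appearing once each in genome A and eleven times in total in
genome B, ~500 nt of shared sequence.

Design choices worth knowing:

* **Exact-count GC calibration.**  Rather than i.i.d. Bernoulli draws,
  each class receives exactly `round(N_class × target)` G/C bases
  (uniformly G vs C, positions shuffled).  Repeat placements, their
  GC-rich bodies and the engineered flanking bases are planned *first*
  and counted as fixed, and the class background is then calibrated so
  the realized class GC equals the designed target to rounding — even
  though the planted repeats are much more GC-rich than their intergenic
  surroundings.  This makes "designed vs measured" comparisons sharp at
  any class size instead of being limited by binomial noise.
* **Codon pools.**  Codon-position GC is calibrated over all codons
  except terminal stops (matching the measurement convention), with the
  fixed ATG starts counted as fixed contributions.  Internal stop codons
  are repaired by swapping third-position letters between codons, which
  preserves the exact per-position counts.
* **Planted repeats are exactly maximal.**  Every copy of a repeat block
  gets flanking letters that are pairwise distinct across copies (in
  block orientation space), so no planted pair can extend by chance and
  truth coordinates are recovered literally.  At most 3 copies of a
  shared block per genome keeps the four-letter flank budget.
* **Trees and alignments.**  `generate_tree_and_alignments()` simulates
  a birth–death tree, applies mild lognormal rate noise (sd 0.15, kept
  small so that designed rate multipliers dominate the baseline
  root-to-tip spread), and gives each designated fast taxon a terminal
  branch of multiplier × the mean pendant length — a rate relative to
  the average lineage, which stays meaningful even when the taxon's own
  pendant edge happened to be short.  Alignments are presence/absence
  scaffolds: each column is fully conserved with probability
  `conservation` (default 0.6) and independent random residues
  otherwise — enough structure for occupancy, concatenation and
  column-filter logic, deliberately *not* a substitution-model
  simulation.

What passing the synthetic tests does and does not show: the generator
emulates the compositional structure (per-class and per-codon-position
GC, planted exact repeats, controlled occupancy and rate
heterogeneity), not real mutational processes, codon usage, repeat
families, or alignment uncertainty.  Agreement with generator truth
validates the bookkeeping and algorithms; agreement with published
values on the deposited records validates the conventions.

## Problem sizes used by the test suite

The suite validates the repeat finder against the brute-force oracle on
200 random sequences of 0.1–2 kb (both alphabets, both orientations),
recovers designed GC on 20 seeded genomes (eighteen 36-kb and two
175.7-kb genomes, the large ones exercising the ≥ 30-kb classes),
checks root-to-tip distances on 50-taxon random trees, and runs the
full landscape workflow on a 65.4-kb / 175.7-kb genome pair — sizes
chosen to mirror the study conditions while keeping a full run in the
order of a minute.

## Known limitations

* Only exact repeats are found; degenerate/approximate repeats and
  repeat-family clustering are out of scope.
* The GenBank reader covers the feature-table subset these genomes use
  (`CDS`/`rRNA`/`tRNA`/`intron`, `join`/`complement`, origin-spanning
  locations); mixed-strand `join`s are refused.
* Published repeat fractions depend on the original detector's unstated
  parameters, so "~7% repeats" and "~500 nt shared" are
  order-of-magnitude expectations, not exact targets.
* Tree inference, alignment, and RNA-editing analysis are deliberately
  outside the package: trees and alignments are consumed, not inferred.
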